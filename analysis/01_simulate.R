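#!/usr/bin/env Rscript
# Generate the synthetic assay corpora.
#
# Two experiments are simulated with the biased-random-walk generator:
#   (a) "developmental": 3 stages x 3 group sizes x 5 videos = 45 videos.
#       Feeding stages get strong attraction (+0.9); the nonfeeding stage
#       actively avoids (-0.5).
#   (b) "populations": 5 populations of 8 late-feeding larvae with their
#       collection latitudes as covariate, 29/32/19/18/21 videos. All
#       populations share the same attraction (+0.9): the ground truth is
#       "no latitude effect", so downstream tests should find none.
# Tracks and design tables are written under results/tracks/.

suppressPackageStartupMessages(library(larvagg))

out_dir <- "results/tracks"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
scheme <- sampling_scheme() # 90-min videos, 15-s extraction

## developmental-stage experiment -------------------------------------
dev_groups <- list()
for (stage in c("early_feeding", "late_feeding", "nonfeeding")) {
  for (nl in c(2, 5, 8)) {
    dev_groups <- c(dev_groups, list(list(
      label = sprintf("%s_n%d", stage, nl),
      n_videos = 5, n_individuals = nl,
      params = movement_params(
        attraction = if (stage == "nonfeeding") -0.5 else 0.9))))
  }
}
dev <- generate_experiment(experiment_design(dev_groups, scheme = scheme,
                                             seed = 20260901))
write_tracks(dev$tracks, file.path(out_dir, "developmental_tracks.csv"))
write.csv(dev$design_table, file.path(out_dir, "developmental_design.csv"),
          row.names = FALSE, quote = FALSE)
cat(sprintf("developmental corpus: %d videos (%d groups)\n",
            length(dev$tracks), length(dev_groups)))

## population / latitude experiment -----------------------------------
pops <- data.frame(
  label = c("bitely_mi", "grayling_mi", "orange_springs_fl",
            "lexington_ky", "piscataway_nj"),
  n_videos = c(29, 32, 19, 18, 21),
  latitude = c(43.79, 44.66, 29.51, 38.01, 40.55))
pop_groups <- lapply(seq_len(nrow(pops)), function(i) {
  list(label = pops$label[i], n_videos = pops$n_videos[i],
       n_individuals = 8,
       params = movement_params(attraction = 0.9),
       covariate = pops$latitude[i])
})
pop <- generate_experiment(experiment_design(pop_groups, scheme = scheme,
                                             seed = 20260902))
write_tracks(pop$tracks, file.path(out_dir, "population_tracks.csv"))
write.csv(pop$design_table, file.path(out_dir, "population_design.csv"),
          row.names = FALSE, quote = FALSE)
cat(sprintf("population corpus: %d videos across %d populations\n",
            length(pop$tracks), nrow(pops)))
cat("done: tracks and design tables under", out_dir, "\n")
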