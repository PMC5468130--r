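# Shared fixtures and independent oracles, built in code at test time.

# expected distance between two uniform points in a disk of radius r
disk_pair_mean <- function(r) 128 * r / (45 * pi)

# a track where the same positions repeat in every frame
constant_track <- function(positions, n_frames = 30, interval = 180,
                           video_id = "const", arena = larvagg::arena()) {
  coords <- array(rep(as.vector(positions), n_frames),
                  dim = c(nrow(positions), 2L, n_frames))
  video_track(video_id, interval * (seq_len(n_frames) - 1L), coords,
              arena = arena)
}

# a raw-cadence track with independent uniform positions per frame
random_raw_track <- function(n = 4, n_frames = 360, interval = 15,
                             video_id = "raw", arena = larvagg::arena()) {
  pts <- sample_uniform_in_disk(n * n_frames, arena)
  coords <- array(0, dim = c(n, 2L, n_frames))
  coords[, 1L, ] <- pts[, 1L]
  coords[, 2L, ] <- pts[, 2L]
  video_track(video_id, interval * (seq_len(n_frames) - 1L), coords,
              arena = arena)
}

# brute-force oracle: pooled mean pairwise distance over the frames a
# scheme retains, recomputed directly from the raw coordinate array
brute_force_pooled_mean <- function(track, scheme) {
  stride <- scheme$analysis_interval_s / scheme$raw_interval_s
  keep <- seq(1, dim(track$coords)[3], by = stride)
  keep <- keep[-seq_len(scheme$acclimation_frames)]
  if (scheme$acclimation_frames == 0) {
    keep <- seq(1, dim(track$coords)[3], by = stride)
  }
  all_d <- c()
  n <- dim(track$coords)[1]
  for (t in keep) {
    for (i in 1:(n - 1)) {
      for (j in (i + 1):n) {
        all_d <- c(all_d, sqrt(sum((track$coords[i, , t] -
                                      track$coords[j, , t])^2)))
      }
    }
  }
  mean(all_d)
}

# brute-force one-way ANOVA from first principles (sums of squares)
brute_force_anova <- function(values, groups) {
  groups <- as.character(groups)
  gm <- mean(values)
  labs <- unique(groups)
  ss_b <- 0
  ss_w <- 0
  for (g in labs) {
    v <- values[groups == g]
    ss_b <- ss_b + length(v) * (mean(v) - gm)^2
    ss_w <- ss_w + sum((v - mean(v))^2)
  }
  df_b <- length(labs) - 1
  df_w <- length(values) - length(labs)
  F <- (ss_b / df_b) / (ss_w / df_w)
  list(F = F, df_between = df_b, df_within = df_w,
       p = stats::pf(F, df_b, df_w, lower.tail = FALSE),
       SS_between = ss_b, SS_within = ss_w)
}
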