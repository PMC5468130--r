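#' Configuration for the random-dispersal null model
#'
#' The null hypothesis is complete spatial randomness (CSR): each
#' individual's position is independent and uniform over the arena disk.
#' A null "video" is `n_frames` independent uniform placements of
#' `n_individuals` points, summarised exactly like an observed video, and
#' the reference distribution is built from `n_videos` such videos. The
#' defaults (100 videos of 30 frames, 95% interval) mirror the assay's
#' simulation procedure.
#'
#' @param n_individuals Group size (points per frame), `>= 2`.
#' @param arena An [arena()].
#' @param n_videos Number of simulated videos, `>= 2`.
#' @param n_frames Frames per simulated video, `>= 1`.
#' @param ci_level Confidence level for the percentile band, in (0, 1).
#' @param seed Integer seed making the distribution reproducible.
#' @return An object of class `"null_config"`.
#' @export
null_config <- function(n_individuals, arena = larvagg::arena(), n_videos = 100,
                        n_frames = 30, ci_level = 0.95, seed = NULL) {
  if (!is_count(n_individuals, min = 2L)) {
    stop_larvagg("n_individuals must be an integer >= 2", "larvagg_invalid_config")
  }
  if (!is_count(n_videos, min = 2L)) {
    stop_larvagg("n_videos must be an integer >= 2", "larvagg_invalid_config")
  }
  if (!is_count(n_frames, min = 1L)) {
    stop_larvagg("n_frames must be an integer >= 1", "larvagg_invalid_config")
  }
  if (!is.numeric(ci_level) || length(ci_level) != 1L ||
      ci_level <= 0 || ci_level >= 1) {
    stop_larvagg("ci_level must be in (0, 1)", "larvagg_invalid_config")
  }
  stopifnot(inherits(arena, "arena"))
  structure(
    list(n_individuals = as.integer(n_individuals), arena = arena,
         n_videos = as.integer(n_videos), n_frames = as.integer(n_frames),
         ci_level = as.numeric(ci_level),
         seed = if (is.null(seed)) NULL else as.integer(seed)),
    class = "null_config"
  )
}

#' Sample points uniformly over the arena disk
#'
#' Uniform over the disk *area*: the radius is `R * sqrt(U)`, not
#' `R * U`, so density does not pile up at the centre. Draws from the
#' current RNG stream; seed with [set.seed()] (or via the `seed` fields of
#' the higher-level configs) for reproducibility.
#'
#' @param n Number of points.
#' @param arena An [arena()].
#' @return An `n x 2` matrix of positions (cm).
#' @export
sample_uniform_in_disk <- function(n, arena = larvagg::arena()) {
  theta <- stats::runif(n, 0, 2 * pi)
  rad <- arena$radius_cm * sqrt(stats::runif(n))
  cbind(x = rad * cos(theta), y = rad * sin(theta))
}

#' Simulate one CSR null video
#'
#' Every frame is an independent uniform placement of the group in the
#' arena; frames are nominally 180 s apart so the track is a valid
#' [video_track()] consumable by [summarize_video()] (with zero
#' acclimation frames, since a null video has no placement artefact to
#' discard).
#'
#' @param config A [null_config()].
#' @param video_id Identifier for the simulated track.
#' @return A [video_track()].
#' @export
simulate_null_video <- function(config, video_id = "null") {
  stopifnot(inherits(config, "null_config"))
  n <- config$n_individuals
  nf <- config$n_frames
  pts <- sample_uniform_in_disk(n * nf, config$arena)
  coords <- array(0, dim = c(n, 2L, nf))
  coords[, 1L, ] <- pts[, 1L]
  coords[, 2L, ] <- pts[, 2L]
  video_track(video_id, seq.int(0L, by = 180L, length.out = nf), coords,
              arena = config$arena,
              metadata = list(source = "csr_null"))
}

# sampling scheme under which a null (or otherwise analysis-cadence)
# track passes through summarize_video unchanged
null_scheme <- function(n_frames) {
  sampling_scheme(raw_interval_s = 180, analysis_interval_s = 180,
                  acclimation_frames = 0, duration_s = 180 * n_frames)
}

#' Build the CSR reference distribution of mean pairwise distances
#'
#' Simulates `n_videos` null videos, runs each through the same
#' [summarize_video()] code path as observed data (procedural identity
#' with the assay), and records the empirical distribution of video-level
#' mean pairwise distances with its percentile confidence band. The band
#' uses quantile type 6, whose order-statistic interval has expected
#' coverage equal to the nominal level for a fresh CSR video — the
#' property the band is used for when classifying observed videos.
#'
#' @param config A [null_config()].
#' @return An object of class `"null_distribution"`: `config`,
#'   `video_means` (cm), `ci_lower`, `ci_upper`, `grand_mean`,
#'   `seed_used`.
#' @examples
#' nd <- build_null_distribution(null_config(2, seed = 1))
#' nd$grand_mean  # ~ 6.56 cm for the 14.5-cm dish
#' @export
build_null_distribution <- function(config) {
  stopifnot(inherits(config, "null_config"))
  scheme <- null_scheme(config$n_frames)
  video_means <- with_seed(config$seed, {
    vapply(seq_len(config$n_videos), function(i) {
      tr <- simulate_null_video(config, video_id = sprintf("null_%04d", i))
      summarize_video(tr, scheme)$mean_pairwise_distance
    }, numeric(1))
  })
  a <- (1 - config$ci_level) / 2
  ci <- unname(stats::quantile(video_means, c(a, 1 - a), type = 6))
  structure(
    list(config = config,
         video_means = video_means,
         ci_lower = ci[1], ci_upper = ci[2],
         grand_mean = mean(video_means),
         seed_used = config$seed),
    class = "null_distribution"
  )
}

#' @export
print.null_distribution <- function(x, ...) {
  cat(sprintf(
    "<null_distribution> CSR, n = %d in %.3g-cm arena: %d videos x %d frames\n  grand mean %.4f cm, %g%% band [%.4f, %.4f] cm\n",
    x$config$n_individuals, x$config$arena$diameter_cm,
    x$config$n_videos, x$config$n_frames, x$grand_mean,
    100 * x$config$ci_level, x$ci_lower, x$ci_upper))
  invisible(x)
}

#' Classify an observed video against the CSR band
#'
#' Compares the video's log mean pairwise distance with the natural log
#' of the null band. Below the band the group is more clumped than random
#' ("aggregative"); above it, more evenly spread ("overdispersed");
#' inside it, indistinguishable from random placement. Because ln is
#' monotone the verdict is identical to banding on the linear scale; the
#' log scale is used to match all downstream statistics.
#'
#' @param summary An `"aggregation_summary"` from [summarize_video()].
#' @param null A `"null_distribution"` for the same group size and arena.
#' @return An object of class `"null_classification"`: `label` (one of
#'   `"aggregative"`, `"random"`, `"overdispersed"`), `log_observed`,
#'   `log_band` (length-2 vector).
#' @export
classify_video <- function(summary, null) {
  stopifnot(inherits(summary, "aggregation_summary"),
            inherits(null, "null_distribution"))
  if (summary$n_individuals != null$config$n_individuals) {
    stop_larvagg(
      sprintf("group size mismatch: video has %d individuals, null simulated %d",
              summary$n_individuals, null$config$n_individuals),
      "larvagg_incompatible")
  }
  if (abs(summary$arena$diameter_cm - null$config$arena$diameter_cm) > 1e-9) {
    stop_larvagg("arena mismatch between video and null distribution",
                 "larvagg_incompatible")
  }
  classify_log_mean(summary$log_mean_pairwise_distance, null)
}

# band comparison on the log scale, shared by classify_video and the
# per-group classification in compare_with_null_group
classify_log_mean <- function(log_observed, null) {
  band <- log(c(null$ci_lower, null$ci_upper))
  label <- if (log_observed < band[1]) {
    "aggregative"
  } else if (log_observed > band[2]) {
    "overdispersed"
  } else {
    "random"
  }
  structure(
    list(label = label, log_observed = log_observed, log_band = band),
    class = "null_classification"
  )
}

#' @export
print.null_classification <- function(x, ...) {
  cat(sprintf("<null_classification> %s (ln observed %.4f vs band [%.4f, %.4f])\n",
              x$label, x$log_observed, x$log_band[1], x$log_band[2]))
  invisible(x)
}
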