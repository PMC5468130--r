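#' All pairwise distances within one frame
#'
#' Euclidean distances between every pair of individuals in a single
#' frame, returned in lexicographic (i < j) pair order — the order
#' `(1,2), (1,3), ..., (1,n), (2,3), ...`.
#'
#' @param positions An `n x 2` matrix of positions (cm), `n >= 2`, or a
#'   [video_track()] together with a frame index in `frame`.
#' @param frame Frame index when `positions` is a track.
#' @return Numeric vector of `n(n-1)/2` distances in cm.
#' @examples
#' pairwise_distances(rbind(c(0, 0), c(3, 4)))  # 5
#' @export
pairwise_distances <- function(positions, frame = NULL) {
  if (inherits(positions, "video_track")) {
    positions <- frame_positions(positions, frame)
  }
  positions <- as.matrix(positions)
  if (nrow(positions) < 2L) {
    stop_larvagg("a frame needs at least 2 positions to have pairwise distances",
                 "larvagg_invalid_frame")
  }
  # stats::dist emits the lower triangle column by column, which is
  # exactly the (1,2),(1,3),...,(2,3),... order required here
  as.vector(stats::dist(positions))
}

#' Subsample a raw track to the analysis cadence
#'
#' Retains frames at times 0, `analysis_interval_s`,
#' `2 * analysis_interval_s`, ... relative to the first frame. The input
#' track must be regularly spaced at `raw_interval_s` (checked to within
#' 0.5 s, the slack a frame-extraction tool can introduce).
#'
#' @param track A [video_track()] at raw extraction cadence.
#' @param scheme A [sampling_scheme()].
#' @return A [video_track()] with only the analysed frames.
#' @export
subsample_frames <- function(track, scheme = sampling_scheme()) {
  stopifnot(inherits(track, "video_track"), inherits(scheme, "sampling_scheme"))
  nf <- n_frames(track)
  if (nf > 1L) {
    gaps <- diff(track$time_s)
    bad <- which(abs(gaps - scheme$raw_interval_s) > 0.5)
    if (length(bad) > 0) {
      stop_larvagg(
        sprintf("irregular frame spacing: gap between frames %d and %d is %.3f s, expected %g s",
                bad[1], bad[1] + 1L, gaps[bad[1]], scheme$raw_interval_s),
        "larvagg_sampling_error")
    }
  }
  stride <- as.integer(round(scheme$analysis_interval_s / scheme$raw_interval_s))
  keep <- seq.int(1L, nf, by = stride)
  subset_frames(track, keep)
}

#' Discard the acclimation period
#'
#' Drops the first `acclimation_frames` analysed frames: positions early
#' in a recording reflect where the animals were placed (and handling
#' agitation), not their aggregative behaviour.
#'
#' @param track A [video_track()] already at analysis cadence.
#' @param scheme A [sampling_scheme()].
#' @return A [video_track()] with the leading frames removed.
#' @export
trim_acclimation <- function(track, scheme = sampling_scheme()) {
  stopifnot(inherits(track, "video_track"), inherits(scheme, "sampling_scheme"))
  k <- scheme$acclimation_frames
  nf <- n_frames(track)
  if (k >= nf) {
    stop_larvagg(
      sprintf("discarding %d acclimation frames would empty a %d-frame track",
              k, nf),
      "larvagg_empty_track")
  }
  if (k == 0L) return(track)
  subset_frames(track, seq.int(k + 1L, nf))
}

#' Summarise a video into its aggregative-tendency statistic
#'
#' Applies the sampling scheme (subsample to the analysis cadence, then
#' discard the acclimation frames) and pools all pairwise distances from
#' the retained frames into a single arithmetic mean — the video's mean
#' pairwise distance — together with its natural log, the scale on which
#' all downstream statistics operate. Because every frame contributes the
#' same number of pairs, the pooled mean equals the mean of the per-frame
#' mean distances, which are also returned for time-series plots.
#'
#' @param track A raw [video_track()].
#' @param scheme A [sampling_scheme()]; use
#'   `sampling_scheme(raw_interval_s = s, analysis_interval_s = s,
#'   acclimation_frames = 0, ...)` for tracks already at analysis cadence.
#' @return An object of class `"aggregation_summary"` with fields
#'   `video_id`, `n_individuals`, `n_frames_used`,
#'   `mean_pairwise_distance` (cm), `log_mean_pairwise_distance`,
#'   `per_frame_means` (data frame `time_s`, `mean_distance_cm`),
#'   `arena`, `metadata`.
#' @examples
#' tr <- video_track("v1", 0, rbind(c(0, 0), c(3, 4)))
#' s <- sampling_scheme(15, 15, 0, 15)
#' summarize_video(tr, s)$mean_pairwise_distance  # 5
#' @export
summarize_video <- function(track, scheme = sampling_scheme()) {
  analyzed <- subsample_frames(track, scheme)
  retained <- trim_acclimation(analyzed, scheme)
  nf <- n_frames(retained)
  frame_means <- vapply(seq_len(nf), function(i) {
    mean(pairwise_distances(frame_positions(retained, i)))
  }, numeric(1))
  # constant n per frame: pooling all distances == averaging frame means
  m <- mean(frame_means)
  if (m <= 0) {
    stop_larvagg(
      sprintf("video %s: all individuals coincident in every retained frame; log mean distance undefined",
              track$video_id),
      "larvagg_log_undefined")
  }
  structure(
    list(video_id = track$video_id,
         n_individuals = track$n_individuals,
         n_frames_used = nf,
         mean_pairwise_distance = m,
         log_mean_pairwise_distance = log(m),
         per_frame_means = data.frame(time_s = retained$time_s,
                                      mean_distance_cm = frame_means),
         arena = track$arena,
         metadata = track$metadata),
    class = "aggregation_summary"
  )
}

#' @export
print.aggregation_summary <- function(x, ...) {
  cat(sprintf("<aggregation_summary> %s: n = %d, %d frames, mean pairwise distance %.4f cm (ln = %.4f)\n",
              x$video_id, x$n_individuals, x$n_frames_used,
              x$mean_pairwise_distance, x$log_mean_pairwise_distance))
  invisible(x)
}

#' Plot the per-frame mean distance time series
#'
#' @param x An `"aggregation_summary"`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.aggregation_summary <- function(x, ...) {
  graphics::plot(x$per_frame_means$time_s, x$per_frame_means$mean_distance_cm,
                 type = "b", xlab = "time (s)",
                 ylab = "mean pairwise distance (cm)",
                 main = x$video_id, ...)
  graphics::abline(h = x$mean_pairwise_distance, lty = 2)
  invisible(x)
}

#' Summarise many tracks into one table
#'
#' @param tracks List of [video_track()] objects.
#' @param scheme A [sampling_scheme()].
#' @return List with `summaries` (list of `"aggregation_summary"`) and
#'   `table` (data frame matching the summary CSV schema:
#'   `video_id, n_individuals, n_frames_used, mean_pairwise_distance_cm,
#'   log_mean_pairwise_distance`).
#' @export
summarize_tracks <- function(tracks, scheme = sampling_scheme()) {
  summaries <- lapply(tracks, summarize_video, scheme = scheme)
  table <- data.frame(
    video_id = vapply(summaries, `[[`, character(1), "video_id"),
    n_individuals = vapply(summaries, `[[`, integer(1), "n_individuals"),
    n_frames_used = vapply(summaries, `[[`, integer(1), "n_frames_used"),
    mean_pairwise_distance_cm =
      vapply(summaries, `[[`, numeric(1), "mean_pairwise_distance"),
    log_mean_pairwise_distance =
      vapply(summaries, `[[`, numeric(1), "log_mean_pairwise_distance"),
    stringsAsFactors = FALSE
  )
  list(summaries = summaries, table = table)
}
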