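#' Position track for one video
#'
#' A `video_track` holds the time-ordered head-capsule positions of every
#' individual in one arena recording. Positions are stored as an
#' `n_individuals x 2 x n_frames` array in cm, arena-centred coordinates;
#' individual identity is the row index, stable across frames.
#'
#' @param video_id Character identifier for the video.
#' @param time_s Numeric vector of frame times (seconds since recording
#'   start), strictly increasing, all `>= 0`.
#' @param coords Numeric array with dim `c(n_individuals, 2, n_frames)`
#'   (x in column 1, y in column 2), or for a single frame an
#'   `n_individuals x 2` matrix.
#' @param arena The [arena()] the positions live in.
#' @param metadata Named list of treatment metadata (e.g. `stage`,
#'   `population`, `latitude`, `species`, `relatedness_treatment`).
#' @return An object of class `"video_track"`.
#' @export
video_track <- function(video_id, time_s, coords, arena = larvagg::arena(),
                        metadata = list()) {
  if (is.matrix(coords)) {
    coords <- array(coords, dim = c(nrow(coords), 2L, 1L))
  }
  if (!is.array(coords) || length(dim(coords)) != 3L || dim(coords)[2] != 2L) {
    stop_larvagg("coords must be an n x 2 x n_frames array",
                 "larvagg_invalid_track")
  }
  n <- dim(coords)[1]
  nf <- dim(coords)[3]
  if (n < 2L) {
    stop_larvagg("a video track needs at least 2 individuals",
                 "larvagg_invalid_track")
  }
  if (nf < 1L) {
    stop_larvagg("a video track needs at least 1 frame",
                 "larvagg_invalid_track")
  }
  time_s <- as.numeric(time_s)
  if (length(time_s) != nf) {
    stop_larvagg("length(time_s) must equal the number of frames",
                 "larvagg_invalid_track")
  }
  if (any(!is.finite(time_s)) || any(time_s < 0)) {
    stop_larvagg("frame times must be finite and >= 0",
                 "larvagg_invalid_track")
  }
  if (nf > 1L && any(diff(time_s) <= 0)) {
    stop_larvagg("frame times must be strictly increasing",
                 "larvagg_invalid_track")
  }
  if (any(!is.finite(coords))) {
    stop_larvagg("positions must be finite", "larvagg_invalid_track")
  }
  flat <- matrix(aperm(coords, c(1, 3, 2)), ncol = 2)
  bad <- which(!in_arena(flat, arena))
  if (length(bad) > 0) {
    stop_larvagg(
      sprintf("position outside the %.3g-cm arena (first offending individual/frame pair %d)",
              arena$diameter_cm, bad[1]),
      "larvagg_outside_arena")
  }
  structure(
    list(video_id = as.character(video_id),
         arena = arena,
         n_individuals = as.integer(n),
         time_s = time_s,
         coords = coords,
         metadata = metadata),
    class = "video_track"
  )
}

#' @export
print.video_track <- function(x, ...) {
  cat(sprintf("<video_track> %s: %d individuals, %d frames (t = %g..%g s), arena %.3g cm\n",
              x$video_id, x$n_individuals, n_frames(x),
              x$time_s[1], x$time_s[length(x$time_s)], x$arena$diameter_cm))
  if (length(x$metadata)) {
    cat("  metadata:", paste(names(x$metadata), unlist(x$metadata),
                             sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' Number of frames in a track
#' @param track A [video_track()].
#' @export
n_frames <- function(track) {
  dim(track$coords)[3]
}

#' Extract one frame's positions
#'
#' @param track A [video_track()].
#' @param i Frame index (1-based).
#' @return An `n_individuals x 2` matrix of positions (cm).
#' @export
frame_positions <- function(track, i) {
  track$coords[, , i, drop = FALSE][, , 1]
}

#' Convert a track to the long tabular form
#'
#' One row per individual per frame, matching the on-disk track CSV schema
#' (`video_id, frame_index, time_s, larva_id, x_cm, y_cm`; `frame_index`
#' is 0-based, `larva_id` is the stable individual index).
#'
#' @param x A [video_track()].
#' @param ... Unused.
#' @export
as.data.frame.video_track <- function(x, ...) {
  n <- x$n_individuals
  nf <- n_frames(x)
  data.frame(
    video_id = rep(x$video_id, n * nf),
    frame_index = rep(seq_len(nf) - 1L, each = n),
    time_s = rep(x$time_s, each = n),
    larva_id = rep(seq_len(n), times = nf),
    x_cm = as.vector(x$coords[, 1, ]),
    y_cm = as.vector(x$coords[, 2, ]),
    stringsAsFactors = FALSE
  )
}

# Internal: rebuild a track keeping only the frames in `keep` (indices).
subset_frames <- function(track, keep) {
  video_track(track$video_id, track$time_s[keep],
              track$coords[, , keep, drop = FALSE],
              arena = track$arena, metadata = track$metadata)
}
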