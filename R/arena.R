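#' Circular test arena
#'
#' The assay arena is a petri dish, modelled as a disk in a Cartesian
#' coordinate frame with its origin at the dish centre and all geometry in
#' centimetres. The default matches the 14.5-cm dish used for the larval
#' assays.
#'
#' @param diameter_cm Dish diameter in cm; must be positive.
#' @return An object of class `"arena"` with fields `diameter_cm` and
#'   `radius_cm`.
#' @examples
#' a <- arena()
#' a$radius_cm
#' @export
arena <- function(diameter_cm = 14.5) {
  if (!is.numeric(diameter_cm) || length(diameter_cm) != 1L ||
      !is.finite(diameter_cm) || diameter_cm <= 0) {
    stop_larvagg("arena diameter must be a single positive number",
                 "larvagg_invalid_arena")
  }
  structure(
    list(diameter_cm = as.numeric(diameter_cm),
         radius_cm = as.numeric(diameter_cm) / 2),
    class = "arena"
  )
}

#' @export
print.arena <- function(x, ...) {
  cat(sprintf("<arena> circular, diameter %.3g cm (origin at centre)\n",
              x$diameter_cm))
  invisible(x)
}

# Containment tolerance: annotated head capsules can sit exactly on the
# dish wall, so a hair of numerical slack is allowed.
ARENA_TOL <- 1e-9

#' Check that positions lie inside an arena
#'
#' @param xy Two-column matrix of positions (cm).
#' @param arena An [arena()].
#' @return Logical vector, one element per row of `xy`.
#' @keywords internal
in_arena <- function(xy, arena) {
  xy <- as.matrix(xy)
  rowSums(xy^2) <= (arena$radius_cm + ARENA_TOL)^2
}

#' Frame sampling scheme for a video assay
#'
#' Describes how a recording is reduced to analysed frames: frames are
#' extracted from the video every `raw_interval_s` seconds, subsampled to
#' one frame every `analysis_interval_s` seconds, and the first
#' `acclimation_frames` analysed frames are discarded because early
#' positions reflect experimental placement and handling agitation rather
#' than behaviour. The defaults reproduce the assay cadence: a 90-min
#' (5,400 s) video at 15-s extraction gives 360 raw frames, 180-s
#' subsampling gives 30 analysed frames, and discarding 12 acclimation
#' frames (2,160 s) retains 18.
#'
#' @param raw_interval_s Seconds between extracted frames.
#' @param analysis_interval_s Seconds between analysed frames; must be a
#'   positive integer multiple of `raw_interval_s`.
#' @param acclimation_frames Leading analysed frames to discard.
#' @param duration_s Total recording length in seconds.
#' @return An object of class `"sampling_scheme"`.
#' @examples
#' s <- sampling_scheme()
#' n_raw_frames(s)       # 360
#' n_analyzed_frames(s)  # 30
#' n_retained_frames(s)  # 18
#' @export
sampling_scheme <- function(raw_interval_s = 15,
                            analysis_interval_s = 180,
                            acclimation_frames = 12,
                            duration_s = 5400) {
  if (!is.numeric(raw_interval_s) || raw_interval_s <= 0) {
    stop_larvagg("raw_interval_s must be positive", "larvagg_invalid_scheme")
  }
  stride <- analysis_interval_s / raw_interval_s
  if (!is.finite(stride) || stride < 1 || abs(stride - round(stride)) > 1e-9) {
    stop_larvagg(
      "analysis_interval_s must be a positive integer multiple of raw_interval_s",
      "larvagg_invalid_scheme")
  }
  if (!is_count(acclimation_frames)) {
    stop_larvagg("acclimation_frames must be a nonnegative integer",
                 "larvagg_invalid_scheme")
  }
  if (!is.numeric(duration_s) || duration_s <= 0) {
    stop_larvagg("duration_s must be positive", "larvagg_invalid_scheme")
  }
  scheme <- structure(
    list(raw_interval_s = as.numeric(raw_interval_s),
         analysis_interval_s = as.numeric(analysis_interval_s),
         acclimation_frames = as.integer(acclimation_frames),
         duration_s = as.numeric(duration_s)),
    class = "sampling_scheme"
  )
  if (scheme$acclimation_frames >= n_analyzed_frames(scheme)) {
    stop_larvagg(
      sprintf("acclimation_frames (%d) must be smaller than the number of analysed frames (%d)",
              scheme$acclimation_frames, n_analyzed_frames(scheme)),
      "larvagg_invalid_scheme")
  }
  scheme
}

#' @rdname sampling_scheme
#' @param scheme A [sampling_scheme()].
#' @export
n_raw_frames <- function(scheme) {
  as.integer(floor(scheme$duration_s / scheme$raw_interval_s + 1e-9))
}

#' @rdname sampling_scheme
#' @export
n_analyzed_frames <- function(scheme) {
  as.integer(floor(scheme$duration_s / scheme$analysis_interval_s + 1e-9))
}

#' @rdname sampling_scheme
#' @export
n_retained_frames <- function(scheme) {
  n_analyzed_frames(scheme) - scheme$acclimation_frames
}

#' @export
print.sampling_scheme <- function(x, ...) {
  cat(sprintf(
    "<sampling_scheme> %g s video: extract every %g s (%d frames), analyse every %g s (%d frames), discard %d acclimation -> %d retained\n",
    x$duration_s, x$raw_interval_s, n_raw_frames(x),
    x$analysis_interval_s, n_analyzed_frames(x),
    x$acclimation_frames, n_retained_frames(x)))
  invisible(x)
}
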