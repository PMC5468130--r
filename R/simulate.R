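#' Movement parameters for the synthetic larva walk
#'
#' A deliberately minimal biased random walk whose single behavioural
#' dial is `attraction`: each 15-s step combines an isotropic random
#' direction with a unit vector toward the centroid of neighbours within
#' `interaction_range_cm` (falling back to the nearest individual when
#' none is in range, so the rule degrades gracefully at n = 2). Positive
#' attraction biases movement toward neighbours, 0 gives a pure random
#' walk, negative biases away. Step lengths are |N(step_cm, step_sd_cm)|.
#' The wall is specularly reflecting (radial fold), which preserves the
#' uniform-disk equilibrium of the unbiased walk.
#'
#' This is not a mechanistic larva model: its job is to produce tracks
#' whose aggregation strength is a known monotone function of one
#' parameter, so parameter-recovery and power analyses have ground truth.
#'
#' @param attraction Dimensionless weight in \[-1, 1\].
#' @param step_cm Mean step length per raw frame interval (cm); default
#'   0.5, on the order of a larva body length per 15 s.
#' @param step_sd_cm Step-length spread (cm).
#' @param interaction_range_cm Distance within which neighbours exert
#'   bias (cm). The default (15 cm) exceeds the default dish diameter, so
#'   every individual senses the whole group — in a 14.5-cm arena larvae
#'   plausibly perceive conspecifics anywhere in the dish. Narrowing the
#'   range makes interactions local, which can trap strong-attraction
#'   groups in several mutually blind subclusters.
#' @return An object of class `"movement_params"`.
#' @export
movement_params <- function(attraction = 0, step_cm = 0.5,
                            step_sd_cm = 0.25, interaction_range_cm = 15) {
  if (!is.numeric(attraction) || length(attraction) != 1L ||
      !is.finite(attraction) || abs(attraction) > 1) {
    stop_larvagg("attraction must be in [-1, 1]", "larvagg_invalid_params")
  }
  if (!is.numeric(step_cm) || step_cm <= 0) {
    stop_larvagg("step_cm must be positive", "larvagg_invalid_params")
  }
  if (!is.numeric(step_sd_cm) || step_sd_cm < 0) {
    stop_larvagg("step_sd_cm must be nonnegative", "larvagg_invalid_params")
  }
  if (!is.numeric(interaction_range_cm) || interaction_range_cm <= 0) {
    stop_larvagg("interaction_range_cm must be positive", "larvagg_invalid_params")
  }
  structure(
    list(attraction = as.numeric(attraction),
         step_cm = as.numeric(step_cm),
         step_sd_cm = as.numeric(step_sd_cm),
         interaction_range_cm = as.numeric(interaction_range_cm)),
    class = "movement_params"
  )
}

#' Place a group equidistantly on the arena perimeter
#'
#' The assay starts every video with the larvae spaced equally around the
#' dish wall: n points at radius `diameter/2` with consecutive angular
#' gaps of `2*pi/n`, the whole ring rotated by a random phase (or a
#' supplied one).
#'
#' @param n Group size, `>= 2`.
#' @param arena An [arena()].
#' @param rotation Optional fixed rotation in radians; drawn uniformly
#'   from the current RNG stream when `NULL`.
#' @return An `n x 2` matrix of positions (cm).
#' @export
place_on_perimeter <- function(n, arena = larvagg::arena(), rotation = NULL) {
  if (!is_count(n, min = 2L)) {
    stop_larvagg("perimeter placement needs n >= 2", "larvagg_invalid_params")
  }
  if (is.null(rotation)) rotation <- stats::runif(1, 0, 2 * pi)
  theta <- rotation + 2 * pi * (seq_len(n) - 1L) / n
  r <- arena$radius_cm
  cbind(x = r * cos(theta), y = r * sin(theta))
}

# one walk step for all individuals at once; pos is n x 2
step_colony <- function(pos, params, arena) {
  n <- nrow(pos)
  a <- params$attraction
  # unit vectors toward the neighbour centroid (within range, else nearest)
  d <- as.matrix(stats::dist(pos))
  diag(d) <- Inf
  u <- matrix(0, n, 2)
  if (a != 0) {
    for (i in seq_len(n)) {
      nb <- which(d[i, ] <= params$interaction_range_cm)
      if (length(nb) == 0L) nb <- which.min(d[i, ])
      target <- colMeans(pos[nb, , drop = FALSE])
      v <- target - pos[i, ]
      len <- sqrt(sum(v^2))
      if (len > 0) u[i, ] <- v / len
      # coincident with the target: leave u = 0, the random part decides
    }
  }
  phi <- stats::runif(n, 0, 2 * pi)
  eps <- cbind(cos(phi), sin(phi))
  len <- abs(stats::rnorm(n, params$step_cm, params$step_sd_cm))
  disp <- len * ((1 - abs(a)) * eps + a * u)
  new <- pos + disp
  # radial fold: reflect overshoot back across the wall
  r <- sqrt(rowSums(new^2))
  R <- arena$radius_cm
  over <- r > R
  if (any(over)) {
    r_new <- 2 * R - r[over]
    if (any(r_new < 0)) {
      stop_larvagg("step too large to reflect back into the arena; reduce step_cm",
                   "larvagg_invalid_params")
    }
    scale <- ifelse(r[over] > 0, r_new / r[over], 0)
    new[over, ] <- new[over, , drop = FALSE] * scale
  }
  new
}

#' Simulate one colony's position track
#'
#' Individuals start equidistant on the perimeter (random phase) and take
#' one biased-random-walk step per raw frame interval; the result is a
#' raw-resolution [video_track()] ready for [summarize_video()].
#'
#' @param n Group size, `>= 2`.
#' @param params A [movement_params()].
#' @param arena An [arena()].
#' @param scheme A [sampling_scheme()]; its `duration_s` and
#'   `raw_interval_s` set the number of raw frames (360 by default).
#' @param video_id Identifier for the track.
#' @param metadata Named list stored on the track.
#' @return A [video_track()].
#' @examples
#' set.seed(1)
#' tr <- simulate_colony(5, movement_params(attraction = 0.9))
#' summarize_video(tr)
#' @export
simulate_colony <- function(n, params = movement_params(), arena = larvagg::arena(),
                            scheme = sampling_scheme(), video_id = "sim",
                            metadata = list()) {
  stopifnot(inherits(params, "movement_params"))
  nf <- n_raw_frames(scheme)
  coords <- array(0, dim = c(n, 2L, nf))
  pos <- place_on_perimeter(n, arena)
  coords[, , 1L] <- pos
  if (nf > 1L) {
    for (t in 2:nf) {
      pos <- step_colony(pos, params, arena)
      coords[, , t] <- pos
    }
  }
  video_track(video_id, scheme$raw_interval_s * (seq_len(nf) - 1L), coords,
              arena = arena, metadata = metadata)
}

#' Define a multi-group synthetic experiment
#'
#' @param groups List of group descriptors, each a list with elements
#'   `label`, `n_videos`, `n_individuals`, `params` (a
#'   [movement_params()]), and optionally `covariate` (a number recorded
#'   for every video of the group) and `metadata` (named list).
#' @param arena Shared [arena()].
#' @param scheme Shared [sampling_scheme()].
#' @param seed Integer seed; the whole corpus is reproducible from it.
#' @return An object of class `"experiment_design"`.
#' @export
experiment_design <- function(groups, arena = larvagg::arena(),
                              scheme = sampling_scheme(), seed = NULL) {
  labels <- vapply(groups, `[[`, character(1), "label")
  if (anyDuplicated(labels)) {
    stop_larvagg("group labels must be unique", "larvagg_invalid_design")
  }
  for (g in groups) {
    if (!is_count(g$n_videos, min = 1L)) {
      stop_larvagg(sprintf("group '%s': n_videos must be >= 1", g$label),
                   "larvagg_invalid_design")
    }
    if (!is_count(g$n_individuals, min = 2L)) {
      stop_larvagg(sprintf("group '%s': n_individuals must be >= 2", g$label),
                   "larvagg_invalid_design")
    }
    stopifnot(inherits(g$params, "movement_params"))
  }
  structure(
    list(groups = groups, arena = arena, scheme = scheme,
         seed = if (is.null(seed)) NULL else as.integer(seed)),
    class = "experiment_design"
  )
}

#' Generate a synthetic experiment
#'
#' Simulates every video of every group in the design and returns the
#' tracks together with the `video_id, group, covariate` design table
#' consumed by the group-comparison layer.
#'
#' @param design An [experiment_design()].
#' @return List with `tracks` (named list of [video_track()]) and
#'   `design_table` (data frame `video_id, group, covariate`).
#' @export
generate_experiment <- function(design) {
  stopifnot(inherits(design, "experiment_design"))
  with_seed(design$seed, {
    tracks <- list()
    rows <- list()
    for (g in design$groups) {
      for (i in seq_len(g$n_videos)) {
        vid <- sprintf("%s_%03d", g$label, i)
        if (vid %in% names(tracks)) {
          stop_larvagg(sprintf("duplicate video id '%s'", vid),
                       "larvagg_invalid_design")
        }
        md <- c(list(group = g$label), g$metadata)
        tracks[[vid]] <- simulate_colony(
          g$n_individuals, g$params, design$arena, design$scheme,
          video_id = vid, metadata = md)
        rows[[vid]] <- data.frame(
          video_id = vid, group = g$label,
          covariate = if (is.null(g$covariate)) NA_real_ else g$covariate,
          stringsAsFactors = FALSE)
      }
    }
    list(tracks = tracks, design_table = do.call(rbind, c(rows, list(make.row.names = FALSE))))
  })
}
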