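#' Write tracks to the track CSV format
#'
#' One row per individual per frame, header
#' `video_id,frame_index,time_s,larva_id,x_cm,y_cm`. Coordinates are
#' written at full double precision so a write/read round trip is
#' bitwise exact.
#'
#' @param tracks A [video_track()] or list of them.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_tracks <- function(tracks, path) {
  if (inherits(tracks, "video_track")) tracks <- list(tracks)
  long <- do.call(rbind, lapply(tracks, as.data.frame))
  long$x_cm <- sprintf("%.17g", long$x_cm)
  long$y_cm <- sprintf("%.17g", long$y_cm)
  utils::write.csv(long, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

TRACK_COLUMNS <- c("video_id", "frame_index", "time_s", "larva_id",
                   "x_cm", "y_cm")

#' Read position tracks from a track CSV
#'
#' Parses the `video_id,frame_index,time_s,larva_id,x_cm,y_cm` schema,
#' groups rows by video, orders frames by `frame_index` (authoritative;
#' `time_s` is checked for monotonicity), and validates every track
#' invariant on load: constant individual count per frame, strictly
#' increasing times, and containment in the arena. Violations raise a
#' parse error naming the offending data row.
#'
#' @param path Track CSV file.
#' @param arena The [arena()] the coordinates live in.
#' @param cm_per_unit Scale factor applied to the coordinates, for raw
#'   annotation exports in pixels calibrated against the known dish
#'   diameter; default 1 (already in cm).
#' @param allow_partial Drop frames with a missing individual (with a
#'   warning) instead of erroring. Positions are never imputed.
#' @return Named list of [video_track()] objects, one per video.
#' @export
read_tracks <- function(path, arena = larvagg::arena(), cm_per_unit = 1,
                        allow_partial = FALSE) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(TRACK_COLUMNS, names(df))
  if (length(missing_cols) > 0) {
    stop_larvagg(sprintf("track file %s: missing column(s) %s", path,
                         paste(missing_cols, collapse = ", ")),
                 "larvagg_parse_error")
  }
  df$.row <- seq_len(nrow(df)) + 1L # data row number incl. header line
  df$x_cm <- df$x_cm * cm_per_unit
  df$y_cm <- df$y_cm * cm_per_unit
  bad <- which(!in_arena(cbind(df$x_cm, df$y_cm), arena))
  if (length(bad) > 0) {
    stop_larvagg(
      sprintf("track file %s, row %d: position (%.4g, %.4g) outside the %.3g-cm arena",
              path, df$.row[bad[1]], df$x_cm[bad[1]], df$y_cm[bad[1]],
              arena$diameter_cm),
      "larvagg_parse_error")
  }
  tracks <- list()
  for (vid in unique(df$video_id)) {
    sub <- df[df$video_id == vid, , drop = FALSE]
    sub <- sub[order(sub$frame_index, sub$larva_id), , drop = FALSE]
    roster <- sort(unique(sub$larva_id))
    n <- length(roster)
    frames <- split(sub, sub$frame_index)
    counts <- vapply(frames, nrow, integer(1))
    if (any(counts != n)) {
      short <- frames[[which(counts != n)[1]]]
      if (!allow_partial) {
        stop_larvagg(
          sprintf("track file %s, video %s: frame %s has %d of %d individuals (near row %d)",
                  path, vid, short$frame_index[1], nrow(short), n,
                  short$.row[1]),
          "larvagg_parse_error")
      }
      warning(sprintf("video %s: dropping %d incomplete frame(s)", vid,
                      sum(counts != n)), call. = FALSE)
      frames <- frames[counts == n]
    }
    nf <- length(frames)
    if (nf == 0L) {
      stop_larvagg(sprintf("video %s has no complete frames", vid),
                   "larvagg_parse_error")
    }
    time_s <- vapply(frames, function(f) f$time_s[1], numeric(1))
    if (nf > 1L && any(diff(time_s) <= 0)) {
      i <- which(diff(time_s) <= 0)[1]
      stop_larvagg(
        sprintf("track file %s, video %s: non-increasing time at frame %s (row %d)",
                path, vid, names(frames)[i + 1L], frames[[i + 1L]]$.row[1]),
        "larvagg_parse_error")
    }
    coords <- array(0, dim = c(n, 2L, nf))
    for (j in seq_len(nf)) {
      f <- frames[[j]]
      idx <- match(f$larva_id, roster)
      coords[idx, 1L, j] <- f$x_cm
      coords[idx, 2L, j] <- f$y_cm
    }
    tracks[[vid]] <- video_track(vid, time_s, coords, arena = arena)
  }
  tracks
}

#' Write a summary table to CSV
#'
#' Schema: `video_id,n_individuals,n_frames_used,
#' mean_pairwise_distance_cm,log_mean_pairwise_distance`.
#'
#' @param summary_table Data frame from [summarize_tracks()].
#' @param path Output file.
#' @export
write_summary_table <- function(summary_table, path) {
  utils::write.csv(summary_table, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a null distribution to CSV
#'
#' One row per simulated video (`replicate,mean_pairwise_distance_cm`)
#' followed by a companion `<path>_summary.csv` holding the grand mean
#' and confidence band.
#'
#' @param null A `"null_distribution"`.
#' @param path Output file for the per-replicate means.
#' @export
write_null_distribution <- function(null, path) {
  utils::write.csv(
    data.frame(replicate = seq_along(null$video_means),
               mean_pairwise_distance_cm = null$video_means),
    path, row.names = FALSE, quote = FALSE)
  summary_path <- sub("\\.csv$", "_summary.csv", path)
  if (identical(summary_path, path)) summary_path <- paste0(path, "_summary.csv")
  utils::write.csv(
    data.frame(n_individuals = null$config$n_individuals,
               diameter_cm = null$config$arena$diameter_cm,
               n_videos = null$config$n_videos,
               n_frames = null$config$n_frames,
               ci_level = null$config$ci_level,
               grand_mean_cm = null$grand_mean,
               ci_lower_cm = null$ci_lower,
               ci_upper_cm = null$ci_upper,
               seed = if (is.null(null$seed_used)) NA else null$seed_used),
    summary_path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Pipeline configuration
#'
#' @param tracks Either a path to a track CSV or a list of
#'   [video_track()] objects (e.g. from [generate_experiment()]).
#' @param design Data frame `video_id,group[,covariate]` mapping videos
#'   to treatment groups.
#' @param out_dir Directory for output tables (created if needed).
#' @param arena An [arena()].
#' @param scheme A [sampling_scheme()].
#' @param null_n_videos,null_n_frames,ci_level Null-model settings.
#' @param alpha Family-wise error rate for Tukey intervals.
#' @param seed Integer seed for the null simulations.
#' @return An object of class `"run_config"`.
#' @export
run_config <- function(tracks, design, out_dir, arena = larvagg::arena(),
                       scheme = sampling_scheme(), null_n_videos = 100,
                       null_n_frames = 30, ci_level = 0.95, alpha = 0.05,
                       seed = 1L) {
  if (is.character(tracks) && !file.exists(tracks)) {
    stop_larvagg(sprintf("track file %s does not exist", tracks),
                 "larvagg_invalid_config")
  }
  if (!all(c("video_id", "group") %in% names(design))) {
    stop_larvagg("design table needs video_id and group columns",
                 "larvagg_invalid_config")
  }
  structure(
    list(tracks = tracks, design = design, out_dir = out_dir,
         arena = arena, scheme = scheme,
         null_n_videos = as.integer(null_n_videos),
         null_n_frames = as.integer(null_n_frames),
         ci_level = ci_level, alpha = alpha, seed = as.integer(seed)),
    class = "run_config"
  )
}

#' Run the full assay pipeline
#'
#' Loads (or accepts) tracks, summarises every video, builds a CSR null
#' for each group size present, and — separately per group size, since
#' distances from different group sizes are not directly comparable —
#' runs the ANOVA + Tukey comparison with the random pseudo-group and
#' the band classification. All tables are written under
#' `config$out_dir` along with a manifest recording the seed and a hash
#' of the configuration; rerunning the same config reproduces the
#' outputs exactly.
#'
#' @param config A [run_config()].
#' @return Named list of `"comparison_result"` objects, one per group
#'   size (names like `"n5"`), with the summary table attached as
#'   attribute `"summary_table"`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  tracks <- if (is.character(config$tracks)) {
    read_tracks(config$tracks, arena = config$arena)
  } else {
    config$tracks
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  sm <- summarize_tracks(tracks, config$scheme)
  write_summary_table(sm$table, file.path(config$out_dir, "summaries.csv"))
  pfm <- do.call(rbind, lapply(sm$summaries, function(s) {
    cbind(video_id = s$video_id, s$per_frame_means)
  }))
  utils::write.csv(pfm, file.path(config$out_dir, "per_frame_means.csv"),
                   row.names = FALSE, quote = FALSE)

  results <- list()
  sizes <- sort(unique(sm$table$n_individuals))
  for (ni in sizes) {
    sub <- sm$table[sm$table$n_individuals == ni, , drop = FALSE]
    null <- build_null_distribution(null_config(
      ni, arena = config$arena, n_videos = config$null_n_videos,
      n_frames = config$null_n_frames, ci_level = config$ci_level,
      seed = config$seed + ni))
    write_null_distribution(null, file.path(config$out_dir,
                                            sprintf("null_n%d.csv", ni)))
    obs <- observations_from_design(sub, config$design)
    res <- compare_with_null_group(obs, null, alpha = config$alpha)
    an <- res$anova
    utils::write.csv(
      data.frame(n_individuals = ni, F = an$F, df_between = an$df_between,
                 df_within = an$df_within, p = an$p,
                 SS_between = an$SS_between, SS_within = an$SS_within),
      file.path(config$out_dir, sprintf("anova_n%d.csv", ni)),
      row.names = FALSE, quote = FALSE)
    utils::write.csv(res$tukey$pairs,
                     file.path(config$out_dir, sprintf("tukey_n%d.csv", ni)),
                     row.names = FALSE, quote = FALSE)
    utils::write.csv(res$classification,
                     file.path(config$out_dir,
                               sprintf("classification_n%d.csv", ni)),
                     row.names = FALSE, quote = FALSE)
    results[[sprintf("n%d", ni)]] <- res
  }

  manifest <- c(
    sprintf("larvagg run manifest"),
    sprintf("seed: %d", config$seed),
    sprintf("config_hash: %s", config_hash(config[setdiff(names(config), "tracks")])),
    sprintf("n_videos: %d", nrow(sm$table)),
    sprintf("group_sizes: %s", paste(sizes, collapse = ", ")),
    sprintf("arena_diameter_cm: %g", config$arena$diameter_cm),
    sprintf("analysis_interval_s: %g", config$scheme$analysis_interval_s),
    sprintf("acclimation_frames: %d", config$scheme$acclimation_frames),
    sprintf("null_n_videos: %d", config$null_n_videos),
    sprintf("ci_level: %g", config$ci_level),
    sprintf("alpha: %g", config$alpha)
  )
  writeLines(manifest, file.path(config$out_dir, "manifest.txt"))
  attr(results, "summary_table") <- sm$table
  results
}
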