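#' Grouped video-level observations
#'
#' The unit of replication is the video; the response is its log mean
#' pairwise distance. Groups are treatment levels (developmental stage,
#' relatedness treatment, population, species, ...). An optional
#' continuous covariate (e.g. population latitude in decimal degrees) can
#' accompany each video for regression-style tests.
#'
#' @param value Numeric vector of log mean pairwise distances, one per
#'   video.
#' @param group Vector of group labels, same length as `value`.
#' @param covariate Optional numeric covariate, same length as `value`.
#' @param n_individuals Optional group size shared by all videos; checked
#'   against a null distribution when one is attached.
#' @param arena Optional [arena()] the videos were recorded in.
#' @return An object of class `"grouped_observations"`.
#' @export
grouped_observations <- function(value, group, covariate = NULL,
                                 n_individuals = NULL, arena = NULL) {
  if (length(value) == 0L) {
    stop_larvagg("no observations supplied", "larvagg_invalid_observations")
  }
  if (length(group) != length(value)) {
    stop_larvagg("value and group must have the same length",
                 "larvagg_invalid_observations")
  }
  if (!is.null(covariate) && length(covariate) != length(value)) {
    stop_larvagg("covariate must have one entry per video",
                 "larvagg_invalid_observations")
  }
  if (any(!is.finite(value))) {
    stop_larvagg("values must be finite", "larvagg_invalid_observations")
  }
  group <- factor(as.character(group), levels = unique(as.character(group)))
  structure(
    list(value = as.numeric(value), group = group,
         covariate = if (is.null(covariate)) NULL else as.numeric(covariate),
         n_individuals = if (is.null(n_individuals)) NULL
                         else as.integer(n_individuals),
         arena = arena),
    class = "grouped_observations"
  )
}

#' Build grouped observations from a summary table and a design table
#'
#' @param summary_table Data frame as produced by [summarize_tracks()].
#' @param design Data frame with columns `video_id`, `group` and
#'   optionally `covariate`.
#' @return A [grouped_observations()] object.
#' @export
observations_from_design <- function(summary_table, design) {
  idx <- match(summary_table$video_id, design$video_id)
  if (any(is.na(idx))) {
    stop_larvagg(
      sprintf("video %s missing from the design table",
              summary_table$video_id[which(is.na(idx))[1]]),
      "larvagg_invalid_observations")
  }
  n_ind <- unique(summary_table$n_individuals)
  grouped_observations(
    value = summary_table$log_mean_pairwise_distance,
    group = design$group[idx],
    covariate = if ("covariate" %in% names(design)) design$covariate[idx],
    n_individuals = if (length(n_ind) == 1L) n_ind
  )
}

check_anova_input <- function(obs) {
  stopifnot(inherits(obs, "grouped_observations"))
  k <- nlevels(obs$group)
  n <- length(obs$value)
  if (k < 2L) {
    stop_larvagg("ANOVA needs at least 2 groups", "larvagg_invalid_observations")
  }
  if (any(table(obs$group) == 0L)) {
    stop_larvagg("every group must contain at least one video",
                 "larvagg_invalid_observations")
  }
  if (n < k + 1L) {
    stop_larvagg("total N must exceed the number of groups",
                 "larvagg_invalid_observations")
  }
  if (stats::var(obs$value) == 0) {
    stop_larvagg("all observations identical; ANOVA is degenerate",
                 "larvagg_degenerate_data")
  }
  invisible(k)
}

#' One-way ANOVA on log mean pairwise distances
#'
#' Classical fixed-effects one-way ANOVA (no Welch correction), fitted
#' via [stats::lm()]. Reports the full sums-of-squares decomposition so
#' the F statistic can be audited: `F = (SS_between/df_between) /
#' (SS_within/df_within)` with `df = (k - 1, N - k)`. A variance-
#' homogeneity diagnostic (ratio of largest to smallest group variance)
#' is attached but not enforced.
#'
#' @param obs A [grouped_observations()].
#' @return An object of class `"anova_result"`: `F`, `df_between`,
#'   `df_within`, `p`, `group_means`, `grand_mean`, `SS_between`,
#'   `SS_within`, `infinite_F` flag, `variance_ratio`.
#' @export
one_way_anova <- function(obs) {
  k <- check_anova_input(obs)
  fit <- stats::lm(obs$value ~ obs$group)
  # near-zero residual variance triggers R's "unreliable F" warning; that
  # case is detected and reported as an infinite F below
  an <- suppressWarnings(stats::anova(fit))
  ss_b <- an[["Sum Sq"]][1]
  ss_w <- an[["Sum Sq"]][2]
  df_b <- an[["Df"]][1]
  df_w <- an[["Df"]][2]
  group_means <- tapply(obs$value, obs$group, mean)
  gvar <- tapply(obs$value, obs$group, stats::var)
  gvar <- gvar[!is.na(gvar) & tabulate(obs$group) > 1]
  inf_flag <- FALSE
  total <- ss_b + ss_w
  if (ss_w <= total * 1e-12) {
    # all within-group variance exhausted but group means differ
    Fstat <- Inf
    p <- 0
    inf_flag <- TRUE
  } else {
    Fstat <- an[["F value"]][1]
    p <- an[["Pr(>F)"]][1]
  }
  structure(
    list(F = Fstat, df_between = df_b, df_within = df_w, p = p,
         group_means = group_means,
         grand_mean = mean(obs$value),
         SS_between = ss_b, SS_within = ss_w,
         infinite_F = inf_flag,
         variance_ratio = if (length(gvar) > 1 && min(gvar) > 0)
           max(gvar) / min(gvar) else NA_real_),
    class = "anova_result"
  )
}

#' @export
print.anova_result <- function(x, ...) {
  cat(sprintf("<anova_result> F(%d, %d) = %.4f, p = %.4g\n",
              x$df_between, x$df_within, x$F, x$p))
  invisible(x)
}

#' Tukey HSD post hoc comparisons
#'
#' All-pairs comparisons with family-wise error control via the
#' studentized range distribution, computed with [stats::TukeyHSD()] on
#' the fitted one-way model. Unequal group sizes use the Tukey–Kramer
#' harmonic adjustment (the default behaviour of `TukeyHSD`), which
#' reduces to classical Tukey for balanced designs.
#'
#' @param obs A [grouped_observations()].
#' @param alpha Family-wise error rate for the adjusted intervals.
#' @return An object of class `"tukey_result"`: data frame `pairs` with
#'   columns `group1`, `group2`, `diff` (mean of `group1` minus mean of
#'   `group2`), `lwr`, `upr`, `p_adj`; plus `alpha`, `df_within`,
#'   `n_groups`.
#' @export
tukey_hsd <- function(obs, alpha = 0.05) {
  k <- check_anova_input(obs)
  fit <- stats::aov(value ~ group, data = data.frame(value = obs$value,
                                                     group = obs$group))
  tk <- stats::TukeyHSD(fit, conf.level = 1 - alpha)$group
  nm <- strsplit(rownames(tk), "-", fixed = TRUE)
  pairs <- data.frame(
    group1 = vapply(nm, `[`, character(1), 1),
    group2 = vapply(nm, `[`, character(1), 2),
    diff = tk[, "diff"], lwr = tk[, "lwr"], upr = tk[, "upr"],
    p_adj = tk[, "p adj"],
    row.names = NULL, stringsAsFactors = FALSE
  )
  structure(
    list(pairs = pairs, alpha = alpha,
         df_within = stats::df.residual(fit), n_groups = k),
    class = "tukey_result"
  )
}

#' @export
print.tukey_result <- function(x, ...) {
  cat(sprintf("<tukey_result> %d groups, df = %d, family alpha = %g\n",
              x$n_groups, x$df_within, x$alpha))
  print(x$pairs, digits = 4)
  invisible(x)
}

#' Look up one Tukey pair
#'
#' @param tukey A `"tukey_result"`.
#' @param a,b Group labels (order-insensitive).
#' @return The matching row of `tukey$pairs`.
#' @export
tukey_pair <- function(tukey, a, b) {
  p <- tukey$pairs
  hit <- (p$group1 == a & p$group2 == b) | (p$group1 == b & p$group2 == a)
  if (!any(hit)) {
    stop_larvagg(sprintf("no Tukey comparison between '%s' and '%s'", a, b),
                 "larvagg_invalid_observations")
  }
  p[hit, , drop = FALSE]
}

#' Compare treatment groups with the simulated random model
#'
#' Appends the natural logs of the null distribution's simulated video
#' means as an extra pseudo-group (labelled `"random"` by default) and
#' reruns the one-way ANOVA and Tukey HSD, so each treatment's contrast
#' with random dispersal is a regular Tukey comparison — exactly how the
#' assay reports "vs. random" p values. Each treatment group is also
#' classified against the null band (below / within / above), the
#' figure-style verdict.
#'
#' @param obs A [grouped_observations()] of log mean pairwise distances.
#' @param null A `"null_distribution"` for the same group size and arena.
#' @param alpha Family-wise error rate for the Tukey intervals.
#' @param null_label Label for the pseudo-group.
#' @return An object of class `"comparison_result"`: `anova` (on the
#'   augmented data), `tukey`, `classification` (data frame `group`,
#'   `log_mean`, `label`), `null`, `null_label`.
#' @export
compare_with_null_group <- function(obs, null, alpha = 0.05,
                                    null_label = "random") {
  stopifnot(inherits(obs, "grouped_observations"),
            inherits(null, "null_distribution"))
  if (length(obs$value) == 0L || nlevels(obs$group) == 0L) {
    stop_larvagg("no treatment groups to compare", "larvagg_invalid_observations")
  }
  if (!is.null(obs$n_individuals) &&
      obs$n_individuals != null$config$n_individuals) {
    stop_larvagg(
      sprintf("group size mismatch: observations have %d individuals per video, null simulated %d",
              obs$n_individuals, null$config$n_individuals),
      "larvagg_incompatible")
  }
  if (!is.null(obs$arena) &&
      abs(obs$arena$diameter_cm - null$config$arena$diameter_cm) > 1e-9) {
    stop_larvagg("arena mismatch between observations and null distribution",
                 "larvagg_incompatible")
  }
  if (null_label %in% levels(obs$group)) {
    stop_larvagg(sprintf("group label '%s' collides with the null pseudo-group",
                         null_label),
                 "larvagg_invalid_observations")
  }
  aug <- grouped_observations(
    value = c(obs$value, log(null$video_means)),
    group = c(as.character(obs$group),
              rep(null_label, length(null$video_means)))
  )
  an <- one_way_anova(aug)
  tk <- tukey_hsd(aug, alpha = alpha)
  cls <- lapply(levels(obs$group), function(g) {
    classify_log_mean(mean(obs$value[obs$group == g]), null)
  })
  classification <- data.frame(
    group = levels(obs$group),
    log_mean = vapply(cls, `[[`, numeric(1), "log_observed"),
    label = vapply(cls, `[[`, character(1), "label"),
    stringsAsFactors = FALSE
  )
  structure(
    list(anova = an, tukey = tk, classification = classification,
         null = null, null_label = null_label),
    class = "comparison_result"
  )
}

#' @export
print.comparison_result <- function(x, ...) {
  print(x$anova)
  print(x$tukey)
  cat("classification vs the random band:\n")
  print(x$classification)
  invisible(x)
}

#' F-test for a continuous predictor of aggregative tendency
#'
#' Simple linear regression of log mean pairwise distance on a continuous
#' covariate such as population latitude; the F statistic with
#' `df = (1, N - 2)` tests a zero slope.
#'
#' @param obs A [grouped_observations()] whose `covariate` is set for
#'   every video.
#' @return An `"anova_result"` with `df_between = 1`, plus `slope`,
#'   `intercept` and `r_squared` fields.
#' @export
continuous_predictor_anova <- function(obs) {
  stopifnot(inherits(obs, "grouped_observations"))
  if (is.null(obs$covariate) || any(!is.finite(obs$covariate))) {
    stop_larvagg("a finite covariate is required for every video",
                 "larvagg_invalid_observations")
  }
  if (length(obs$value) < 3L) {
    stop_larvagg("at least 3 videos are needed to test a continuous predictor",
                 "larvagg_invalid_observations")
  }
  if (stats::var(obs$covariate) == 0) {
    stop_larvagg("covariate is constant; slope is not identifiable",
                 "larvagg_degenerate_covariate")
  }
  fit <- stats::lm(obs$value ~ obs$covariate)
  an <- suppressWarnings(stats::anova(fit))
  sm <- suppressWarnings(summary(fit))
  ss_w <- an[["Sum Sq"]][2]
  total <- sum(an[["Sum Sq"]])
  if (ss_w <= total * 1e-12) {
    Fstat <- Inf; p <- 0; inf_flag <- TRUE
  } else {
    Fstat <- an[["F value"]][1]; p <- an[["Pr(>F)"]][1]; inf_flag <- FALSE
  }
  structure(
    list(F = Fstat, df_between = an[["Df"]][1], df_within = an[["Df"]][2],
         p = p,
         group_means = NULL, grand_mean = mean(obs$value),
         SS_between = an[["Sum Sq"]][1], SS_within = ss_w,
         infinite_F = inf_flag,
         variance_ratio = NA_real_,
         slope = unname(stats::coef(fit)[2]),
         intercept = unname(stats::coef(fit)[1]),
         r_squared = sm$r.squared),
    class = "anova_result"
  )
}
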