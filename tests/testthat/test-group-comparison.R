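test_that("degrees of freedom reproduce every assay design", {
  set.seed(70)
  df_of <- function(sizes) {
    obs <- grouped_observations(stats::rnorm(sum(sizes)),
                                rep(seq_along(sizes), times = sizes))
    an <- one_way_anova(obs)
    c(an$df_between, an$df_within)
  }
  expect_equal(df_of(c(5, 5, 5)), c(2, 12))        # 3 stages x 5 videos
  expect_equal(df_of(c(17, 14, 15)), c(2, 43))     # relatedness
  expect_equal(df_of(c(29, 32, 19, 18, 21)), c(4, 114)) # populations
  expect_equal(df_of(c(40, 40, 39)), c(2, 116))    # genetic clusters
  expect_equal(df_of(c(7, 8, 4)), c(2, 16))        # species
})

test_that("ANOVA matches a first-principles sums-of-squares computation", {
  obs <- grouped_observations(c(0, 0, 1, 1, 1, 1, 2, 2),
                              rep(c("a", "b"), each = 4))
  an <- one_way_anova(obs)
  oracle <- brute_force_anova(obs$value, obs$group)
  expect_equal(an$F, oracle$F, tolerance = 1e-10)
  expect_equal(an$p, oracle$p, tolerance = 1e-10)
  expect_equal(an$SS_between, oracle$SS_between, tolerance = 1e-10)
  expect_equal(an$SS_within, oracle$SS_within, tolerance = 1e-10)
  # and on a noisy unbalanced table
  set.seed(71)
  v <- stats::rnorm(26)
  g <- rep(c("a", "b", "c", "d"), times = c(9, 4, 6, 7))
  an2 <- one_way_anova(grouped_observations(v, g))
  or2 <- brute_force_anova(v, g)
  expect_equal(an2$F, or2$F, tolerance = 1e-10)
  expect_equal(an2$p, or2$p, tolerance = 1e-10)
})

test_that("identical groups give F = 0 and p = 1", {
  obs <- grouped_observations(c(1, 2, 3, 1, 2, 3), rep(c("a", "b"), each = 3))
  an <- one_way_anova(obs)
  expect_equal(an$F, 0, tolerance = 1e-12)
  expect_equal(an$p, 1, tolerance = 1e-12)
})

test_that("F is invariant to shifting and scaling the response", {
  set.seed(72)
  v <- stats::rnorm(15)
  g <- rep(c("a", "b", "c"), each = 5)
  f0 <- one_way_anova(grouped_observations(v, g))$F
  expect_equal(one_way_anova(grouped_observations(v + 100, g))$F, f0)
  expect_equal(one_way_anova(grouped_observations(v * 7, g))$F, f0)
})

test_that("degenerate responses are flagged or rejected", {
  # zero within-group variance, different means: infinite F
  an <- one_way_anova(grouped_observations(c(1, 1, 2, 2),
                                           rep(c("a", "b"), each = 2)))
  expect_true(an$infinite_F)
  expect_equal(an$F, Inf)
  expect_equal(an$p, 0)
  # every observation identical: no test possible
  expect_error(one_way_anova(grouped_observations(rep(3, 6),
                                                  rep(c("a", "b"), each = 3))),
               class = "larvagg_degenerate_data")
  expect_error(one_way_anova(grouped_observations(stats::rnorm(5),
                                                  rep("a", 5))),
               class = "larvagg_invalid_observations")
})

test_that("two-group Tukey collapses to the pooled-variance t test", {
  set.seed(73)
  v <- c(stats::rnorm(7), stats::rnorm(9, mean = 0.8))
  g <- rep(c("a", "b"), times = c(7, 9))
  tk <- tukey_hsd(grouped_observations(v, g))
  tt <- stats::t.test(v[g == "b"], v[g == "a"], var.equal = TRUE)
  expect_equal(tk$pairs$p_adj, tt$p.value, tolerance = 1e-8)
})

test_that("Tukey adjusted p values match the studentized-range arithmetic", {
  set.seed(74)
  v <- stats::rnorm(15, mean = rep(c(0, 0.5, 1.5), each = 5))
  g <- rep(c("a", "b", "c"), each = 5)
  obs <- grouped_observations(v, g)
  tk <- tukey_hsd(obs)
  # independent route: q = |diff| / sqrt(MSW/2 * (1/ni + 1/nj)),
  # p from ptukey with k groups and N - k df
  msw <- brute_force_anova(v, g)$SS_within / 12
  for (r in seq_len(nrow(tk$pairs))) {
    mi <- mean(v[g == tk$pairs$group1[r]])
    mj <- mean(v[g == tk$pairs$group2[r]])
    q <- abs(mi - mj) / sqrt(msw / 2 * (1 / 5 + 1 / 5))
    expect_equal(tk$pairs$p_adj[r],
                 stats::ptukey(q, 3, 12, lower.tail = FALSE),
                 tolerance = 1e-6)
  }
  # diff column is signed consistently with the group means
  r1 <- tukey_pair(tk, "a", "b")
  expect_equal(abs(r1$diff), abs(mean(v[g == "a"]) - mean(v[g == "b"])),
               tolerance = 1e-12)
})

test_that("Tukey-Kramer arithmetic holds for unbalanced groups", {
  set.seed(75)
  sizes <- c(17, 14, 15)
  v <- stats::rnorm(sum(sizes))
  g <- rep(c("same", "same_pop", "diff_pop"), times = sizes)
  obs <- grouped_observations(v, g)
  tk <- tukey_hsd(obs)
  msw <- brute_force_anova(v, g)$SS_within / (sum(sizes) - 3)
  ns <- stats::setNames(sizes, c("same", "same_pop", "diff_pop"))
  for (r in seq_len(nrow(tk$pairs))) {
    gi <- tk$pairs$group1[r]; gj <- tk$pairs$group2[r]
    q <- abs(mean(v[g == gi]) - mean(v[g == gj])) /
      sqrt(msw / 2 * (1 / ns[[gi]] + 1 / ns[[gj]]))
    expect_equal(tk$pairs$p_adj[r],
                 stats::ptukey(q, 3, sum(sizes) - 3, lower.tail = FALSE),
                 tolerance = 1e-6)
  }
})

test_that("comparison with the null pseudo-group wires everything together", {
  nd <- build_null_distribution(null_config(5, n_videos = 100, seed = 81))
  set.seed(82)
  scheme <- sampling_scheme(180, 180, 0, 30 * 180)
  # two strongly aggregative groups well below the null
  v <- c(stats::rnorm(5, log(1.5), 0.1), stats::rnorm(5, log(2), 0.1))
  obs <- grouped_observations(v, rep(c("early", "late"), each = 5),
                              n_individuals = 5)
  res <- compare_with_null_group(obs, nd)
  expect_s3_class(res$anova, "anova_result")
  expect_equal(res$anova$df_between, 2) # early, late, random
  expect_equal(res$anova$df_within, 110 - 3)
  expect_true(all(res$classification$label == "aggregative"))
  p_vs_random <- c(tukey_pair(res$tukey, "early", "random")$p_adj,
                   tukey_pair(res$tukey, "late", "random")$p_adj)
  expect_true(all(p_vs_random < 1e-4))
  # incompatible group size is refused
  obs8 <- grouped_observations(v, rep(c("early", "late"), each = 5),
                               n_individuals = 8)
  expect_error(compare_with_null_group(obs8, nd),
               class = "larvagg_incompatible")
  # an empty treatment map is refused
  expect_error(compare_with_null_group(list(), nd))
})

test_that("CSR-drawn groups rarely differ from the null pseudo-group", {
  scheme <- sampling_scheme(180, 180, 0, 30 * 180)
  set.seed(83)
  ok <- vapply(1:50, function(i) {
    nd <- build_null_distribution(null_config(5, n_videos = 100))
    v <- log(vapply(1:8, function(j) {
      summarize_video(simulate_null_video(null_config(5)),
                      scheme)$mean_pairwise_distance
    }, numeric(1)))
    res <- compare_with_null_group(
      grouped_observations(v, rep("obs", 8), n_individuals = 5), nd)
    tukey_pair(res$tukey, "obs", "random")$p_adj > 0.05
  }, logical(1))
  # nominal non-rejection rate 95%; allow generous binomial slack at n=50
  expect_gte(mean(ok), 0.84)
})

test_that("a ln(2) shift from the null is detected essentially always", {
  scheme <- sampling_scheme(180, 180, 0, 30 * 180)
  set.seed(84)
  hits <- vapply(1:20, function(i) {
    nd <- build_null_distribution(null_config(5, n_videos = 100))
    v <- log(vapply(1:15, function(j) {
      summarize_video(simulate_null_video(null_config(5)),
                      scheme)$mean_pairwise_distance
    }, numeric(1))) - log(2)
    res <- compare_with_null_group(
      grouped_observations(v, rep("treat", 15), n_individuals = 5), nd)
    tukey_pair(res$tukey, "treat", "random")$p_adj < 0.001
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("the latitude-style regression F test has the right shape", {
  set.seed(85)
  # 119 videos -> df (1, 117)
  lat <- stats::runif(119, 29, 46)
  v <- stats::rnorm(119, mean = 2)
  an <- continuous_predictor_anova(grouped_observations(v, rep("all", 119),
                                                        covariate = lat))
  expect_equal(c(an$df_between, an$df_within), c(1, 117))
  expect_true(an$p > 0 && an$p < 1)
  # an exactly linear response is detected with certainty
  v2 <- 0.3 + 0.01 * lat
  an2 <- continuous_predictor_anova(grouped_observations(v2, rep("all", 119),
                                                         covariate = lat))
  expect_equal(an2$p, 0)
  expect_equal(an2$r_squared, 1, tolerance = 1e-8)
  # degenerate covariate is refused
  expect_error(
    continuous_predictor_anova(grouped_observations(v, rep("all", 119),
                                                    covariate = rep(1, 119))),
    class = "larvagg_degenerate_covariate")
  expect_error(
    continuous_predictor_anova(grouped_observations(v, rep("all", 119))),
    class = "larvagg_invalid_observations")
})

test_that("the regression slope matches least squares", {
  set.seed(86)
  x <- stats::runif(30, 0, 10)
  y <- 1 + 0.2 * x + stats::rnorm(30, sd = 0.3)
  an <- continuous_predictor_anova(grouped_observations(y, rep("g", 30),
                                                        covariate = x))
  beta <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  expect_equal(an$slope, beta, tolerance = 1e-10)
  expect_equal(an$intercept, mean(y) - beta * mean(x), tolerance = 1e-10)
})
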