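test_that("pairwise distances reproduce hand-computed geometry", {
  expect_equal(pairwise_distances(rbind(c(0, 0), c(3, 4))), 5)
  expect_equal(pairwise_distances(rbind(c(1, 1), c(1, 1), c(1, 1))),
               c(0, 0, 0))
  expect_equal(pairwise_distances(rbind(c(0, 0), c(1, 0), c(0, 1))),
               c(1, 1, sqrt(2)))
  expect_error(pairwise_distances(rbind(c(0, 0))),
               class = "larvagg_invalid_frame")
})

test_that("pairwise distances are symmetric, complete and bounded", {
  set.seed(42)
  a <- larvagg::arena()
  for (n in 2:10) {
    pts <- sample_uniform_in_disk(n, a)
    d <- pairwise_distances(pts)
    expect_length(d, n * (n - 1) / 2)
    expect_true(all(d <= a$diameter_cm))
    expect_equal(d, pairwise_distances(pts[, 2:1])) # reflect coords
  }
  # d(x, y) == d(y, x) and d(x, x) == 0
  for (i in 1:20) {
    xy <- sample_uniform_in_disk(2, a)
    expect_equal(pairwise_distances(xy), pairwise_distances(xy[2:1, ]))
    expect_equal(pairwise_distances(xy[c(1, 1), ]), 0)
  }
  # lexicographic (i < j) order: put a recognisable distance pattern in
  pts <- rbind(c(0, 0), c(1, 0), c(3, 0), c(6, 0))
  expect_equal(pairwise_distances(pts), c(1, 3, 6, 2, 5, 3))
})

test_that("subsampling keeps frames at multiples of the analysis interval", {
  set.seed(1)
  scheme <- sampling_scheme()
  tr360 <- random_raw_track(n = 3, n_frames = 360, interval = 15)
  sub <- subsample_frames(tr360, scheme)
  expect_equal(n_frames(sub), 30)
  expect_equal(sub$time_s, 180 * (0:29))
  # identity when the track is already at analysis cadence
  tr30 <- random_raw_track(n = 3, n_frames = 30, interval = 180)
  s180 <- sampling_scheme(raw_interval_s = 180)
  expect_equal(subsample_frames(tr30, s180)$coords, tr30$coords)
  # a short 24-frame raw track keeps only t = 0 and t = 180
  tr24 <- random_raw_track(n = 3, n_frames = 24, interval = 15)
  sub24 <- subsample_frames(tr24, scheme)
  expect_equal(n_frames(sub24), 2)
  expect_equal(sub24$time_s, c(0, 180))
})

test_that("irregular frame spacing is rejected with the frame named", {
  set.seed(2)
  tr <- random_raw_track(n = 2, n_frames = 10, interval = 15)
  tr$time_s[6] <- tr$time_s[6] + 7 # 7-s jitter exceeds the 0.5-s slack
  err <- expect_error(subsample_frames(tr, sampling_scheme()),
                      class = "larvagg_sampling_error")
  expect_match(conditionMessage(err), "frames 5 and 6")
})

test_that("acclimation trimming drops exactly the leading frames", {
  set.seed(3)
  tr30 <- random_raw_track(n = 3, n_frames = 30, interval = 180)
  s <- function(k) sampling_scheme(180, 180, k, 30 * 180)
  expect_equal(n_frames(trim_acclimation(tr30, s(12))), 18)
  expect_equal(trim_acclimation(tr30, s(0))$coords, tr30$coords)
  tr13 <- random_raw_track(n = 3, n_frames = 13, interval = 180)
  trimmed <- trim_acclimation(tr13, s(12))
  expect_equal(n_frames(trimmed), 1)
  expect_equal(trimmed$time_s, tr13$time_s[13])
  expect_error(trim_acclimation(tr13, sampling_scheme(180, 180, 13, 14 * 180)),
               class = "larvagg_empty_track")
})

test_that("summarize_video pools distances and logs them", {
  # two individuals fixed 5 cm apart for the whole default-cadence video
  tr <- constant_track(rbind(c(0, 0), c(3, 4)), n_frames = 360, interval = 15)
  sm <- summarize_video(tr, sampling_scheme())
  expect_equal(sm$n_frames_used, 18)
  expect_equal(sm$mean_pairwise_distance, 5)
  expect_equal(sm$log_mean_pairwise_distance, log(5))
  # single retained frame, hand-computed distances
  tr1 <- video_track("one", 0, rbind(c(0, 0), c(1, 0), c(0, 1)))
  sm1 <- summarize_video(tr1, sampling_scheme(180, 180, 0, 180))
  expect_equal(sm1$mean_pairwise_distance, (1 + 1 + sqrt(2)) / 3)
  expect_equal(sm1$log_mean_pairwise_distance, log((2 + sqrt(2)) / 3))
  expect_equal(nrow(sm1$per_frame_means), 1)
})

test_that("summary equals brute-force pooling of the retained raw frames", {
  set.seed(4)
  scheme <- sampling_scheme()
  for (n in c(2, 5)) {
    tr <- random_raw_track(n = n, n_frames = 360, interval = 15)
    sm <- summarize_video(tr, scheme)
    expect_equal(sm$mean_pairwise_distance,
                 brute_force_pooled_mean(tr, scheme), tolerance = 1e-12)
    expect_equal(sm$n_frames_used, 18)
    expect_equal(nrow(sm$per_frame_means), 18)
  }
})

test_that("the log transform preserves the ranking of videos", {
  set.seed(5)
  sms <- lapply(1:8, function(i) {
    summarize_video(random_raw_track(n = 3, n_frames = 360), sampling_scheme())
  })
  m <- vapply(sms, `[[`, numeric(1), "mean_pairwise_distance")
  lg <- vapply(sms, `[[`, numeric(1), "log_mean_pairwise_distance")
  expect_equal(order(m), order(lg))
})

test_that("an all-coincident video raises a log-undefined error", {
  tr <- constant_track(rbind(c(1, 1), c(1, 1)), n_frames = 30, interval = 180)
  expect_error(summarize_video(tr, sampling_scheme(180, 180, 0, 30 * 180)),
               class = "larvagg_log_undefined")
})

test_that("track and scheme invariants are enforced at construction", {
  expect_error(video_track("v", 0, rbind(c(0, 0))),
               class = "larvagg_invalid_track")
  expect_error(video_track("v", c(0, 0), array(0, c(2, 2, 2))),
               class = "larvagg_invalid_track")
  expect_error(video_track("v", 0, rbind(c(10, 10), c(0, 0))),
               class = "larvagg_outside_arena")
  # a point exactly on the wall is legal
  expect_silent(video_track("v", 0, rbind(c(7.25, 0), c(0, 0))))
  expect_error(sampling_scheme(15, 100), class = "larvagg_invalid_scheme")
  expect_error(sampling_scheme(15, 180, 30, 5400),
               class = "larvagg_invalid_scheme")
  expect_error(arena(-1), class = "larvagg_invalid_arena")
})
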