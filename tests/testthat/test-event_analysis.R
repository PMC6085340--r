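test_that("event detection finds threshold crossings and durations", {
  t <- seq(0, 10, by = 0.1)
  v <- as.numeric(t >= 3.0 & t < 5.5)
  ev <- detect_events(tibble::tibble(time_s = t, value = v), hands = "left")
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$onset_s, 3.0)
  expect_equal(ev$duration_s, 2.5)
  flat <- detect_events(tibble::tibble(time_s = t, value = 0 * t))
  expect_equal(nrow(flat), 0L)
  # trailing unmatched onset dropped with a warning
  v2 <- as.numeric(t >= 8)
  expect_warning(ev2 <- detect_events(tibble::tibble(time_s = t, value = v2)),
                 "trailing")
  expect_equal(nrow(ev2), 0L)
})

test_that("the generator's sensor trace reproduces its event log", {
  ses <- quick_session()
  ev <- detect_events(ses$sensor, hands = ses$events$hand)
  expect_equal(nrow(ev), nrow(ses$events))
  expect_lt(max(abs(ev$onset_s - ses$events$onset_s)), 0.13)
  expect_equal(ev$hand, ses$events$hand)
})

# small deterministic hemodynamic series: two channels, both species
toy_hb <- function(curves, events, dt = 0.13, n_t = 400) {
  # curves: function(channel, species, hand) -> response scale
  t <- (0:(n_t - 1)) * dt
  rows <- list()
  bump <- exp(-(seq(0, 5, by = dt) - 2)^2 / 0.5)
  for (chn in 1:2) for (sp in c("HbO", "HbR")) {
    y <- numeric(n_t)
    for (k in seq_len(nrow(events))) {
      i0 <- round(events$onset_s[k] / dt) + 1
      idx <- i0 + seq_along(bump) - 1
      ok <- idx <= n_t
      y[idx[ok]] <- y[idx[ok]] +
        curves(chn, sp, events$hand[k]) * bump[ok]
    }
    rows[[length(rows) + 1]] <- tibble::tibble(
      time_s = t, channel = chn, species = sp, delta_umol = y)
  }
  dplyr::bind_rows(rows)
}

toy_events <- function(n = 8, iti = 6) {
  tibble::tibble(trial = 1:n, onset_s = 5 + (0:(n - 1)) * iti,
                 end_s = 5.5 + (0:(n - 1)) * iti,
                 hand = rep(c("left", "right"), length.out = n),
                 duration_s = 0.5)
}

test_that("block averages of identical trials have zero SD and the trial shape", {
  ev <- toy_events()
  hb <- toy_hb(function(ch, sp, hand) 1, ev)
  blk <- epoch_and_average(hb, ev, window = c(-1, 4))
  expect_true(all(blk$sd < 1e-6))
  expect_equal(unique(blk$n_trials), 4L)
  one <- blk[blk$channel == 1 & blk$species == "HbO" & blk$hand == "left", ]
  i_peak <- which.max(one$mean)
  expect_equal(one$time_s[i_peak], 2.0, tolerance = 0.14)  # bump peak ~2 s
})

test_that("epochs falling outside the recording are dropped with a warning", {
  ev <- toy_events()
  ev$onset_s[8] <- 51   # too close to the end for a +4 s window
  hb <- toy_hb(function(ch, sp, hand) 1, ev)
  expect_warning(blk <- epoch_and_average(hb, ev, window = c(-1, 4)),
                 "dropped")
  expect_equal(sort(unique(blk$n_trials)), c(3L, 4L))
})

test_that("paired t-curves match the textbook computation on a toy table", {
  left <- c(1.2, 0.9, 1.1, 1.4, 1.0)
  right <- c(0.7, 0.8, 0.6, 1.0, 0.7)
  ev <- toy_events(10)   # alternating left/right: 5 pairs in temporal order
  scales <- ifelse(ev$hand == "left", left[ceiling(seq_len(10) / 2)],
                   right[ceiling(seq_len(10) / 2)])
  dt <- 0.13
  bump <- exp(-(seq(0, 5, by = dt) - 2)^2 / 0.5)
  y <- numeric(520)
  for (k in 1:10) {
    i0 <- round(ev$onset_s[k] / dt) + 1
    idx <- i0 + seq_along(bump) - 1; ok <- idx <= 520
    y[idx[ok]] <- y[idx[ok]] + scales[k] * bump[ok]
  }
  hb <- toy_hb(function(ch, sp, hand) 0, ev, n_t = 520)
  hb$delta_umol[hb$channel == 1 & hb$species == "HbO"] <- y
  tc <- paired_t_curve(hb, ev, window = c(0, 4))
  sub <- tc[tc$channel == 1 & tc$species == "HbO", ]
  i_peak <- which.min(abs(sub$time_s - 1.95))
  # oracle: stats::t.test on the five (left, right) pairs; at any fixed
  # epoch sample the response is scale * bump-gain, so t is scale-free in
  # the gain and matches the paired test on the scales themselves
  tt <- t.test(left, right, paired = TRUE)
  expect_equal(sub$t[i_peak], unname(tt$statistic), tolerance = 1e-6)
  expect_equal(sub$df[i_peak], 4)
  expect_equal(sub$p[i_peak], tt$p.value, tolerance = 1e-6)
})

test_that("identical groups give t = 0 and label swaps negate t exactly", {
  ev <- toy_events()
  hb <- toy_hb(function(ch, sp, hand) 1, ev)
  tc <- paired_t_curve(hb, ev, window = c(0, 4))
  expect_true(all(tc$t == 0))
  expect_true(all(tc$p == 1))
  hb2 <- toy_hb(function(ch, sp, hand) if (hand == "left") 1.5 else 0.5, ev)
  tc2 <- paired_t_curve(hb2, ev, window = c(0, 4))
  ev_sw <- dplyr::mutate(ev, hand = ifelse(hand == "left", "right", "left"))
  tc_sw <- paired_t_curve(hb2, ev_sw, window = c(0, 4))
  expect_equal(tc_sw$t, -tc2$t)
  expect_error(paired_t_curve(hb2, ev[1:3, ], window = c(0, 4)), "equal")
})

test_that("peak metrics are gated by the t-curve and signed by the extremum", {
  ev <- toy_events()
  hb <- toy_hb(function(ch, sp, hand) {
    base <- if (hand == "left") 1.6 else 0.4       # lateralized -> gate fires
    if (ch == 2) base <- 1                         # identical -> no gate
    if (sp == "HbR") -0.5 * base else base
  }, ev)
  blk <- epoch_and_average(hb, ev, window = c(0, 4))
  tc <- paired_t_curve(hb, ev, window = c(0, 4))
  pm <- peak_metrics(blk, tc)
  g1 <- pm[pm$channel == 1, ]
  expect_true(all(g1$significant))
  # HbO peak positive at the bump time; HbR valley negative
  hbo <- g1[g1$species == "HbO" & g1$hand == "left", ]
  hbr <- g1[g1$species == "HbR" & g1$hand == "left", ]
  expect_gt(hbo$max_amplitude, 0)
  expect_lt(hbr$max_amplitude, 0)
  expect_equal(hbo$time_of_max_s, 2.0, tolerance = 0.14)
  g2 <- pm[pm$channel == 2, ]
  expect_true(all(!g2$significant))
  expect_true(all(is.na(g2$max_amplitude)))
})

test_that("Pearson correlations match the closed-form covariance formula", {
  x <- c(1, 2, 4, 7); y <- c(2, 3, 9, 12)
  r_closed <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  ev <- toy_events(4)
  # build block with exactly these as HbO/HbR curves
  blk <- tibble::tibble(
    channel = 1L, species = rep(c("HbO", "HbR"), each = 4),
    hand = "left", time_s = rep(1:4, 2), mean = c(x, y), sd = 0,
    n_trials = 2L)
  class(blk) <- c("block_average", class(blk))
  out <- hbo_hbr_correlation(blk)
  expect_equal(out$r, r_closed, tolerance = 1e-12)
  # exact proportionality gives r = -1
  blk2 <- blk
  blk2$mean[blk2$species == "HbR"] <- -0.3 * x
  expect_equal(hbo_hbr_correlation(blk2)$r, -1)
  blk3 <- blk
  blk3$mean[blk3$species == "HbR"] <- 5
  expect_true(hbo_hbr_correlation(blk3)$degenerate)
})

test_that("independent noise gives small, insignificant HbO-HbR correlations", {
  ok <- 0
  for (s in 1:50) {
    set.seed(400 + s)
    blk <- tibble::tibble(
      channel = 1L, species = rep(c("HbO", "HbR"), each = 120),
      hand = "left", time_s = rep(1:120, 2), mean = rnorm(240), sd = 0,
      n_trials = 2L)
    class(blk) <- c("block_average", class(blk))
    if (hbo_hbr_correlation(blk)$p > 0.05) ok <- ok + 1
  }
  expect_gte(ok, 45)
})

test_that("hemisphere averages correlate with behavior (r = 1 when linear)", {
  sessions <- 1:4
  metrics <- dplyr::bind_rows(lapply(sessions, function(s) {
    tibble::tibble(session = s, channel = c(16L, 19L),
                   side = c("left", "right"),
                   species = "HbO", hand = c("right", "left"),
                   significant = TRUE,
                   max_amplitude = 0.5 + 0.25 * s,
                   time_of_max_s = 2 + 0.1 * s)
  }))
  behavior <- tibble::tibble(session = sessions,
                             retrieval_time_s = 0.8 + 0.2 * sessions)
  out <- hemisphere_average_and_correlate(metrics, behavior)
  expect_equal(out$r, rep(1, nrow(out)), tolerance = 1e-9)
  expect_error(
    hemisphere_average_and_correlate(metrics[metrics$session < 3, ],
                                     behavior[1:2, ]),
    "3 sessions")
})

test_that("Box-Cox at lambda = -1 matches its closed form", {
  expect_equal(boxcox_neg1(1), 0)
  expect_equal(boxcox_neg1(2), 0.5)
  expect_error(boxcox_neg1(c(1, 0, 2)), "non-positive")
})

test_that("Bartlett p-values are null-uniform for equal-variance groups", {
  # groups built so the lambda = -1 transform is exactly normal
  pvals <- sapply(1:200, function(s) {
    set.seed(7000 + s)
    z <- rnorm(90, 0.2, 0.1)        # transformed scale, well below 1
    x <- 1 / (1 - z)                # inverse of 1 - 1/x
    g <- rep(c("a.left", "a.right", "b.left"), each = 30)
    bs <- behavior_stats(tibble::tibble(
      session = sub("\\..*", "", g), hand = sub(".*\\.", "", g),
      duration_s = x))
    bs$bartlett$p.value
  })
  ks <- stats::ks.test(pvals, "punif")
  expect_gt(ks$p.value, 0.01)
})

test_that("Tukey-Kramer flags exactly the shifted group pairs", {
  set.seed(99)
  base <- 1 / (1 - rnorm(40, 0.2, 0.05))
  shifted <- 1 / (1 - rnorm(35, 0.5, 0.05))   # big mean shift, unequal n
  ev <- tibble::tibble(
    session = rep(c("s1", "s1", "s2"), times = c(40, 40, 35)),
    hand = rep(c("left", "right", "left"), times = c(40, 40, 35)),
    duration_s = c(base, 1 / (1 - rnorm(40, 0.2, 0.05)), shifted))
  bs <- behavior_stats(ev)
  td <- tidy(bs)
  flagged <- td$contrast[td$adj_p < 0.01]
  expect_setequal(flagged, c("s2.left-s1.left", "s2.left-s1.right"))
  gl <- glance(bs)
  expect_lt(gl$anova_p, 0.01)
  expect_named(gl, c("bartlett_stat", "bartlett_p", "anova_f", "anova_p",
                     "df_between", "df_within"))
})

test_that("event logs round-trip through CSV", {
  ev <- toy_events()
  f <- withr::local_tempfile(fileext = ".csv")
  write_event_log(ev, f)
  back <- read_event_log(f)
  expect_equal(as.data.frame(back), as.data.frame(ev))
})
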