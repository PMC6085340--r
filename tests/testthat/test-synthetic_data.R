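test_that("simulated behavior has the session structure and is seed-deterministic", {
  cfg <- sim_config()
  ev <- simulate_behavior(cfg, 123)
  expect_equal(nrow(ev), 150L)
  expect_equal(as.integer(table(ev$hand)), c(75L, 75L))
  expect_true(all(diff(ev$onset_s) > 0))
  expect_true(all(ev$duration_s > 0))
  # mean inter-trial interval near 20 s
  expect_equal(mean(diff(ev$onset_s)), 20, tolerance = 0.1)
  expect_identical(simulate_behavior(cfg, 123), ev)
  expect_false(identical(simulate_behavior(cfg, 124)$onset_s, ev$onset_s))
})

test_that("retrieval duration means are recovered within 2 standard errors", {
  cfg <- sim_config()
  ev <- simulate_behavior(cfg, 321)
  for (h in c("left", "right")) {
    x <- log(ev$duration_s[ev$hand == h])
    mu <- cfg$duration_meanlog + log(cfg$duration_hand_factor[[h]])
    se <- cfg$duration_sdlog / sqrt(length(x))
    expect_lt(abs(mean(x) - mu), 2.5 * se)
  }
})

test_that("hand-M1 responses are strictly contralateral in the ground truth", {
  cfg <- quick_config()
  ev <- simulate_behavior(cfg, 5)
  ch <- paper_channels()
  tr <- suppressMessages(simulate_hemodynamics(ev, ch, cfg, 6))
  dt <- cfg$sample_interval_s
  left_m1 <- which(ch$region == "hand_M1" & ch$side == "left")
  right_m1 <- which(ch$region == "hand_M1" & ch$side == "right")
  for (k in which(ev$hand == "left")[1:3]) {
    idx <- round(ev$onset_s[k] / dt) + 1 + round(2.43 / dt)
    expect_true(all(abs(tr$hbo[idx, left_m1]) < 1e-12) ||
                  all(tr$hbo[idx, left_m1] <
                        0.05 * max(tr$hbo[idx, right_m1])))
    expect_gt(max(tr$hbo[idx, right_m1]), 0.5)
  }
})

test_that("noise-free single-trial peaks land at the configured latencies", {
  cfg <- sim_config(n_trials = 2, amplitude_cv = 0, channel_gain_sd = 0,
                    iti_s = 40, amplitude_coupling = 0, time_coupling = 0)
  ev <- simulate_behavior(cfg, 9)
  ch <- paper_channels()
  tr <- suppressMessages(simulate_hemodynamics(ev, ch, cfg, 10))
  dt <- cfg$sample_interval_s
  for (reg in c("PMA", "hand_M1", "mouth_M1")) {
    ci <- which(ch$region == reg)[1]
    k <- if (reg == "hand_M1") {
      which(ev$hand == setdiff(c("left", "right"), ch$side[ci]))[1]
    } else 1
    i0 <- round(ev$onset_s[k] / dt) + 1
    win <- i0 + seq(0, round(12 / dt))
    tpk <- (which.max(tr$hbo[win, ci]) - 1) * dt
    expect_equal(tpk, cfg$regions[[reg]]$peak_time_s, tolerance = dt + 1e-9)
  }
})

test_that("coupled-mode HbR is exactly anti-proportional to HbO", {
  ses <- quick_session()
  expect_equal(ses$truth$hbr, -ses$truth$config$hbr_ratio * ses$truth$hbo)
  active <- which(colSums(abs(ses$truth$hbo)) > 0)
  for (ci in active[1:3]) {
    expect_equal(cor(ses$truth$hbo[, ci], ses$truth$hbr[, ci]), -1)
  }
  cfg0 <- quick_config(hbr_mode = "zero")
  ev <- simulate_behavior(cfg0, 2)
  tr0 <- suppressMessages(
    simulate_hemodynamics(ev, paper_channels(), cfg0, 3))
  expect_true(all(tr0$hbr == 0))
})

test_that("restraint modes reroute or silence responses", {
  chm <- paper_channels()
  cfg_r <- quick_config(restraint = "right_restrained")
  ev_r <- simulate_behavior(cfg_r, 31)
  expect_true(all(ev_r$hand == "left"))
  tr_r <- suppressMessages(simulate_hemodynamics(ev_r, chm, cfg_r, 32))
  left_m1 <- which(chm$region == "hand_M1" & chm$side == "left")
  right_m1 <- which(chm$region == "hand_M1" & chm$side == "right")
  expect_equal(max(abs(tr_r$hbo[, left_m1])), 0)
  expect_gt(max(tr_r$hbo[, right_m1]), 0.5)
  cfg_m <- quick_config(restraint = "mouth_only")
  tr_m <- suppressMessages(
    simulate_hemodynamics(simulate_behavior(cfg_m, 33), chm, cfg_m, 34))
  mouth <- which(chm$region == "mouth_M1")
  other <- which(!chm$region %in% c("mouth_M1", "unassigned"))
  expect_gt(max(tr_m$hbo[, mouth]), 0.3)
  expect_equal(max(abs(tr_m$hbo[, other])), 0)
})

test_that("noise/drift-free sessions invert exactly; drift is removed by detrend", {
  ses0 <- simulate_session(quick_config(), seed = 77, noise = FALSE,
                           drift = FALSE)
  hb0 <- process_absorbance(ses0$absorbance, ses0$path_lengths,
                            detrend = FALSE, cutoff_hz = NULL)
  truth0 <- tidy(ses0$truth)
  m0 <- dplyr::inner_join(hb0, dplyr::rename(truth0, truth = delta_umol),
                          by = c("time_s", "channel", "species"))
  expect_lt(max(abs(m0$delta_umol - m0$truth)), 1e-8)

  ses1 <- simulate_session(quick_config(), seed = 78, noise = FALSE,
                           drift = TRUE)
  hb1 <- process_absorbance(ses1$absorbance, ses1$path_lengths)
  ref1 <- pipeline_reference_truth(ses1$truth)
  m1 <- dplyr::inner_join(hb1, dplyr::rename(ref1, truth = delta_umol),
                          by = c("time_s", "channel", "species"))
  active <- ses1$channels$channel[ses1$channels$region != "unassigned"]
  rel <- m1 |>
    dplyr::filter(channel %in% active) |>
    dplyr::group_by(channel, species) |>
    dplyr::summarise(rel = sqrt(mean((delta_umol - truth)^2)) /
                       sqrt(mean(truth^2)), .groups = "drop")
  expect_lt(max(rel$rel), 0.01)
})

test_that("two channels with equal hemodynamics but different path lengths calibrate equally", {
  cfg <- quick_config()
  chm <- tibble::tibble(channel = 1:2, region = "mouth_M1", side = "left")
  cfg$channel_gain_sd <- 0
  ev <- simulate_behavior(cfg, 55)
  tr <- simulate_hemodynamics(ev, chm, cfg, 56)
  pl <- tibble::tibble(channel = rep(1:2, each = 3),
                       wavelength_nm = rep(c(780, 805, 830), 2),
                       l_mm = rep(c(2.5, 6), each = 3))
  fw <- forward_absorbance(tr, path_lengths = pl, seed = 57,
                           noise = FALSE, drift = FALSE)
  cal <- calibrate_by_path_length(average_duplicates(fw$absorbance), pl)
  w <- tidyr::pivot_wider(cal, names_from = "channel",
                          values_from = "od_per_mm")
  expect_equal(w$`1`, w$`2`, tolerance = 1e-12)
})

test_that("full sessions are reproducible from (config, seed)", {
  a <- simulate_session(quick_config(), seed = 99)
  b <- simulate_session(quick_config(), seed = 99)
  expect_identical(a$absorbance, b$absorbance)
  expect_identical(a$events, b$events)
  expect_identical(a$sensor, b$sensor)
})
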