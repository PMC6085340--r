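dup_fixture <- function(od_a, od_b, cycles = length(od_a)) {
  tibble::tibble(
    cycle = rep(seq_len(cycles), each = 2),
    time_s = rep((seq_len(cycles) - 1) * 0.13, each = 2),
    channel = 1L, wavelength_nm = 805,
    direction = rep(c("ab", "ba"), cycles),
    od = as.numeric(rbind(od_a, od_b)))
}

test_that("duplicate averaging is the per-cycle arithmetic mean", {
  out <- average_duplicates(dup_fixture(c(0.10, 0.3), c(0.12, 0.3)))
  expect_equal(out$od, c(0.11, 0.3))
  expect_equal(nrow(out), 2L)           # one sample per cycle
  broken <- dup_fixture(0.1, 0.2)[-2, ]
  extra <- dplyr::bind_rows(broken, dup_fixture(0.5, 0.6)[1, ])
  expect_error(average_duplicates(broken), "odd number")
  expect_error(average_duplicates(extra), "missing directed")
})

test_that("path-length calibration divides by L and validates it", {
  df <- tibble::tibble(time_s = 0, channel = 1L, wavelength_nm = 805,
                       od = 0.02)
  pl <- tibble::tibble(channel = 1L, wavelength_nm = 805, l_mm = 4)
  expect_equal(calibrate_by_path_length(df, pl)$od_per_mm, 0.005)
  pl2 <- dplyr::mutate(pl, l_mm = 8)
  expect_equal(calibrate_by_path_length(df, pl2)$od_per_mm, 0.0025)
  expect_error(calibrate_by_path_length(df, dplyr::mutate(pl, l_mm = 0)),
               "positive")
  expect_error(
    calibrate_by_path_length(dplyr::mutate(df, wavelength_nm = 830), pl),
    "830")
})

series_fixture <- function(values, dt = 0.13) {
  tibble::tibble(time_s = (seq_along(values) - 1) * dt, channel = 1L,
                 wavelength_nm = 805, od_per_mm = values)
}

test_that("cubic detrending removes polynomials exactly and keeps sinusoids", {
  t <- (0:999) * 0.13
  cubic <- 2 + 0.01 * t - 1e-4 * t^2 + 5e-7 * t^3
  out <- detrend_poly3(series_fixture(cubic))
  expect_lt(max(abs(out$od_per_mm)), 1e-8)
  expect_lt(max(abs(detrend_poly3(series_fixture(rep(3, 100)))$od_per_mm)),
            1e-10)
  sinus <- sin(2 * pi * 1.5 * t)
  out2 <- detrend_poly3(series_fixture(cubic + sinus))
  expect_lt(sqrt(mean((out2$od_per_mm - sinus)^2)) / sqrt(mean(sinus^2)),
            0.01)
  expect_lt(abs(mean(out2$od_per_mm)), 1e-10)
  expect_error(detrend_poly3(series_fixture(1:5)), "at least 8")
})

test_that("the Butterworth low-pass has unit DC gain and the textbook roll-off", {
  t <- (0:4999) * 0.13
  expect_equal(butterworth_lowpass(series_fixture(rep(1, 200)))$od_per_mm,
               rep(1, 200), tolerance = 1e-6)
  slow <- sin(2 * pi * 0.05 * t)
  out <- butterworth_lowpass(series_fixture(slow))
  core <- 500:4500   # avoid edge transients
  expect_lt(max(abs(out$od_per_mm[core] - slow[core])), 0.02)
  fast <- sin(2 * pi * 3 * t)
  outf <- butterworth_lowpass(series_fixture(fast))
  atten_db <- -20 * log10(max(abs(outf$od_per_mm[core])))
  expect_gt(atten_db, 24)
  expect_error(butterworth_lowpass(series_fixture(slow), cutoff_hz = 4),
               "Nyquist")
})

mbll_fixture <- function(hbo_umol, hbr_umol, extinction, l_mm = 1) {
  wl <- sort(unique(extinction$wavelength_nm))
  rows <- lapply(wl, function(w) {
    eo <- extinction$epsilon[extinction$species == "HbO" &
                               extinction$wavelength_nm == w]
    er <- extinction$epsilon[extinction$species == "HbR" &
                               extinction$wavelength_nm == w]
    tibble::tibble(
      time_s = (seq_along(hbo_umol) - 1) * 0.13, channel = 1L,
      wavelength_nm = w,
      od_per_mm = (eo * hbo_umol / 1000 + er * hbr_umol / 1000))
  })
  dplyr::bind_rows(rows)
}

test_that("MBLL inversion round-trips forward-generated concentrations", {
  ext <- default_extinction_table()
  df <- mbll_fixture(rep(1.0, 5), rep(-0.5, 5), ext)
  hb <- mbll_transform(df, ext)
  expect_equal(hb$delta_umol[hb$species == "HbO"], rep(1.0, 5),
               tolerance = 1e-10)
  expect_equal(hb$delta_umol[hb$species == "HbR"], rep(-0.5, 5),
               tolerance = 1e-10)
  zero <- mbll_transform(mbll_fixture(rep(0, 4), rep(0, 4), ext), ext)
  expect_true(all(zero$delta_umol == 0))
})

test_that("MBLL rejects degenerate extinction tables", {
  ext <- default_extinction_table()
  df <- mbll_fixture(1, -0.5, ext)
  expect_error(mbll_transform(dplyr::filter(df, wavelength_nm == 780), ext),
               "two wavelengths")
  # proportional columns: rank-deficient 2x2 system
  ext2 <- tibble::tibble(species = rep(c("HbO", "HbR"), each = 2),
                         wavelength_nm = rep(c(780, 830), 2),
                         epsilon = c(0.1, 0.2, 0.05, 0.1))
  df2 <- dplyr::filter(df, wavelength_nm %in% c(780, 830))
  expect_error(mbll_transform(df2, ext2), "rank deficient")
})

test_that("MBLL noise propagation stays within the pseudo-inverse bound", {
  ext <- default_extinction_table()
  n <- 4000
  sigma <- 1e-4
  df <- mbll_fixture(rep(1.0, n), rep(-0.4, n), ext)
  with_seed <- function(seed, code) { set.seed(seed); code }
  df$od_per_mm <- df$od_per_mm + with_seed(1, rnorm(nrow(df), 0, sigma))
  hb <- mbll_transform(df, ext)
  E <- matrix(ext$epsilon[order(ext$species, ext$wavelength_nm)], ncol = 2,
              dimnames = list(NULL, c("HbO", "HbR")))
  pinv <- solve(crossprod(E), t(E))
  for (i in 1:2) {
    sp <- c("HbO", "HbR")[i]
    true <- c(1.0, -0.4)[i]
    sd_prop <- sqrt(sum(pinv[i, ]^2)) * sigma * 1000   # umol per sample
    bias <- abs(mean(hb$delta_umol[hb$species == sp]) - true)
    expect_lt(bias, 3 * sd_prop / sqrt(n))
  }
})

test_that("the chain is linear in the input absorbance", {
  ses <- quick_session()
  hb1 <- process_absorbance(ses$absorbance, ses$path_lengths)
  ab3 <- dplyr::mutate(ses$absorbance, od = 3 * od)
  hb3 <- process_absorbance(ab3, ses$path_lengths)
  expect_equal(hb3$delta_umol, 3 * hb1$delta_umol, tolerance = 1e-9)
})
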