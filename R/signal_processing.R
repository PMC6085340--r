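## Absorbance-to-hemoglobin pipeline: duplicate averaging, partial-path
## calibration, cubic detrending, zero-phase Butterworth low-pass, and
## modified Beer-Lambert inversion. All stages take and return tidy
## tibbles; heavy lifting happens on time-by-series matrices internally.

# reshape a tidy series to a time-by-series matrix; series are defined by
# the key columns, data must lie on a uniform time grid
# numeric compound key used to skip the arrange() when input is already
# in canonical (keys, time) order -- the common case in the pipeline
series_sort_key <- function(df, key_cols) {
  k <- 0
  for (col in key_cols) {
    v <- df[[col]]
    if (!is.numeric(v)) v <- match(v, sort(unique(v)))
    rng <- range(v)
    k <- k * (rng[2] - rng[1] + 1) + (v - rng[1])
  }
  t <- df$time_s
  k * (max(t) - min(t) + 1) + (t - min(t))
}

series_wide <- function(df, value_col, key_cols) {
  if (is.unsorted(series_sort_key(df, key_cols))) {
    df <- arrange(df, dplyr::across(dplyr::all_of(c(key_cols, "time_s"))))
  }
  times <- sort(unique(df$time_s))
  n_t <- length(times)
  if (nrow(df) %% n_t != 0) {
    abort("series are not on a common uniform time grid")
  }
  n_k <- nrow(df) / n_t
  M <- matrix(df[[value_col]], nrow = n_t, ncol = n_k)
  keys <- df[seq(1, nrow(df), by = n_t), key_cols, drop = FALSE]
  list(times = times, M = M, keys = as_tibble(keys))
}

series_long <- function(wide, value_col) {
  n_t <- length(wide$times)
  out <- wide$keys[rep(seq_len(nrow(wide$keys)), each = n_t), , drop = FALSE]
  out$time_s <- rep(wide$times, nrow(wide$keys))
  out[[value_col]] <- as.numeric(wide$M)
  relocate(as_tibble(out), "time_s")
}

sample_interval <- function(times) {
  dt <- diff(sort(unique(times)))
  if (length(dt) == 0) abort("need at least two time points")
  if (max(dt) - min(dt) > 1e-6 * median(dt)) {
    abort("time base is not uniformly sampled")
  }
  median(dt)
}

#' Average the two directed measurements of each channel per cycle
#'
#' In a bidirectional array every channel is measured twice per switching
#' cycle (a to b, then b to a); their arithmetic mean is one sample per
#' cycle (130 ms in the reference configuration).
#'
#' @param df Tibble with columns `cycle`, `time_s`, `channel`,
#'   `wavelength_nm`, `direction`, `od`.
#' @return Tibble `time_s`, `channel`, `wavelength_nm`, `od`, one row per
#'   (cycle, channel, wavelength).
#' @export
average_duplicates <- function(df) {
  # direction is deliberately left out of the key: the two directed
  # measurements of a pair tie, and the pair check below validates them
  key <- (df$channel * 2001 + df$wavelength_nm) *
    (max(df$cycle) + 1) + df$cycle
  if (is.unsorted(key)) {
    df <- arrange(df, .data$channel, .data$wavelength_nm, .data$cycle,
                  .data$direction)
  }
  if (nrow(df) %% 2 != 0) abort("odd number of directed measurements")
  odd <- seq(1, nrow(df), by = 2)
  even <- odd + 1
  same <- df$cycle[odd] == df$cycle[even] &
    df$channel[odd] == df$channel[even] &
    df$wavelength_nm[odd] == df$wavelength_nm[even] &
    df$direction[odd] != df$direction[even]
  if (!all(same)) {
    bad <- which(!same)[1]
    abort(paste0("missing directed measurement near cycle ",
                 df$cycle[odd[bad]], ", channel ", df$channel[odd[bad]]))
  }
  tibble(time_s = df$time_s[odd], channel = df$channel[odd],
         wavelength_nm = df$wavelength_nm[odd],
         od = (df$od[odd] + df$od[even]) / 2)
}

#' Calibrate absorbance by simulated partial optical path length
#'
#' Divides each channel/wavelength absorbance by its partial optical path
#' length from the photon-transport simulation, yielding per-unit-path
#' absorbance (OD/mm) so that hemodynamic responses are comparable across
#' channels with different depth sensitivities. The gray-matter partial
#' path length is the default calibration denominator (the comparison of
#' interest is cortical); a table of total mean path lengths can be
#' supplied instead.
#'
#' @param df Tibble `time_s`, `channel`, `wavelength_nm`, `od`.
#' @param path_lengths Tibble `channel`, `wavelength_nm`, `l_mm` (> 0).
#' @return Tibble with `od` replaced by calibrated `od_per_mm`.
#' @export
calibrate_by_path_length <- function(df, path_lengths) {
  need <- distinct(df, .data$channel, .data$wavelength_nm)
  got <- inner_join(need, path_lengths, by = c("channel", "wavelength_nm"))
  if (nrow(got) < nrow(need)) {
    miss <- dplyr::anti_join(need, path_lengths,
                             by = c("channel", "wavelength_nm"))
    abort(paste0("no path length for channel ", miss$channel[1],
                 " at ", miss$wavelength_nm[1], " nm"))
  }
  if (any(!is.finite(path_lengths$l_mm) | path_lengths$l_mm <= 0)) {
    abort("path lengths must be positive and finite")
  }
  idx <- match(df$channel * 1e4 + df$wavelength_nm,
               path_lengths$channel * 1e4 + path_lengths$wavelength_nm)
  out <- df
  out$od_per_mm <- out$od / path_lengths$l_mm[idx]
  select(out, -"od")
}

#' Remove session-scale baseline drift by cubic fitting
#'
#' Fits and subtracts a least-squares third-degree polynomial over the
#' whole session, independently per channel and wavelength. Optode-coupling
#' drift is a session-scale phenomenon, so the fit spans the full recording
#' rather than individual trials.
#'
#' @param df Tidy series tibble.
#' @param value_col Name of the value column (default `"od_per_mm"`).
#' @return Same shape, detrended (column means approximately zero).
#' @export
detrend_poly3 <- function(df, value_col = "od_per_mm") {
  key_cols <- setdiff(names(df), c("time_s", value_col))
  w <- series_wide(df, value_col, key_cols)
  if (length(w$times) < 8) abort("need at least 8 samples to fit a cubic")
  X <- cbind(1, stats::poly(w$times, 3))
  w$M <- w$M - X %*% qr.coef(qr(X), w$M)
  series_long(w, value_col)
}

#' Zero-phase Butterworth low-pass filter
#'
#' Removes high-frequency noise with a fourth-order Butterworth low-pass
#' at 0.7 Hz (defaults). The filter is applied forward and backward
#' (zero-phase), so response latencies and times-to-peak are not skewed by
#' filter delay.
#'
#' @param df Tidy series tibble on a uniform time grid.
#' @param order Filter order.
#' @param cutoff_hz -3 dB cutoff frequency (single pass), Hz; must be
#'   below the Nyquist frequency.
#' @param value_col Name of the value column.
#' @return Same shape, filtered. DC gain is exactly 1.
#' @export
butterworth_lowpass <- function(df, order = 4, cutoff_hz = 0.7,
                                value_col = "od_per_mm") {
  key_cols <- setdiff(names(df), c("time_s", value_col))
  w <- series_wide(df, value_col, key_cols)
  fs <- 1 / sample_interval(w$times)
  if (cutoff_hz >= fs / 2) {
    abort(paste0("cutoff ", cutoff_hz, " Hz is at or above Nyquist (",
                 fs / 2, " Hz)"))
  }
  bf <- signal::butter(order, cutoff_hz / (fs / 2), type = "low")
  n <- nrow(w$M)
  pad <- min(n - 1, 100)   # odd-reflection padding absorbs edge transients
  for (k in seq_len(ncol(w$M))) {
    x <- w$M[, k]
    xp <- c(2 * x[1] - rev(x[2:(pad + 1)]), x,
            2 * x[n] - rev(x[(n - pad):(n - 1)]))
    y1 <- signal::filter(bf, xp)
    y2 <- rev(signal::filter(bf, rev(y1)))
    w$M[, k] <- y2[pad + seq_len(n)]
  }
  series_long(w, value_col)
}

#' Default hemoglobin molar extinction table
#'
#' Decadic molar absorption coefficients of oxy- and deoxyhemoglobin at
#' the three measurement wavelengths, in mm^-1 mM^-1. The values are a
#' documented stand-in compiled from standard hemoglobin spectra
#' tabulations (the instrument's own translation matrix is not published);
#' substitute any table with the same columns.
#'
#' @return Tibble `species` (`"HbO"`/`"HbR"`), `wavelength_nm`, `epsilon`.
#' @export
default_extinction_table <- function() {
  path <- system.file("extdata", "extinction_coefficients.csv",
                      package = "nirsim")
  if (nzchar(path)) {
    return(readr::read_csv(path, show_col_types = FALSE, col_types = "cdd"))
  }
  extinction_builtin()
}

extinction_builtin <- function() {
  tibble(species = rep(c("HbO", "HbR"), each = 3),
         wavelength_nm = rep(c(780, 805, 830), 2),
         epsilon = c(0.0736, 0.0830, 0.0974,
                     0.1105, 0.0820, 0.0693))
}

extinction_matrix <- function(extinction, wavelengths) {
  E <- matrix(0, nrow = length(wavelengths), ncol = 2,
              dimnames = list(NULL, c("HbO", "HbR")))
  for (i in seq_along(wavelengths)) {
    for (j in c("HbO", "HbR")) {
      hit <- extinction$species == j &
        abs(extinction$wavelength_nm - wavelengths[i]) < 1e-9
      if (!any(hit)) {
        abort(paste0("extinction table lacks ", j, " at ",
                     wavelengths[i], " nm"))
      }
      E[i, j] <- extinction$epsilon[hit][1]
    }
  }
  if (any(E <= 0)) abort("extinction coefficients must be positive")
  E
}

#' Modified Beer-Lambert inversion to hemoglobin concentration changes
#'
#' Solves, per time point and channel, the overdetermined linear system
#' `dA_cal(lambda) = eps_HbO(lambda) dHbO + eps_HbR(lambda) dHbR` in the
#' least-squares sense via the pseudo-inverse of the wavelengths-by-2
#' extinction matrix. With calibrated absorbance in OD/mm and extinction
#' in mm^-1 mM^-1 the concentrations come out in mM and are reported in
#' micromolar.
#'
#' @param df Calibrated tidy series (`time_s`, `channel`, `wavelength_nm`,
#'   `od_per_mm`) with at least two wavelengths.
#' @param extinction Extinction table, see [default_extinction_table()].
#' @return Tibble `time_s`, `channel`, `species`, `delta_umol` of class
#'   `hb_series`.
#' @export
mbll_transform <- function(df, extinction = default_extinction_table()) {
  wl <- sort(unique(df$wavelength_nm))
  if (length(wl) < 2) abort("need at least two wavelengths for MBLL")
  E <- extinction_matrix(extinction, wl)
  if (qr(E)$rank < 2) abort("extinction matrix is rank deficient")
  pinv <- solve(crossprod(E), t(E))      # 2 x n_wavelengths
  w <- series_wide(df, "od_per_mm", c("channel", "wavelength_nm"))
  stopifnot(identical(sort(unique(w$keys$wavelength_nm)), wl))
  chans <- unique(w$keys$channel)
  n_t <- length(w$times)
  hbo <- hbr <- matrix(0, nrow = n_t, ncol = length(chans))
  for (ci in seq_along(chans)) {
    cols <- which(w$keys$channel == chans[ci])
    cols <- cols[match(wl, w$keys$wavelength_nm[cols])]
    sol <- pinv %*% t(w$M[, cols, drop = FALSE])   # 2 x n_t, in mM
    hbo[, ci] <- sol[1, ]
    hbr[, ci] <- sol[2, ]
  }
  # emit channel-major / species-minor so downstream epoching sees its
  # canonical order and can skip re-sorting
  vals <- matrix(0, n_t, 2 * length(chans))
  vals[, seq(1, ncol(vals), by = 2)] <- hbo
  vals[, seq(2, ncol(vals), by = 2)] <- hbr
  out <- tibble(
    time_s = rep(w$times, times = 2 * length(chans)),
    channel = rep(chans, each = 2 * n_t),
    species = rep(rep(c("HbO", "HbR"), each = n_t), length(chans)),
    delta_umol = as.numeric(vals) * 1000)
  class(out) <- c("hb_series", class(out))
  out
}

#' Run the canonical processing chain
#'
#' Duplicate averaging, path-length calibration, cubic detrend, zero-phase
#' Butterworth low-pass, then MBLL inversion -- in that order.
#'
#' @param absorbance Duplicate-level absorbance tibble (see
#'   [average_duplicates()]) or an already-averaged series.
#' @param path_lengths Calibration table (`channel`, `wavelength_nm`,
#'   `l_mm`).
#' @param extinction Extinction table.
#' @param filter_order,cutoff_hz Low-pass settings; `cutoff_hz = NULL`
#'   skips the filter.
#' @param detrend Apply the cubic detrend?
#' @return An `hb_series` tibble (micromolar).
#' @export
process_absorbance <- function(absorbance, path_lengths,
                               extinction = default_extinction_table(),
                               filter_order = 4, cutoff_hz = 0.7,
                               detrend = TRUE) {
  df <- if ("direction" %in% names(absorbance)) {
    average_duplicates(absorbance)
  } else {
    absorbance
  }
  df <- calibrate_by_path_length(df, path_lengths)
  if (detrend) df <- detrend_poly3(df)
  if (!is.null(cutoff_hz)) {
    df <- butterworth_lowpass(df, order = filter_order,
                              cutoff_hz = cutoff_hz)
  }
  mbll_transform(df, extinction)
}
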