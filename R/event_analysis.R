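## Event-related statistics: event detection from the retrieval sensor,
## time-locked block averaging, paired t-curves for the left/right-hand
## contrast, significance-gated peak metrics, behavior statistics, and
## hemodynamics-behavior correlations.

#' Detect retrieval events from a sensor trace
#'
#' Onsets at upward threshold crossings, ends at downward crossings;
#' durations are end minus onset. Hand labels alternate starting from
#' `first_hand` unless an explicit vector is supplied. A trailing onset
#' without a matching end is dropped with a warning.
#'
#' @param trace Tibble `time_s`, `value` on a uniform grid.
#' @param threshold Crossing threshold (within the trace range).
#' @param hands Either a length-2 vector to alternate over, or one label,
#'   or an explicit per-event vector.
#' @param first_hand Starting hand for the alternation rule.
#' @return Tibble of class `event_log`: `trial`, `onset_s`, `end_s`,
#'   `hand`, `duration_s`.
#' @export
detect_events <- function(trace, threshold = 0.5,
                          hands = c("left", "right"), first_hand = "left") {
  v <- trace$value >= threshold
  dv <- diff(c(FALSE, v))
  on_i <- which(dv == 1)
  off_i <- which(dv == -1)
  if (length(on_i) > length(off_i)) {
    warn("trailing event without an end crossing dropped")
    on_i <- on_i[seq_along(off_i)]
  }
  if (length(on_i) == 0) {
    return(structure(tibble(trial = integer(), onset_s = numeric(),
                            end_s = numeric(), hand = character(),
                            duration_s = numeric()),
                     class = c("event_log", class(tibble()))))
  }
  onset <- trace$time_s[on_i]
  ends <- trace$time_s[off_i]
  n <- length(onset)
  hand <- if (length(hands) == n) {
    hands
  } else if (length(hands) == 1) {
    rep(hands, n)
  } else {
    start <- match(first_hand, hands)
    hands[((seq_len(n) - 1 + start - 1) %% length(hands)) + 1]
  }
  out <- tibble(trial = seq_len(n), onset_s = onset, end_s = ends,
                hand = hand, duration_s = ends - onset)
  class(out) <- c("event_log", class(out))
  out
}

## shared epoch extraction --------------------------------------------------

# returns list(rel_times, epochs = array (n_rel, n_trials, n_series),
#              keys, events_kept)
epoch_extract <- function(hb, events, window) {
  w <- series_wide(hb, "delta_umol", c("channel", "species"))
  dt <- sample_interval(w$times)
  i0 <- round((events$onset_s - w$times[1]) / dt) + 1
  rel <- seq(round(window[1] / dt), round(window[2] / dt))
  keep <- i0 + rel[1] >= 1 & i0 + rel[length(rel)] <= length(w$times)
  if (!all(keep)) {
    warn(paste0(sum(!keep), " trial(s) with epochs outside the recording ",
                "dropped"))
  }
  ev <- events[keep, , drop = FALSE]
  i0 <- i0[keep]
  idx <- outer(rel, i0, "+")                       # n_rel x n_trials
  E <- w$M[as.vector(idx), , drop = FALSE]         # (n_rel*n_trials) x K
  dim(E) <- c(length(rel), length(i0), ncol(w$M))
  list(rel_times = rel * dt, epochs = E, keys = w$keys, events = ev)
}

#' Time-locked block averages
#'
#' Epochs each trial on a window time-locked (t = 0) to movement onset
#' (nearest-sample alignment; no sub-sample interpolation at the native
#' 130 ms base) and averages across trials per hand, channel and species.
#'
#' @param hb An `hb_series` tibble (from [mbll_transform()]).
#' @param events An `event_log`.
#' @param window `c(pre, post)` seconds around onset.
#' @return Tibble of class `block_average`: `channel`, `species`, `hand`,
#'   `time_s` (relative to onset), `mean`, `sd`, `n_trials`.
#' @export
epoch_and_average <- function(hb, events, window = c(-2, 15)) {
  ep <- epoch_extract(hb, events, window)
  out <- list()
  for (h in unique(ep$events$hand)) {
    tr <- which(ep$events$hand == h)
    A <- ep$epochs[, tr, , drop = FALSE]
    A2 <- aperm(A, c(2, 1, 3))                     # trials x rel x K
    n <- length(tr)
    mu <- colMeans(A2, dims = 1)                   # rel x K
    s2 <- (colSums(A2^2, dims = 1) - n * mu^2) / max(n - 1, 1)
    sdv <- sqrt(pmax(s2, 0))
    k <- nrow(ep$keys)
    out[[h]] <- tibble(
      channel = rep(ep$keys$channel, each = length(ep$rel_times)),
      species = rep(ep$keys$species, each = length(ep$rel_times)),
      hand = h,
      time_s = rep(ep$rel_times, k),
      mean = as.numeric(mu), sd = as.numeric(sdv), n_trials = n)
  }
  out <- bind_rows(out)
  attr(out, "window") <- window
  class(out) <- c("block_average", class(out))
  out
}

#' Per-timepoint paired t-curves for the left/right-hand contrast
#'
#' Pairs the k-th left-hand trial with the k-th right-hand trial in
#' temporal order (the task alternates hands, making this the natural
#' pairing) and computes, at every epoch time point, the paired t statistic
#' and two-sided p-value of left minus right, per channel and species.
#' `pairing = "welch"` gives an unpaired unequal-variance alternative.
#'
#' @inheritParams epoch_and_average
#' @param pairing `"order"` (paired, default) or `"welch"`.
#' @return Tibble of class `t_curve`: `channel`, `species`, `time_s`, `t`,
#'   `p`, `df`.
#' @export
paired_t_curve <- function(hb, events, window = c(-2, 15),
                           pairing = c("order", "welch")) {
  pairing <- match.arg(pairing)
  ep <- epoch_extract(hb, events, window)
  hl <- which(ep$events$hand == "left")
  hr <- which(ep$events$hand == "right")
  if (pairing == "order" && length(hl) != length(hr)) {
    abort(paste0("paired t-test needs equal trial counts; got ",
                 length(hl), " left vs ", length(hr), " right"))
  }
  if (pairing == "order") {
    Dif <- ep$epochs[, hl, , drop = FALSE] - ep$epochs[, hr, , drop = FALSE]
    A2 <- aperm(Dif, c(2, 1, 3))
    n <- length(hl)
    mu <- colMeans(A2, dims = 1)
    s2 <- (colSums(A2^2, dims = 1) - n * mu^2) / (n - 1)
    tval <- mu / sqrt(pmax(s2, .Machine$double.eps) / n)
    dof <- n - 1
  } else {
    stat <- function(tr) {
      A2 <- aperm(ep$epochs[, tr, , drop = FALSE], c(2, 1, 3))
      n <- length(tr)
      mu <- colMeans(A2, dims = 1)
      s2 <- (colSums(A2^2, dims = 1) - n * mu^2) / (n - 1)
      list(mu = mu, v = s2 / n, n = n)
    }
    L <- stat(hl); R <- stat(hr)
    tval <- (L$mu - R$mu) / sqrt(L$v + R$v)
    dof <- (L$v + R$v)^2 / (L$v^2 / (L$n - 1) + R$v^2 / (R$n - 1))
  }
  pval <- 2 * pt(-abs(tval), dof)
  k <- nrow(ep$keys)
  out <- tibble(
    channel = rep(ep$keys$channel, each = length(ep$rel_times)),
    species = rep(ep$keys$species, each = length(ep$rel_times)),
    time_s = rep(ep$rel_times, k),
    t = as.numeric(tval), p = as.numeric(pval),
    df = if (length(dof) == 1) dof else as.numeric(dof))
  attr(out, "window") <- window
  class(out) <- c("t_curve", class(out))
  out
}

#' Significance-gated peak metrics
#'
#' Where the t-curve of a channel/species reaches p below `alpha` at some
#' time point (the gate), reports the signed extremum of the block-averaged
#' response (peak or valley, whichever has the larger magnitude; ties break
#' to the earliest time point) and the time elapsed from onset to it.
#' Channels whose gate never fires get `significant = FALSE` and missing
#' metrics.
#'
#' @param block A `block_average`.
#' @param tcurve The matching `t_curve` (same epoch window).
#' @param alpha Gate level on the t-curve p-values.
#' @return Tibble of class `peak_metrics`: `channel`, `species`, `hand`,
#'   `significant`, `max_amplitude`, `time_of_max_s`.
#' @export
peak_metrics <- function(block, tcurve, alpha = 0.05) {
  gate <- tcurve |>
    group_by(.data$channel, .data$species) |>
    summarise(significant = any(.data$p < alpha), .groups = "drop")
  ext <- block |>
    group_by(.data$channel, .data$species, .data$hand) |>
    summarise(
      max_amplitude = .data$mean[which.max(abs(.data$mean))[1]],
      time_of_max_s = .data$time_s[which.max(abs(.data$mean))[1]],
      .groups = "drop")
  out <- left_join(ext, gate, by = c("channel", "species"))
  out$significant[is.na(out$significant)] <- FALSE
  out$max_amplitude[!out$significant] <- NA_real_
  out$time_of_max_s[!out$significant] <- NA_real_
  out <- relocate(out, "significant", .after = "hand")
  class(out) <- c("peak_metrics", class(out))
  out
}

#' Hemisphere-averaged peak metrics versus retrieval time
#'
#' Averages significant peak metrics over the channels of each hemisphere
#' (using each hemisphere's contralateral-hand trials, where the hand-M1
#' response lives) per session and species, then correlates the averages
#' (Pearson) against the session's time required for food retrieval,
#' normalized to the initial session.
#'
#' @param metrics Row-bound [peak_metrics()] of several sessions with a
#'   `session` column and a `side` column (anatomical hemisphere of each
#'   channel, e.g. joined from [paper_region_table()]).
#' @param behavior Tibble `session`, `retrieval_time_s` (per-session mean).
#' @param initial_session Session identifier used for normalization
#'   (default: the first in sort order).
#' @return Tibble: `hemisphere`, `species`, `metric`, `r`, `p`, `n`.
#' @export
hemisphere_average_and_correlate <- function(metrics, behavior,
                                             initial_session = NULL) {
  if (length(unique(metrics$session)) < 3) {
    abort("need at least 3 sessions to correlate")
  }
  if (is.null(initial_session)) {
    initial_session <- sort(unique(behavior$session))[1]
  }
  ref <- behavior$retrieval_time_s[behavior$session == initial_session][1]
  behavior$retrieval_norm <- behavior$retrieval_time_s / ref
  contra <- c(left = "right", right = "left")
  hemi <- metrics |>
    filter(.data$significant, .data$hand == contra[.data$side]) |>
    group_by(.data$session, .data$side, .data$species) |>
    summarise(max_amplitude = mean(.data$max_amplitude),
              time_of_max_s = mean(.data$time_of_max_s), .groups = "drop") |>
    left_join(behavior, by = "session")
  rows <- list()
  for (s in unique(hemi$side)) for (sp in unique(hemi$species)) {
    sub <- hemi[hemi$side == s & hemi$species == sp, ]
    for (m in c("max_amplitude", "time_of_max_s")) {
      x <- sub[[m]]; y <- sub$retrieval_norm
      if (length(x) < 3 || sd(x) == 0 || sd(y) == 0) {
        rows[[length(rows) + 1]] <- tibble(
          hemisphere = s, species = sp, metric = m,
          r = NA_real_, p = NA_real_, n = length(x),
          degenerate = TRUE)
        next
      }
      ct <- cor.test(x, y)
      rows[[length(rows) + 1]] <- tibble(
        hemisphere = s, species = sp, metric = m,
        r = unname(ct$estimate), p = ct$p.value, n = length(x),
        degenerate = FALSE)
    }
  }
  bind_rows(rows)
}

#' Correlation between oxy- and deoxyhemoglobin responses
#'
#' Pearson correlation between the block-averaged HbO and HbR time courses
#' per channel and hand: functional cortical hemodynamics shows a
#' distinctive negative linear HbO-HbR relationship.
#'
#' @param block A `block_average` containing both species.
#' @return Tibble: `channel`, `hand`, `r`, `p`, `n`, `degenerate`.
#' @export
hbo_hbr_correlation <- function(block) {
  wide <- block |>
    select("channel", "species", "hand", "time_s", "mean") |>
    pivot_wider(names_from = "species", values_from = "mean")
  out <- list()
  for (ch in unique(wide$channel)) for (h in unique(wide$hand)) {
    sub <- wide[wide$channel == ch & wide$hand == h, ]
    if (nrow(sub) < 3 || sd(sub$HbO) == 0 || sd(sub$HbR) == 0) {
      out[[length(out) + 1]] <- tibble(channel = ch, hand = h, r = NA_real_,
                                       p = NA_real_, n = nrow(sub),
                                       degenerate = TRUE)
      next
    }
    ct <- cor.test(sub$HbO, sub$HbR)
    out[[length(out) + 1]] <- tibble(channel = ch, hand = h,
                                     r = unname(ct$estimate), p = ct$p.value,
                                     n = nrow(sub), degenerate = FALSE)
  }
  bind_rows(out)
}

#' Read / write event logs as CSV
#'
#' Columns `onset_s`, `end_s`, `hand` (plus `trial`, `duration_s`, which
#' are recomputed on read if absent).
#'
#' @param path CSV path.
#' @return An `event_log` tibble (read); `path`, invisibly (write).
#' @export
read_event_log <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  if (!"trial" %in% names(df)) df$trial <- seq_len(nrow(df))
  if (!"duration_s" %in% names(df)) df$duration_s <- df$end_s - df$onset_s
  out <- select(df, "trial", "onset_s", "end_s", "hand", "duration_s")
  class(out) <- c("event_log", class(out))
  out
}

#' @param events Event log to write.
#' @rdname read_event_log
#' @export
write_event_log <- function(events, path) {
  readr::write_csv(events, path)
  invisible(path)
}

## behavior statistics ------------------------------------------------------

#' Box-Cox transform with lambda = -1
#'
#' `(x^lambda - 1) / lambda` at `lambda = -1`, i.e. `1 - 1/x`; defined for
#' positive durations only.
#'
#' @param x Positive numeric vector (seconds).
#' @return Transformed vector.
#' @export
boxcox_neg1 <- function(x) {
  if (any(!is.finite(x) | x <= 0)) {
    bad <- which(!is.finite(x) | x <= 0)
    abort(paste0("non-positive durations at positions: ",
                 paste(head(bad, 5), collapse = ", ")))
  }
  1 - 1 / x
}

#' Behavior statistics over sessions and hands
#'
#' Normalizes retrieval durations with the Box-Cox transform at
#' lambda = -1, tests homoscedasticity of the transformed groups with
#' Bartlett's test, compares group means with one-way ANOVA over the
#' session-by-hand groups, and corrects pairwise comparisons with the
#' Tukey-Kramer method (unequal group sizes supported).
#'
#' @param events Tibble with `session`, `hand`, `duration_s` (one row per
#'   trial; bind several sessions' event logs).
#' @return Object of class `behavior_stats` with elements `data`,
#'   `bartlett`, `anova`, `tukey`. Use [tidy()]/[glance()] for tabular
#'   summaries.
#' @export
behavior_stats <- function(events) {
  bc <- boxcox_neg1(events$duration_s)
  grp <- factor(paste(events$session, events$hand, sep = "."))
  if (nlevels(grp) < 2) abort("need at least two session/hand groups")
  bart <- bartlett.test(bc, grp)
  fit <- aov(bc ~ grp)
  tk <- TukeyHSD(fit)
  structure(list(data = mutate(events, boxcox = bc, group = grp),
                 bartlett = bart, anova = fit, tukey = tk),
            class = "behavior_stats")
}

#' @export
print.behavior_stats <- function(x, ...) {
  cat("<behavior_stats> ", nlevels(x$data$group), " groups, ",
      nrow(x$data), " trials\n", sep = "")
  cat("  Bartlett p = ", signif(x$bartlett$p.value, 4), "\n", sep = "")
  sm <- summary(x$anova)[[1]]
  cat("  ANOVA F = ", signif(sm[1, "F value"], 4), ", p = ",
      signif(sm[1, "Pr(>F)"], 4), "\n", sep = "")
  invisible(x)
}

#' @method tidy behavior_stats
#' @export
tidy.behavior_stats <- function(x, ...) {
  tk <- as.data.frame(x$tukey$grp)
  tibble(contrast = rownames(tk), estimate = tk$diff,
         conf_low = tk$lwr, conf_high = tk$upr, adj_p = tk$`p adj`)
}

#' @method glance behavior_stats
#' @export
glance.behavior_stats <- function(x, ...) {
  sm <- summary(x$anova)[[1]]
  tibble(bartlett_stat = unname(x$bartlett$statistic),
         bartlett_p = x$bartlett$p.value,
         anova_f = sm[1, "F value"], anova_p = sm[1, "Pr(>F)"],
         df_between = sm[1, "Df"], df_within = sm[2, "Df"])
}
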