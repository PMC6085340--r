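## autoplot() methods for the main result types, mirroring the usual
## figure layouts: sweep curves vs d_SD, block-averaged responses with SD
## bands, and per-channel t-curve panels.

#' @method autoplot sensitivity_sweep
#' @export
autoplot.sensitivity_sweep <- function(object, ...) {
  long <- pivot_longer(as_tibble(object),
                       c("intensity", "l_gray", "regional_l_gray"),
                       names_to = "quantity", values_to = "value")
  long$quantity <- factor(long$quantity,
                          levels = c("intensity", "l_gray",
                                     "regional_l_gray"),
                          labels = c("detected intensity I (a.u.)",
                                     "L_gray (mm)",
                                     "regional L_gray (mm)"))
  ggplot(long, aes(x = .data$d_sd, y = .data$value,
                   color = .data$alignment)) +
    geom_line() + geom_point() +
    facet_wrap(~quantity, scales = "free_y") +
    labs(x = "source-detector distance d_SD (mm)", y = NULL,
         color = "alignment") +
    theme_bw()
}

#' @method autoplot block_average
#' @export
autoplot.block_average <- function(object, channels = NULL, ...) {
  df <- as_tibble(object)
  if (!is.null(channels)) df <- df[df$channel %in% channels, ]
  ggplot(df, aes(x = .data$time_s, y = .data$mean, color = .data$species,
                 fill = .data$species)) +
    geom_ribbon(aes(ymin = .data$mean - .data$sd,
                    ymax = .data$mean + .data$sd),
                alpha = 0.2, color = NA) +
    geom_line() +
    facet_grid(channel ~ hand) +
    geom_hline(yintercept = 0, linewidth = 0.2) +
    labs(x = "time from onset (s)", y = expression(Delta * "Hb (" * mu * "M)"),
         color = NULL, fill = NULL) +
    theme_bw()
}

#' @method autoplot t_curve
#' @export
autoplot.t_curve <- function(object, channels = NULL, alpha = 0.05, ...) {
  df <- as_tibble(object)
  if (!is.null(channels)) df <- df[df$channel %in% channels, ]
  crit <- qt(1 - alpha / 2, df = max(df$df))
  ggplot(df, aes(x = .data$time_s, y = .data$t, color = .data$species)) +
    geom_line() +
    geom_hline(yintercept = c(-crit, crit), linetype = "dotted") +
    geom_hline(yintercept = 0, linewidth = 0.2) +
    facet_wrap(~channel) +
    labs(x = "time from onset (s)", y = "paired t (left - right)",
         color = NULL) +
    theme_bw()
}
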