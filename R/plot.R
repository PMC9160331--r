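# Convenience plotting: per-trial cohort bands in the style of the model's
# standard diagnostic panels (internal state, action values, intake
# probability, reward).  Not part of the tested numerical contract.

.band_panel <- function(trial, mu, sd, col, main, ylab, hline = NULL) {
  lo <- mu - 2 * sd; hi <- mu + 2 * sd
  graphics::matplot(trial, cbind(lo, hi), type = "n", main = main,
                    xlab = "trial", ylab = ylab)
  for (j in seq_len(ncol(mu))) {
    graphics::polygon(c(trial, rev(trial)), c(lo[, j], rev(hi[, j])),
                      col = grDevices::adjustcolor(col[j], alpha.f = 0.25),
                      border = NA)
    graphics::lines(trial, mu[, j], col = col[j], lwd = 2)
  }
  if (!is.null(hline))
    graphics::abline(h = hline, lty = 3)
}

#' Diagnostic panels for a cohort
#'
#' Plots, per trial, the cohort mean with a +/- 2 SD band of the internal
#' state(s) (with the setpoint dotted), the action values, the choice
#' probabilities and the reward.
#'
#' @param x An `hrl_cohort`.
#' @param which Subset of `c("state", "q", "p", "reward")`.
#' @param ... Unused.
#' @return `x`, invisibly.
#' @export
plot.hrl_cohort <- function(x, which = c("state", "q", "p", "reward"), ...) {
  which <- match.arg(which, several.ok = TRUE)
  s <- summarize_cohort(x)
  cfg <- x$config
  pt <- s$per_trial
  old <- graphics::par(mfrow = c(length(which), 1), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  pick <- function(prefix, names)
    list(mu = as.matrix(pt[paste0(prefix, names, "_mean")]),
         sd = as.matrix(pt[paste0(prefix, names, "_sd")]))
  cols <- grDevices::palette.colors(max(cfg$n_dimensions,
                                        length(cfg$action_labels)))
  for (w in which) {
    if (w == "state") {
      v <- pick("H_", cfg$dim_names)
      .band_panel(pt$trial, v$mu, v$sd, cols, "internal state",
                  "H", hline = cfg$drive$setpoint)
    } else if (w == "q") {
      v <- pick("Q_", cfg$action_labels)
      .band_panel(pt$trial, v$mu, v$sd, cols, "action values", "Q")
    } else if (w == "p") {
      v <- pick("P_", cfg$action_labels)
      .band_panel(pt$trial, v$mu, v$sd, cols, "choice probability", "P")
    } else {
      v <- list(mu = cbind(pt$reward_mean), sd = cbind(pt$reward_sd))
      .band_panel(pt$trial, v$mu, v$sd, cols, "reward", "r")
    }
  }
  invisible(x)
}
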