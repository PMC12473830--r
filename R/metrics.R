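#' Goodness-of-fit metric battery
#'
#' Computes the six-metric battery used to compare simulated and observed
#' profiles:
#' \itemize{
#'   \item RMSE: `sqrt(mean((pred - obs)^2))`.
#'   \item MAPE (%): `100 * mean(|pred - obs| / |obs|)` over pairs with
#'     `obs > 0` (below-LOQ observations stored as 0 are excluded).
#'   \item AFE: `10^(mean(log10(pred / obs)))`, the geometric-mean fold
#'     error, over pairs with both values > 0; ideal 1. The absolute variant
#'     AAFE `10^(mean(|log10(pred / obs)|))` is reported alongside.
#'   \item bias: `mean(pred - obs)`; ideal 0.
#'   \item R2: `1 - sum((obs - pred)^2) / sum((obs - mean(obs))^2)`; may be
#'     negative when the predictions do worse than the observed mean.
#'   \item Pearson r.
#' }
#' Metrics with fewer than 2 valid pairs are reported as `NA` (undefined),
#' never coerced to 0. `n_points` records how many pairs each metric used.
#'
#' @param pred,obs Numeric vectors of equal length (>= 2), paired by time.
#' @return An object of class `metrics_report`: list with `rmse`, `mape`,
#'   `afe`, `aafe`, `bias`, `r_squared`, `pearson_r`, and `n_points`.
#' @export
compute_metrics <- function(pred, obs) {
  if (length(pred) != length(obs))
    stop("pred and obs must have equal length", call. = FALSE)
  if (length(pred) < 2) stop("need at least 2 pairs", call. = FALSE)
  if (any(!is.finite(pred)) || any(!is.finite(obs)))
    stop("pred and obs must be finite", call. = FALSE)
  n <- length(pred)
  pos_o <- obs > 0
  pos_po <- pos_o & pred > 0

  rmse <- sqrt(mean((pred - obs)^2))
  bias <- mean(pred - obs)
  mape <- if (sum(pos_o) >= 2) 100 * mean(abs(pred[pos_o] - obs[pos_o]) / obs[pos_o]) else NA_real_
  afe <- if (sum(pos_po) >= 2) 10^mean(log10(pred[pos_po] / obs[pos_po])) else NA_real_
  aafe <- if (sum(pos_po) >= 2) 10^mean(abs(log10(pred[pos_po] / obs[pos_po]))) else NA_real_
  ss_tot <- sum((obs - mean(obs))^2)
  r_squared <- if (ss_tot > 0) 1 - sum((obs - pred)^2) / ss_tot else NA_real_
  pearson_r <- if (stats::sd(pred) > 0 && stats::sd(obs) > 0)
    stats::cor(pred, obs) else NA_real_

  structure(
    list(rmse = rmse, mape = mape, afe = afe, aafe = aafe, bias = bias,
         r_squared = r_squared, pearson_r = pearson_r,
         n_points = c(rmse = n, mape = sum(pos_o), afe = sum(pos_po),
                      bias = n, r_squared = n, pearson_r = n)),
    class = "metrics_report"
  )
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf(
    "RMSE %.4g | MAPE %.4g%% | AFE %.4g (AAFE %.4g) | bias %.4g | R2 %.4g | r %.4g\n",
    x$rmse, x$mape, x$afe, x$aafe, x$bias, x$r_squared, x$pearson_r))
  invisible(x)
}
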