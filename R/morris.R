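#' Morris elementary-effects sensitivity screening
#'
#' Standard one-at-a-time Morris trajectories on a `levels`-point grid in the
#' unit hypercube, mapped linearly onto the supplied parameter ranges. For a
#' trajectory starting at a random grid point, each parameter is perturbed
#' once by `delta = levels / (2 * (levels - 1))` (direction chosen to stay in
#' `[0, 1]`), giving one elementary effect per parameter per trajectory:
#' `EE = (f(x + delta e_i) - f(x)) / delta` in scaled-range units. Reported
#' are `mu_star` (mean absolute EE, importance) and `sigma` (EE standard
#' deviation, interaction/nonlinearity) per parameter.
#'
#' @param f Function taking a named numeric parameter vector and returning a
#'   scalar model output (e.g. epidermis accumulation at 36 h).
#' @param ranges Named list of `c(lower, upper)` parameter ranges.
#' @param n_trajectories Number of trajectories (>= 4).
#' @param levels Number of grid levels (even, >= 4).
#' @param seed Integer seed; results are reproducible for a fixed seed.
#' @return An object of class `morris_result`: data frame `parameter`,
#'   `mu_star`, `sigma`, plus attributes `n_trajectories`, `levels`, `seed`.
#' @export
morris_screen <- function(f, ranges, n_trajectories = 8, levels = 4, seed = 1) {
  if (n_trajectories < 4) stop("n_trajectories must be >= 4", call. = FALSE)
  if (levels < 4 || levels %% 2 != 0)
    stop("levels must be an even integer >= 4", call. = FALSE)
  pn <- names(ranges)
  if (is.null(pn) || any(!nzchar(pn)))
    stop("ranges must be a named list", call. = FALSE)
  lo <- vapply(ranges, `[`, numeric(1), 1)
  hi <- vapply(ranges, `[`, numeric(1), 2)
  if (any(!is.finite(c(lo, hi))) || any(lo >= hi))
    stop("ranges must be finite c(lower, upper)", call. = FALSE)
  k <- length(pn)
  delta <- levels / (2 * (levels - 1))
  base_grid <- (seq_len(levels / 2) - 1) / (levels - 1)  # start levels with room for +delta

  set.seed(seed)
  ee <- matrix(NA_real_, n_trajectories, k, dimnames = list(NULL, pn))
  dropped <- 0L
  for (tr in seq_len(n_trajectories)) {
    x <- base_grid[sample.int(length(base_grid), k, replace = TRUE)]
    dir <- sample(c(-1, 1), k, replace = TRUE)
    # flip directions that would leave [0, 1]
    dir <- ifelse(x + dir * delta < 0 | x + dir * delta > 1, -dir, dir)
    ord <- sample.int(k)
    fx <- f(stats::setNames(lo + (hi - lo) * x, pn))
    traj <- rep(NA_real_, k)
    ok <- is.finite(fx)
    if (ok) {
      for (i in ord) {
        x2 <- x
        x2[i] <- x[i] + dir[i] * delta
        fx2 <- f(stats::setNames(lo + (hi - lo) * x2, pn))
        if (!is.finite(fx2)) { ok <- FALSE; break }
        traj[i] <- (fx2 - fx) / (dir[i] * delta)
        x <- x2
        fx <- fx2
      }
    }
    if (ok) ee[tr, ] <- traj else dropped <- dropped + 1L
  }
  if (dropped > 0L)
    warning(dropped, " trajectory(ies) dropped due to non-finite model output",
            call. = FALSE)
  keep <- stats::complete.cases(ee)
  if (!any(keep)) stop("all trajectories produced non-finite output", call. = FALSE)
  ee <- ee[keep, , drop = FALSE]
  out <- data.frame(
    parameter = pn,
    mu_star = apply(abs(ee), 2, mean),
    sigma = apply(ee, 2, stats::sd),
    row.names = NULL
  )
  structure(out, class = c("morris_result", "data.frame"),
            n_trajectories = sum(keep), levels = levels, seed = seed)
}
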