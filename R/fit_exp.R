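#' Single-exponential half-time fit of an efflux curve
#'
#' Fits `f(t) = A * exp(-lambda * t)` (optionally plus a plateau `c`) to a
#' residence-fraction time course by Levenberg-Marquardt least squares and
#' reports the half-time `t_half = ln(2) / lambda` with an asymptotic 95%
#' confidence interval (delta method on the parameter covariance). This is
#' the per-curve quantification used for ER-exit and Golgi-exit kinetics
#' before any compartment modeling.
#'
#' Non-decaying data (best-fit `lambda <= 0`) raise a classed
#' `rush_failed_fit` error carrying the offending rate estimate rather
#' than silently clipping.
#'
#' @param times Hours, strictly increasing, `>= 0`.
#' @param values Residence fractions (or any decaying signal).
#' @param with_plateau If `TRUE`, fit an additive plateau; needs >= 4
#'   points. Default off: the assay's curves decay to zero.
#' @return Object of class `exp_fit`: list with `t_half`, `rate`,
#'   `amplitude`, `plateau`, `ci95_t_half`, `rss`, `fitted`.
#' @examples
#' t <- seq(0, 6, by = 0.5)
#' fit_single_exponential(t, exp(-log(2) / 2 * t))$t_half  # 2
#' @export
fit_single_exponential <- function(times, values, with_plateau = FALSE) {
  if (inherits(times, "rush_dataset")) {
    values <- times$values
    times <- times$times
  }
  n_min <- if (with_plateau) 4L else 3L
  if (length(times) < n_min || length(values) != length(times)) {
    stop(sprintf("need at least %d (time, value) pairs", n_min), call. = FALSE)
  }
  if (is.unsorted(times, strictly = TRUE) || any(times < 0)) {
    stop("`times` must be strictly increasing and non-negative", call. = FALSE)
  }
  if (diff(range(values)) < .Machine$double.eps^0.5) {
    stop_failed_fit("degenerate curve: all values equal, no decay to fit",
                    lambda = NA_real_)
  }

  # log-linear start; shift values if a plateau is fitted
  c0 <- if (with_plateau) min(values) * 0.9 else 0
  pos <- values - c0 > 1e-8
  lam0 <- if (sum(pos) >= 2) {
    sl <- stats::coef(stats::lm(log(values[pos] - c0) ~ times[pos]))[2]
    max(as.numeric(-sl), 1e-3)
  } else 1
  A0 <- max(values) - c0
  par0 <- if (with_plateau) c(A = A0, lambda = lam0, c = c0) else c(A = A0, lambda = lam0)

  resid_fn <- function(p) {
    cc <- if (with_plateau) p[["c"]] else 0
    values - (p[["A"]] * exp(-p[["lambda"]] * times) + cc)
  }
  fit <- minpack.lm::nls.lm(par = par0, fn = resid_fn,
                            control = minpack.lm::nls.lm.control(
                              maxiter = 500, ftol = 1e-12, ptol = 1e-12))
  p <- fit$par
  lambda <- p[["lambda"]]
  if (!is.finite(lambda) || lambda <= 0) {
    stop_failed_fit("non-decaying data: best-fit rate is not positive",
                    lambda = lambda)
  }
  rss <- sum(fit$fvec^2)
  dof <- length(values) - length(p)
  se_lambda <- NA_real_
  if (dof > 0) {
    # nls.lm's `hessian` is t(J) %*% J; covariance = sigma^2 * solve(J'J)
    cov <- tryCatch(solve(fit$hessian) * rss / dof, error = function(e) NULL)
    if (!is.null(cov)) {
      v <- cov["lambda", "lambda"]
      if (is.finite(v) && v >= 0) se_lambda <- sqrt(v)
    }
  }
  t_half <- log(2) / lambda
  se_t <- log(2) / lambda^2 * se_lambda
  ci <- if (is.finite(se_t)) t_half + c(-1, 1) * stats::qt(0.975, dof) * se_t
        else c(NA_real_, NA_real_)
  structure(
    list(t_half = t_half, rate = lambda, amplitude = p[["A"]],
         plateau = if (with_plateau) p[["c"]] else 0,
         ci95_t_half = ci, rss = rss,
         fitted = values - fit$fvec),
    class = "exp_fit"
  )
}

#' @export
print.exp_fit <- function(x, ...) {
  cat(sprintf("<exp_fit> t_half = %.4g h (rate %.4g /h), amplitude %.3g, rss %.3g\n",
              x$t_half, x$rate, x$amplitude, x$rss))
  if (all(is.finite(x$ci95_t_half))) {
    cat(sprintf("  95%% CI on t_half: [%.4g, %.4g] h\n",
                x$ci95_t_half[1], x$ci95_t_half[2]))
  }
  invisible(x)
}

stop_failed_fit <- function(msg, lambda) {
  cond <- structure(
    class = c("rush_failed_fit", "error", "condition"),
    list(message = msg, call = sys.call(-1), lambda = lambda)
  )
  stop(cond)
}
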