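#' Combined chi-square objective over efflux datasets
#'
#' The global objective is the unweighted sum of squared residuals over
#' all datasets and time points, `chi2 = sum_i sum_j (y_ij - yhat_ij)^2`,
#' where `yhat` is the model residence fraction of the organelle each
#' dataset tracks (ER fraction for ER release, Golgi fraction for Golgi
#' release). Optional inverse-variance weighting by per-point `sd` is
#' available but off by default to match the plain objective.
#'
#' @param params A [model_params()] object.
#' @param datasets List of [rush_dataset()] objects.
#' @param constructs A [construct_table()] resolving every dataset's
#'   construct.
#' @param mode Model evaluation mode, see [model_fractions()].
#' @param weighted If `TRUE`, residuals are divided by per-point `sd`.
#' @return Scalar chi-square.
#' @export
chi_square <- function(params, datasets, constructs,
                       mode = "rapid_equilibrium", weighted = FALSE) {
  sum(global_residuals(params, datasets, constructs, mode, weighted)^2)
}

global_residuals <- function(params, datasets, constructs,
                             mode = "rapid_equilibrium", weighted = FALSE) {
  res <- lapply(datasets, function(ds) {
    if (!ds$construct %in% names(constructs)) {
      stop(sprintf("dataset '%s': construct not in table", dataset_key(ds)),
           call. = FALSE)
    }
    fr <- tryCatch(
      model_fractions(params, constructs[[ds$construct]], ds$release_site,
                      ds$times, mode = mode),
      error = function(e) {
        stop(sprintf("model evaluation failed for dataset '%s': %s",
                     dataset_key(ds), conditionMessage(e)), call. = FALSE)
      })
    r <- ds$values - tracked_fraction(fr, ds$release_site)
    if (weighted) {
      if (is.null(ds$sd)) {
        stop(sprintf("weighted fit requested but dataset '%s' has no sd",
                     dataset_key(ds)), call. = FALSE)
      }
      r <- r / ds$sd
    }
    r
  })
  unlist(res, use.names = FALSE)
}

#' Global multistart Levenberg-Marquardt fit of the trafficking model
#'
#' Fits the compartment model simultaneously to a collection of efflux
#' datasets (canonically the eight construct-by-release-site curves of the
#' four-probe panel). Free parameters are `k_a`, `k_b` and the ER-exit
#' partition coefficients: one for full-length and one for TMD-only
#' constructs in the four-parameter variant, plus a separate coefficient
#' for `split_construct` in the five-parameter variant. Raft partition
#' coefficients are fixed data from GPMV measurements, never fitted.
#'
#' Parameters are optimized in log space (which enforces positivity)
#' with `minpack.lm::nls.lm`. Each restart draws its start log-uniformly
#' over `start_range`; the global best by chi-square is returned, ties
#' broken by the lowest restart index. The whole procedure is a pure
#' function of its arguments including `seed`.
#'
#' @inheritParams chi_square
#' @param variant `"four_param"` or `"five_param"`.
#' @param n_restarts Number of random restarts (>= 1); 1000 matches the
#'   canonical protocol.
#' @param seed Integer RNG seed; identical inputs give a bit-identical
#'   result.
#' @param start_range Range of the log-uniform start distribution, per
#'   parameter, in natural units (1/h for rates, dimensionless for
#'   partition coefficients).
#' @param bounds Box constraints on every free parameter (natural units),
#'   applied in log space. Wide by default; a numerical guard that keeps
#'   the optimizer in finite-arithmetic territory, not a prior.
#' @param split_construct Construct receiving its own ER-exit coefficient
#'   in the five-parameter variant.
#' @return Object of class `rush_global_fit`: best [model_params()],
#'   `chi2`, per-restart chi-squares, per-dataset residuals, provenance
#'   (`seed`, `n_restarts`, `variant`, `converged`).
#' @export
global_fit <- function(datasets, constructs = default_construct_table(),
                       variant = c("four_param", "five_param"),
                       n_restarts = 1000, seed = 1,
                       start_range = c(1e-2, 1e2), bounds = c(1e-8, 1e8),
                       split_construct = "LAT-allL",
                       mode = "rapid_equilibrium", weighted = FALSE) {
  variant <- match.arg(variant)
  if (!is.numeric(n_restarts) || n_restarts < 1) {
    stop("`n_restarts` must be >= 1", call. = FALSE)
  }
  n_restarts <- as.integer(n_restarts)
  if (!length(datasets) || !all(vapply(datasets, inherits, logical(1), "rush_dataset"))) {
    stop("`datasets` must be a non-empty list of rush_dataset objects", call. = FALSE)
  }
  keys <- vapply(datasets, dataset_key, character(1))
  if (anyDuplicated(keys)) {
    stop("duplicate (construct, release_site) datasets in fit collection", call. = FALSE)
  }

  free_names <- c("k_a", "k_b", "kp_erex.full_length", "kp_erex.tmd_only")
  split_key <- NULL
  if (variant == "five_param") {
    if (!split_construct %in% names(constructs)) {
      stop(sprintf("five_param variant: split_construct '%s' not in construct table",
                   split_construct), call. = FALSE)
    }
    split_key <- split_construct
    constructs[[split_construct]]$erex_key <- split_key
    free_names <- c(free_names, paste0("kp_erex.", split_key))
  }
  k <- length(free_names)

  params_from_theta <- function(theta) {
    kp <- c(full_length = exp(theta[3]), tmd_only = exp(theta[4]))
    if (!is.null(split_key)) kp[split_key] <- exp(theta[5])
    model_params(k_a = exp(theta[1]), k_b = exp(theta[2]), kp_erex = kp)
  }
  resid_fn <- function(theta) {
    global_residuals(params_from_theta(theta), datasets, constructs,
                     mode = mode, weighted = weighted)
  }

  set.seed(as.integer(seed))
  starts <- matrix(stats::runif(n_restarts * k, log(start_range[1]),
                                log(start_range[2])),
                   nrow = n_restarts, ncol = k)

  chi2s <- rep(Inf, n_restarts)
  conv <- logical(n_restarts)
  pars <- matrix(NA_real_, n_restarts, k)
  diagnostics <- character(n_restarts)
  for (i in seq_len(n_restarts)) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = starts[i, ], fn = resid_fn,
                         lower = rep(log(bounds[1]), k),
                         upper = rep(log(bounds[2]), k),
                         control = minpack.lm::nls.lm.control(
                           maxiter = 500, ftol = 1e-10)),
      error = function(e) e)
    if (inherits(fit, "error")) {
      diagnostics[i] <- conditionMessage(fit)
      next
    }
    chi2s[i] <- sum(fit$fvec^2)
    pars[i, ] <- fit$par
    conv[i] <- fit$info %in% 1:4
    diagnostics[i] <- fit$message
  }
  if (all(!is.finite(chi2s))) {
    stop(paste0("all restarts failed to converge; first diagnostics: ",
                paste(utils::head(unique(diagnostics), 3), collapse = " | ")),
         call. = FALSE)
  }
  best <- which.min(chi2s)  # ties: lowest index
  best_params <- params_from_theta(pars[best, ])
  per_ds <- lapply(datasets, function(ds) {
    fr <- model_fractions(best_params, constructs[[ds$construct]],
                          ds$release_site, ds$times, mode = mode)
    ds$values - tracked_fraction(fr, ds$release_site)
  })
  names(per_ds) <- keys

  free <- stats::setNames(exp(pars[best, ]), free_names)
  structure(
    list(params = best_params, free = free, chi2 = chi2s[best],
         variant = variant, n_restarts = n_restarts, seed = as.integer(seed),
         restart_chi2s = chi2s, converged = conv[best],
         per_dataset_residuals = per_ds, dataset_keys = keys,
         n_points = sum(lengths(lapply(datasets, `[[`, "values"))),
         data_checksum = sum(unlist(lapply(datasets, `[[`, "values"))),
         split_construct = split_key, mode = mode),
    class = "rush_global_fit"
  )
}

#' @export
print.rush_global_fit <- function(x, ...) {
  cat(sprintf("<rush_global_fit> %s, chi2 = %.6g (%d restarts, seed %d)\n",
              x$variant, x$chi2, x$n_restarts, x$seed))
  cat("  best-fit free parameters:\n")
  for (nm in names(x$free)) {
    unit <- if (nm %in% c("k_a", "k_b")) " /h" else ""
    cat(sprintf("    %-22s %.5g%s\n", nm, x$free[[nm]], unit))
  }
  invisible(x)
}

#' Compare nested model variants
#'
#' Contrasts the four- and five-parameter global fits on the same data.
#' Because the five-parameter space nests the four-parameter one, the
#' five-parameter chi-square can only be lower when both multistarts found
#' their global optima; a negative `delta_chi2` is flagged as a restart
#' failure. An AIC-style score `n * log(chi2 / n) + 2k` is reported for
#' each fit.
#'
#' @param fit4,fit5 `rush_global_fit` objects for the four- and
#'   five-parameter variants, fit to identical datasets.
#' @return List with `delta_chi2` (`chi2_4 - chi2_5`), `aic`, parameter
#'   counts, and `nesting_violated`.
#' @export
compare_variants <- function(fit4, fit5) {
  stopifnot(inherits(fit4, "rush_global_fit"), inherits(fit5, "rush_global_fit"))
  if (!setequal(fit4$dataset_keys, fit5$dataset_keys) ||
      fit4$n_points != fit5$n_points ||
      abs(fit4$data_checksum - fit5$data_checksum) > 1e-12) {
    stop("fits were not produced on identical datasets", call. = FALSE)
  }
  k4 <- length(fit4$free); k5 <- length(fit5$free)
  n <- fit4$n_points
  delta <- fit4$chi2 - fit5$chi2
  list(
    delta_chi2 = delta,
    n_params = c(fit4 = k4, fit5 = k5),
    aic = c(fit4 = n * log(fit4$chi2 / n) + 2 * k4,
            fit5 = n * log(fit5$chi2 / n) + 2 * k5),
    nesting_violated = (k5 > k4) && (delta < -1e-8)
  )
}
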