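#' Model parameters for the secretory trafficking model
#'
#' The model tracks a cargo over five states: bulk ER, ER exit sites, the
#' non-raft Golgi pool, the raft Golgi pool, and an absorbing post-Golgi
#' state. Inter-organelle transport initiates only from the minor
#' sub-compartments: ER exit sites feed the Golgi with rate `k_a`, and the
#' Golgi raft pool feeds the post-Golgi state with rate `k_b`. Occupancy of
#' the minor sub-compartments is governed by partition coefficients
#' (concentration ratios): `kp_erex` between exit sites and bulk ER, and
#' the construct's fixed `kp_raft` between the raft and non-raft Golgi
#' pools.
#'
#' @param k_a ER-exit-site to Golgi rate constant, 1/hour, `> 0`.
#' @param k_b Golgi-raft to post-Golgi rate constant, 1/hour, `> 0`.
#' @param kp_erex Named numeric vector of ER-exit partition coefficients
#'   (`> 0`), with at least the keys `full_length` and `tmd_only`; extra
#'   construct-specific keys support the five-parameter model variant.
#' @param exchange_rate Intra-organelle exchange rate, 1/hour, used by the
#'   full ODE mode. The default `1e4` is fast compared to fitted transport
#'   rates, so the full system operates in the rapid-equilibrium regime.
#' @param size_fraction_erex,size_fraction_raft Relative size of the minor
#'   sub-compartment within its organelle, in (0,1). With the default 0.5
#'   an organelle amount fraction equals `kp/(kp + 1)`, so GPMV-measured
#'   partition coefficients are usable directly.
#' @return An object of class `model_params`.
#' @export
model_params <- function(k_a, k_b,
                         kp_erex = c(full_length = 4.5, tmd_only = 0.225),
                         exchange_rate = 1e4,
                         size_fraction_erex = 0.5,
                         size_fraction_raft = 0.5) {
  chk_rate <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
      stop(sprintf("`%s` must be a single finite value > 0", nm), call. = FALSE)
    }
  }
  chk_rate(k_a, "k_a"); chk_rate(k_b, "k_b"); chk_rate(exchange_rate, "exchange_rate")
  if (!is.numeric(kp_erex) || is.null(names(kp_erex)) ||
      !all(c("full_length", "tmd_only") %in% names(kp_erex))) {
    stop("`kp_erex` must be a named numeric vector with keys 'full_length' and 'tmd_only'",
         call. = FALSE)
  }
  if (!all(is.finite(kp_erex)) || any(kp_erex <= 0)) {
    stop("all `kp_erex` entries must be finite and > 0", call. = FALSE)
  }
  chk_frac <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0 || x >= 1) {
      stop(sprintf("`%s` must lie strictly inside (0, 1)", nm), call. = FALSE)
    }
  }
  chk_frac(size_fraction_erex, "size_fraction_erex")
  chk_frac(size_fraction_raft, "size_fraction_raft")
  structure(
    list(k_a = as.numeric(k_a), k_b = as.numeric(k_b),
         kp_erex = kp_erex, exchange_rate = as.numeric(exchange_rate),
         size_fraction_erex = as.numeric(size_fraction_erex),
         size_fraction_raft = as.numeric(size_fraction_raft)),
    class = "model_params"
  )
}

#' @export
print.model_params <- function(x, ...) {
  cat("<model_params>\n")
  cat(sprintf("  k_a = %g /h, k_b = %g /h\n", x$k_a, x$k_b))
  cat(sprintf("  kp_erex: %s\n",
              paste(sprintf("%s = %g", names(x$kp_erex), x$kp_erex), collapse = ", ")))
  cat(sprintf("  exchange_rate = %g /h, size fractions (erex, raft) = (%g, %g)\n",
              x$exchange_rate, x$size_fraction_erex, x$size_fraction_raft))
  invisible(x)
}

# State ordering used throughout.
state_names <- function() {
  c("er_bulk", "er_exit", "golgi_nonraft", "golgi_raft", "post_golgi")
}

#' Amount fraction in the minor sub-compartment at partition equilibrium
#'
#' Converts a concentration-ratio partition coefficient into the fraction
#' of an organelle's cargo that sits in the minor sub-compartment (exit
#' sites or raft pool), given the sub-compartment's relative size `a`:
#' `f = kp * a / (kp * a + (1 - a))`.
#'
#' @param kp Partition coefficient (minor over bulk concentration), `>= 0`.
#' @param size_fraction Relative size `a` of the minor sub-compartment,
#'   strictly inside (0,1).
#' @return Amount fraction in `[0, 1)`; 0 exactly when `kp = 0`, and
#'   monotone increasing in `kp`.
#' @examples
#' equilibrium_split(1, 0.5)   # 0.5
#' equilibrium_split(3, 0.5)   # 0.75
#' @export
equilibrium_split <- function(kp, size_fraction) {
  if (!is.numeric(kp) || any(!is.finite(kp)) || any(kp < 0)) {
    stop("`kp` must be finite and >= 0", call. = FALSE)
  }
  if (!is.numeric(size_fraction) || length(size_fraction) != 1L ||
      !is.finite(size_fraction) || size_fraction <= 0 || size_fraction >= 1) {
    stop("`size_fraction` must lie strictly inside (0, 1)", call. = FALSE)
  }
  kp * size_fraction / (kp * size_fraction + (1 - size_fraction))
}

#' Rate matrix of the five-state trafficking system
#'
#' Builds the generator `M` of the linear system `dX/dt = M X` for one
#' construct. Intra-organelle exchange is reversible first-order exchange:
#' the forward (bulk to minor) rate is `exchange_rate` and the backward
#' rate is chosen so the equilibrium minor/bulk amount ratio equals
#' `kp * a / (1 - a)`; a partition coefficient of zero closes the forward
#' edge instead. Mass arriving at the Golgi from ER exit sites is deposited
#' according to the Golgi equilibrium split (indistinguishable from any
#' other split in the fast-exchange regime). The post-Golgi state is
#' absorbing, so every column of `M` sums to zero.
#'
#' @param params A [model_params()] object.
#' @param construct A [construct_spec()]; its `kp_raft` is fixed data.
#' @return A 5x5 matrix with dimnames over the states
#'   `er_bulk, er_exit, golgi_nonraft, golgi_raft, post_golgi`.
#' @export
build_rate_matrix <- function(params, construct) {
  stopifnot(inherits(params, "model_params"), inherits(construct, "construct_spec"))
  key <- resolve_erex_key(construct, params)
  kp_e <- unname(params$kp_erex[[key]])
  kp_r <- construct$kp_raft
  a_e <- params$size_fraction_erex
  a_r <- params$size_fraction_raft
  ex <- params$exchange_rate

  exchange_pair <- function(kp, a) {
    # forward = bulk -> minor, backward = minor -> bulk
    if (kp == 0) return(c(forward = 0, backward = ex))
    r <- kp * a / (1 - a)  # equilibrium minor/bulk amount ratio
    c(forward = ex, backward = ex / r)
  }
  er <- exchange_pair(kp_e, a_e)
  go <- exchange_pair(kp_r, a_r)
  f_raft <- equilibrium_split(kp_r, a_r)

  n <- state_names()
  M <- matrix(0, 5, 5, dimnames = list(n, n))
  M["er_exit", "er_bulk"] <- er[["forward"]]
  M["er_bulk", "er_exit"] <- er[["backward"]]
  M["golgi_nonraft", "er_exit"] <- params$k_a * (1 - f_raft)
  M["golgi_raft", "er_exit"] <- params$k_a * f_raft
  M["golgi_raft", "golgi_nonraft"] <- go[["forward"]]
  M["golgi_nonraft", "golgi_raft"] <- go[["backward"]]
  M["post_golgi", "golgi_raft"] <- params$k_b
  diag(M) <- -colSums(M)
  M
}

#' Initial state for a synchronized-release experiment
#'
#' Places the full cargo amount in the hook organelle (ER hook or Golgi
#' hook), split between its two sub-compartments at the partition
#' equilibrium, mirroring the pre-release steady state of the assay.
#'
#' @param release_site `"ER"` or `"Golgi"`.
#' @param params A [model_params()] object.
#' @param construct A [construct_spec()].
#' @param total Total cargo amount, `> 0`.
#' @return Named numeric vector over the five states.
#' @export
initial_state <- function(release_site = c("ER", "Golgi"), params, construct,
                          total = 1) {
  release_site <- match.arg(release_site)
  stopifnot(inherits(params, "model_params"), inherits(construct, "construct_spec"))
  if (!is.numeric(total) || length(total) != 1L || !is.finite(total) || total <= 0) {
    stop("`total` must be a single finite value > 0", call. = FALSE)
  }
  x <- stats::setNames(numeric(5), state_names())
  if (release_site == "ER") {
    key <- resolve_erex_key(construct, params)
    f <- equilibrium_split(unname(params$kp_erex[[key]]), params$size_fraction_erex)
    x["er_exit"] <- total * f
    x["er_bulk"] <- total * (1 - f)
  } else {
    f <- equilibrium_split(construct$kp_raft, params$size_fraction_raft)
    x["golgi_raft"] <- total * f
    x["golgi_nonraft"] <- total * (1 - f)
  }
  x
}

#' Solve the linear trafficking system
#'
#' Propagates an initial state through `dX/dt = M X` by matrix-exponential
#' evaluation at each requested time, which is exact for this linear
#' system up to floating-point rounding.
#'
#' @param M 5x5 rate matrix from [build_rate_matrix()]; columns must sum
#'   to zero (mass conservation), or an invalid-model error is raised.
#' @param init Initial state vector (length 5, non-negative).
#' @param times Hours; sorted, non-negative.
#' @return Object of class `rush_trajectory`: list with `times` and a
#'   `length(times) x 5` state matrix `states`.
#' @export
solve_trajectory <- function(M, init, times) {
  if (!is.matrix(M) || !all(dim(M) == c(5L, 5L)) || !all(is.finite(M))) {
    stop("`M` must be a finite 5x5 matrix", call. = FALSE)
  }
  scale <- max(1, max(abs(M)))
  if (any(abs(colSums(M)) > 1e-9 * scale)) {
    stop("invalid model: rate-matrix columns do not sum to zero (mass not conserved)",
         call. = FALSE)
  }
  if (length(init) != 5L || any(!is.finite(init)) || any(init < 0)) {
    stop("`init` must be 5 finite non-negative abundances", call. = FALSE)
  }
  if (is.unsorted(times) || any(times < 0) || any(!is.finite(times))) {
    stop("`times` must be sorted, finite and non-negative", call. = FALSE)
  }
  init <- as.numeric(init)
  states <- matrix(0, length(times), 5L,
                   dimnames = list(NULL, state_names()))
  for (i in seq_along(times)) {
    if (times[i] == 0) {
      states[i, ] <- init
    } else {
      E <- as.matrix(Matrix::expm(Matrix::Matrix(M * times[i])))
      states[i, ] <- as.numeric(E %*% init)
    }
  }
  # rounding of the exponential can leave tiny negative mass
  states[states < 0 & states > -1e-9] <- 0
  structure(list(times = as.numeric(times), states = states),
            class = "rush_trajectory")
}

#' @export
print.rush_trajectory <- function(x, ...) {
  cat(sprintf("<rush_trajectory> %d time points over [%g, %g] h\n",
              length(x$times), min(x$times), max(x$times)))
  invisible(x)
}

#' Organelle residence fractions along a trajectory
#'
#' Collapses the five model states into the three observable organelle
#' fractions: ER (bulk + exit sites), Golgi (non-raft + raft) and
#' post-Golgi, each normalized by the conserved total.
#'
#' @param traj A `rush_trajectory`.
#' @return `data.frame` with columns `time_h`, `er_fraction`,
#'   `golgi_fraction`, `post_fraction`; rows sum to 1.
#' @export
residence_fractions <- function(traj) {
  stopifnot(inherits(traj, "rush_trajectory"))
  tot <- rowSums(traj$states)
  if (any(tot <= 0)) {
    stop("trajectory total abundance must be > 0", call. = FALSE)
  }
  s <- traj$states
  data.frame(
    time_h = traj$times,
    er_fraction = (s[, "er_bulk"] + s[, "er_exit"]) / tot,
    golgi_fraction = (s[, "golgi_nonraft"] + s[, "golgi_raft"]) / tot,
    post_fraction = s[, "post_golgi"] / tot
  )
}

#' Residence fractions under the rapid-equilibrium reduction
#'
#' In the fast-exchange limit, sub-compartment occupancies track their
#' partition equilibria and the three-organelle system reduces to
#' effective first-order efflux with rates `alpha = k_a * f_ex` (ER) and
#' `beta = k_b * f_raft` (Golgi), where `f_ex` and `f_raft` are the
#' [equilibrium_split()] amount fractions. ER release follows the standard
#' two-step chain solution; Golgi release is a single exponential. The
#' degenerate case `alpha == beta` is handled by its confluent limit
#' `alpha * t * exp(-alpha * t)`.
#'
#' @inheritParams build_rate_matrix
#' @param release_site `"ER"` or `"Golgi"`.
#' @param times Hours, non-negative.
#' @return `data.frame` as in [residence_fractions()].
#' @export
reduced_model_fractions <- function(params, construct,
                                    release_site = c("ER", "Golgi"), times) {
  release_site <- match.arg(release_site)
  stopifnot(inherits(params, "model_params"), inherits(construct, "construct_spec"))
  if (any(times < 0) || any(!is.finite(times))) {
    stop("`times` must be finite and non-negative", call. = FALSE)
  }
  key <- resolve_erex_key(construct, params)
  f_ex <- equilibrium_split(unname(params$kp_erex[[key]]), params$size_fraction_erex)
  f_raft <- equilibrium_split(construct$kp_raft, params$size_fraction_raft)
  alpha <- params$k_a * f_ex
  beta <- params$k_b * f_raft
  if (release_site == "Golgi") {
    golgi <- exp(-beta * times)
    return(data.frame(time_h = times, er_fraction = 0,
                      golgi_fraction = golgi, post_fraction = 1 - golgi))
  }
  er <- exp(-alpha * times)
  if (abs(beta - alpha) < 1e-12 * max(alpha, beta, 1)) {
    golgi <- alpha * times * exp(-alpha * times)
  } else {
    golgi <- alpha / (beta - alpha) * (exp(-alpha * times) - exp(-beta * times))
  }
  data.frame(time_h = times, er_fraction = er, golgi_fraction = golgi,
             post_fraction = pmax(1 - er - golgi, 0))
}

#' Residence fractions for one construct and release site
#'
#' Front end dispatching between the explicit five-state ODE solution
#' (`mode = "full_ode"`) and the rapid-equilibrium closed form
#' (`mode = "rapid_equilibrium"`, the default used in fitting). At the
#' default `exchange_rate` the two agree to better than 1e-3.
#'
#' @inheritParams reduced_model_fractions
#' @param mode `"rapid_equilibrium"` or `"full_ode"`.
#' @return `data.frame` as in [residence_fractions()].
#' @export
model_fractions <- function(params, construct, release_site = c("ER", "Golgi"),
                            times, mode = c("rapid_equilibrium", "full_ode")) {
  mode <- match.arg(mode)
  release_site <- match.arg(release_site)
  if (mode == "rapid_equilibrium") {
    return(reduced_model_fractions(params, construct, release_site, times))
  }
  M <- build_rate_matrix(params, construct)
  x0 <- initial_state(release_site, params, construct, total = 1)
  residence_fractions(solve_trajectory(M, x0, times))
}
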