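# Independent high-accuracy integrator oracle for the linear system.
oracle_states <- function(M, init, times) {
  deriv <- function(t, y, parms) list(as.numeric(M %*% y))
  out <- deSolve::lsoda(y = as.numeric(init), times = times, func = deriv,
                        rtol = 1e-10, atol = 1e-13)
  unname(as.matrix(out[, -1, drop = FALSE]))
}

# Random valid parameter draw on the scales the model is used at.
random_params <- function() {
  model_params(
    k_a = 10^stats::runif(1, -1, 1),
    k_b = 10^stats::runif(1, -1, 1),
    kp_erex = c(full_length = 10^stats::runif(1, -0.5, 1),
                tmd_only = 10^stats::runif(1, -1.5, 0))
  )
}

random_construct <- function() {
  construct_spec("probe", kp_raft = 10^stats::runif(1, -1, 1),
                 erex_class = sample(c("full_length", "tmd_only"), 1))
}

# Effective efflux rates (the identifiable parameter combinations).
effective_rates <- function(params, construct) {
  key <- if (!is.null(construct$erex_key)) construct$erex_key else construct$erex_class
  f_ex <- equilibrium_split(unname(params$kp_erex[[key]]), params$size_fraction_erex)
  f_raft <- equilibrium_split(construct$kp_raft, params$size_fraction_raft)
  c(alpha = params$k_a * f_ex, beta = params$k_b * f_raft)
}

# Construct table with a sixfold ER-exit contrast between the two
# full-length probes (LAT keeps the shared coefficient, LAT-allL gets its
# own), plus generating parameters carrying the extra coefficient.
sixfold_truth <- function() {
  ct <- default_construct_table()
  ct[["LAT-allL"]]$erex_key <- "LAT-allL"
  params <- model_params(
    k_a = default_truth_params()$k_a,
    k_b = default_truth_params()$k_b,
    kp_erex = c(full_length = 4.5, tmd_only = 0.225, `LAT-allL` = 0.75)
  )
  list(params = params, constructs = ct)
}
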