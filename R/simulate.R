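#' Measurement-noise specification for simulated efflux curves
#'
#' Two noise models mirror the assay's two readouts: additive Gaussian
#' noise on an organelle intensity fraction (imaging readout), and
#' binomial sampling of ER-positive cells out of `n_cells` scored cells
#' (population readout). Replicates are averaged, as experiments average
#' independent repeats.
#'
#' @param kind `"gaussian_additive"` or `"binomial_cells"`.
#' @param sd Gaussian noise standard deviation (fraction units); default
#'   0.03, the scale of replicate scatter in intensity-fraction data.
#' @param n_cells Cells scored per time point for the binomial readout;
#'   default 20.
#' @param n_replicates Independent replicates averaged per point.
#' @return Object of class `noise_model`.
#' @export
noise_model <- function(kind = c("gaussian_additive", "binomial_cells"),
                        sd = 0.03, n_cells = 20, n_replicates = 3) {
  kind <- match.arg(kind)
  if (kind == "gaussian_additive" && (!is.finite(sd) || sd <= 0)) {
    stop("gaussian noise needs `sd` > 0", call. = FALSE)
  }
  if (kind == "binomial_cells" && (n_cells < 1)) {
    stop("binomial noise needs `n_cells` >= 1", call. = FALSE)
  }
  if (n_replicates < 1) stop("`n_replicates` must be >= 1", call. = FALSE)
  structure(list(kind = kind, sd = sd, n_cells = as.integer(n_cells),
                 n_replicates = as.integer(n_replicates)),
            class = "noise_model")
}

#' Ground truth for a simulated experiment suite
#'
#' Fixes everything that determines a synthetic suite: the generating
#' model parameters, the construct panel, the sampling times, the noise
#' model (or `NULL` for noiseless curves) and the seed. Given the same
#' truth, every generator in the package returns identical output.
#'
#' @param params Generating [model_params()].
#' @param constructs [construct_table()] of simulated probes.
#' @param times Sampling times, hours.
#' @param noise A [noise_model()] or `NULL` for exact model curves.
#' @param seed Integer seed.
#' @param mode Model evaluation mode for the mean curves.
#' @return Object of class `synthetic_truth`.
#' @export
synthetic_truth <- function(params = default_truth_params(),
                            constructs = default_construct_table(),
                            times = default_sampling_times(),
                            noise = noise_model("gaussian_additive"),
                            seed = 1, mode = "rapid_equilibrium") {
  stopifnot(inherits(params, "model_params"), inherits(constructs, "construct_table"))
  if (!is.null(noise)) stopifnot(inherits(noise, "noise_model"))
  structure(list(params = params, constructs = constructs,
                 times = as.numeric(times), noise = noise,
                 seed = as.integer(seed), mode = mode),
            class = "synthetic_truth")
}

#' Default generating parameters of the benchmark suite
#'
#' Chosen so the reduced model reproduces the half-time anchors of the
#' four-probe panel: ER exit at 0.7 h for full-length and ~3.1 h for
#' TMD-only constructs (a 20-fold contrast in ER-exit partition
#' coefficients), and Golgi exit at ~0.5 h for the raft probes versus
#' ~1.1 h for the raft-depleted ones.
#'
#' @return A [model_params()] object.
#' @export
default_truth_params <- function() {
  # k_a: ln2 / 0.7h divided by the full-length exit-site occupancy 4.5/5.5
  # k_b: ln2 / 0.5h divided by the raft occupancy 1.8/2.8
  model_params(
    k_a = log(2) / 0.7 / (4.5 / 5.5),
    k_b = log(2) / 0.5 / (1.8 / 2.8),
    kp_erex = c(full_length = 4.5, tmd_only = 0.225)
  )
}

#' Default sampling grid, hours
#' @return Numeric vector spanning 0-8 h, denser early where curves move.
#' @export
default_sampling_times <- function() {
  c(0, 0.25, 0.5, 0.75, 1, 1.5, 2, 3, 4, 6, 8)
}

# Deterministic per-dataset seed: stable under construct/site identity.
dataset_seed <- function(truth, construct, release_site) {
  idx <- match(construct, names(truth$constructs))
  site <- match(release_site, c("ER", "Golgi"))
  (truth$seed * 1009L + idx * 131L + site * 7L) %% .Machine$integer.max
}

#' Simulate one synchronized-release efflux dataset
#'
#' Evaluates the generating model's residence fraction (ER fraction for ER
#' release, Golgi fraction for Golgi release) at the truth's sampling
#' times, then applies the truth's noise model per replicate and averages.
#' Gaussian noise is clipped to `[0, 1]` after addition; the number of
#' clipped draws is recorded in the `n_clipped` attribute.
#'
#' @param truth A [synthetic_truth()].
#' @param construct Construct name from the truth's panel.
#' @param release_site `"ER"` or `"Golgi"`.
#' @return A [rush_dataset()]; noisy datasets carry per-point `sd` across
#'   replicates and an `n_clipped` attribute.
#' @export
generate_rush_timecourse <- function(truth, construct,
                                     release_site = c("ER", "Golgi")) {
  release_site <- match.arg(release_site)
  stopifnot(inherits(truth, "synthetic_truth"))
  if (!construct %in% names(truth$constructs)) {
    stop(sprintf("construct '%s' not in truth's panel", construct), call. = FALSE)
  }
  fr <- model_fractions(truth$params, truth$constructs[[construct]],
                        release_site, truth$times, mode = truth$mode)
  mean_curve <- tracked_fraction(fr, release_site)
  nm <- truth$noise
  if (is.null(nm)) {
    ds <- rush_dataset(construct, release_site, truth$times, mean_curve)
    attr(ds, "n_clipped") <- 0L
    return(ds)
  }
  set.seed(dataset_seed(truth, construct, release_site))
  reps <- matrix(NA_real_, nm$n_replicates, length(truth$times))
  n_clipped <- 0L
  for (r in seq_len(nm$n_replicates)) {
    if (nm$kind == "gaussian_additive") {
      y <- mean_curve + stats::rnorm(length(mean_curve), 0, nm$sd)
      n_clipped <- n_clipped + sum(y < 0 | y > 1)
      y <- pmin(pmax(y, 0), 1)
    } else {
      y <- stats::rbinom(length(mean_curve), nm$n_cells, mean_curve) / nm$n_cells
    }
    reps[r, ] <- y
  }
  values <- colMeans(reps)
  sds <- if (nm$n_replicates > 1) apply(reps, 2, stats::sd) else NULL
  if (!is.null(sds)) sds[sds <= 0] <- NA
  has_sd <- !is.null(sds) && all(is.finite(sds))
  ds <- rush_dataset(construct, release_site, truth$times, values,
                     sd = if (has_sd) sds else NULL,
                     n = rep(nm$n_replicates, length(values)),
                     readout = if (nm$kind == "binomial_cells")
                       "fraction_cells_er_positive" else "organelle_intensity_fraction")
  attr(ds, "n_clipped") <- n_clipped
  ds
}

#' Simulate the benchmark suite of eight efflux datasets
#'
#' The canonical simulated design: the four-probe panel released from the
#' ER and from the Golgi, eight datasets in all, generated from
#' [default_truth_params()] so that the panel's qualitative orderings hold
#' (full-length constructs exit the ER faster than TMD-only ones; raft
#' probes exit the Golgi faster than raft-depleted ones).
#'
#' @param seed Integer seed.
#' @param noise A [noise_model()], or `NULL` for noiseless curves.
#' @param params,constructs,times Override the generating truth.
#' @return List with elements `truth` (the [synthetic_truth()]) and
#'   `datasets` (named list of eight [rush_dataset()] objects).
#' @export
generate_benchmark_suite <- function(seed = 1,
                                     noise = noise_model("gaussian_additive"),
                                     params = default_truth_params(),
                                     constructs = default_construct_table(),
                                     times = default_sampling_times()) {
  truth <- synthetic_truth(params = params, constructs = constructs,
                           times = times, noise = noise, seed = seed)
  grid <- expand.grid(construct = names(constructs),
                      release_site = c("ER", "Golgi"),
                      stringsAsFactors = FALSE)
  datasets <- lapply(seq_len(nrow(grid)), function(i) {
    generate_rush_timecourse(truth, grid$construct[i], grid$release_site[i])
  })
  names(datasets) <- paste(grid$construct, grid$release_site, sep = ":")
  list(truth = truth, datasets = datasets)
}

#' Simulate a fraction-of-ER-positive-cells time course
#'
#' Emulates the population readout used when single-cell kinetics are too
#' slow for live imaging: each cell's ER content decays exponentially with
#' a per-cell rate drawn from a mean-one lognormal (coefficient of
#' variation `cv`), a cell is scored ER-positive while its content exceeds
#' `threshold`, and the positive fraction among `n_cells` is averaged over
#' replicates. With `cv = 0` the expected curve is a step at
#' `t* = ln(1/threshold) / rate`; heterogeneity smears the step into the
#' sigmoid that a single exponential approximates in practice.
#'
#' @param rate Mean ER-exit rate, 1/hour, `> 0`.
#' @param threshold Detection threshold on relative ER content, in (0,1).
#' @param times Hours.
#' @param n_cells Cells scored per replicate and time point.
#' @param n_replicates Replicates averaged.
#' @param cv Lognormal coefficient of variation of per-cell rates.
#' @param seed Integer seed.
#' @return `data.frame` with columns `time_h`, `value` (positive
#'   fraction), `sd` across replicates.
#' @export
generate_population_er_positive <- function(rate, threshold = 0.5, times,
                                            n_cells = 20, n_replicates = 3,
                                            cv = 0.3, seed = 1) {
  if (!is.finite(rate) || rate <= 0) stop("`rate` must be > 0", call. = FALSE)
  if (threshold <= 0 || threshold >= 1) {
    stop("`threshold` must lie in (0, 1)", call. = FALSE)
  }
  if (cv < 0) stop("`cv` must be >= 0", call. = FALSE)
  set.seed(as.integer(seed))
  sdlog <- sqrt(log(1 + cv^2))
  reps <- matrix(NA_real_, n_replicates, length(times))
  for (r in seq_len(n_replicates)) {
    cell_rates <- rate * stats::rlnorm(n_cells, meanlog = -sdlog^2 / 2, sdlog = sdlog)
    # content_i(t) = exp(-rate_i * t); positive while content > threshold
    positive <- outer(cell_rates, times, function(k, t) exp(-k * t) > threshold)
    reps[r, ] <- colMeans(positive)
  }
  data.frame(time_h = as.numeric(times), value = colMeans(reps),
             sd = if (n_replicates > 1) apply(reps, 2, stats::sd) else NA_real_)
}

#' Simulate a two-channel GPMV membrane line scan
#'
#' Builds a 1-D intensity profile crossing a phase-separated vesicle
#' twice: two Gaussian membrane peaks over a flat background. The
#' construct channel's background-subtracted peak heights are
#' `amplitude * kp_true` (raft crossing) and `amplitude` (non-raft), so
#' their ratio is exactly `kp_true`. The disordered-phase marker channel
#' is anti-correlated: bright on the non-raft crossing, dim (by
#' `marker_contrast`) on the raft crossing. Which crossing is the raft
#' one is randomized per vesicle; the generating layout is kept in the
#' `truth` element for round-trip tests.
#'
#' @param kp_true Generating raft partition coefficient, `>= 0`.
#' @param background Baseline intensity per channel.
#' @param amplitude Background-subtracted non-raft construct peak height,
#'   `> 0`; also the marker's bright-peak height.
#' @param noise_sd Additive Gaussian noise, intensity units.
#' @param n_points Profile length (>= 16).
#' @param marker_contrast Bright/dim ratio of the marker channel.
#' @param seed Integer seed.
#' @return Object of class `gpmv_profile`: `positions`,
#'   `construct_channel`, `marker_channel`, `background`, `truth`.
#' @export
generate_gpmv_linescan <- function(kp_true, background = 50, amplitude = 50,
                                   noise_sd = 0, n_points = 64,
                                   marker_contrast = 4, seed = 1) {
  if (!is.finite(kp_true) || kp_true < 0) stop("`kp_true` must be >= 0", call. = FALSE)
  if (amplitude <= 0) stop("`amplitude` must be > 0", call. = FALSE)
  if (n_points < 16) stop("`n_points` must be >= 16", call. = FALSE)
  set.seed(as.integer(seed))
  pos <- seq_len(n_points)
  p1 <- round(n_points / 4); p2 <- round(3 * n_points / 4)
  raft_first <- stats::runif(1) < 0.5
  raft_pos <- if (raft_first) p1 else p2
  nonraft_pos <- if (raft_first) p2 else p1
  width <- n_points / 24
  peak <- function(center) exp(-((pos - center)^2) / (2 * width^2))
  construct <- background +
    amplitude * kp_true * peak(raft_pos) +
    amplitude * peak(nonraft_pos)
  marker <- background +
    (amplitude / marker_contrast) * peak(raft_pos) +
    amplitude * peak(nonraft_pos)
  if (noise_sd > 0) {
    construct <- construct + stats::rnorm(n_points, 0, noise_sd)
    marker <- marker + stats::rnorm(n_points, 0, noise_sd)
  }
  structure(
    list(positions = pos,
         construct_channel = pmax(construct, 0),
         marker_channel = pmax(marker, 0),
         background = c(construct = background, marker = background),
         truth = list(kp_true = kp_true, raft_position = raft_pos,
                      nonraft_position = nonraft_pos)),
    class = "gpmv_profile"
  )
}

#' Simulate a correlated two-channel image pair
#'
#' Generates two images whose in-mask pixel pairs follow a bivariate
#' normal with correlation `rho_target`; pixels outside the mask are
#' independent background noise. `rho_target = 1` duplicates the channel
#' exactly. The default mask is a centered disk.
#'
#' @param rho_target Target Pearson correlation in `[-1, 1]`.
#' @param dim Image dimensions `c(rows, cols)`.
#' @param mask Logical matrix of the same dimension; must contain at
#'   least one pixel. `NULL` for the default disk.
#' @param mean,sd In-mask signal mean and standard deviation.
#' @param background,background_sd Out-of-mask noise parameters.
#' @param seed Integer seed.
#' @return List with `image_a`, `image_b` (matrices) and `mask`.
#' @export
generate_coloc_pair <- function(rho_target, dim = c(64, 64), mask = NULL,
                                mean = 100, sd = 20,
                                background = 10, background_sd = 2, seed = 1) {
  if (!is.finite(rho_target) || abs(rho_target) > 1) {
    stop("`rho_target` must lie in [-1, 1]", call. = FALSE)
  }
  if (is.null(mask)) mask <- disk_mask(dim, radius_frac = 0.4)
  if (!is.logical(mask) || !all(base::dim(mask) == dim)) {
    stop("`mask` must be a logical matrix matching `dim`", call. = FALSE)
  }
  n_in <- sum(mask)
  if (n_in < 1) stop("empty mask", call. = FALSE)
  set.seed(as.integer(seed))
  a <- matrix(stats::rnorm(prod(dim), background, background_sd), dim[1], dim[2])
  b <- matrix(stats::rnorm(prod(dim), background, background_sd), dim[1], dim[2])
  z1 <- stats::rnorm(n_in)
  a[mask] <- mean + sd * z1
  if (abs(rho_target) == 1) {
    b[mask] <- mean + sd * sign(rho_target) * z1
  } else {
    z2 <- stats::rnorm(n_in)
    b[mask] <- mean + sd * (rho_target * z1 + sqrt(1 - rho_target^2) * z2)
  }
  list(image_a = a, image_b = b, mask = mask)
}

#' Circular mask helper
#' @param dim Image dimensions `c(rows, cols)`.
#' @param radius_frac Disk radius as a fraction of the smaller dimension.
#' @param center Disk center (row, col); default image center.
#' @return Logical matrix.
#' @export
disk_mask <- function(dim, radius_frac = 0.4, center = (dim + 1) / 2) {
  r <- radius_frac * min(dim)
  rows <- matrix(seq_len(dim[1]), dim[1], dim[2])
  cols <- matrix(seq_len(dim[2]), dim[1], dim[2], byrow = TRUE)
  (rows - center[1])^2 + (cols - center[2])^2 <= r^2
}

#' Render a synthetic cell image from a Golgi residence fraction
#'
#' Draws a cell as a large disk with a smaller Golgi disk inside it and
#' distributes a fixed total signal so that `golgi_fraction` of it lies in
#' the Golgi mask and the rest is spread over the remaining cell area,
#' plus a constant background and optional Gaussian noise. Measuring the
#' rendered image with [organelle_fraction()] recovers the generating
#' fraction, closing the render/measure round trip.
#'
#' @param golgi_fraction Fraction of cellular signal in the Golgi, `[0, 1]`.
#' @param dim Image dimensions.
#' @param total Total cellular signal (summed intensity above background).
#'   The default gives confocal-like per-pixel signal well above the noise
#'   floor, so the positive-part background subtraction of the
#'   measurement introduces negligible bias.
#' @param background Constant background level.
#' @param noise_sd Additive Gaussian noise.
#' @param seed Integer seed.
#' @return List with `image`, `golgi_mask`, `cell_mask`, `background`.
#' @export
render_golgi_image <- function(golgi_fraction, dim = c(48, 48), total = 1e5,
                               background = 20, noise_sd = 0, seed = 1) {
  if (!is.finite(golgi_fraction) || golgi_fraction < 0 || golgi_fraction > 1) {
    stop("`golgi_fraction` must lie in [0, 1]", call. = FALSE)
  }
  cell <- disk_mask(dim, radius_frac = 0.45)
  golgi <- disk_mask(dim, radius_frac = 0.12,
                     center = (dim + 1) / 2 + c(0, round(dim[2] * 0.12)))
  golgi <- golgi & cell
  rest <- cell & !golgi
  img <- matrix(background, dim[1], dim[2])
  img[golgi] <- background + total * golgi_fraction / sum(golgi)
  img[rest] <- background + total * (1 - golgi_fraction) / sum(rest)
  if (noise_sd > 0) {
    set.seed(as.integer(seed))
    img <- img + matrix(stats::rnorm(prod(dim), 0, noise_sd), dim[1], dim[2])
    img[img < 0] <- 0
  }
  list(image = img, golgi_mask = golgi, cell_mask = cell, background = background)
}
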