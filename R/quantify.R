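#' Locate the raft and non-raft membrane crossings in a line scan
#'
#' A line scan across a phase-separated vesicle crosses the membrane
#' twice. The two largest local maxima of the summed two-channel profile
#' are taken as the crossings; the crossing with the lower
#' disordered-phase-marker intensity is labelled the raft phase (the
#' marker strongly partitions to the disordered phase). Profiles without
#' two sufficiently prominent peaks are rejected with a classed
#' `rush_vesicle_rejected` error so callers can count exclusions.
#'
#' @param profile A `gpmv_profile` (see [generate_gpmv_linescan()]), or
#'   any list with `positions`, `construct_channel`, `marker_channel`.
#' @param prominence Minimum peak height above the profile floor,
#'   as a fraction of the profile's dynamic range. Default 0.2.
#' @param min_separation Minimum distance between the two peaks, points.
#' @return List with `raft`, `nonraft` (positions, index units) and
#'   `raft_marker`, `nonraft_marker` intensities.
#' @export
identify_phases <- function(profile, prominence = 0.2, min_separation = 6L) {
  validate_profile(profile)
  s <- profile$construct_channel + profile$marker_channel
  n <- length(s)
  rng <- diff(range(s))
  if (rng <= 0) stop_vesicle_rejected("flat profile: no membrane peaks")
  # interior local maxima (plateaus count once)
  cand <- which(diff(sign(diff(s))) < 0) + 1L
  cand <- cand[s[cand] - min(s) >= prominence * rng]
  if (length(cand) < 2L) {
    stop_vesicle_rejected("fewer than two peaks above the prominence threshold")
  }
  cand <- cand[order(s[cand], decreasing = TRUE)]
  p1 <- cand[1]
  p2 <- cand[which(abs(cand - p1) >= min_separation)[1]]
  if (is.na(p2)) {
    stop_vesicle_rejected("the two candidate peaks are not separated membrane crossings")
  }
  m <- profile$marker_channel
  raft <- if (m[p1] < m[p2]) p1 else p2
  nonraft <- if (raft == p1) p2 else p1
  list(raft = profile$positions[raft], nonraft = profile$positions[nonraft],
       raft_index = raft, nonraft_index = nonraft,
       raft_marker = m[raft], nonraft_marker = m[nonraft])
}

#' Per-vesicle raft partition coefficient from a line scan
#'
#' The raft partition coefficient is the ratio of background-subtracted
#' construct intensities in the raft versus non-raft phase. Peak
#' intensities are averaged over a fixed window (default 3 points)
#' centered on each membrane crossing. When no background is supplied it
#' is estimated per channel as the modal intensity of points away from
#' both peaks. A non-positive background-subtracted non-raft intensity
#' rejects the vesicle.
#'
#' @param profile A `gpmv_profile`.
#' @param background Construct-channel background intensity; `NULL` to
#'   estimate from off-peak points.
#' @param window Peak averaging window, points (odd).
#' @param ... Passed to [identify_phases()].
#' @return Single non-negative partition coefficient.
#' @export
compute_kp <- function(profile, background = NULL, window = 3L, ...) {
  phases <- identify_phases(profile, ...)
  x <- profile$construct_channel
  half <- (window - 1L) %/% 2L
  win_mean <- function(i) {
    idx <- max(1L, i - half):min(length(x), i + half)
    mean(x[idx])
  }
  i_raft <- win_mean(phases$raft_index)
  i_nonraft <- win_mean(phases$nonraft_index)
  if (is.null(background)) {
    off <- abs(seq_along(x) - phases$raft_index) > 3L * window &
      abs(seq_along(x) - phases$nonraft_index) > 3L * window
    background <- if (sum(off) >= 4) intensity_mode(x[off]) else min(x)
  }
  denom <- i_nonraft - background
  if (denom <= 0) {
    stop_vesicle_rejected("non-raft background-subtracted intensity is not positive")
  }
  max((i_raft - background) / denom, 0)
}

# Modal intensity via kernel density peak; robust for flat backgrounds.
intensity_mode <- function(x) {
  if (length(unique(x)) == 1L) return(x[1])
  d <- stats::density(x, n = 512)
  d$x[which.max(d$y)]
}

#' Hierarchical summary of per-vesicle partition coefficients
#'
#' Experiments, not vesicles, are the unit of replication: vesicle values
#' are averaged within each independent experiment, and the grand mean and
#' standard deviation are computed over experiment means.
#'
#' @param kp Numeric vector of per-vesicle partition coefficients.
#' @param experiment Factor/vector of experiment labels, one per vesicle.
#' @return Object of class `kp_measurement` with `per_vesicle_kp`,
#'   `per_experiment_means`, `grand_mean`, `sd`, `n_vesicles`,
#'   `n_experiments`.
#' @export
summarize_kp <- function(kp, experiment) {
  if (length(kp) != length(experiment) || !length(kp)) {
    stop("`kp` and `experiment` must be non-empty and equal length", call. = FALSE)
  }
  if (any(!is.finite(kp)) || any(kp < 0)) {
    stop("partition coefficients must be finite and >= 0", call. = FALSE)
  }
  means <- tapply(kp, experiment, mean)
  structure(
    list(per_vesicle_kp = kp,
         per_experiment_means = as.numeric(means),
         experiments = names(means),
         grand_mean = mean(means),
         sd = if (length(means) > 1) stats::sd(means) else NA_real_,
         n_vesicles = length(kp), n_experiments = length(means)),
    class = "kp_measurement"
  )
}

#' @export
print.kp_measurement <- function(x, ...) {
  cat(sprintf("<kp_measurement> K_p = %.3g +/- %.3g (%d experiments, %d vesicles)\n",
              x$grand_mean, x$sd, x$n_experiments, x$n_vesicles))
  invisible(x)
}

#' Compare raft affinity between two construct groups
#'
#' Welch's two-sample t-test on per-experiment mean partition
#' coefficients. Groups with fewer than two experiments are refused:
#' a single experiment mean carries no between-experiment variance.
#'
#' @param group_a,group_b `kp_measurement` objects.
#' @return List with `statistic`, `p_value`, `df`, group means.
#' @export
compare_kp_groups <- function(group_a, group_b) {
  stopifnot(inherits(group_a, "kp_measurement"), inherits(group_b, "kp_measurement"))
  if (group_a$n_experiments < 2 || group_b$n_experiments < 2) {
    stop("each group needs >= 2 independent experiments for a comparison",
         call. = FALSE)
  }
  ht <- stats::t.test(group_a$per_experiment_means, group_b$per_experiment_means,
                      var.equal = FALSE)
  list(statistic = unname(ht$statistic), p_value = ht$p.value,
       df = unname(ht$parameter),
       mean_a = group_a$grand_mean, mean_b = group_b$grand_mean)
}

#' Pearson colocalization within a mask
#'
#' Pearson correlation of two channels restricted to in-mask pixels, the
#' standard colocalization readout for organelle-masked super-resolution
#' or confocal image pairs. Invariant to per-channel affine intensity
#' transforms with positive gain.
#'
#' @param image_a,image_b Numeric matrices of identical dimension.
#' @param mask Logical matrix; `NULL` uses every pixel.
#' @return Correlation in `[-1, 1]`.
#' @export
pearson_coloc <- function(image_a, image_b, mask = NULL) {
  if (!all(dim(image_a) == dim(image_b))) {
    stop("images must have identical dimensions", call. = FALSE)
  }
  if (is.null(mask)) mask <- matrix(TRUE, nrow(image_a), ncol(image_a))
  if (!all(dim(mask) == dim(image_a))) {
    stop("mask must match the image dimensions", call. = FALSE)
  }
  a <- image_a[mask]; b <- image_b[mask]
  if (length(a) < 2L) stop("need >= 2 in-mask pixels", call. = FALSE)
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    stop("undefined correlation: zero variance in a channel within the mask",
         call. = FALSE)
  }
  stats::cor(a, b)
}

#' Fraction of cellular signal inside an organelle mask
#'
#' Background-subtracted intensities are floored at zero and summed; the
#' organelle fraction is the in-mask sum over the whole-cell sum. This is
#' the readout behind fraction-in-Golgi curves measured against a
#' Golgi-marker mask.
#'
#' @param image Numeric matrix.
#' @param mask Logical organelle mask (nonzero = inside).
#' @param background Scalar background level subtracted before summing.
#' @param cell_mask Optional logical mask of the whole cell; default all
#'   pixels.
#' @return Fraction in `[0, 1]`.
#' @export
organelle_fraction <- function(image, mask, background = 0, cell_mask = NULL) {
  mask <- mask != 0
  if (!all(dim(mask) == dim(image))) {
    stop("mask must match the image dimensions", call. = FALSE)
  }
  if (is.null(cell_mask)) cell_mask <- matrix(TRUE, nrow(image), ncol(image))
  cell_mask <- cell_mask != 0
  sig <- pmax(image - background, 0)
  total <- sum(sig[cell_mask])
  if (total <= 0) stop("undefined fraction: zero total cell signal", call. = FALSE)
  sum(sig[mask & cell_mask]) / total
}

stop_vesicle_rejected <- function(msg) {
  cond <- structure(
    class = c("rush_vesicle_rejected", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  )
  stop(cond)
}

validate_profile <- function(profile) {
  need <- c("positions", "construct_channel", "marker_channel")
  if (!all(need %in% names(profile))) {
    stop("profile must have positions, construct_channel and marker_channel",
         call. = FALSE)
  }
  n <- length(profile$positions)
  if (n < 16L || length(profile$construct_channel) != n ||
      length(profile$marker_channel) != n) {
    stop("profile channels must be equal length with >= 16 points", call. = FALSE)
  }
  if (any(profile$construct_channel < 0) || any(profile$marker_channel < 0)) {
    stop("intensities must be non-negative", call. = FALSE)
  }
  invisible(profile)
}
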