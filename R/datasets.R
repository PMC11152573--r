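#' One efflux experiment as a dataset
#'
#' Bundles a residence-fraction time course with the construct and
#' release site that produced it. ER-release datasets record the ER
#' residence fraction over time, Golgi-release datasets the Golgi
#' fraction, matching how the assay is read out at each hook.
#'
#' @param construct Construct name (must resolve in the construct table
#'   used for fitting).
#' @param release_site `"ER"` or `"Golgi"`.
#' @param times Hours, strictly increasing, `>= 0`.
#' @param values Residence fractions; small normalization overshoot is
#'   tolerated (`[-0.05, 1.05]`).
#' @param sd Optional per-point standard deviations (`> 0`).
#' @param n Optional per-point sample counts.
#' @param readout `"organelle_intensity_fraction"` (imaging readout) or
#'   `"fraction_cells_er_positive"` (population readout).
#' @return Object of class `rush_dataset`.
#' @export
rush_dataset <- function(construct, release_site = c("ER", "Golgi"),
                         times, values, sd = NULL, n = NULL,
                         readout = c("organelle_intensity_fraction",
                                     "fraction_cells_er_positive")) {
  release_site <- match.arg(release_site)
  readout <- match.arg(readout)
  times <- as.numeric(times); values <- as.numeric(values)
  if (length(times) != length(values) || length(times) < 1L) {
    stop("`times` and `values` must be non-empty and equal length", call. = FALSE)
  }
  if (is.unsorted(times, strictly = TRUE) || any(times < 0)) {
    stop("`times` must be strictly increasing and non-negative", call. = FALSE)
  }
  if (any(!is.finite(values)) || any(values < -0.05) || any(values > 1.05)) {
    stop("`values` must be finite residence fractions within [-0.05, 1.05]",
         call. = FALSE)
  }
  if (!is.null(sd)) {
    sd <- as.numeric(sd)
    if (length(sd) != length(times) || any(!is.finite(sd)) || any(sd <= 0)) {
      stop("`sd`, when given, must be positive and per-point", call. = FALSE)
    }
  }
  if (!is.null(n)) {
    n <- as.integer(n)
    if (length(n) != length(times) || any(n < 1L)) {
      stop("`n`, when given, must be per-point counts >= 1", call. = FALSE)
    }
  }
  structure(
    list(construct = construct, release_site = release_site,
         times = times, values = values, sd = sd, n = n, readout = readout),
    class = "rush_dataset"
  )
}

#' @export
print.rush_dataset <- function(x, ...) {
  cat(sprintf("<rush_dataset> %s, %s release, %d points over [%g, %g] h\n",
              x$construct, x$release_site, length(x$times),
              min(x$times), max(x$times)))
  invisible(x)
}

dataset_key <- function(ds) paste(ds$construct, ds$release_site, sep = ":")

# The organelle fraction a dataset reports, from a model fraction table.
tracked_fraction <- function(fractions, release_site) {
  if (release_site == "ER") fractions$er_fraction else fractions$golgi_fraction
}
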