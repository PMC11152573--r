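#' Read efflux datasets from a delimited-text table
#'
#' Expects a comma-separated file with header columns `construct`,
#' `release_site`, `time_h`, `value` and optionally `sd` and `n`. Rows are
#' grouped into one dataset per (construct, release site), sorted by time;
#' duplicate (construct, site, time) rows are averaged with a warning.
#' Malformed cells raise parse errors naming the offending row.
#'
#' @param path File path.
#' @param time_unit `"h"` (default) or `"min"`; minute input is converted
#'   to hours.
#' @return Named list of [rush_dataset()] objects, keyed
#'   `construct:release_site`.
#' @export
read_timecourse_table <- function(path, time_unit = c("h", "min")) {
  time_unit <- match.arg(time_unit)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("construct", "release_site", "time_h", "value")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop(sprintf("missing required column(s): %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  for (col in c("time_h", "value", intersect(c("sd", "n"), names(df)))) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) & !is.na(df[[col]]) & df[[col]] != "")
    if (length(bad)) {
      stop(sprintf("non-numeric '%s' at row %d: '%s'", col, bad[1], df[[col]][bad[1]]),
           call. = FALSE)
    }
    df[[col]] <- v
  }
  bad_val <- which(!is.finite(df$value) | df$value < -0.05 | df$value > 1.05)
  if (length(bad_val)) {
    stop(sprintf("value outside [-0.05, 1.05] at row %d: %g",
                 bad_val[1], df$value[bad_val[1]]), call. = FALSE)
  }
  if (time_unit == "min") df$time_h <- df$time_h / 60
  if (!all(df$release_site %in% c("ER", "Golgi"))) {
    stop("release_site must be 'ER' or 'Golgi'", call. = FALSE)
  }

  split_keys <- paste(df$construct, df$release_site, sep = ":")
  out <- lapply(split(df, split_keys), function(g) {
    if (anyDuplicated(g$time_h)) {
      warning(sprintf("duplicate time points in '%s:%s' averaged",
                      g$construct[1], g$release_site[1]), call. = FALSE)
      agg <- stats::aggregate(g[intersect(c("value", "sd", "n"), names(g))],
                              by = list(time_h = g$time_h), FUN = mean)
      g <- cbind(construct = g$construct[1], release_site = g$release_site[1], agg)
    }
    g <- g[order(g$time_h), ]
    rush_dataset(g$construct[1], g$release_site[1], g$time_h, g$value,
                 sd = if ("sd" %in% names(g) && all(is.finite(g$sd)) &&
                          all(g$sd > 0)) g$sd else NULL,
                 n = if ("n" %in% names(g) && all(is.finite(g$n))) g$n else NULL)
  })
  out[order(names(out))]
}

#' Write efflux datasets to a delimited-text table
#'
#' Inverse of [read_timecourse_table()]: the written file reads back to
#' the same datasets.
#'
#' @param datasets List of [rush_dataset()] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_timecourse_table <- function(datasets, path) {
  rows <- lapply(datasets, function(ds) {
    df <- data.frame(construct = ds$construct, release_site = ds$release_site,
                     time_h = ds$times, value = ds$values)
    df$sd <- if (is.null(ds$sd)) NA_real_ else ds$sd
    df$n <- if (is.null(ds$n)) NA_integer_ else ds$n
    df
  })
  df <- do.call(rbind, rows)
  if (all(is.na(df$sd))) df$sd <- NULL
  if (all(is.na(df$n))) df$n <- NULL
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Export model residence-fraction trajectories as delimited text
#'
#' @param fractions `data.frame` from [model_fractions()] or
#'   [residence_fractions()].
#' @param construct,release_site Labels recorded with each row.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trajectory_table <- function(fractions, construct, release_site, path) {
  df <- cbind(fractions, construct = construct, release_site = release_site)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a global-fit report
#'
#' Writes a human-readable text report and a machine-readable JSON twin
#' (`<path>.json`) containing the variant, best-fit parameters with
#' units, the chi-square, restart statistics and the seed that reproduces
#' the run.
#'
#' @param fit A `rush_global_fit`.
#' @param path Path of the text report; the JSON twin gets `.json`
#'   appended.
#' @return Invisibly, the JSON path.
#' @export
write_fit_report <- function(fit, path) {
  stopifnot(inherits(fit, "rush_global_fit"))
  finite <- fit$restart_chi2s[is.finite(fit$restart_chi2s)]
  lines <- c(
    "Global trafficking-model fit",
    sprintf("variant: %s (%d free parameters)", fit$variant, length(fit$free)),
    sprintf("chi2: %.10g", fit$chi2),
    sprintf("restarts: %d (%d converged to finite chi2)",
            fit$n_restarts, length(finite)),
    sprintf("seed: %d", fit$seed),
    sprintf("restart chi2 quartiles: %s",
            paste(signif(stats::quantile(finite), 6), collapse = ", ")),
    "best-fit parameters:",
    vapply(names(fit$free), function(nm) {
      unit <- if (nm %in% c("k_a", "k_b")) "1/h" else "dimensionless"
      sprintf("  %s = %.8g [%s]", nm, fit$free[[nm]], unit)
    }, character(1))
  )
  writeLines(lines, path)
  json_path <- paste0(path, ".json")
  jsonlite::write_json(
    list(variant = fit$variant,
         free = as.list(fit$free),
         chi2 = fit$chi2,
         n_restarts = fit$n_restarts,
         seed = fit$seed,
         converged = fit$converged,
         restart_chi2s = fit$restart_chi2s,
         dataset_keys = fit$dataset_keys,
         mode = fit$mode),
    json_path, auto_unbox = TRUE, digits = NA)
  invisible(json_path)
}

#' Read back the machine-readable twin of a fit report
#'
#' @param json_path Path written by [write_fit_report()].
#' @return List mirroring the exported fields.
#' @export
read_fit_report <- function(json_path) {
  jsonlite::read_json(json_path, simplifyVector = TRUE)
}

#' Record a reproducibility manifest for an analysis step
#'
#' Captures the command label, its full parameter set, the seed(s), MD5
#' digests of the input files and the package version, so a stochastic
#' step can be re-run bit-identically from the manifest alone.
#'
#' @param command Label of the analysis step.
#' @param params Named list of parameters.
#' @param seed Integer seed(s) used.
#' @param inputs Character vector of input file paths (digested).
#' @param path Output JSON path.
#' @return Invisibly, the manifest as a list.
#' @export
write_run_manifest <- function(command, params, seed, inputs = character(), path) {
  digests <- if (length(inputs)) as.list(tools::md5sum(inputs)) else list()
  manifest <- list(
    command = command,
    params = params,
    seed = seed,
    input_digests = digests,
    package_version = as.character(utils::packageVersion("rushkinetics")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' Write an intensity image or binary mask as TIFF
#'
#' Images are written as 32-bit float TIFF with intensities scaled by
#' `scale` (so values up to `scale` survive the format's unit range);
#' masks as 8-bit TIFF with nonzero meaning in-mask.
#'
#' @param image Numeric matrix of non-negative intensities.
#' @param path Output path.
#' @param scale Intensity corresponding to full scale.
#' @return `path`, invisibly.
#' @export
write_image_tiff <- function(image, path, scale = 65535) {
  if (any(image < 0) || any(image > scale)) {
    stop(sprintf("intensities must lie in [0, %g]", scale), call. = FALSE)
  }
  tiff::writeTIFF(image / scale, path, bits.per.sample = 32L)
  invisible(path)
}

#' @rdname write_image_tiff
#' @export
read_image_tiff <- function(path, scale = 65535) {
  tiff::readTIFF(path) * scale
}

#' @rdname write_image_tiff
#' @param mask Logical (or 0/1) matrix.
#' @export
write_mask_tiff <- function(mask, path) {
  tiff::writeTIFF((mask != 0) * 1, path, bits.per.sample = 8L)
  invisible(path)
}

#' @rdname write_image_tiff
#' @export
read_mask_tiff <- function(path) {
  tiff::readTIFF(path) > 0
}
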