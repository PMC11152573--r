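#' Define a cargo construct
#'
#' A construct is a transmembrane cargo characterized by its measured raft
#' partition coefficient (the concentration ratio between the ordered and
#' disordered phase of a GPMV) and by the class of ER-exit partition
#' coefficient it uses in the trafficking model: full-length constructs
#' carry the cytosolic export motif, TMD-only constructs do not.
#'
#' @param name Short label, e.g. `"LAT"`.
#' @param kp_raft Raft partition coefficient, dimensionless, `>= 0`.
#'   Measured in GPMVs and held fixed during model fitting.
#' @param erex_class Either `"full_length"` or `"tmd_only"`; selects which
#'   ER-exit partition coefficient of [model_params()] applies.
#' @param erex_key Optional label of a construct-specific ER-exit partition
#'   coefficient. When set, it takes precedence over `erex_class`; this is
#'   how the five-parameter model variant lets one full-length construct
#'   carry its own ER-exit affinity.
#' @return An object of class `construct_spec`.
#' @seealso [default_construct_table()], [model_params()]
#' @export
construct_spec <- function(name, kp_raft,
                           erex_class = c("full_length", "tmd_only"),
                           erex_key = NULL) {
  erex_class <- match.arg(erex_class)
  if (!is.character(name) || length(name) != 1L || !nzchar(name)) {
    stop("`name` must be a non-empty string", call. = FALSE)
  }
  if (!is.numeric(kp_raft) || length(kp_raft) != 1L ||
      !is.finite(kp_raft) || kp_raft < 0) {
    stop("`kp_raft` must be a single finite value >= 0", call. = FALSE)
  }
  if (!is.null(erex_key) &&
      (!is.character(erex_key) || length(erex_key) != 1L || !nzchar(erex_key))) {
    stop("`erex_key` must be NULL or a non-empty string", call. = FALSE)
  }
  structure(
    list(name = name, kp_raft = as.numeric(kp_raft),
         erex_class = erex_class, erex_key = erex_key),
    class = "construct_spec"
  )
}

#' @export
print.construct_spec <- function(x, ...) {
  key <- if (is.null(x$erex_key)) x$erex_class else x$erex_key
  cat(sprintf("<construct_spec> %s  kp_raft = %g  erex = %s\n",
              x$name, x$kp_raft, key))
  invisible(x)
}

#' Build a construct table
#'
#' @param ... `construct_spec` objects.
#' @return Named list of constructs, class `construct_table`.
#' @export
construct_table <- function(...) {
  specs <- list(...)
  if (length(specs) == 1L && is.list(specs[[1]]) &&
      !inherits(specs[[1]], "construct_spec")) {
    specs <- specs[[1]]
  }
  ok <- vapply(specs, inherits, logical(1), "construct_spec")
  if (!all(ok)) stop("all entries must be construct_spec objects", call. = FALSE)
  names(specs) <- vapply(specs, `[[`, character(1), "name")
  if (anyDuplicated(names(specs))) {
    stop("duplicate construct names in table", call. = FALSE)
  }
  structure(specs, class = "construct_table")
}

#' Default LAT-based probe panel
#'
#' The four-probe design used throughout: a raft-preferring full-length
#' adapter (LAT), its TMD-only version, the full-length protein with its TMD
#' swapped for a raft-excluded poly-Leu TMD (LAT-allL), and the isolated
#' poly-Leu TMD (allL-TMD). Raft partition coefficients are on the scale
#' measured for these probes in GPMVs: ~1.8 for the raft-preferring TMD and
#' ~0.4 for the raft-depleted one.
#'
#' @return A `construct_table` with entries `LAT`, `LAT-TMD`, `LAT-allL`,
#'   `allL-TMD`.
#' @export
default_construct_table <- function() {
  construct_table(
    construct_spec("LAT",      kp_raft = 1.8, erex_class = "full_length"),
    construct_spec("LAT-TMD",  kp_raft = 1.8, erex_class = "tmd_only"),
    construct_spec("LAT-allL", kp_raft = 0.4, erex_class = "full_length"),
    construct_spec("allL-TMD", kp_raft = 0.4, erex_class = "tmd_only")
  )
}

# Resolve which kp_erex entry a construct uses (override key wins).
resolve_erex_key <- function(construct, params) {
  key <- if (!is.null(construct$erex_key)) construct$erex_key else construct$erex_class
  if (!key %in% names(params$kp_erex)) {
    stop(sprintf("construct '%s' needs kp_erex['%s'], which is not in the model parameters",
                 construct$name, key), call. = FALSE)
  }
  key
}
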