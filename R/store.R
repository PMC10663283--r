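#' Sample store: uniform points in a polytope
#'
#' A `sample_store` holds sampled points (rows) over labeled
#' `(muscle, time-index)` variables (columns), together with provenance
#' metadata: sampling method, RNG seed, burn-in, thinning, the
#' activation-contraction limit `delta` and the configuration fingerprint of
#' the run that produced it.
#'
#' @param samples numeric matrix, `n_samples x n_vars`, values in `[0,1]`.
#' @param var_labels data.frame with `muscle`, `time`, `label` per column.
#' @param provenance named list of metadata.
#' @return An object of class `sample_store`.
#' @export
sample_store <- function(samples, var_labels, provenance = list()) {
  samples <- as.matrix(samples)
  storage.mode(samples) <- "double"
  stopifnot(is.data.frame(var_labels),
            all(c("muscle", "time", "label") %in% names(var_labels)))
  if (ncol(samples) != nrow(var_labels)) {
    stop("sample columns (", ncol(samples), ") do not match variable labels (",
         nrow(var_labels), ")")
  }
  if (any(samples < -1e-9) || any(samples > 1 + 1e-9)) {
    stop("stored activations must lie in [0, 1] (tolerance 1e-9)")
  }
  colnames(samples) <- var_labels$label
  structure(list(samples = samples, var_labels = var_labels,
                 provenance = provenance),
            class = "sample_store")
}

new_sample_store <- function(X, spec, config, method, chart_dim) {
  prov <- list(method = method,
               rng_seed = config$rng_seed,
               burn_in = config$burn_in,
               thin = config$thin,
               chart_dim = chart_dim,
               delta = spec$meta$delta,
               fingerprint = spec$meta$fingerprint,
               run_fingerprint = spec$meta$run_fingerprint,
               seed_activation = spec$meta$seed,
               clamp = spec$meta$clamp,
               schema = "actspace-samples-1")
  sample_store(X, spec$var_labels, prov)
}

#' @export
print.sample_store <- function(x, ...) {
  cat("Sample store: ", nrow(x$samples), " sample(s) x ", ncol(x$samples),
      " variable(s) [", x$provenance$method %||% "unknown", "]\n", sep = "")
  if (!is.null(x$provenance$delta)) {
    cat("  delta =", x$provenance$delta,
        " rng_seed =", x$provenance$rng_seed %||% NA, "\n")
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Audit sampled points against a polytope specification
#'
#' Checks every sample row for box-bound and inequality violations (tolerance
#' `tol_ineq`) and equality residuals (tolerance `tol_eq`); for trajectory
#' polytopes this covers the per-slice wrench reproduction
#' `max_t ||H a_t - w_t||_inf` and the activation-contraction (rate-limit)
#' rows.
#'
#' @param store a [sample_store].
#' @param spec the [polytope_spec] the samples are claimed to satisfy.
#' @param tol_eq equality residual tolerance (default 1e-6).
#' @param tol_ineq bound/inequality tolerance (default 1e-9).
#' @return A list: `pass` (logical), `max_eq_residual`, `max_bound_violation`,
#'   `max_ineq_violation`, `n_failed` and a one-line `summary`.
#' @export
audit_samples <- function(store, spec, tol_eq = 1e-6, tol_ineq = 1e-9) {
  X <- store$samples[, spec$var_labels$label, drop = FALSE]
  eq_res <- if (nrow(spec$eq_mat) > 0L) {
    max(abs(X %*% t(spec$eq_mat) - rep(spec$eq_rhs, each = nrow(X))))
  } else 0
  bound_viol <- max(c(spec$lower - t(X), t(X) - spec$upper, -Inf))
  ineq_viol <- if (nrow(spec$ineq_mat) > 0L) {
    max(X %*% t(spec$ineq_mat) - rep(spec$ineq_rhs, each = nrow(X)))
  } else -Inf
  row_eq <- if (nrow(spec$eq_mat) > 0L) {
    apply(abs(X %*% t(spec$eq_mat) - rep(spec$eq_rhs, each = nrow(X))), 1, max)
  } else rep(0, nrow(X))
  row_bad <- row_eq > tol_eq
  pass <- eq_res <= tol_eq && bound_viol <= tol_ineq && ineq_viol <= tol_ineq
  list(pass = pass,
       max_eq_residual = eq_res,
       max_bound_violation = max(bound_viol, 0),
       max_ineq_violation = max(ineq_viol, 0),
       n_failed = sum(row_bad) + as.integer(bound_viol > tol_ineq) +
         as.integer(ineq_viol > tol_ineq),
       summary = sprintf(
         "eq residual %.3g (tol %.1g), bound violation %.3g, ineq violation %.3g",
         eq_res, tol_eq, max(bound_viol, 0), max(ineq_viol, 0)))
}

STORE_SCHEMA <- "actspace-samples-1"

#' Save / load a sample store
#'
#' `save_samples` writes a store either as plain CSV with a single JSON
#' metadata header line (prefix `# `, lossless `%.17g` values) or, for large
#' runs, as an Arrow Feather file with the metadata embedded (requires the
#' `arrow` package).  `load_samples` reads either format back, restoring
#' values, labels and provenance exactly; files with an unknown schema
#' version are refused.
#'
#' @param store a [sample_store].
#' @param path output path; format is inferred from the extension
#'   (`.feather`/`.arrow` for Feather, anything else CSV) unless given.
#' @param format `"csv"` or `"feather"`.
#' @return `save_samples` returns `path` invisibly; `load_samples` a
#'   [sample_store].
#' @export
save_samples <- function(store, path,
                         format = c("auto", "csv", "feather")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(feather|arrow)$", path)) "feather" else "csv"
  }
  meta <- list(schema = STORE_SCHEMA,
               var_labels = store$var_labels,
               provenance = store$provenance)
  meta_json <- as.character(jsonlite::toJSON(meta, auto_unbox = TRUE,
                                             digits = NA, null = "null"))
  if (format == "csv") {
    header <- paste(colnames(store$samples), collapse = ",")
    body <- apply(store$samples, 1, function(r)
      paste(sprintf("%.17g", r), collapse = ","))
    writeLines(c(paste0("# ", meta_json), header, body), path)
  } else {
    if (!requireNamespace("arrow", quietly = TRUE)) {
      stop("the feather store format requires the 'arrow' package")
    }
    tb <- arrow::arrow_table(as.data.frame(store$samples, check.names = FALSE))
    tb <- tb$ReplaceSchemaMetadata(list(actspace = meta_json))
    arrow::write_feather(tb, path)
  }
  invisible(path)
}

#' @rdname save_samples
#' @export
load_samples <- function(path) {
  if (!file.exists(path)) stop("sample store not found: ", path)
  if (grepl("\\.(feather|arrow)$", path)) {
    if (!requireNamespace("arrow", quietly = TRUE)) {
      stop("reading a feather store requires the 'arrow' package")
    }
    tb <- arrow::read_feather(path, as_data_frame = FALSE)
    meta_json <- tb$metadata$actspace
    if (is.null(meta_json)) stop("not an activation sample store: ", path)
    meta <- jsonlite::fromJSON(meta_json)
    X <- as.matrix(as.data.frame(tb))
  } else {
    first <- readLines(path, n = 1L)
    if (!startsWith(first, "# ")) {
      stop("not an activation sample store (missing metadata header): ", path)
    }
    meta <- jsonlite::fromJSON(substring(first, 3L))
    df <- utils::read.csv(path, skip = 1L, check.names = FALSE)
    X <- as.matrix(df)
  }
  if (is.null(meta$schema) || !identical(meta$schema, STORE_SCHEMA)) {
    stop("unknown sample-store schema version: ",
         meta$schema %||% "<missing>", " (expected ", STORE_SCHEMA, ")")
  }
  vl <- as.data.frame(meta$var_labels)
  if (!identical(colnames(X), vl$label)) {
    stop("column labels in the file body do not match the stored metadata")
  }
  sample_store(X, vl, as.list(meta$provenance))
}
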