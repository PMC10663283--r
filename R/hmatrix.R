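#' Activation-to-wrench model
#'
#' An `h_matrix` holds the linear map from muscle activations to the isometric
#' endpoint wrench of a tendon-driven limb: `w = H a`, with activations
#' `a` normalized to `[0,1]` (1 = 100% of a muscle's maximal tension
#' contribution).  Rows are wrench components, columns are muscles.
#'
#' @param values numeric matrix, `n_wrench x n_muscles`; all entries finite.
#' @param muscle_names character vector of column labels.
#' @param wrench_names character vector of row labels; the standard fingertip
#'   convention is `c("fx","fy","fz","ty")`.
#' @return An object of class `h_matrix`.
#' @export
h_matrix <- function(values,
                     muscle_names = colnames(values),
                     wrench_names = rownames(values)) {
  values <- as.matrix(values)
  if (is.null(muscle_names)) muscle_names <- paste0("m", seq_len(ncol(values)))
  if (is.null(wrench_names)) wrench_names <- paste0("w", seq_len(nrow(values)))
  storage.mode(values) <- "double"
  if (nrow(values) < 1L || ncol(values) < 1L) {
    stop("h_matrix needs at least one wrench row and one muscle column")
  }
  if (!all(is.finite(values))) stop("h_matrix entries must all be finite")
  if (length(muscle_names) != ncol(values)) {
    stop("muscle_names length (", length(muscle_names),
         ") does not match number of columns (", ncol(values), ")")
  }
  if (length(wrench_names) != nrow(values)) {
    stop("wrench_names length (", length(wrench_names),
         ") does not match number of rows (", nrow(values), ")")
  }
  dimnames(values) <- list(wrench_names, muscle_names)
  structure(list(values = values,
                 muscle_names = as.character(muscle_names),
                 wrench_names = as.character(wrench_names)),
            class = "h_matrix")
}

#' @export
print.h_matrix <- function(x, ...) {
  cat("Activation-to-wrench model: ", nrow(x$values), " wrench component(s) x ",
      ncol(x$values), " muscle(s)\n", sep = "")
  print(round(x$values, 4))
  invisible(x)
}

n_muscles <- function(model) ncol(model$values)
n_wrench <- function(model) nrow(model$values)

#' Read an activation-to-wrench matrix from CSV
#'
#' The expected dialect is comma-separated with a header row of muscle names
#' and a first column of wrench component names (conventional order
#' `fx, fy, fz, ty`).  The numeric body must be complete and rectangular.
#'
#' @param path path to a CSV file.
#' @return An [h_matrix].
#' @export
read_h_matrix <- function(path) {
  if (!file.exists(path)) stop("H matrix file not found: ", path)
  nf <- utils::count.fields(path, sep = ",", quote = "\"")
  if (length(unique(nf)) != 1L) {
    bad <- which(nf != nf[1])[1]
    stop("ragged CSV: row ", bad, " has ", nf[bad],
         " fields where row 1 has ", nf[1])
  }
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("H matrix CSV needs a label column plus >= 1 muscle column")
  wrench_names <- as.character(df[[1]])
  body <- df[, -1, drop = FALSE]
  for (j in seq_along(body)) {
    col <- body[[j]]
    if (is.character(col)) {
      suppressWarnings(num <- as.numeric(col))
    } else {
      num <- as.numeric(col)
    }
    bad <- which(is.na(num))
    if (length(bad) > 0L) {
      stop("non-numeric or missing cell at row '", wrench_names[bad[1]],
           "', column '", colnames(body)[j], "'")
    }
    body[[j]] <- num
  }
  h_matrix(as.matrix(body), muscle_names = colnames(body),
           wrench_names = wrench_names)
}

#' Write an activation-to-wrench matrix to CSV
#'
#' Inverse of [read_h_matrix]; values are written with 17 significant digits
#' so the round trip is lossless.
#'
#' @param model an [h_matrix].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_h_matrix <- function(model, path) {
  header <- paste(c("wrench", model$muscle_names), collapse = ",")
  rows <- vapply(seq_len(nrow(model$values)), function(i) {
    paste(c(model$wrench_names[i],
            sprintf("%.17g", model$values[i, ])), collapse = ",")
  }, character(1))
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Generate a synthetic activation-to-wrench model
#'
#' Draws a random redundant (`n_muscles > n_wrench`) activation-to-wrench
#' matrix and rescales it so that every wrench of the task's sequence is
#' strictly producible with activations in `[0,1]`.  The construction is:
#' standard-normal entries, columns scaled to unit Euclidean norm, then a
#' single global scale `s = 2 * max(lambda)` where `lambda` are nonnegative
#' cone coefficients (`H0 lambda = w`, found by nonnegative least squares)
#' over all task wrenches, which places a known feasible activation in
#' `[0, 0.5]^n` for every slice.  A candidate is accepted only if every
#' single-moment polytope has an interior point with margin above
#' `min_margin` and the stacked trajectory polytope at the task's
#' activation-contraction limit `task$delta` is nonempty; otherwise it is
#' redrawn, up to `max_attempts` times.  Deterministic given `rng_seed`.
#'
#' @param n_muscles number of muscles (columns); must exceed `n_wrench` so a
#'   null space (muscle redundancy) exists.
#' @param n_wrench number of wrench components (rows).
#' @param rng_seed integer seed; the function is a pure function of its
#'   arguments including this seed.
#' @param task a [task_spec]; its wrench sequence defines the feasibility
#'   requirement and its `delta` the rate limit that must be bridgeable.
#' @param min_margin minimal interior margin (activation units) required of
#'   each single-moment polytope.
#' @param max_attempts redraw budget before failing.
#' @return An [h_matrix] with muscles named `m1..m<n>` and wrench rows named
#'   by the task convention.
#' @export
generate_synthetic_h <- function(n_muscles, n_wrench, rng_seed,
                                 task = task_spec(),
                                 min_margin = 0.01,
                                 max_attempts = 50L) {
  if (n_muscles <= n_wrench) {
    stop("need n_muscles > n_wrench for muscle redundancy (got ",
         n_muscles, " <= ", n_wrench, ")")
  }
  wrench_names <- if (n_wrench == 4L) c("fx", "fy", "fz", "ty")
                  else paste0("w", seq_len(n_wrench))
  muscle_names <- paste0("m", seq_len(n_muscles))
  with_local_seed(rng_seed, {
    for (attempt in seq_len(max_attempts)) {
      h0 <- matrix(stats::rnorm(n_wrench * n_muscles), n_wrench, n_muscles)
      h0 <- sweep(h0, 2, sqrt(colSums(h0^2)), "/")
      model0 <- h_matrix(h0, muscle_names, wrench_names)
      seq0 <- build_task_wrenches(task, model0)
      lam_max <- 0
      ok <- TRUE
      for (t in seq_len(nrow(seq0$wrenches))) {
        w <- seq0$wrenches[t, ]
        nn <- pracma::lsqnonneg(h0, w)
        if (sqrt(nn$resid.norm) > 1e-8 * max(1, sqrt(sum(w^2)))) {
          ok <- FALSE
          break
        }
        lam_max <- max(lam_max, nn$x)
      }
      if (!ok || lam_max <= 0) next
      model <- h_matrix(2 * lam_max * h0, muscle_names, wrench_names)
      seqs <- build_task_wrenches(task, model)
      margins <- rep(NA_real_, nrow(seqs$wrenches))
      for (t in seq_len(nrow(seqs$wrenches))) {
        p <- tryCatch(build_moment_polytope(model, seqs$wrenches[t, ]),
                      error = function(e) NULL)
        if (is.null(p)) { ok <- FALSE; break }
        ip <- tryCatch(find_interior_point(p), error = function(e) NULL)
        if (is.null(ip) || attr(ip, "margin") < min_margin) { ok <- FALSE; break }
      }
      if (!ok) next
      traj <- tryCatch(build_trajectory_polytope(model, seqs, task$delta),
                       error = function(e) NULL)
      if (is.null(traj)) next
      return(model)
    }
    stop("could not generate a feasible synthetic model in ", max_attempts,
         " attempts; relax the task or the margin requirement")
  })
}

#' Analytic planar toy model
#'
#' Returns the two-muscle, one-wrench model `H = [1, 1]` together with a
#' constant-wrench task `w = 1` over 7 slices of 50 ms.  The single-moment
#' feasible set is the line segment `a1 + a2 = 1` inside the unit square,
#' whose geometry is known in closed form (a uniform point on it has each
#' coordinate uniform on `[0,1]`), which makes it the reference fixture for
#' sampler validation.
#'
#' @param n_steps number of time slices for the toy task.
#' @param delta activation-contraction limit carried by the toy task.
#' @return A list with elements `model` ([h_matrix]) and `task` ([task_spec]).
#' @export
make_planar_toy <- function(n_steps = 7L, delta = 1) {
  model <- h_matrix(matrix(c(1, 1), 1, 2),
                    muscle_names = c("m1", "m2"),
                    wrench_names = "fx")
  task <- task_spec(magnitude = 1, arc_degrees = 0, n_steps = n_steps,
                    step_ms = 50, delta = delta)
  list(model = model, task = task)
}
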