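#' Convex polytope specification over labeled activation variables
#'
#' A `polytope_spec` stores a convex polytope in halfspace form over labeled
#' `(muscle, time-index)` variables: equality rows `A_eq x = b_eq`,
#' inequality rows `A_ub x <= b_ub`, and box bounds `lower <= x <= upper`
#' (activations, so `lower >= 0` and `upper <= 1`).  Row origins are recorded
#' for diagnostics (`wrench[t]`, `lipschitz[muscle,t]`, `seed`, `clamp`).
#'
#' @param eq_mat,eq_rhs equality rows and right-hand side.
#' @param ineq_mat,ineq_rhs inequality rows and right-hand side (may be empty).
#' @param lower,upper elementwise box bounds.
#' @param var_labels data.frame with columns `muscle`, `time`, `label`,
#'   one row per variable, in column order of the matrices.
#' @param row_origin_eq,row_origin_ineq character tags, one per row.
#' @param meta free-form provenance list (delta, task hash, ...).
#' @return An object of class `polytope_spec`.
#' @export
polytope_spec <- function(eq_mat, eq_rhs,
                          ineq_mat = NULL, ineq_rhs = NULL,
                          lower, upper, var_labels,
                          row_origin_eq = NULL, row_origin_ineq = NULL,
                          meta = list()) {
  eq_mat <- as.matrix(eq_mat)
  n <- ncol(eq_mat)
  if (is.null(ineq_mat)) {
    ineq_mat <- matrix(0, 0L, n)
    ineq_rhs <- numeric(0)
  }
  ineq_mat <- as.matrix(ineq_mat)
  stopifnot(is.data.frame(var_labels),
            all(c("muscle", "time", "label") %in% names(var_labels)))
  if (nrow(var_labels) != n || ncol(ineq_mat) != n) {
    stop("column counts of eq_mat/ineq_mat must equal the number of variable labels")
  }
  if (length(eq_rhs) != nrow(eq_mat) || length(ineq_rhs) != nrow(ineq_mat)) {
    stop("right-hand-side lengths do not match their matrices")
  }
  if (length(lower) != n || length(upper) != n) stop("bounds length mismatch")
  if (any(lower > upper)) stop("lower bound exceeds upper bound")
  if (any(lower < 0) || any(upper > 1)) {
    stop("activation bounds must stay within [0, 1]")
  }
  if (is.null(row_origin_eq)) row_origin_eq <- rep("eq", nrow(eq_mat))
  if (is.null(row_origin_ineq)) row_origin_ineq <- rep("ineq", nrow(ineq_mat))
  structure(list(eq_mat = eq_mat, eq_rhs = as.numeric(eq_rhs),
                 ineq_mat = ineq_mat, ineq_rhs = as.numeric(ineq_rhs),
                 lower = as.numeric(lower), upper = as.numeric(upper),
                 var_labels = var_labels,
                 row_origin_eq = as.character(row_origin_eq),
                 row_origin_ineq = as.character(row_origin_ineq),
                 meta = meta),
            class = "polytope_spec")
}

#' @export
print.polytope_spec <- function(x, ...) {
  cat("Polytope over ", ncol(x$eq_mat), " variable(s): ",
      nrow(x$eq_mat), " equality row(s), ", nrow(x$ineq_mat),
      " inequality row(s), box bounds [",
      min(x$lower), ", ", max(x$upper), "]\n", sep = "")
  if (!is.null(x$meta$delta)) {
    cat("  activation-contraction limit delta =", x$meta$delta, "\n")
  }
  invisible(x)
}

n_vars <- function(spec) ncol(spec$eq_mat)

make_var_labels <- function(muscle_names, times) {
  grid <- expand.grid(muscle = muscle_names, time = times,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid <- grid[order(grid$time), , drop = FALSE]  # time-major, muscle-minor
  grid$label <- paste0(grid$muscle, "@t", grid$time)
  rownames(grid) <- NULL
  grid
}

#' Feasible activation space of a single wrench
#'
#' Builds the single-moment polytope `{a : H a = w, a in [0,1]^n}` — the
#' feasible activation space of one endpoint wrench — and verifies that it is
#' nonempty by an interior-point solve.
#'
#' @param model an [h_matrix].
#' @param w numeric wrench vector matching the model's wrench convention.
#' @param time time index recorded in the variable labels.
#' @return A [polytope_spec] with one variable per muscle.
#' @export
build_moment_polytope <- function(model, w, time = 0L) {
  w <- as.numeric(w)
  if (length(w) != n_wrench(model)) {
    stop("wrench length ", length(w), " does not match model (",
         n_wrench(model), " components)")
  }
  if (!all(is.finite(w))) stop("wrench components must be finite")
  m <- n_muscles(model)
  spec <- polytope_spec(
    eq_mat = model$values, eq_rhs = w,
    lower = rep(0, m), upper = rep(1, m),
    var_labels = make_var_labels(model$muscle_names, time),
    row_origin_eq = paste0("wrench[t", time, ",", model$wrench_names, "]"),
    meta = list(kind = "moment", time = time))
  ip <- tryCatch(find_interior_point(spec), error = function(e) e)
  if (inherits(ip, "error")) {
    stop("infeasible wrench: the moment polytope is empty (",
         conditionMessage(ip), ")", call. = FALSE)
  }
  spec
}

#' Stacked spatiotemporal trajectory polytope
#'
#' Builds the polytope of all activation trajectories that reproduce a
#' prescribed wrench sequence under the activation-contraction constraint:
#' variables are all `(muscle, slice)` activations in time-major order;
#' equality rows apply the model blockwise per slice (`H a_t = w_t`);
#' inequality rows encode the Lipschitz rate limit
#' `|a_{t+1,i} - a_{t,i}| <= delta` as two rows per muscle and consecutive
#' slice pair; bounds are `[0,1]` throughout.  For the reference 7-muscle,
#' 4-wrench model over 7 slices this is the 49-variable system with 28
#' equality and 84 rate rows.
#'
#' With `delta = 0` the rate rows collapse to equalities (all slices
#' identical), keeping the polytope's relative interior well defined.
#'
#' Infeasibility is diagnosed by solving growing prefixes of the stacked
#' system and reporting the first prefix length that fails.
#'
#' @param model an [h_matrix].
#' @param seq a [wrench_sequence].
#' @param delta activation-contraction limit in `[0,1]`; defaults to the
#'   task's value.
#' @return A [polytope_spec] over `n_muscles * n_steps` variables.
#' @export
build_trajectory_polytope <- function(model, seq, delta = seq$task$delta) {
  if (delta < 0 || delta > 1) stop("delta must lie in [0, 1]")
  W <- seq$wrenches
  T <- nrow(W)
  m <- n_muscles(model)
  nw <- n_wrench(model)
  nv <- m * T
  times <- seq_len(T) - 1L

  eq_mat <- kronecker(diag(T), model$values)
  eq_rhs <- as.numeric(t(W))
  row_origin_eq <- as.vector(t(outer(times, model$wrench_names,
                                     function(t, w) paste0("wrench[t", t, ",", w, "]"))))

  # Lipschitz rows: +/- (x_{t+1,i} - x_{t,i}) <= delta
  n_pair <- m * (T - 1L)
  D <- matrix(0, n_pair, nv)
  org <- character(n_pair)
  k <- 0L
  for (t in seq_len(T - 1L)) {
    for (i in seq_len(m)) {
      k <- k + 1L
      D[k, (t - 1L) * m + i] <- -1
      D[k, t * m + i] <- 1
      org[k] <- paste0("lipschitz[", model$muscle_names[i], ",t", t - 1L,
                       "->t", t, "]")
    }
  }

  if (delta == 0) {
    eq_mat <- rbind(eq_mat, D)
    eq_rhs <- c(eq_rhs, rep(0, n_pair))
    row_origin_eq <- c(row_origin_eq, sub("^lipschitz", "constant", org))
    ineq_mat <- NULL
    ineq_rhs <- NULL
    row_origin_ineq <- NULL
  } else {
    ineq_mat <- rbind(D, -D)
    ineq_rhs <- rep(delta, 2L * n_pair)
    row_origin_ineq <- c(paste0("+", org), paste0("-", org))
  }

  spec <- polytope_spec(
    eq_mat = eq_mat, eq_rhs = eq_rhs,
    ineq_mat = ineq_mat, ineq_rhs = ineq_rhs,
    lower = rep(0, nv), upper = rep(1, nv),
    var_labels = make_var_labels(model$muscle_names, times),
    row_origin_eq = row_origin_eq, row_origin_ineq = row_origin_ineq,
    meta = list(kind = "trajectory", delta = delta, n_steps = T,
                n_muscles = m, n_wrench = nw,
                fingerprint = config_fingerprint(model, seq$task, delta),
                run_fingerprint = config_fingerprint(model, seq$task)))

  ip <- tryCatch(find_interior_point(spec), error = function(e) e)
  if (inherits(ip, "error")) {
    # diagnose with growing prefixes
    first_bad <- NA_integer_
    for (k in 2:T) {
      sub <- trajectory_prefix(model, W, delta, k)
      ok <- tryCatch({ find_interior_point(sub); TRUE },
                     error = function(e) FALSE)
      if (!ok) { first_bad <- k; break }
    }
    stop("infeasible trajectory polytope at delta = ", delta,
         if (!is.na(first_bad)) paste0(": first infeasible prefix has ",
                                       first_bad, " slices")
         else ": slices feasible individually but stacked system degenerate",
         " (", conditionMessage(ip), ")", call. = FALSE)
  }
  spec
}

# Stacked system restricted to the first k slices (diagnostic helper).
trajectory_prefix <- function(model, W, delta, k) {
  m <- n_muscles(model)
  nv <- m * k
  eq_mat <- kronecker(diag(k), model$values)
  eq_rhs <- as.numeric(t(W[seq_len(k), , drop = FALSE]))
  n_pair <- m * (k - 1L)
  D <- matrix(0, n_pair, nv)
  idx <- 0L
  for (t in seq_len(k - 1L)) for (i in seq_len(m)) {
    idx <- idx + 1L
    D[idx, (t - 1L) * m + i] <- -1
    D[idx, t * m + i] <- 1
  }
  if (delta == 0) {
    polytope_spec(eq_mat = rbind(eq_mat, D), eq_rhs = c(eq_rhs, rep(0, n_pair)),
                  lower = rep(0, nv), upper = rep(1, nv),
                  var_labels = make_var_labels(model$muscle_names, seq_len(k) - 1L))
  } else {
    polytope_spec(eq_mat = eq_mat, eq_rhs = eq_rhs,
                  ineq_mat = rbind(D, -D), ineq_rhs = rep(delta, 2L * n_pair),
                  lower = rep(0, nv), upper = rep(1, nv),
                  var_labels = make_var_labels(model$muscle_names, seq_len(k) - 1L))
  }
}

#' Seed (initial-activation) point
#'
#' A seed pins the first slice of a trajectory polytope to a fixed feasible
#' activation pattern; a clamped seed pins the final slice to the same values
#' as well.
#'
#' @param activation numeric vector in `[0,1]`, one value per muscle.
#' @param clamp logical; also pin the final slice.
#' @param muscles optional muscle names; when present, [add_seed_constraint]
#'   aligns the seed to the polytope's muscle order by name.
#' @return An object of class `seed_point`.
#' @export
seed_point <- function(activation, clamp = FALSE, muscles = names(activation)) {
  activation <- as.numeric(activation)
  if (any(!is.finite(activation))) stop("seed activations must be finite")
  if (any(activation < 0) || any(activation > 1)) {
    stop("seed activations must lie in [0, 1]")
  }
  if (!is.null(muscles) && length(muscles) != length(activation)) {
    stop("muscle names do not match the activation length")
  }
  structure(list(activation = activation, clamp = isTRUE(clamp),
                 muscles = muscles),
            class = "seed_point")
}

#' Pin a trajectory polytope to a seed
#'
#' Appends equality rows forcing the `t = 0` slice of a trajectory polytope
#' to equal the seed's activation pattern (and, for a clamped seed, the final
#' slice too).  The seed must lie in `[0,1]` and be feasible for the first
#' moment polytope, i.e. reproduce the first wrench; the two failure modes
#' raise distinct errors.
#'
#' @param spec a trajectory [polytope_spec].
#' @param seed a [seed_point] (or bare numeric vector, taken as unclamped).
#' @param tol tolerance on the first-slice wrench residual.
#' @return A new [polytope_spec] with the seed (and clamp) rows appended.
#' @export
add_seed_constraint <- function(spec, seed, tol = 1e-8) {
  if (!inherits(seed, "seed_point")) seed <- seed_point(seed)
  vl <- spec$var_labels
  times <- sort(unique(vl$time))
  t0 <- times[1]
  tN <- times[length(times)]
  i0 <- which(vl$time == t0)
  m <- length(i0)
  if (length(seed$activation) != m) {
    stop("seed length ", length(seed$activation),
         " does not match the number of muscles (", m, ")")
  }
  if (!is.null(seed$muscles)) {
    pos <- match(vl$muscle[i0], seed$muscles)
    if (anyNA(pos)) {
      stop("seed muscle names do not cover the polytope's muscles: missing ",
           paste(setdiff(vl$muscle[i0], seed$muscles), collapse = ", "))
    }
    seed$activation <- seed$activation[pos]
  }
  # first-moment feasibility: the seed must reproduce the first wrench
  eq0 <- grepl(paste0("^wrench\\[t", t0, ","), spec$row_origin_eq)
  if (any(eq0)) {
    A0 <- spec$eq_mat[eq0, i0, drop = FALSE]
    resid <- max(abs(A0 %*% seed$activation - spec$eq_rhs[eq0]))
    if (resid > tol * max(1, max(abs(spec$eq_rhs[eq0])))) {
      stop("seed is not feasible for the first moment polytope: wrench ",
           "residual ", format(resid), call. = FALSE)
    }
  }
  pin <- function(idx, tag) {
    rows <- matrix(0, length(idx), n_vars(spec))
    rows[cbind(seq_along(idx), idx)] <- 1
    list(rows = rows, origin = paste0(tag, "[", vl$label[idx], "]"))
  }
  p0 <- pin(i0, "seed")
  eq_mat <- rbind(spec$eq_mat, p0$rows)
  eq_rhs <- c(spec$eq_rhs, seed$activation)
  origin <- c(spec$row_origin_eq, p0$origin)
  if (seed$clamp && tN != t0) {
    iN <- which(vl$time == tN)
    pN <- pin(iN, "clamp")
    eq_mat <- rbind(eq_mat, pN$rows)
    eq_rhs <- c(eq_rhs, seed$activation)
    origin <- c(origin, pN$origin)
  }
  meta <- spec$meta
  meta$seed <- seed$activation
  meta$clamp <- seed$clamp
  polytope_spec(eq_mat = eq_mat, eq_rhs = eq_rhs,
                ineq_mat = spec$ineq_mat, ineq_rhs = spec$ineq_rhs,
                lower = spec$lower, upper = spec$upper,
                var_labels = vl,
                row_origin_eq = origin, row_origin_ineq = spec$row_origin_ineq,
                meta = meta)
}

#' Dump a polytope as labeled plain text
#'
#' Writes an LP-style listing of all rows (tagged with their origin) for
#' inspection and debugging.
#'
#' @param spec a [polytope_spec].
#' @param path output path; defaults to printing to the console.
#' @return `path` (or the lines, invisibly, when printing).
#' @export
export_polytope_text <- function(spec, path = NULL) {
  fmt_row <- function(coef, rel, rhs, tag) {
    nz <- which(abs(coef) > 1e-12)
    terms <- paste0(sprintf("%+.6g", coef[nz]), "*", spec$var_labels$label[nz])
    paste0(tag, ": ", paste(terms, collapse = " "), " ", rel, " ",
           sprintf("%.6g", rhs))
  }
  lines <- c(
    sprintf("polytope: %d variables", n_vars(spec)),
    vapply(seq_len(nrow(spec$eq_mat)), function(i)
      fmt_row(spec$eq_mat[i, ], "=", spec$eq_rhs[i], spec$row_origin_eq[i]),
      character(1)),
    vapply(seq_len(nrow(spec$ineq_mat)), function(i)
      fmt_row(spec$ineq_mat[i, ], "<=", spec$ineq_rhs[i], spec$row_origin_ineq[i]),
      character(1)),
    sprintf("bounds: 0 <= %s <= 1", spec$var_labels$label))
  if (is.null(path)) {
    invisible(lines)
  } else {
    writeLines(lines, path)
    invisible(path)
  }
}
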