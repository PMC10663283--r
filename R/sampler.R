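#' Markov-chain configuration for polytope sampling
#'
#' @param n_samples number of retained samples (>= 1).
#' @param burn_in discarded initial steps (>= 0).
#' @param thin keep every `thin`-th state after burn-in (>= 1).
#' @param rng_seed integer seed; sampling is deterministic given the seed.
#' @return An object of class `chain_config`.
#' @export
chain_config <- function(n_samples, burn_in = 1000L, thin = 10L, rng_seed = 1L) {
  if (n_samples < 1L) stop("n_samples must be >= 1")
  if (burn_in < 0L) stop("burn_in must be >= 0")
  if (thin < 1L) stop("thin must be >= 1")
  structure(list(n_samples = as.integer(n_samples),
                 burn_in = as.integer(burn_in),
                 thin = as.integer(thin),
                 rng_seed = as.integer(rng_seed)),
            class = "chain_config")
}

stop_infeasible <- function(msg, point = NULL) {
  stop(errorCondition(msg, point = point,
                      class = c("actspace_infeasible", "actspace_error")))
}

stop_degenerate <- function(msg, point = NULL) {
  stop(errorCondition(msg, point = point,
                      class = c("actspace_degenerate", "actspace_error")))
}

#' Interior point of a polytope
#'
#' Finds a Chebyshev-center-style point: restricted to the equality manifold,
#' it maximizes the minimal slack over all inequality and bound rows (with a
#' tiny quadratic regularization for uniqueness).  Raises a classed error
#' when the polytope is empty (`actspace_infeasible`) or when its relative
#' interior has zero volume (`actspace_degenerate`; the offending point — for
#' a zero-dimensional chart, the unique feasible point — travels with the
#' condition object).
#'
#' @param spec a [polytope_spec].
#' @param margin_tol slack below which the interior is declared degenerate.
#' @return A feasible point (numeric vector) with attributes `margin` and
#'   `chart_dim`.
#' @export
find_interior_point <- function(spec, margin_tol = 1e-9) {
  x0 <- tryCatch(eq_particular_solution(spec$eq_mat, spec$eq_rhs),
                 error = function(e) stop_infeasible(conditionMessage(e)))
  nb <- eq_null_basis(spec$eq_mat)
  d <- ncol(nb$basis)
  if (d == 0L) {
    viol <- max(c(spec$lower - x0, x0 - spec$upper,
                  if (nrow(spec$ineq_mat) > 0L)
                    spec$ineq_mat %*% x0 - spec$ineq_rhs else -Inf))
    if (viol > margin_tol) {
      stop_infeasible(paste0("equalities pin a unique point that violates ",
                             "the inequalities by ", format(viol)))
    }
    stop_degenerate("zero-dimensional chart: the polytope is a single point",
                    point = structure(drop(x0), margin = 0, chart_dim = 0L))
  }
  ci <- chart_inequalities(spec, x0, nb$basis)
  mm <- max_margin_point(ci$G, ci$h)
  x <- drop(x0 + nb$basis %*% mm$z)
  if (mm$margin < -margin_tol) {
    stop_infeasible(paste0("polytope is empty: best attainable margin ",
                           format(mm$margin)))
  }
  if (mm$margin <= margin_tol) {
    stop_degenerate(paste0("polytope has a zero-volume relative interior ",
                           "(margin ", format(mm$margin), ")"),
                    point = structure(x, margin = mm$margin, chart_dim = d))
  }
  structure(x, margin = mm$margin, chart_dim = d)
}

#' Null-space chart of a polytope
#'
#' Re-expresses a polytope in the orthonormal coordinates of the equality
#' null space around a feasible anchor: points are `x = anchor + basis %*% z`
#' (so equalities hold identically), and all inequality and bound rows become
#' unit-norm rows `G z <= h` in chart coordinates.
#'
#' @param spec a [polytope_spec].
#' @param anchor feasible point satisfying the equalities to `1e-8`;
#'   defaults to [find_interior_point].
#' @return An object of class `nullspace_chart` with fields `anchor`,
#'   `basis`, `G`, `h`, `origin`, `dim` and `tol_warning` (rank detection
#'   ambiguity flag, recorded in provenance).
#' @export
build_chart <- function(spec, anchor = find_interior_point(spec)) {
  if (nrow(spec$eq_mat) > 0L) {
    resid <- max(abs(spec$eq_mat %*% as.numeric(anchor) - spec$eq_rhs))
    if (resid > 1e-8) {
      stop("anchor violates the equality rows (residual ", format(resid), ")")
    }
  }
  nb <- eq_null_basis(spec$eq_mat)
  if (nb$tol_warning) {
    warning("singular values near the rank tolerance: chart dimension may be ",
            "ambiguous", call. = FALSE)
  }
  d <- ncol(nb$basis)
  if (d == 0L) {
    return(structure(list(anchor = as.numeric(anchor),
                          basis = nb$basis, G = matrix(0, 0L, 0L),
                          h = numeric(0), origin = character(0),
                          dim = 0L, tol_warning = nb$tol_warning),
                     class = "nullspace_chart"))
  }
  ci <- chart_inequalities(spec, as.numeric(anchor), nb$basis)
  structure(list(anchor = as.numeric(anchor), basis = nb$basis,
                 G = ci$G, h = ci$h, origin = ci$origin,
                 dim = d, tol_warning = nb$tol_warning),
            class = "nullspace_chart")
}

#' @export
print.nullspace_chart <- function(x, ...) {
  cat("Null-space chart: dimension ", x$dim, ", ", nrow(x$G),
      " inequality row(s)\n", sep = "")
  invisible(x)
}

#' Feasible chord along a direction
#'
#' From a strictly feasible chart point `z`, returns the interval
#' `(lo, hi)` with `lo < 0 < hi` such that `z + t*d` stays inside the
#' polytope exactly for `t` in `[lo, hi]`.  Rows nearly orthogonal to the
#' direction (directional component below `skip_tol`) do not bound the chord
#' and are skipped.
#'
#' @param z chart point (strictly feasible).
#' @param d unit direction in chart coordinates.
#' @param chart a [build_chart] result.
#' @param skip_tol threshold on the directional component.
#' @return Numeric `c(lo, hi)`.
#' @export
chord_extent <- function(z, d, chart, skip_tol = 1e-13) {
  slack <- chart$h - drop(chart$G %*% z)
  if (any(slack < -1e-9)) {
    stop("chord_extent needs a strictly feasible starting point (min slack ",
         format(min(slack)), ")")
  }
  Gd <- drop(chart$G %*% d)
  pos <- Gd > skip_tol
  neg <- Gd < -skip_tol
  if (!any(pos) || !any(neg)) {
    stop("unbounded chord: direction escapes all inequality rows ",
         "(should be impossible with box bounds)")
  }
  hi <- min(slack[pos] / Gd[pos])
  lo <- max(slack[neg] / Gd[neg])
  c(lo = min(lo, 0), hi = max(hi, 0))
}

#' Hit-and-Run uniform sampling of a polytope
#'
#' Runs the Hit-and-Run Markov chain on the null-space chart of the
#' polytope: from the current interior point, draw an isotropic random
#' direction, compute the feasible chord, and jump to a uniform point on it.
#' The chain's stationary distribution is uniform over the polytope.  Chains
#' are deterministic given `config$rng_seed`; retained states are mapped back
#' to ambient activation coordinates, and every retained sample is audited
#' against the bounds/inequalities (tolerance 1e-9) and equalities
#' (tolerance 1e-6) before the store is returned.
#'
#' For a degenerate polytope whose chart has dimension zero, the unique
#' feasible point is returned `n_samples` times with a warning.
#'
#' @param spec a [polytope_spec].
#' @param config a [chain_config].
#' @return A [sample_store].
#' @export
hit_and_run <- function(spec, config) {
  ip <- tryCatch(find_interior_point(spec), error = function(e) e)
  if (inherits(ip, "actspace_degenerate")) {
    pt <- ip$point
    if (is.null(pt)) stop(ip)
    warning("degenerate polytope: returning the unique feasible point ",
            config$n_samples, " times", call. = FALSE)
    X <- matrix(rep(as.numeric(pt), each = config$n_samples),
                config$n_samples, n_vars(spec))
    return(new_sample_store(X, spec, config, method = "hit_and_run",
                            chart_dim = attr(pt, "chart_dim")))
  }
  if (inherits(ip, "error")) stop(ip)
  chart <- build_chart(spec, ip)
  d <- chart$dim
  G <- chart$G
  h <- chart$h
  n <- config$n_samples
  Z <- matrix(NA_real_, n, d)
  with_local_seed(config$rng_seed, {
    z <- numeric(d)
    total <- config$burn_in + n * config$thin
    kept <- 0L
    for (step in seq_len(total)) {
      dir <- stats::rnorm(d)
      dir <- dir / sqrt(sum(dir^2))
      M <- G %*% cbind(z, dir)
      slack <- h - M[, 1L]
      Gd <- M[, 2L]
      pos <- Gd > 1e-13
      neg <- Gd < -1e-13
      hi <- if (any(pos)) min(slack[pos] / Gd[pos]) else
        stop("unbounded chord in Hit-and-Run step ", step)
      lo <- if (any(neg)) max(slack[neg] / Gd[neg]) else
        stop("unbounded chord in Hit-and-Run step ", step)
      hi <- max(hi, 0)
      lo <- min(lo, 0)
      z <- z + stats::runif(1, lo, hi) * dir
      if (step > config$burn_in && (step - config$burn_in) %% config$thin == 0L) {
        kept <- kept + 1L
        Z[kept, ] <- z
      }
    }
  })
  X <- Z %*% t(chart$basis)
  X <- sweep(X, 2L, chart$anchor, "+")
  store <- new_sample_store(X, spec, config, method = "hit_and_run",
                            chart_dim = d)
  audit <- audit_samples(store, spec)
  if (!audit$pass) {
    stop("internal error: retained samples failed the constraint audit (",
         audit$summary, ")")
  }
  store
}

#' Brute-force rejection sampling oracle
#'
#' Proposes uniform points in an axis-aligned outer box of the chart
#' (obtained by interval arithmetic from the ambient box bounds) and keeps
#' the feasible ones, which is exactly uniform by construction.  Intended as
#' an independent ground truth for validating [hit_and_run] on
#' low-dimensional fixtures; guarded to chart dimension <= 4.
#'
#' @param spec a [polytope_spec].
#' @param n number of samples.
#' @param rng_seed integer seed.
#' @param min_acceptance abort threshold on the observed acceptance rate.
#' @return A [sample_store].
#' @export
rejection_oracle <- function(spec, n, rng_seed, min_acceptance = 1e-4) {
  ip <- tryCatch(find_interior_point(spec), error = function(e) e)
  if (inherits(ip, "actspace_degenerate")) {
    pt <- ip$point
    if (is.null(pt)) stop(ip)
    X <- matrix(rep(as.numeric(pt), each = n), n, n_vars(spec))
    return(new_sample_store(X, spec, chain_config(n, 0L, 1L, rng_seed),
                            method = "rejection",
                            chart_dim = attr(pt, "chart_dim")))
  }
  if (inherits(ip, "error")) stop(ip)
  chart <- build_chart(spec, ip)
  d <- chart$dim
  if (d > 4L) {
    stop("rejection_oracle is guarded to chart dimension <= 4 (got ", d,
         "): the acceptance rate would be impractical")
  }
  # outer box of the chart by interval arithmetic on z = t(basis) %*% (x - anchor)
  lo_amb <- spec$lower - chart$anchor
  hi_amb <- spec$upper - chart$anchor
  B <- chart$basis  # n_vars x d
  box_lo <- colSums(pmin(B * lo_amb, B * hi_amb))
  box_hi <- colSums(pmax(B * lo_amb, B * hi_amb))
  Z <- matrix(NA_real_, n, d)
  with_local_seed(rng_seed, {
    kept <- 0L
    proposed <- 0
    chunk <- max(2048L, 4L * n)
    repeat {
      P <- matrix(stats::runif(chunk * d, rep(box_lo, each = chunk),
                               rep(box_hi, each = chunk)), chunk, d)
      S <- P %*% t(chart$G)
      ok <- rowSums(S > rep(chart$h, each = chunk)) == 0L
      idx <- which(ok)
      proposed <- proposed + chunk
      if (length(idx) > 0L) {
        take <- idx[seq_len(min(length(idx), n - kept))]
        Z[kept + seq_along(take), ] <- P[take, , drop = FALSE]
        kept <- kept + length(take)
      }
      if (kept >= n) break
      if (proposed >= 1e5 && (kept / proposed) < min_acceptance) {
        stop("rejection_oracle acceptance rate ", format(kept / proposed),
             " below ", min_acceptance, " after ", proposed, " proposals; ",
             "use hit_and_run for this geometry")
      }
    }
  })
  X <- Z %*% t(chart$basis)
  X <- sweep(X, 2L, chart$anchor, "+")
  new_sample_store(X, spec, chain_config(n, 0L, 1L, rng_seed),
                   method = "rejection", chart_dim = d)
}
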