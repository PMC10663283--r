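# Internal linear-algebra machinery: equality-manifold charts and
# max-margin interior points.

# Rank tolerance for null-space extraction: max singular value x 1e-10.
RANK_TOL_FACTOR <- 1e-10

# Minimum-norm solution of A x = b with a consistency check; stops with an
# infeasibility error when the equality system is contradictory.
eq_particular_solution <- function(A, b, tol = 1e-8) {
  if (nrow(A) == 0L) return(numeric(ncol(A)))
  sv <- svd(A)
  keep <- sv$d > max(sv$d[1], .Machine$double.eps) * RANK_TOL_FACTOR
  x <- sv$v[, keep, drop = FALSE] %*%
    ((crossprod(sv$u[, keep, drop = FALSE], b)) / sv$d[keep])
  resid <- max(abs(A %*% x - b))
  if (resid > tol * max(1, max(abs(b)))) {
    stop("infeasible equality system: residual ", format(resid),
         " exceeds tolerance (contradictory constraints)",
         call. = FALSE)
  }
  drop(x)
}

# Orthonormal basis of the null space of A (columns), by SVD.
# Returns list(basis, rank, tol_warning): tol_warning flags singular values
# within a factor 100 of the rank threshold (ambiguous rank detection).
eq_null_basis <- function(A) {
  n <- ncol(A)
  if (nrow(A) == 0L) {
    return(list(basis = diag(n), rank = 0L, tol_warning = FALSE))
  }
  sv <- svd(A, nu = 0, nv = n)
  d <- c(sv$d, rep(0, n - length(sv$d)))
  thr <- max(d[1], .Machine$double.eps) * RANK_TOL_FACTOR
  rank <- sum(d > thr)
  ambiguous <- any(d > thr / 100 & d < thr * 100)
  basis <- sv$v[, seq_len(n) > rank, drop = FALSE]
  list(basis = basis, rank = rank, tol_warning = ambiguous)
}

# All inequality information of a polytope expressed in chart coordinates
# z around a point x0 on the equality manifold: G z <= h, rows normalized to
# unit norm.  Near-zero rows (directions killed by the chart) are dropped if
# satisfied, and raise an infeasibility error otherwise.
chart_inequalities <- function(spec, x0, basis) {
  G <- rbind(if (nrow(spec$ineq_mat) > 0L) spec$ineq_mat %*% basis,
             basis, -basis)
  h <- c(if (nrow(spec$ineq_mat) > 0L) spec$ineq_rhs - spec$ineq_mat %*% x0,
         spec$upper - x0, x0 - spec$lower)
  origin <- c(spec$row_origin_ineq,
              paste0("upper[", spec$var_labels$label, "]"),
              paste0("lower[", spec$var_labels$label, "]"))
  nrm <- sqrt(rowSums(G^2))
  degenerate <- nrm < 1e-12
  if (any(degenerate)) {
    viol <- degenerate & (h < -1e-9)
    if (any(viol)) {
      stop("infeasible: constraint(s) ", paste(origin[viol], collapse = ", "),
           " cannot be satisfied on the equality manifold", call. = FALSE)
    }
    G <- G[!degenerate, , drop = FALSE]
    h <- h[!degenerate]
    origin <- origin[!degenerate]
    nrm <- nrm[!degenerate]
  }
  list(G = G / nrm, h = as.numeric(h / nrm), origin = origin)
}

# Regularized max-margin (Chebyshev-style) point of {z : G z <= h} with
# unit-norm rows: maximize r s.t. G z + r <= h, via a quadratic program with
# a small ridge for strict convexity.  Returns list(z, margin).
max_margin_point <- function(G, h, ridge = 1e-7) {
  d <- ncol(G)
  m <- nrow(G)
  if (m == 0L) return(list(z = numeric(d), margin = Inf))
  Dmat <- diag(2 * ridge, d + 1L)
  dvec <- c(rep(0, d), 1)
  Amat <- t(cbind(-G, -1))
  sol <- tryCatch(
    quadprog::solve.QP(Dmat, dvec, Amat, bvec = -h, meq = 0L),
    error = function(e) {
      stop("interior-point solve failed: ", conditionMessage(e), call. = FALSE)
    })
  list(z = sol$solution[seq_len(d)], margin = sol$solution[d + 1L])
}
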