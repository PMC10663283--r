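#' Trajectory set
#'
#' Activation trajectories as an `n_traj x T x n_muscles` tensor, with time
#' and muscle labels and the provenance of the store they came from.
#'
#' @param tensor 3-D numeric array (trajectory, time, muscle), values in
#'   `[0,1]`.
#' @param muscles,times dimension labels.
#' @param provenance named metadata list.
#' @return An object of class `trajectory_set`.
#' @export
trajectory_set <- function(tensor, muscles, times, provenance = list()) {
  stopifnot(length(dim(tensor)) == 3L)
  if (dim(tensor)[2] != length(times) || dim(tensor)[3] != length(muscles)) {
    stop("tensor shape inconsistent with time/muscle labels")
  }
  if (any(tensor < -1e-9) || any(tensor > 1 + 1e-9)) {
    stop("activations must lie in [0, 1]")
  }
  dimnames(tensor) <- list(NULL, paste0("t", times), muscles)
  structure(list(tensor = tensor, muscles = muscles, times = times,
                 provenance = provenance),
            class = "trajectory_set")
}

#' @export
print.trajectory_set <- function(x, ...) {
  cat("Trajectory set: ", dim(x$tensor)[1], " trajectories x ",
      dim(x$tensor)[2], " slices x ", dim(x$tensor)[3], " muscles\n", sep = "")
  invisible(x)
}

n_trajectories <- function(ts) dim(ts$tensor)[1]

#' Reshape a sample store into trajectories
#'
#' Rearranges a store over `(muscle, time)` variables into the
#' `n_traj x T x n_muscles` tensor, driven entirely by the variable labels
#' (never by column position), so permuted stores reshape identically.  The
#' labels must form a complete muscle-by-time grid.
#'
#' @param store a [sample_store].
#' @return A [trajectory_set].
#' @export
reshape_to_trajectories <- function(store) {
  vl <- store$var_labels
  muscles <- sort(unique(vl$muscle))   # canonical order: label-sorted
  times <- sort(unique(vl$time))
  want <- as.vector(outer(muscles, times, function(m, t) paste0(m, "@t", t)))
  missing <- setdiff(want, vl$label)
  if (length(missing) > 0L) {
    stop("variable labels do not form a complete (muscle x time) grid; ",
         "missing: ", paste(missing, collapse = ", "))
  }
  extra <- setdiff(vl$label, want)
  if (length(extra) > 0L) {
    stop("unexpected variable labels: ", paste(extra, collapse = ", "))
  }
  n <- nrow(store$samples)
  tensor <- array(NA_real_, c(n, length(times), length(muscles)))
  for (j in seq_along(muscles)) {
    for (k in seq_along(times)) {
      tensor[, k, j] <- store$samples[, paste0(muscles[j], "@t", times[k])]
    }
  }
  trajectory_set(tensor, muscles, times, store$provenance)
}

#' Activation-contraction speeds
#'
#' Differentiates trajectories by forward first difference along time:
#' `speed_{t,i} = a_{t+1,i} - a_{t,i}` (dimensionless activation change per
#' slice).  Under an activation-contraction limit delta, every speed lies in
#' `[-delta, delta]`.
#'
#' @param ts a [trajectory_set] with at least two slices.
#' @return An object of class `speed_set`: tensor `n_traj x (T-1) x n_muscles`.
#' @export
activation_speeds <- function(ts) {
  T <- dim(ts$tensor)[2]
  if (T < 2L) stop("need at least two time slices to differentiate")
  sp <- ts$tensor[, -1L, , drop = FALSE] - ts$tensor[, -T, , drop = FALSE]
  structure(list(tensor = sp, muscles = ts$muscles,
                 times = ts$times[-length(ts$times)],
                 provenance = ts$provenance),
            class = "speed_set")
}

#' @export
print.speed_set <- function(x, ...) {
  cat("Speed set: ", dim(x$tensor)[1], " trajectories x ", dim(x$tensor)[2],
      " steps x ", dim(x$tensor)[3], " muscles\n", sep = "")
  invisible(x)
}

#' Per-trajectory, per-muscle maximal absolute speed
#'
#' @param ss a [speed_set] (or [trajectory_set], differentiated first).
#' @return Numeric matrix `n_traj x n_muscles` of `max_t |speed|`.
#' @export
max_abs_speed <- function(ss) {
  if (inherits(ss, "trajectory_set")) ss <- activation_speeds(ss)
  out <- apply(abs(ss$tensor), c(1L, 3L), max)
  colnames(out) <- ss$muscles
  out
}

#' Filter trajectories by an activation-contraction limit
#'
#' Keeps trajectories whose maximal absolute speed over all muscles and
#' steps is at most `delta` — the selection used to pick viable seed
#' trajectories before seeded re-sampling.
#'
#' @param ts a [trajectory_set].
#' @param delta limit in `[0,1]`; the comparison is exact (`<= delta`).
#' @return A [trajectory_set] (possibly with zero trajectories).
#' @export
filter_by_delta <- function(ts, delta) {
  if (delta < 0 || delta > 1) stop("delta must lie in [0, 1]")
  mx <- apply(max_abs_speed(ts), 1L, max)
  keep <- mx <= delta
  trajectory_set(ts$tensor[keep, , , drop = FALSE], ts$muscles, ts$times,
                 c(ts$provenance, list(filter_delta = delta)))
}

#' Select seed points from a trajectory set
#'
#' Uniformly chooses `k` trajectories without replacement (deterministic
#' given `rng_seed`, returned in draw order) and keeps only their first
#' (`t = 0`) activation slices as seeds — the later slices are discarded.
#'
#' @param ts a nonempty [trajectory_set].
#' @param k number of seeds; at most the number of trajectories.
#' @param rng_seed integer seed.
#' @param clamp logical, passed through to each [seed_point].
#' @return A list of [seed_point]s.
#' @export
select_seeds <- function(ts, k, rng_seed, clamp = FALSE) {
  n <- n_trajectories(ts)
  if (n == 0L) stop("no trajectories to select seeds from")
  if (k > n) stop("requested ", k, " seeds from ", n, " trajectories")
  idx <- with_local_seed(rng_seed, sample.int(n, k))
  lapply(idx, function(i)
    seed_point(ts$tensor[i, 1L, ], clamp = clamp, muscles = ts$muscles))
}

#' Per-timestep principal components of the unseeded distribution
#'
#' Fits, for each time slice, a PCA on the unseeded slice-`t` activation
#' vectors (centered, unscaled) and keeps the first two loadings — the plane
#' used to visualize and measure how seeding shrinks the reachable space.
#' The loading sign convention is deterministic: the largest-magnitude
#' component of each loading is positive.
#'
#' @param unseeded a [trajectory_set] drawn from the unseeded polytope.
#' @param min_traj minimal trajectories required per slice
#'   (default `n_muscles + 1`).
#' @return A list of `pc_model` objects (one per slice), each with `center`,
#'   `loadings` (muscles x 2), `explained` (variance shares) and
#'   `n_informative` (components with nonzero variance).
#' @export
fit_pc_per_timestep <- function(unseeded,
                                min_traj = dim(unseeded$tensor)[3] + 1L) {
  n <- n_trajectories(unseeded)
  if (n < min_traj) {
    stop("need at least ", min_traj, " trajectories per slice to fit the ",
         "per-timestep PCA (got ", n, ")")
  }
  T <- dim(unseeded$tensor)[2]
  lapply(seq_len(T), function(t) {
    slice <- unseeded$tensor[, t, ]
    pc <- stats::prcomp(slice, center = TRUE, scale. = FALSE)
    var_tol <- max(pc$sdev[1], .Machine$double.eps) * 1e-8
    n_informative <- sum(pc$sdev > var_tol)
    L <- pc$rotation[, 1:2, drop = FALSE]
    for (j in 1:2) {
      piv <- which.max(abs(L[, j]))
      if (L[piv, j] < 0) L[, j] <- -L[, j]
    }
    total <- sum(pc$sdev^2)
    structure(list(time = unseeded$times[t],
                   center = pc$center,
                   loadings = L,
                   explained = if (total > 0) pc$sdev[1:2]^2 / total else c(NA, NA),
                   n_informative = n_informative,
                   rank_deficient = n_informative < 2L),
              class = "pc_model")
  })
}

#' Project a slice of trajectories into a fitted PC plane
#'
#' Projects the slice-`t` activations of any trajectory set (seeded or
#' unseeded) through the unseeded PC model for that slice: centered
#' dot-products with the PC1/PC2 loadings, so seeded and unseeded data share
#' one chart.
#'
#' @param ts a [trajectory_set].
#' @param models list of `pc_model`s from [fit_pc_per_timestep].
#' @param t time index (1-based position among the fitted slices).
#' @return Numeric matrix `n_traj x 2` with columns `PC1`, `PC2`.
#' @export
project_timestep <- function(ts, models, t) {
  if (t < 1L || t > length(models)) {
    stop("time index ", t, " outside the fitted slices (1..", length(models), ")")
  }
  mod <- models[[t]]
  slice <- ts$tensor[, t, ]
  if (is.null(dim(slice))) slice <- matrix(slice, nrow = 1L)
  out <- sweep(slice, 2L, mod$center) %*% mod$loadings
  colnames(out) <- c("PC1", "PC2")
  out
}

#' Area of a planar convex hull
#'
#' Exact (shoelace) area of the 2-D convex hull of a point set.  Fewer than
#' three points, or a collinear set, yields area 0 with attribute
#' `degenerate = TRUE`.
#'
#' @param points numeric matrix with two columns.
#' @return The hull area (with a `degenerate` attribute).
#' @export
hull_area <- function(points) {
  points <- as.matrix(points)
  if (ncol(points) != 2L) stop("hull_area expects a 2-column point set")
  if (nrow(points) < 3L) return(structure(0, degenerate = TRUE))
  idx <- grDevices::chull(points[, 1L], points[, 2L])
  if (length(idx) < 3L) return(structure(0, degenerate = TRUE))
  v <- points[idx, , drop = FALSE]
  x <- v[, 1L]; y <- v[, 2L]
  area <- abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
  if (area <= .Machine$double.eps * max(1, max(abs(v))^2)) {
    return(structure(0, degenerate = TRUE))
  }
  structure(area, degenerate = FALSE)
}

#' Seeded-to-unseeded hull-area reduction ratio
#'
#' The fraction of the unseeded reachable space (in the PC plane) still
#' reachable under seeding: `hull_area(seeded) / hull_area(unseeded)`.
#' Arguments may be 2-D point sets or precomputed scalar areas (e.g. printed
#' pixel areas from a traced figure).
#'
#' @param seeded,unseeded 2-column point matrices, or single nonnegative
#'   numbers taken as areas.
#' @return The ratio (a fraction; multiply by 100 for percent).
#' @export
seeded_reduction_ratio <- function(seeded, unseeded) {
  as_area <- function(x, who) {
    if (is.numeric(x) && length(x) == 1L) {
      if (x < 0) stop(who, " area must be nonnegative")
      return(as.numeric(x))
    }
    as.numeric(hull_area(x))
  }
  a_seed <- as_area(seeded, "seeded")
  a_un <- as_area(unseeded, "unseeded")
  if (a_un <= 0) stop("degenerate unseeded hull: ratio undefined")
  a_seed / a_un
}

#' Per-muscle occupancy and speed summary
#'
#' Summarizes, per muscle, the visited activation levels and the
#' activation-contraction speeds: min, quartiles (linear interpolation,
#' `type = 7`), and max.  Used to compare how tightening the
#' activation-contraction limit shrinks each muscle's explored subspace.
#'
#' @param ts a [trajectory_set].
#' @return A data.frame with one row per (muscle, quantity) pair.
#' @export
occupancy_summary <- function(ts) {
  ss <- activation_speeds(ts)
  qs <- function(v) stats::quantile(v, c(0, 0.25, 0.5, 0.75, 1), type = 7,
                                    names = FALSE)
  rows <- lapply(seq_along(ts$muscles), function(j) {
    a <- qs(as.vector(ts$tensor[, , j]))
    s <- qs(as.vector(ss$tensor[, , j]))
    data.frame(muscle = rep(ts$muscles[j], 2L),
               quantity = c("activation", "speed"),
               min = c(a[1], s[1]), q25 = c(a[2], s[2]),
               median = c(a[3], s[3]), q75 = c(a[4], s[4]),
               max = c(a[5], s[5]))
  })
  out <- do.call(rbind, rows)
  if (!is.null(ts$provenance$delta)) out$delta <- ts$provenance$delta
  rownames(out) <- NULL
  out
}
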