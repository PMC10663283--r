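#' Isometric force-redirection task specification
#'
#' Describes the endpoint task: a force of fixed magnitude whose direction
#' rotates through `arc_degrees` and symmetrically back over `n_steps` time
#' slices of `step_ms` each, under an activation-contraction limit `delta`
#' (the maximal change, as a fraction of maximal activation, any muscle may
#' undergo between consecutive slices).
#'
#' The defaults are the reference finger task: a 10 N force starting pure
#' palmar (`fx`), rotating 30 degrees proximally (toward `fz`) and back,
#' over seven 50-ms slices.
#'
#' @param magnitude force magnitude in N; must be positive.
#' @param arc_degrees total rotation in degrees, in `[0, 180)`.
#' @param n_steps number of time slices (>= 2).
#' @param step_ms slice duration in milliseconds.
#' @param delta activation-contraction limit in `[0, 1]`.
#' @return An object of class `task_spec`.
#' @export
task_spec <- function(magnitude = 10, arc_degrees = 30, n_steps = 7L,
                      step_ms = 50, delta = 0.12) {
  if (!is.numeric(magnitude) || magnitude <= 0) stop("magnitude must be > 0")
  if (arc_degrees < 0 || arc_degrees >= 180) stop("arc_degrees must lie in [0, 180)")
  if (n_steps < 2L) stop("n_steps must be >= 2")
  if (step_ms <= 0) stop("step_ms must be > 0")
  if (delta < 0 || delta > 1) stop("delta must lie in [0, 1]")
  structure(list(magnitude = as.numeric(magnitude),
                 arc_degrees = as.numeric(arc_degrees),
                 n_steps = as.integer(n_steps),
                 step_ms = as.numeric(step_ms),
                 delta = as.numeric(delta)),
            class = "task_spec")
}

#' @export
print.task_spec <- function(x, ...) {
  cat("Force-redirection task: ", x$magnitude, " N, ", x$arc_degrees,
      " deg arc, ", x$n_steps, " x ", x$step_ms, " ms slices, delta = ",
      x$delta, "\n", sep = "")
  invisible(x)
}

#' Build the time-indexed wrench sequence of a task
#'
#' The rotation progress is a single cosine period peaking at the middle
#' index: the instantaneous angle at slice `t` (0-based) is
#' `theta_t = (arc/2) * (1 - cos(2*pi*t/(T-1)))`, so the sequence starts and
#' ends at a pure first-component force and is time-symmetric
#' (`w_t == w_{T-1-t}` componentwise).  The force rotates in the plane of the
#' two wrench components named by `plane` (default `fx` toward `fz`, i.e. the
#' palmar force rotating proximally about the ulnar axis); all other
#' components, including torque, are held at zero.
#'
#' @param task a [task_spec].
#' @param model an [h_matrix]; its wrench convention fixes the length and
#'   order of each wrench vector.  Models with a single wrench component are
#'   supported as a planar reduction when `arc_degrees == 0` (constant task).
#' @param plane integer or character pair naming the rotation plane among the
#'   model's wrench components.
#' @return An object of class `wrench_sequence`: a list with `wrenches`
#'   (matrix `n_steps x n_wrench`, rows `t0..t<T-1>`) and `task`.
#' @export
build_task_wrenches <- function(task, model, plane = NULL) {
  T <- task$n_steps
  if (T < 2L) stop("need at least two time slices")
  nw <- n_wrench(model)
  if (is.null(plane)) {
    plane <- if (nw >= 3L) c(1L, 3L) else if (nw == 2L) c(1L, 2L) else 1L
  }
  if (is.character(plane)) plane <- match(plane, model$wrench_names)
  if (anyNA(plane) || any(plane < 1L) || any(plane > nw)) {
    stop("rotation plane components not present in the model's wrench convention")
  }
  if (nw == 1L || length(plane) == 1L) {
    if (task$arc_degrees != 0) {
      stop("a model with a single wrench component only supports a ",
           "constant task (arc_degrees = 0)")
    }
  }
  tt <- seq_len(T) - 1
  theta <- (task$arc_degrees / 2) * (1 - cos(2 * pi * tt / (T - 1))) * pi / 180
  W <- matrix(0, T, nw, dimnames = list(paste0("t", tt), model$wrench_names))
  W[, plane[1]] <- task$magnitude * cos(theta)
  if (length(plane) > 1L) W[, plane[2]] <- task$magnitude * sin(theta)
  structure(list(wrenches = W, task = task), class = "wrench_sequence")
}

#' @export
print.wrench_sequence <- function(x, ...) {
  cat("Wrench sequence over", nrow(x$wrenches), "slices:\n")
  print(round(x$wrenches, 4))
  invisible(x)
}
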