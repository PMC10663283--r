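# Shared fixtures, built in code.

# Reference synthetic 7-muscle, 4-wrench model, feasible for the whole
# delta grid down to 0.05; cached so the suite generates it once.
.fixture_env <- new.env(parent = emptyenv())

synth_task <- function() task_spec(delta = 0.05)

synth_model <- function() {
  if (is.null(.fixture_env$model)) {
    .fixture_env$model <- generate_synthetic_h(7, 4, rng_seed = 1,
                                               task = synth_task())
  }
  .fixture_env$model
}

# Triangle {x >= 0, y >= 0, x + y <= 1}: 2-D fixture with no equality rows.
triangle_spec <- function() {
  polytope_spec(eq_mat = matrix(0, 0, 2), eq_rhs = numeric(0),
                ineq_mat = matrix(c(1, 1), 1, 2), ineq_rhs = 1,
                lower = c(0, 0), upper = c(1, 1),
                var_labels = data.frame(muscle = c("x", "y"), time = 0L,
                                        label = c("x@t0", "y@t0")),
                row_origin_ineq = "simplex")
}

# Unit cube in 3 variables: 3-D chart fixture.
cube_spec <- function(d = 3L) {
  vl <- data.frame(muscle = paste0("m", seq_len(d)), time = 0L,
                   label = paste0("m", seq_len(d), "@t0"))
  polytope_spec(eq_mat = matrix(0, 0, d), eq_rhs = numeric(0),
                lower = rep(0, d), upper = rep(1, d), var_labels = vl)
}

# A tiny trajectory_set built from explicit slices (list of n x m matrices).
manual_trajectories <- function(slices, muscles = NULL) {
  T <- length(slices)
  n <- nrow(slices[[1]])
  m <- ncol(slices[[1]])
  if (is.null(muscles)) muscles <- paste0("m", seq_len(m))
  tensor <- array(NA_real_, c(n, T, m))
  for (t in seq_len(T)) tensor[, t, ] <- slices[[t]]
  trajectory_set(tensor, muscles, seq_len(T) - 1L)
}
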