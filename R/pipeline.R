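#' End-to-end run configuration
#'
#' Bundles everything one experiment needs: the activation-to-wrench model
#' (an [h_matrix], a CSV path, or synthetic-model parameters), the task, the
#' grid of activation-contraction limits, the chain settings, the seeded
#' protocol parameters and the output directory.  All randomness derives
#' from `root_seed` by a fixed rule (`derive_seed`: FNV-1a of
#' "root|delta|stage"), so a rerun with the same configuration reproduces
#' every number.
#'
#' @param model an [h_matrix], a path to an H CSV, or `NULL` to generate a
#'   synthetic model with `synthetic` parameters.
#' @param task a [task_spec].
#' @param delta_grid strictly decreasing activation-contraction limits in
#'   `[0,1]`.
#' @param chain a [chain_config]; its `rng_seed` is ignored in favor of
#'   derived per-stage seeds.
#' @param n_seeds number of seed points for the seeded protocol.
#' @param seed_filter_delta the limit used to filter candidate seed
#'   trajectories (the reference protocol uses ~0.12).
#' @param clamp also run the clamped (first slice = last slice = seed) case.
#' @param root_seed integer root seed.
#' @param out_dir output directory (created on demand).
#' @param synthetic list with `n_muscles`, `n_wrench` for model generation.
#' @return An object of class `run_config`.
#' @export
run_config <- function(model = NULL, task = task_spec(),
                       delta_grid = c(1, 0.5, 0.25, 0.12, 0.05),
                       chain = chain_config(5000L),
                       n_seeds = 10L, seed_filter_delta = 0.12,
                       clamp = TRUE, root_seed = 1L,
                       out_dir = tempfile("actspace_run_"),
                       synthetic = list(n_muscles = 7L, n_wrench = 4L)) {
  if (any(delta_grid < 0) || any(delta_grid > 1)) {
    stop("delta_grid values must lie in [0, 1]")
  }
  if (length(delta_grid) > 1L && any(diff(delta_grid) >= 0)) {
    stop("delta_grid must be strictly decreasing")
  }
  structure(list(model = model, task = task, delta_grid = delta_grid,
                 chain = chain, n_seeds = as.integer(n_seeds),
                 seed_filter_delta = seed_filter_delta,
                 clamp = isTRUE(clamp), root_seed = as.integer(root_seed),
                 out_dir = out_dir, synthetic = synthetic),
            class = "run_config")
}

resolve_model <- function(config) {
  m <- config$model
  if (inherits(m, "h_matrix")) return(m)
  if (is.character(m)) return(read_h_matrix(m))
  gen_task <- config$task
  gen_task$delta <- min(config$task$delta, config$delta_grid)
  generate_synthetic_h(config$synthetic$n_muscles, config$synthetic$n_wrench,
                       rng_seed = derive_seed(config$root_seed, 0, "model"),
                       task = gen_task)
}

ensure_dir <- function(path) {
  if (!dir.exists(path)) dir.create(path, recursive = TRUE)
  path
}

delta_tag <- function(delta) sprintf("delta%.3f", delta)

#' Sample the unseeded trajectory polytope across a delta grid
#'
#' For each activation-contraction limit in the grid: builds the stacked
#' trajectory polytope, runs Hit-and-Run with a seed derived from the root
#' seed, audits every sample against the constraints, and writes the store
#' plus an audit report to the output directory.  Infeasible conditions are
#' recorded and skipped.
#'
#' @param config a [run_config].
#' @param write logical; write stores and audit files to `config$out_dir`.
#' @return Invisibly, a list with `model`, `wrench_seq`, `stores` (named by
#'   delta tag), `audits`, and a `summary` data.frame (delta, status,
#'   n_samples, max residuals, file).
#' @export
sample_conditions <- function(config, write = TRUE) {
  model <- resolve_model(config)
  wseq <- build_task_wrenches(config$task, model)
  if (write) ensure_dir(config$out_dir)
  stores <- list()
  audits <- list()
  rows <- list()
  for (delta in config$delta_grid) {
    tag <- delta_tag(delta)
    spec <- tryCatch(build_trajectory_polytope(model, wseq, delta),
                     error = function(e) e)
    if (inherits(spec, "error")) {
      message("condition ", tag, " infeasible: ", conditionMessage(spec))
      rows[[tag]] <- data.frame(delta = delta, status = "infeasible",
                                n_samples = 0L, max_eq_residual = NA_real_,
                                file = NA_character_)
      next
    }
    cc <- chain_config(config$chain$n_samples, config$chain$burn_in,
                       config$chain$thin,
                       derive_seed(config$root_seed, delta, "unseeded"))
    store <- hit_and_run(spec, cc)
    audit <- audit_samples(store, spec)
    file <- NA_character_
    if (write) {
      file <- file.path(config$out_dir, paste0("unseeded_", tag, ".csv"))
      save_samples(store, file)
      jsonlite::write_json(audit,
                           file.path(config$out_dir, paste0("audit_", tag, ".json")),
                           auto_unbox = TRUE, digits = NA)
    }
    stores[[tag]] <- store
    audits[[tag]] <- audit
    rows[[tag]] <- data.frame(delta = delta, status = "ok",
                              n_samples = nrow(store$samples),
                              max_eq_residual = audit$max_eq_residual,
                              file = file)
  }
  summary <- do.call(rbind, rows)
  rownames(summary) <- NULL
  if (write) {
    utils::write.csv(summary, file.path(config$out_dir, "conditions.csv"),
                     row.names = FALSE)
  }
  invisible(list(model = model, wrench_seq = wseq, stores = stores,
                 audits = audits, summary = summary, config = config))
}

#' Seeded and clamped analysis against an unseeded store
#'
#' Executes the seeded protocol end-to-end: filters the unseeded
#' trajectories by `seed_filter_delta`, draws `n_seeds` of them at random
#' and keeps their first slices as seeds; for each seed, re-samples the
#' trajectory polytope with the first slice pinned to the seed (and, if
#' requested, the clamped variant with the final slice pinned too); fits the
#' per-timestep PCA on the unseeded distribution; projects seeded and
#' unseeded slices into that plane; and reports per-slice convex-hull areas
#' and their seeded/unseeded ratio.
#'
#' @param config a [run_config].
#' @param unseeded a [sample_store] (or a path to one) sampled at
#'   `config$seed_filter_delta` from the matching model/task; the stored
#'   configuration fingerprint is checked and mismatches are refused.
#' @param model the [h_matrix] used for the unseeded run (resolved from the
#'   config when omitted).
#' @param n_seeded samples per seeded chain (defaults to the chain's
#'   `n_samples`).
#' @param write logical; write seeded stores and the hull report.
#' @return Invisibly, a list with `seeds`, `report` (data.frame: seed, time,
#'   clamped, seeded_area, unseeded_area, ratio), `mean_ratio_t1` (mean
#'   unclamped ratio at the second slice), `pc_models` and `stores`.
#' @export
seeded_analysis <- function(config, unseeded, model = NULL,
                            n_seeded = config$chain$n_samples, write = TRUE) {
  if (is.character(unseeded)) unseeded <- load_samples(unseeded)
  if (is.null(model)) model <- resolve_model(config)
  wseq <- build_task_wrenches(config$task, model)
  want_fp <- config_fingerprint(model, config$task, config$seed_filter_delta)
  got_fp <- unseeded$provenance$fingerprint
  if (!is.null(got_fp) && !identical(got_fp, want_fp)) {
    stop("unseeded store does not match this configuration: stored ",
         "fingerprint ", got_fp, " != expected ", want_fp,
         " (model/task/delta differ)")
  }
  ts_un <- reshape_to_trajectories(unseeded)
  filtered <- filter_by_delta(ts_un, config$seed_filter_delta)
  if (n_trajectories(filtered) == 0L) {
    stop("no trajectories survive the activation-contraction filter at ",
         config$seed_filter_delta, "; sample more trajectories or use a ",
         "larger filter delta")
  }
  if (n_trajectories(filtered) < config$n_seeds) {
    stop("only ", n_trajectories(filtered), " trajectories survive the ",
         "filter but ", config$n_seeds, " seeds were requested; sample more ",
         "trajectories or use a larger filter delta")
  }
  seeds <- select_seeds(filtered, config$n_seeds,
                        derive_seed(config$root_seed, config$seed_filter_delta,
                                    "seeds"))
  pc_models <- fit_pc_per_timestep(ts_un)
  T <- length(pc_models)
  un_proj <- lapply(seq_len(T), function(t) project_timestep(ts_un, pc_models, t))
  un_area <- vapply(un_proj, function(p) as.numeric(hull_area(p)), numeric(1))

  spec0 <- build_trajectory_polytope(model, wseq, config$seed_filter_delta)
  variants <- c(FALSE, if (config$clamp) TRUE)
  if (write) ensure_dir(config$out_dir)
  stores <- list()
  rows <- list()
  for (i in seq_along(seeds)) {
    for (cl in variants) {
      sd <- seed_point(seeds[[i]]$activation, clamp = cl)
      spec_s <- add_seed_constraint(spec0, sd)
      cc <- chain_config(n_seeded, config$chain$burn_in, config$chain$thin,
                         derive_seed(config$root_seed,
                                     config$seed_filter_delta,
                                     sprintf("seeded%d_%s", i,
                                             if (cl) "clamped" else "unclamped")))
      st <- suppressWarnings(hit_and_run(spec_s, cc))
      key <- sprintf("seed%02d_%s", i, if (cl) "clamped" else "unclamped")
      stores[[key]] <- st
      if (write) {
        save_samples(st, file.path(config$out_dir, paste0(key, ".csv")))
      }
      ts_s <- reshape_to_trajectories(st)
      for (t in seq_len(T)) {
        pr <- project_timestep(ts_s, pc_models, t)
        sa <- as.numeric(hull_area(pr))
        rows[[length(rows) + 1L]] <- data.frame(
          seed = i, time = ts_un$times[t], clamped = cl,
          seeded_area = sa, unseeded_area = un_area[t],
          ratio = if (un_area[t] > 0) sa / un_area[t] else NA_real_)
      }
    }
  }
  report <- do.call(rbind, rows)
  class(report) <- c("hull_area_report", class(report))
  t1 <- sort(unique(report$time))[2]
  mean_ratio_t1 <- mean(report$ratio[report$time == t1 & !report$clamped])
  if (write) {
    utils::write.csv(report, file.path(config$out_dir, "hull_report.csv"),
                     row.names = FALSE)
  }
  invisible(list(seeds = seeds, report = report,
                 mean_ratio_t1 = mean_ratio_t1,
                 pc_models = pc_models, stores = stores,
                 unseeded_areas = un_area))
}

#' @export
print.hull_area_report <- function(x, ...) {
  cat("Hull-area report:", length(unique(x$seed)), "seed(s),",
      length(unique(x$time)), "slice(s)\n")
  agg <- stats::aggregate(ratio ~ time + clamped, data = x, FUN = mean)
  print(agg)
  invisible(x)
}

#' Tabular and graphical report of a sampling run
#'
#' Writes per-condition speed-distribution and occupancy tables (CSV), and
#' simple figures: per-muscle speed boxplots per condition and, when a
#' seeded analysis is supplied, PC-plane scatter plots with hull overlays.
#' Stores whose configuration fingerprints disagree are refused.
#'
#' @param run result of [sample_conditions].
#' @param seeded optional result of [seeded_analysis].
#' @param out_dir output directory (defaults to the run's).
#' @return Invisibly, the paths written.
#' @export
pipeline_report <- function(run, seeded = NULL, out_dir = run$config$out_dir) {
  if (length(run$stores) == 0L) stop("empty run: no stores to report on")
  fps <- vapply(run$stores, function(s)
    s$provenance$run_fingerprint %||% NA_character_, character(1))
  if (length(unique(stats::na.omit(fps))) > 1L) {
    stop("stores come from different configurations: fingerprints ",
         paste(unique(fps), collapse = " vs "))
  }
  ensure_dir(out_dir)
  paths <- character(0)

  occ <- do.call(rbind, lapply(names(run$stores), function(tag) {
    ts <- reshape_to_trajectories(run$stores[[tag]])
    occupancy_summary(ts)
  }))
  p <- file.path(out_dir, "occupancy.csv")
  utils::write.csv(occ, p, row.names = FALSE)
  paths <- c(paths, p)

  mx <- do.call(rbind, lapply(names(run$stores), function(tag) {
    st <- run$stores[[tag]]
    ts <- reshape_to_trajectories(st)
    m <- max_abs_speed(ts)
    data.frame(delta = st$provenance$delta,
               muscle = rep(colnames(m), each = nrow(m)),
               max_abs_speed = as.vector(m))
  }))
  p <- file.path(out_dir, "max_abs_speed.csv")
  utils::write.csv(mx, p, row.names = FALSE)
  paths <- c(paths, p)

  for (tag in names(run$stores)) {
    st <- run$stores[[tag]]
    ts <- reshape_to_trajectories(st)
    ss <- activation_speeds(ts)
    fig <- file.path(out_dir, paste0("speeds_", tag, ".png"))
    grDevices::png(fig, width = 900, height = 500)
    sp <- lapply(seq_along(ts$muscles), function(j) as.vector(ss$tensor[, , j]))
    names(sp) <- ts$muscles
    graphics::boxplot(sp, outline = FALSE,
                      main = paste0("Activation-contraction speeds (",
                                    tag, ")"),
                      ylab = "activation change per slice")
    graphics::abline(h = c(-1, 1) * (st$provenance$delta %||% 1), lty = 2)
    grDevices::dev.off()
    paths <- c(paths, fig)
  }

  if (!is.null(seeded)) {
    T <- length(seeded$pc_models)
    un_tag <- delta_tag(run$config$seed_filter_delta)
    un_store <- run$stores[[un_tag]]
    if (!is.null(un_store)) {
      ts_un <- reshape_to_trajectories(un_store)
      for (t in seq_len(T)) {
        pr_un <- project_timestep(ts_un, seeded$pc_models, t)
        fig <- file.path(out_dir, sprintf("pc_plane_t%d.png", t - 1L))
        grDevices::png(fig, width = 700, height = 700)
        plot(pr_un, pch = ".", col = "grey50", asp = 1,
             main = sprintf("Feasible activations at slice t=%d (PC plane)",
                            t - 1L))
        hull_overlay <- function(p, col) {
          if (nrow(p) >= 3L) {
            idx <- grDevices::chull(p)
            graphics::polygon(p[idx, 1L], p[idx, 2L], border = col, lwd = 2)
          }
        }
        hull_overlay(pr_un, "black")
        ks <- names(seeded$stores)[!grepl("clamped", names(seeded$stores))]
        cols <- grDevices::hcl.colors(max(length(ks), 2L), "Dark 3")
        for (i in seq_along(ks)) {
          ts_s <- reshape_to_trajectories(seeded$stores[[ks[i]]])
          hull_overlay(project_timestep(ts_s, seeded$pc_models, t), cols[i])
        }
        grDevices::dev.off()
        paths <- c(paths, fig)
      }
    }
  }
  invisible(paths)
}
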