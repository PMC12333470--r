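#' Experiment configuration
#'
#' A fully serializable description of a simulated (or loaded) multi-group
#' open-field experiment; a config plus the package version determines every
#' output bit-exactly.
#'
#' @param groups Named list; each element a list with `n_animals`, `severity`
#'   (0..1), and optionally `restore_velocity_only` (logical). A severity-0
#'   group is a control.
#' @param n_syllables,speed_range,target_mean_duration Generator: repertoire
#'   size, speed range (mm/s), mean syllable dwell time (s).
#' @param session_duration Session length, seconds.
#' @param fps Frame rate, Hz.
#' @param baseline_speed Apparent motionless speed the tracking jitter is
#'   calibrated to, mm/s.
#' @param velocity_slope,usage_beta,stickiness_gain Lesion transform knobs
#'   (see [lesion_transform()]).
#' @param likelihood_threshold Confidence gate for preprocessing.
#' @param n_components PCA components.
#' @param kappa_grid Kappa values for the duration scan.
#' @param K_max,ar_order,n_iter,burn_in AR-HMM size and Gibbs schedule.
#' @param target_duration_ms Kappa-scan target median duration.
#' @param usage_threshold Expression filter for reported tables.
#' @param entropy_base,entropy_mode Entropy conventions.
#' @param q FDR level for BH.
#' @param seed Master seed; per-animal seeds are derived from it.
#' @param use_ground_truth If TRUE, skip AR-HMM fitting and use the
#'   generator's ground-truth labels (fast path for calibration studies).
#' @return Object of class `experiment_config`.
#' @export
experiment_config <- function(groups = list(
                                control = list(n_animals = 6, severity = 0),
                                lesion = list(n_animals = 7, severity = 0.8)),
                              n_syllables = 21, speed_range = c(0, 172),
                              target_mean_duration = 0.4,
                              session_duration = 900, fps = 30,
                              baseline_speed = 30, velocity_slope = 0.6,
                              usage_beta = 0.8, stickiness_gain = 1.5,
                              likelihood_threshold = 0.5, n_components = 5,
                              kappa_grid = c(1e3, 1e4, 1e5),
                              K_max = 30, ar_order = 3, n_iter = 50,
                              burn_in = 25, target_duration_ms = 400,
                              usage_threshold = 0.005, entropy_base = 2,
                              entropy_mode = "rate", q = 0.05, seed = 1L,
                              use_ground_truth = FALSE) {
  cfg <- as.list(environment())
  if (is.null(names(groups)) || any(!nzchar(names(groups))))
    stopf("`groups` must be a named list")
  structure(cfg, class = "experiment_config")
}

#' @rdname experiment_config
#' @param path JSON path.
#' @export
write_config <- function(cfg, path) {
  jsonlite::write_json(unclass(cfg), path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname experiment_config
#' @export
read_config <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$groups <- lapply(obj$groups, as.list)
  do.call(experiment_config, obj)
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stopf("experiment stage '%s' failed: %s", name, conditionMessage(e)))
}

#' Run a full control-vs-condition experiment from a config
#'
#' Simulates every group's cohort (one generator world deformed per group by
#' its condition transform), preprocesses (confidence gating, egocentric
#' alignment, pooled PCA), segments (kappa scan + sticky AR-HMM fit on the
#' pooled latents, or ground-truth labels when configured), computes
#' per-animal metrics, and runs the group statistics: per-syllable
#' Kruskal-Wallis + BH on velocity and usage over the retained (>0.5% usage)
#' alphabet, Mann-Whitney on session velocity / entropy / transition
#' frequency against the first group, and the delta-metric regressions
#' against control syllable velocity.
#'
#' @param cfg An [experiment_config()].
#' @param out_dir Optional output directory; when given, writes the stats
#'   tables, transition summaries, delta regressions, model JSON, config and
#'   a log there as CSV/JSON.
#' @return Results list: `stats_tables` (per group), `alphabet`, `velocity_table`,
#'   `usage_table` (comparison tables), `session_metrics`, `scalar_tests`,
#'   `delta` (per non-control group: table + regressions), `model` (or NULL),
#'   `config`.
#' @export
run_experiment <- function(cfg, out_dir = NULL) {
  stopifnot(inherits(cfg, "experiment_config"))
  group_names <- names(cfg$groups)

  world <- stage("simulate", {
    rep0 <- build_repertoire(cfg$n_syllables, cfg$speed_range,
                             seed = cfg$seed)
    trans0 <- build_transition_model(cfg$n_syllables,
                                     cfg$target_mean_duration, cfg$fps,
                                     seed = cfg$seed + 1L)
    jit <- calibrate_noise(cfg$baseline_speed, cfg$fps)
    animal_id <- 0L
    groups <- lapply(group_names, function(g) {
      spec <- cfg$groups[[g]]
      tf <- lesion_transform(rep0,
                             severity = spec$severity,
                             velocity_slope = cfg$velocity_slope,
                             usage_beta = cfg$usage_beta,
                             stickiness_gain = cfg$stickiness_gain,
                             restore_velocity_only =
                               isTRUE(spec$restore_velocity_only))
      cond <- apply_condition(rep0, trans0, tf)
      sessions <- lapply(seq_len(spec$n_animals), function(i) {
        animal_id <<- animal_id + 1L
        simulate_session(cond$repertoire, cond$transitions,
                         duration = cfg$session_duration, fps = cfg$fps,
                         jitter_sd = jit, seed = cfg$seed * 1000L + animal_id,
                         generate_pose = !cfg$use_ground_truth)
      })
      sessions
    })
    names(groups) <- group_names
    groups
  })

  model <- NULL
  seqs_by_group <- if (cfg$use_ground_truth) {
    stage("labels", lapply(world, function(sessions)
      lapply(sessions, function(s)
        syllable_sequence(s$truth$labels, fps = cfg$fps))))
  } else {
    latents_by_group <- stage("preprocess", {
      poses <- lapply(world, function(sessions)
        lapply(sessions, function(s)
          egocentric_align(gate_and_interpolate(s$recording,
                                                cfg$likelihood_threshold))))
      pca <- fit_pca(unlist(poses, recursive = FALSE), cfg$n_components)
      lapply(poses, function(ps) lapply(ps, transform_pca, model = pca))
    })
    fit <- stage("segmentation", {
      pooled <- unlist(latents_by_group, recursive = FALSE)
      hyper <- arhmm_hyper(K_max = cfg$K_max, ar_order = cfg$ar_order,
                           n_iter = cfg$n_iter, burn_in = cfg$burn_in,
                           seed = cfg$seed)
      scan <- kappa_scan(pooled, hyper, cfg$kappa_grid,
                         cfg$target_duration_ms)
      model <- scan$fit$model
      # decode deterministically per session so labels are reproducible
      idx <- 0L
      lapply(latents_by_group, function(ls) lapply(ls, function(l) {
        idx <<- idx + 1L
        decode(model, l, session = idx)
      }))
    })
    fit
  }

  metrics <- stage("metrics", {
    res <- list()
    for (g in group_names) {
      sessions <- world[[g]]
      seqs <- seqs_by_group[[g]]
      animals <- lapply(seq_along(sessions), function(i) {
        cen <- if (cfg$use_ground_truth) sessions[[i]]$truth$centroid
               else egocentric_align(sessions[[i]]$recording)$centroid
        list(seq = seqs[[i]], centroid = cen)
      })
      st <- syllable_stats(animals)
      scal <- data.frame(
        animal = seq_along(animals),
        session_velocity = vapply(animals, function(a)
          session_velocity(a$centroid, cfg$fps), numeric(1)),
        transition_frequency = vapply(animals, function(a)
          transition_frequency(a$seq), numeric(1)),
        entropy = vapply(animals, function(a)
          entropy(transition_matrix(a$seq, log_base = cfg$entropy_base,
                                    mode = cfg$entropy_mode),
                  cfg$entropy_base, cfg$entropy_mode), numeric(1)))
      res[[g]] <- list(stats = st, scalars = scal)
    }
    res
  })

  results <- stage("stats", {
    pooled_usage <- usage(unlist(seqs_by_group, recursive = FALSE))
    alphabet <- as.integer(filter_expressed(pooled_usage, cfg$usage_threshold))
    values_by_group <- lapply(metrics, function(m) m$stats$per_animal)
    vel_tab <- compare_syllables(values_by_group, "velocity", alphabet, cfg$q)
    use_tab <- compare_syllables(values_by_group, "usage", alphabet, cfg$q)

    ctrl <- group_names[1]
    scalar_tests <- list()
    delta <- list()
    for (g in group_names[-1]) {
      scalar_tests[[g]] <- lapply(
        c("session_velocity", "transition_frequency", "entropy"),
        function(m) {
          mw <- mann_whitney(metrics[[ctrl]]$scalars[[m]],
                             metrics[[g]]$scalars[[m]])
          data.frame(metric = m, U = mw$U, p = mw$p,
                     mean_control = mean(metrics[[ctrl]]$scalars[[m]]),
                     mean_other = mean(metrics[[g]]$scalars[[m]]))
        })
      scalar_tests[[g]] <- do.call(rbind, scalar_tests[[g]])
      dt <- delta_table(metrics[[ctrl]]$stats$table, metrics[[g]]$stats$table)
      dt <- dt[dt$syllable %in% alphabet, ]
      delta[[g]] <- list(
        table = dt,
        velocity_regression = ols_regression(dt$control_velocity,
                                             dt$delta_velocity),
        usage_regression = ols_regression(dt$control_velocity,
                                          dt$delta_usage))
    }
    list(alphabet = alphabet, velocity_table = vel_tab,
         usage_table = use_tab, scalar_tests = scalar_tests, delta = delta)
  })

  out <- list(stats_tables = lapply(metrics, function(m) m$stats$table),
              session_metrics = lapply(metrics, function(m) m$scalars),
              alphabet = results$alphabet,
              velocity_table = results$velocity_table,
              usage_table = results$usage_table,
              scalar_tests = results$scalar_tests,
              delta = results$delta,
              model = model, config = cfg)

  if (!is.null(out_dir)) stage("write", {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_config(cfg, file.path(out_dir, "config.json"))
    for (g in group_names) {
      write.csv(out$stats_tables[[g]],
                file.path(out_dir, paste0("syllable_stats_", g, ".csv")),
                row.names = FALSE)
      write.csv(out$session_metrics[[g]],
                file.path(out_dir, paste0("session_metrics_", g, ".csv")),
                row.names = FALSE)
    }
    write.csv(out$velocity_table, file.path(out_dir, "velocity_comparison.csv"),
              row.names = FALSE)
    write.csv(out$usage_table, file.path(out_dir, "usage_comparison.csv"),
              row.names = FALSE)
    for (g in names(out$delta)) {
      write.csv(out$delta[[g]]$table,
                file.path(out_dir, paste0("delta_", g, ".csv")),
                row.names = FALSE)
      jsonlite::write_json(out$delta[[g]][c("velocity_regression",
                                            "usage_regression")],
                           file.path(out_dir, paste0("delta_regressions_", g,
                                                     ".json")),
                           digits = NA, auto_unbox = TRUE)
    }
    if (!is.null(model))
      save_arhmm_model(model, file.path(out_dir, "arhmm_model.json"))
    writeLines(sprintf("[syllakin] seed=%d groups=%s segmentation=%s",
                       cfg$seed, paste(group_names, collapse = ","),
                       if (cfg$use_ground_truth) "ground_truth" else "arhmm"),
               file.path(out_dir, "run.log"))
  })
  invisible(out)
}
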