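#' Write a delimited table with a metadata header
#'
#' CSV body preceded by `# key: value` comment lines holding the resolved
#' configuration, seed, and any workflow metadata, so every output file
#' can be re-run from its own header.
#'
#' @param df data.frame to write.
#' @param path output path.
#' @param meta named list of metadata (scalars or short vectors).
#' @return The path, invisibly.
#' @export
write_table_with_meta <- function(df, path, meta = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(meta)) {
    for (k in names(meta)) {
      v <- meta[[k]]
      writeLines(paste0("# ", k, ": ", paste(format(v, digits = 15),
                                             collapse = " ")), con)
    }
  }
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Read a table written by [write_table_with_meta()]
#'
#' @param path file path.
#' @return A data.frame; the parsed `# key: value` header is attached as
#'   attribute `"meta"`.
#' @export
read_table_with_meta <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  df <- utils::read.csv(path, comment.char = "#")
  meta <- list()
  for (l in hdr) {
    kv <- sub("^#\\s*", "", l)
    key <- sub(":.*$", "", kv)
    meta[[key]] <- trimws(sub("^[^:]*:", "", kv))
  }
  attr(df, "meta") <- meta
  df
}

#' Load and validate a run configuration
#'
#' Reads a YAML configuration holding the flow regime, species parameters,
#' plots, and simulation controls, validates it against all module
#' preconditions, and returns the resolved config. Validation failures are
#' reported in one itemized error message.
#'
#' @param path YAML file path, or a list already in config shape.
#' @return A validated list of class `run_config` with elements `flow`
#'   (a [flow_regime()]), `species` (a [species_params()]), `plots`
#'   (data.frame or NULL), `simulation` (list with `dt`, `n_paths`,
#'   `seed`, `t_end`, `years`), and `raw` (the input list).
#' @export
load_config <- function(path) {
  cfg <- if (is.character(path)) yaml::read_yaml(path) else path
  errs <- character()
  need <- function(cond, msg) if (!isTRUE(cond)) errs <<- c(errs, msg)

  fl <- cfg$flow
  need(is.list(fl), "missing `flow` block")
  if (is.list(fl)) {
    need(is.numeric(fl$mu), "flow: missing or non-numeric `mu`")
    need(is.numeric(fl$sigma) && isTRUE(fl$sigma > 0),
         "flow: `sigma` missing or not > 0")
    if (!is.null(fl$tau_h)) need(isTRUE(fl$tau_h >= 0), "flow: `tau_h` must be >= 0")
  }
  spc <- cfg$species
  sp <- NULL
  if (is.null(spc)) spc <- list()
  sp <- tryCatch(do.call(species_params, spc),
                 error = function(e) { errs <<- c(errs, paste("species:", conditionMessage(e))); NULL })
  plots <- NULL
  if (!is.null(cfg$plots)) {
    plots <- tryCatch(do.call(rbind, lapply(cfg$plots, as.data.frame)),
                      error = function(e) { errs <<- c(errs, "plots: malformed plot list"); NULL })
    if (!is.null(plots)) {
      need("plot_id" %in% names(plots), "plots: each plot needs `plot_id`")
    }
  }
  sim <- cfg$simulation
  if (is.null(sim)) sim <- list()
  sim <- utils::modifyList(list(dt = 0.01, n_paths = 1000L, seed = 1L,
                                t_end = 1, years = 60L), sim)
  need(isTRUE(sim$dt > 0), "simulation: `dt` must be > 0")
  need(isTRUE(sim$n_paths >= 1), "simulation: `n_paths` must be >= 1")

  if (length(errs)) {
    stop("invalid configuration:\n", paste0("  - ", errs, collapse = "\n"),
         call. = FALSE)
  }
  flow <- flow_regime(mu = fl$mu, sigma = fl$sigma,
                      tau_h = if (is.null(fl$tau_h)) 0 else fl$tau_h)
  structure(list(flow = flow, species = sp, plots = plots, simulation = sim,
                 raw = cfg),
            class = "run_config")
}

config_meta <- function(cfg, extra = NULL) {
  m <- list(
    flow_mu = cfg$flow$mu, flow_sigma = cfg$flow$sigma,
    flow_tau_h = cfg$flow$tau_h,
    lambda = cfg$species$lambda, a_f = cfg$species$a_f,
    A = cfg$species$A, B = cfg$species$B, C = cfg$species$C,
    D = cfg$species$D, T_f = cfg$species$T_f,
    epsilon = cfg$species$epsilon, n_e = cfg$species$n_e,
    dt = cfg$simulation$dt, n_paths = cfg$simulation$n_paths,
    seed = cfg$simulation$seed
  )
  c(m, extra)
}

#' Run a named analysis workflow
#'
#' Dispatches one of the package's workflows against a validated
#' configuration and writes its delimited-text outputs (with full
#' metadata headers) into `out_dir`. Subcommands:
#' `analytic` (stage-moment table), `simulate` (ensemble summary),
#' `lifespan` (lifespan curve over a divergence grid), `transect`
#' (spatial patterns for the three stock gradients), `calibrate`
#' (species-parameter recovery from a samples file), `community`
#' (age-structure simulation), `estimate-flow` (regime estimation +
#' Gaussianity test from a level series), `fixtures` (synthetic hydrology
#' and calibration samples).
#'
#' @param name subcommand name.
#' @param config a `run_config` from [load_config()], or a path/list
#'   accepted by it.
#' @param out_dir output directory (created if absent).
#' @param samples_file,series_file input tables for `calibrate` /
#'   `estimate-flow`.
#' @return Character vector of files written, invisibly.
#' @export
run_subcommand <- function(name, config, out_dir = ".",
                           samples_file = NULL, series_file = NULL) {
  known <- c("analytic", "simulate", "lifespan", "transect", "calibrate",
             "community", "estimate-flow", "fixtures")
  if (!name %in% known) {
    stop("unknown subcommand `", name, "`; expected one of: ",
         paste(known, collapse = ", "), call. = FALSE)
  }
  cfg <- if (inherits(config, "run_config")) config else load_config(config)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  sp <- cfg$species
  fl <- cfg$flow
  sim <- cfg$simulation
  t0 <- proc.time()[["elapsed"]]
  files <- character()
  emit <- function(df, fname, extra = NULL) {
    p <- file.path(out_dir, fname)
    write_table_with_meta(df, p, config_meta(cfg, extra))
    files <<- c(files, p)
  }
  eta1 <- if (!is.null(cfg$plots) && "eta" %in% names(cfg$plots)) {
    cfg$plots$eta[1]
  } else fl$mu  # zero divergence fallback

  switch(name,
    "analytic" = {
      ep <- fl$mu - eta1
      tab <- moment_table(sp, ep, fl$sigma, fl$tau_h,
                          times = c(seq(0, sp$T_f, by = sp$T_f / 10),
                                    seq(sp$T_f + 1, sp$t_maxage, by = 1)))
      emit(tab, "moments.csv", list(eta = eta1, eta_prime = ep,
                                    workflow = "analytic"))
    },
    "simulate" = {
      ens <- simulate_cohort(sp, fl, eta1, t_end = sim$t_end, dt = sim$dt,
                             n_paths = sim$n_paths, seed = sim$seed,
                             mode = if (fl$tau_h > 0) "ou_pathwise" else "wgn_exact")
      emit(ensemble_summary(ens), "ensemble_summary.csv",
           list(eta = eta1, mode = ens$mode, workflow = "simulate"))
    },
    "lifespan" = {
      lc <- lifespan_curve(sp, seq(0, 1.5, by = 0.1),
                           c(0.3, fl$sigma, 0.9), fl$tau_h)
      emit(lc$table, "lifespan.csv", list(workflow = "lifespan"))
    },
    "transect" = {
      for (kind in c("slow", "moderate", "rapid")) {
        prof <- make_profiles(kind, sigma0 = fl$sigma)
        pat <- spatial_pattern(prof, sp, fl$tau_h)
        emit(pat, paste0("transect_", kind, ".csv"),
             list(kind = kind,
                  pattern_abundance = classify_pattern(pat$mean_abundance),
                  pattern_lifespan = classify_pattern(pat$lifespan),
                  workflow = "transect"))
      }
    },
    "calibrate" = {
      if (is.null(samples_file)) stop("calibrate needs `samples_file`", call. = FALSE)
      if (is.null(cfg$plots) || !"altitude" %in% names(cfg$plots)) {
        stop("calibrate needs plots with altitudes in the config", call. = FALSE)
      }
      samples <- read_table_with_meta(samples_file)
      slopes <- fit_plot_slopes(samples)
      res <- solve_species_params(slopes, cfg$plots, fl)
      emit(data.frame(parameter = c("lambda", "a_f",
                                    paste0("eta_", res$plot_id)),
                      value = c(res$lambda, res$a_f, res$eta)),
           "calibration.csv",
           list(residual_norm = res$residual_norm, workflow = "calibrate"))
    },
    "community" = {
      if (is.null(cfg$plots) || !"eta" %in% names(cfg$plots)) {
        stop("community needs plots with `eta` in the config", call. = FALSE)
      }
      drift <- cfg$raw$drift
      regime <- if (!is.null(drift)) {
        make_drifting_regime(fl, drift$mean_amplitude,
                             if (is.null(drift$sd_amplitude)) 0 else drift$sd_amplitude,
                             drift$period, sim$years, sim$years)
      } else fl
      rec <- simulate_community(sp, cfg$plots, regime, years = sim$years,
                                seed = sim$seed,
                                paths_per_cohort = sim$n_paths, dt = sim$dt)
      emit(rec$record, "age_structure.csv", list(workflow = "community"))
      emit(rec$totals, "totals.csv", list(workflow = "community"))
    },
    "estimate-flow" = {
      if (is.null(series_file)) stop("estimate-flow needs `series_file`", call. = FALSE)
      ser <- read_flow_series(series_file)
      est <- estimate_regime(ser)
      gt <- gaussian_fit_test(ser)
      emit(data.frame(parameter = c("mu", "sigma", "tau_h",
                                    "normality_statistic", "normality_p"),
                      value = c(est$mu, est$sigma, est$tau_h,
                                gt$statistic, gt$p_value)),
           "flow_estimate.csv",
           list(normality_test = gt$method, workflow = "estimate-flow"))
    },
    "fixtures" = {
      ser <- sample_water_table(fl, seq(0, 100, by = 0.1),
                                seed = sub_seed(sim$seed, "flow"))
      p1 <- file.path(out_dir, "hydrology.csv")
      write_flow_series(ser, p1, config_meta(cfg, list(workflow = "fixtures")))
      files <- c(files, p1)
      if (!is.null(cfg$plots) && "eta" %in% names(cfg$plots)) {
        sam <- generate_calibration_fixture(sp, cfg$plots, fl,
                                            noise_sd = 0.05, n_times = 8L,
                                            seed = sim$seed)
        emit(sam, "plot_samples.csv", list(workflow = "fixtures"))
      }
    }
  )
  message(sprintf("riparia %s: wrote %d file(s) to %s (seed %s, %.2fs)",
                  name, length(files), out_dir, sim$seed,
                  proc.time()[["elapsed"]] - t0))
  invisible(files)
}
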