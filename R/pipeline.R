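## Orchestration: a single config drives simulate -> screen-call -> map ->
## dock -> fit with per-stage outputs and a self-describing run report.
## The exported functions are the command surface of the package; they are
## what a thin shell wrapper would call.

#' Default pipeline configuration
#'
#' Returns the full default config as a named list; [run_pipeline()]
#' merges user values over these, and the run report echoes the merged
#' config so every run is self-describing.
#'
#' @param ... overrides (nested lists are merged shallowly per section).
#' @return named list of class `run_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    seed = 1L,
    out_dir = tempfile("smcrod_run_"),
    stages = c("simulate", "screen-call", "map", "dock", "fit-exchange"),
    inputs = list(monomer = NULL, efficiency_table = NULL, timecourse = NULL),
    synthetic = list(n_residues = 110L, axis_offset = 9.6, axis_tilt = 0,
                     E_max = 0.9, d0 = 14, slope = 2, noise_sd = 0,
                     exchange_k = log(2) / 49, exchange_Feq = 0.5,
                     exchange_noise_sd = 0,
                     exchange_times = c(0, 5, 10, 20, 40, 80, 120, 160)),
    thresholds = list(axial = 0.20, reach = 14, clash = 4),
    dock = list(n_directions = 200L, offset_spacing = 2, offset_max = 20,
                clash_weight = 1, prefilter = 200L, top_k = 5L,
                refine_maxit = 500L)
  )
  over <- list(...)
  for (nm in names(over)) {
    if (is.list(cfg[[nm]]) && is.list(over[[nm]])) {
      cfg[[nm]][names(over[[nm]])] <- over[[nm]]
    } else cfg[[nm]] <- over[[nm]]
  }
  class(cfg) <- c("run_config", "list")
  cfg
}

#' Read a pipeline config from YAML
#' @param path YAML file.
#' @return a [pipeline_config()] with the file's values merged in.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stopf("config file not found: %s", path)
  do.call(pipeline_config, yaml::read_yaml(path))
}

#' Validate a pipeline config
#'
#' Collects every offending field at once rather than failing on the
#' first.
#'
#' @param config a [pipeline_config()].
#' @return invisibly TRUE; errors with the full list of problems.
#' @export
validate_config <- function(config) {
  problems <- character()
  th <- config$thresholds
  for (nm in c("axial", "reach", "clash")) {
    if (!is.numeric(th[[nm]]) || th[[nm]] <= 0) {
      problems <- c(problems, sprintf("thresholds$%s must be a positive number", nm))
    }
  }
  known <- c("simulate", "screen-call", "map", "dock", "fit-exchange")
  bad <- setdiff(config$stages, known)
  if (length(bad)) problems <- c(problems, sprintf("unknown stage(s): %s", paste(bad, collapse = ", ")))
  for (nm in names(config$inputs)) {
    p <- config$inputs[[nm]]
    if (!is.null(p) && !file.exists(p)) {
      problems <- c(problems, sprintf("inputs$%s: file not found: %s", nm, p))
    }
  }
  if (is.null(config$inputs$monomer) && !"simulate" %in% config$stages &&
      any(c("map", "dock") %in% config$stages)) {
    problems <- c(problems, "map/dock need inputs$monomer when the simulate stage is off")
  }
  if (!is.numeric(config$seed) || length(config$seed) != 1) {
    problems <- c(problems, "seed must be a single integer")
  }
  if (length(problems)) {
    stopf("invalid pipeline config:\n%s", paste("  -", problems, collapse = "\n"))
  }
  invisible(TRUE)
}

#' Run the pipeline
#'
#' Executes the configured stages with per-stage TSV/PDB/JSON outputs in
#' `config$out_dir`, logging stage timings to stderr, and returns (and
#' writes) a run report carrying the merged config, input hashes, package
#' version and all seeds. Reruns with identical config and seed are
#' deterministic.
#'
#' @param config a [pipeline_config()] or path to a YAML config.
#' @return the run report (named list), invisibly; also written as
#'   `report.json` in the output directory.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  if (is.character(config)) config <- read_pipeline_config(config)
  validate_config(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(config$seed)
  report <- list(package_version = as.character(utils::packageVersion("smcrod")),
                 seed = seed, config = unclass(config),
                 input_hashes = list(), stages = list())
  for (nm in names(config$inputs)) {
    p <- config$inputs[[nm]]
    if (!is.null(p)) report$input_hashes[[nm]] <- unname(tools::md5sum(p))
  }
  log_stage <- function(name, expr) {
    t0 <- Sys.time()
    message(sprintf("[%s] starting", name))
    out <- force(expr)
    message(sprintf("[%s] done in %.1f s", name,
                    as.numeric(difftime(Sys.time(), t0, units = "secs"))))
    out
  }
  syn <- config$synthetic
  monomer <- NULL; table <- NULL; truth_axis <- NULL

  if ("simulate" %in% config$stages) {
    log_stage("simulate", {
      monomer <- make_monomer_arm(coil_params(n_residues = syn$n_residues,
                                               seed = seed))
      rod <- make_rod_dimer(monomer, axis_offset = syn$axis_offset,
                            axis_tilt = syn$axis_tilt, seed = seed)
      truth_axis <- rod$axis
      noise <- efficiency_noise_model(E_max = syn$E_max, d0 = syn$d0,
                                      slope = syn$slope,
                                      noise_sd = syn$noise_sd, seed = seed)
      table <- simulate_efficiencies(rod$dimer, ca_atoms(monomer)$resno, noise)
      write_structure(monomer, file.path(config$out_dir, "monomer.pdb"))
      write_structure(rod$dimer, file.path(config$out_dir, "true_dimer.pdb"))
      save_efficiency_table(table, file.path(config$out_dir, "efficiencies.tsv"))
      report$stages$simulate <- list(n_positions = nrow(table),
                                      planted_axis = list(direction = rod$axis$direction,
                                                          point = rod$axis$point))
    })
  }
  if (!is.null(config$inputs$monomer)) monomer <- read_structure(config$inputs$monomer)
  if (!is.null(config$inputs$efficiency_table)) {
    table <- load_efficiency_table(config$inputs$efficiency_table)
  }

  if ("screen-call" %in% config$stages) {
    log_stage("screen-call", {
      axial <- call_axial(table, config$thresholds$axial)
      write.table(data.frame(position = axial),
                  file.path(config$out_dir, "axial_calls.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      report$stages$screen_call <- list(n_tested = sum(table$tested),
                                         n_axial = length(axial))
    })
  }

  dock <- NULL
  if ("dock" %in% config$stages) {
    dock <- log_stage("dock", {
      dp <- do.call(dock_params, c(config$dock,
                                   list(reach_cutoff = config$thresholds$reach,
                                        clash_cutoff = config$thresholds$clash,
                                        axial_threshold = config$thresholds$axial)))
      res <- dock_c2(monomer, table, params = dp, seed = seed)
      write_dock_result(res, file.path(config$out_dir, "dock"))
      info <- list(objective = res$objective, clash_count = res$clash_count,
                   axis = list(direction = res$axis$direction, point = res$axis$point))
      if (!is.null(truth_axis)) {
        info$axis_error_deg <- axis_angle_deg(res$axis$direction, truth_axis$direction)
      }
      report$stages$dock <- info
      res
    })
  }

  if ("map" %in% config$stages) {
    log_stage("map", {
      dimer <- if (!is.null(dock)) dock$dimer else {
        build_c2_dimer(monomer, truth_axis)
      }
      prof <- build_profile(table, dimer, reach_cutoff = config$thresholds$reach)
      write_profile(prof, file.path(config$out_dir, "profile.tsv"))
      cs <- compatibility_score(prof, config$thresholds$axial)
      report$stages$map <- list(n_rows = nrow(prof),
                                 compatibility_score = cs$score,
                                 n_violations = nrow(cs$violations))
    })
  }

  if ("fit-exchange" %in% config$stages) {
    log_stage("fit-exchange", {
      tc <- if (!is.null(config$inputs$timecourse)) {
        d <- read.table(config$inputs$timecourse, header = TRUE, sep = "\t")
        exchange_timecourse(d$time_min %||% d$time, d$fraction)
      } else {
        simulate_exchange(syn$exchange_k, syn$exchange_Feq, syn$exchange_times,
                          noise_sd = syn$exchange_noise_sd, seed = seed)
      }
      fit <- fit_exchange(tc, n_boot = 200, seed = seed)
      report$stages$fit_exchange <- list(half_life_min = fit$half_life,
                                          rate_per_min = fit$rate_k,
                                          plateau = fit$plateau_Feq,
                                          half_life_se = fit$half_life_se)
    })
  }

  jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}
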