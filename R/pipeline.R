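CONFIG_DEFAULTS <- list(
  template = "cw7t_larg",
  n_images = 4L,
  seed = 1L,
  sigma = 0.05,
  grid_n_fs = 9L,
  grid_n_ksw = 9L,
  opt_grid_n_fs = 5L,
  opt_grid_n_ksw = 5L,
  n_hops = 5L,
  hop_stepsize = 0.25,
  temperature = 1.0,
  sqp_max_iter = 60L,
  sqp_ftol = 1e-6,
  phantom_size = 32L,
  concentrations_mM = c(25, 50, 100, 200),
  ksw_truth = c(250, 450, 650, 1050),
  out_dir = "stmrf-run"
)

#' Load and validate a pipeline configuration
#'
#' Reads a YAML (or JSON) run configuration, rejects unknown keys, validates
#' field values and materializes all defaults.
#'
#' @param path Path to a YAML/JSON file, or a named list.
#' @return Validated configuration list (class `stmrf_config`).
#' @export
load_config <- function(path) {
  raw <- if (is.list(path)) path else yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  unknown <- setdiff(names(raw), names(CONFIG_DEFAULTS))
  if (length(unknown) > 0)
    abort(paste("unknown config keys:", paste(unknown, collapse = ", ")))
  cfg <- utils::modifyList(CONFIG_DEFAULTS, raw)
  cfg$template <- match.arg(cfg$template, c("cw7t_larg", "pw3t_larg", "pw3t_mt"))
  check_pos <- function(field, min = 0) {
    v <- cfg[[field]]
    if (!is.numeric(v) || any(!is.finite(v)) || any(v <= min))
      abort(sprintf("config field '%s' must be numeric > %g", field, min))
  }
  for (f in c("n_images", "grid_n_fs", "grid_n_ksw", "opt_grid_n_fs",
              "opt_grid_n_ksw", "hop_stepsize", "temperature",
              "sqp_max_iter", "sqp_ftol", "concentrations_mM", "ksw_truth"))
    check_pos(f)
  if (cfg$sigma < 0) abort("config field 'sigma' must be >= 0")
  if (cfg$n_hops < 0) abort("config field 'n_hops' must be >= 0")
  if (cfg$phantom_size < 32) abort("config field 'phantom_size' must be >= 32")
  if (length(cfg$concentrations_mM) != length(cfg$ksw_truth))
    abort("concentrations_mM and ksw_truth must have equal length")
  structure(cfg, class = c("stmrf_config", "list"))
}

#' Save a configuration in canonical YAML form
#' @param config An `stmrf_config`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  yaml::write_yaml(config[order(names(config))], path, precision = 15)
  invisible(path)
}

config_hash <- function(config) {
  rlang::hash(config[order(names(config))])
}

#' Run the full design-and-evaluate pipeline
#'
#' Executes the three design blocks - dictionary generation, CRB evaluation,
#' schedule optimization - from a random initial schedule, then quantifies a
#' synthetic phantom acquired with both the initial and the optimized
#' schedule and reports the evaluation metrics. All artifacts (schedule YAML,
#' trace, dictionary and map CSVs, JSON report) are written under
#' `config$out_dir`, each stamped with the package version, config hash and
#' seed.
#'
#' @param config An `stmrf_config` (see [load_config()]).
#' @param quiet Suppress per-stage messages.
#' @return List with the optimization result, maps, metric report and the
#'   paths of all written artifacts.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "stmrf_config"))
  say <- function(...) if (!quiet) message(sprintf(...))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  stamp <- list(
    package_version = as.character(utils::packageVersion("stmrf")),
    config_hash = config_hash(config),
    seed = config$seed
  )

  tpl <- protocol_template(config$template, n_images = config$n_images)
  is_mt <- config$template == "pw3t_mt"
  opt_grid <- if (is_mt) {
    mt_grid(config$opt_grid_n_fs, config$opt_grid_n_ksw)
  } else {
    larg_grid(config$opt_grid_n_fs, config$opt_grid_n_ksw)
  }

  say("stage 1/4: random initialization + CRB optimization (seed %d)",
      config$seed)
  sch0 <- random_initial_schedule(tpl$schedule, tpl$bounds, seed = config$seed)
  opt_cfg <- optimizer_config(
    n_hops = config$n_hops, hop_stepsize = config$hop_stepsize,
    temperature = config$temperature, sqp_max_iter = config$sqp_max_iter,
    sqp_ftol = config$sqp_ftol, seed = config$seed + 10000L)
  opt <- optimize_schedule(tpl$pools, opt_grid, sch0, tpl$bounds,
                           crb = crb_config(), config = opt_cfg)
  say("  loss %.6g -> %.6g", opt$initial_loss, opt$best_loss)
  for (i in seq_len(nrow(opt$trace)))
    say("  iteration %d: loss %.6g%s", opt$trace$iteration[i],
        opt$trace$loss[i], if (opt$trace$accepted[i]) " (accepted)" else "")

  say("stage 2/4: quantification dictionary (%d x %d)",
      config$grid_n_fs, config$grid_n_ksw)
  if (is_mt) {
    quant_grid <- mt_grid(config$grid_n_fs, config$grid_n_ksw)
    phantom <- NULL
  } else {
    fs0 <- 3 * min(config$concentrations_mM) / 111e3
    quant_grid <- param_grid(
      fs_values = fs0 * seq_len(config$grid_n_fs + 4L),
      ksw_values = seq(50, 1450, length.out = config$grid_n_ksw)
    )
    phantom <- make_phantom("vial_grid", config$concentrations_mM,
                            config$ksw_truth, size = config$phantom_size,
                            pools = tpl$pools)
  }
  dict_init <- generate_dictionary(tpl$pools, quant_grid, opt$initial_schedule)
  dict_best <- generate_dictionary(tpl$pools, quant_grid, opt$best_schedule)

  report <- NULL
  maps <- NULL
  if (!is.null(phantom)) {
    say("stage 3/4: phantom acquisition + matching (sigma = %g)", config$sigma)
    img0 <- simulate_acquisition(phantom, opt$initial_schedule,
                                 sigma = config$sigma, seed = config$seed)
    img1 <- simulate_acquisition(phantom, opt$best_schedule,
                                 sigma = config$sigma, seed = config$seed + 1L)
    maps0 <- reconstruct_maps(img0, dict_init)
    maps <- reconstruct_maps(img1, dict_best)
    report <- dplyr::bind_rows(
      dplyr::mutate(metric_report(phantom, maps0), schedule = "initial"),
      dplyr::mutate(metric_report(phantom, maps), schedule = "optimized")
    )
  }

  say("stage 4/4: writing artifacts to %s", config$out_dir)
  paths <- list(
    config = file.path(config$out_dir, "config.yaml"),
    schedule_initial = file.path(config$out_dir, "schedule_initial.yaml"),
    schedule_best = file.path(config$out_dir, "schedule_optimized.yaml"),
    trace = file.path(config$out_dir, "trace.json"),
    dictionary = file.path(config$out_dir, "dictionary.csv"),
    report = file.path(config$out_dir, "report.json")
  )
  save_config(config, paths$config)
  write_schedule_yaml(opt$initial_schedule, paths$schedule_initial)
  write_schedule_yaml(opt$best_schedule, paths$schedule_best)
  jsonlite::write_json(
    c(stamp, list(
      initial_loss = opt$initial_loss, best_loss = opt$best_loss,
      trace = dplyr::select(opt$trace, "iteration", "loss", "accepted"))),
    paths$trace, auto_unbox = TRUE, digits = NA)
  write_dictionary_csv(dict_best, paths$dictionary)
  if (!is.null(maps)) {
    paths$maps <- file.path(config$out_dir, "maps.csv")
    write_maps_csv(maps, paths$maps)
  }
  jsonlite::write_json(
    c(stamp, list(report = report)),
    paths$report, auto_unbox = TRUE, digits = NA, na = "null")

  invisible(list(
    optimization = opt, dictionary = dict_best, maps = maps,
    report = report, paths = paths, stamp = stamp
  ))
}
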