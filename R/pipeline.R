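#' Assemble and validate a pipeline configuration
#'
#' Collects everything [run_pipeline()] needs into one validated record.
#' A configuration can also be loaded from a JSON file (the schema is the
#' argument list of this function, with `factors` given as a list of
#' `{name, low, high, unit}` records).
#'
#' @param design_csv path to a design CSV ([read_design()] schema); `NULL`
#'   to generate a fresh central composite design from `factors`.
#' @param responses_csv path to a responses CSV; `NULL` to simulate
#'   responses from the synthetic ground-truth generator (then `synthetic`
#'   applies).
#' @param factors list of [factor_spec()]s; required when `design_csv` is
#'   `NULL`, otherwise used to fix the bounds when reading.
#' @param alpha,n_center design parameters for a generated design.
#' @param transforms named modelling scales per response; default models
#'   particle size on the log10 scale.
#' @param lambda thin-plate smoothing parameter (0 = interpolation).
#' @param goals,weights,objective_method objective specification (see
#'   [objective_spec()]).
#' @param resolution dense-grid resolution of the one-shot optimization.
#' @param bootstrap_B integer vector of resample counts.
#' @param bootstrap_resolution grid resolution inside each resample.
#' @param seed master seed for simulation and bootstrap.
#' @param grid_resolution resolution of exported surface grids.
#' @param stability_threshold relative spread below which the bootstrap
#'   solution is flagged stable.
#' @param synthetic optional [synthetic_config()] overriding the default
#'   generator when simulating.
#' @param outdir output directory for [run_pipeline()].
#' @return a validated `pipeline_config`.
#' @export
pipeline_config <- function(design_csv = NULL, responses_csv = NULL,
                            factors = NULL, alpha = "rotatable",
                            n_center = 2L,
                            transforms = c(size_nm = "log10",
                                           pdi = "identity",
                                           le_pct = "identity"),
                            lambda = 0,
                            goals = c(size_nm = "minimize",
                                      pdi = "minimize",
                                      le_pct = "maximize"),
                            weights = 1, objective_method = "distance",
                            resolution = 201L,
                            bootstrap_B = c(1000L, 2000L, 3000L, 4000L,
                                            5000L),
                            bootstrap_resolution = 61L,
                            seed = 1L, grid_resolution = 50L,
                            stability_threshold = 0.01,
                            synthetic = NULL, outdir = tempfile("rsm_run_")) {
  if (!is.null(design_csv) && !file.exists(design_csv)) {
    stop("design file not found: ", design_csv, call. = FALSE)
  }
  if (!is.null(responses_csv) && !file.exists(responses_csv)) {
    stop("responses file not found: ", responses_csv, call. = FALSE)
  }
  if (is.null(design_csv) && is.null(factors)) {
    factors <- list(factor_spec("pressure_A", 400, 800),
                    factor_spec("pressure_B", 350, 750))
  }
  if (!is.null(factors)) factors <- .check_factors(factors)
  if (length(bootstrap_B) < 1L || any(bootstrap_B < 1)) {
    stop("'bootstrap_B' must be a non-empty vector of positive counts",
         call. = FALSE)
  }
  if (!is.null(synthetic)) stopifnot(inherits(synthetic, "synthetic_config"))
  cfg <- list(design_csv = design_csv, responses_csv = responses_csv,
              factors = factors, alpha = alpha, n_center = n_center,
              transforms = transforms, lambda = lambda, goals = goals,
              weights = weights, objective_method = objective_method,
              resolution = resolution,
              bootstrap_B = as.integer(sort(unique(bootstrap_B))),
              bootstrap_resolution = bootstrap_resolution,
              seed = seed, grid_resolution = grid_resolution,
              stability_threshold = stability_threshold,
              synthetic = synthetic, outdir = outdir)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Load a pipeline configuration from a JSON file
#'
#' @param path JSON file whose fields mirror [pipeline_config()]'s
#'   arguments.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path,
                               call. = FALSE)
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(raw$factors)) {
    raw$factors <- lapply(seq_len(nrow(as.data.frame(raw$factors))),
                          function(i) {
                            f <- as.data.frame(raw$factors)[i, ]
                            factor_spec(f$name, f$low, f$high,
                                        if (is.null(f$unit)) "hPa" else f$unit)
                          })
  }
  raw$transforms <- unlist(raw$transforms)
  raw$goals <- unlist(raw$goals)
  do.call(pipeline_config, raw)
}

# canonical JSON + 32-bit hash used to stamp every pipeline artifact;
# the output location is excluded so reruns elsewhere hash identically
config_hash <- function(cfg) {
  ser <- cfg
  ser$outdir <- NULL
  ser$synthetic <- if (is.null(cfg$synthetic)) NULL else unclass(cfg$synthetic)
  if (!is.null(ser$factors)) ser$factors <- lapply(ser$factors, unclass)
  if (!is.null(ser$synthetic) && !is.null(ser$synthetic$factors)) {
    ser$synthetic$factors <- lapply(ser$synthetic$factors, unclass)
  }
  .hash32(jsonlite::toJSON(ser, auto_unbox = TRUE, digits = NA,
                           null = "null", force = TRUE))
}

.pipeline_fail <- function(stage, e) {
  stop(errorCondition(
    sprintf("pipeline stage '%s' failed: %s", stage, conditionMessage(e)),
    stage = stage, class = c("pipeline_error", "error")))
}

#' Run the full optimization pipeline
#'
#' Executes the complete workflow: load (or generate) the design, load
#' (or simulate) the responses, fit one thin-plate-spline surface per
#' response, score each by leave-one-out cross-validation, locate the
#' multi-objective optimum, bootstrap it for every requested resample
#' count, and check stability across resample counts. Every artifact is
#' written to `cfg$outdir` stamped with a hash of the configuration, and
#' a rerun with the same configuration and seed reproduces all artifacts
#' byte-for-byte (the log file, which carries timestamps, is the one
#' exception).
#'
#' Artifacts: `design.csv`, `responses.csv`, `accuracy.csv`,
#' `loocv_predictions.csv`, `surface_<response>.json`,
#' `grid_<response>.csv`, `optimum.json`, `bootstrap.csv` (one row per B:
#' means and SDs of pressures, transformed responses and objective),
#' `stability.csv`, `manifest.json`, `log.txt`.
#'
#' @param cfg a [pipeline_config()] or path to its JSON form.
#' @return list with `design`, `responses`, `surfaces`, `accuracy`,
#'   `optimum`, `bootstrap` (list of summaries), `stability`, `truth`
#'   (when simulated), `hash`, and `outdir`.
#' @export
run_pipeline <- function(cfg) {
  if (is.character(cfg)) cfg <- read_pipeline_config(cfg)
  stopifnot(inherits(cfg, "pipeline_config"))
  hash <- config_hash(cfg)
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  logfile <- file.path(cfg$outdir, "log.txt")
  log_line <- function(stage, msg) {
    cat(sprintf("%s [%s] %s\n", format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                stage, msg), file = logfile, append = TRUE)
  }
  log_line("config", sprintf("hash=%s seed=%s", hash, format(cfg$seed)))

  # -- design ---------------------------------------------------------
  design <- tryCatch({
    if (is.null(cfg$design_csv)) {
      make_ccd(cfg$factors, alpha = cfg$alpha, n_center = cfg$n_center)
    } else {
      read_design(cfg$design_csv, factors = cfg$factors)
    }
  }, error = function(e) .pipeline_fail("design", e))
  log_line("design", sprintf("%d runs, %d factors", nrow(design),
                             length(attr(design, "factors"))))

  # -- responses ------------------------------------------------------
  resp_stage <- tryCatch({
    if (is.null(cfg$responses_csv)) {
      syn <- cfg$synthetic
      if (is.null(syn)) {
        syn <- synthetic_config(factors = attr(design, "factors"),
                                seed = cfg$seed)
      }
      sim <- generate_experiment(syn, design)
      list(responses = sim$responses, truth = sim$truth)
    } else {
      list(responses = read_responses(cfg$responses_csv, design = design),
           truth = NULL)
    }
  }, error = function(e) .pipeline_fail("responses", e))
  responses <- resp_stage$responses
  truth <- resp_stage$truth
  log_line("responses", sprintf("%d rows%s", nrow(responses),
                                if (is.null(truth)) "" else " (simulated)"))

  write_design(design, file.path(cfg$outdir, "design.csv"),
               comment = paste("config_hash:", hash))
  write_responses(responses, file.path(cfg$outdir, "responses.csv"),
                  comment = paste("config_hash:", hash))

  # -- fits and leave-one-out accuracy --------------------------------
  rnames <- names(cfg$goals)
  surfaces <- tryCatch({
    s <- lapply(rnames, function(nm) {
      fit_tps(design, responses[[nm]], lambda = cfg$lambda,
              transform = cfg$transforms[[nm]], response = nm)
    })
    stats::setNames(s, rnames)
  }, error = function(e) .pipeline_fail("fit", e))
  for (nm in rnames) {
    write_surface(surfaces[[nm]],
                  file.path(cfg$outdir, paste0("surface_", nm, ".json")),
                  extra = list(config_hash = hash))
    grid <- surface_grid(surfaces[[nm]], resolution = cfg$grid_resolution)
    .write_table_full(grid, file.path(cfg$outdir,
                                      paste0("grid_", nm, ".csv")),
                      comment = paste("config_hash:", hash))
  }
  log_line("fit", sprintf("%d surfaces (lambda=%g)", length(surfaces),
                          cfg$lambda))

  accuracy <- tryCatch({
    reports <- lapply(rnames, function(nm) {
      loocv_r(design, responses[[nm]], lambda = cfg$lambda,
              transform = cfg$transforms[[nm]], response = nm)
    })
    names(reports) <- rnames
    reports
  }, error = function(e) .pipeline_fail("loocv", e))
  acc_tab <- data.frame(response = rnames,
                        r = vapply(accuracy, `[[`, numeric(1), "r"))
  .write_table_full(acc_tab, file.path(cfg$outdir, "accuracy.csv"),
                    comment = paste("config_hash:", hash))
  loo_tab <- do.call(rbind, lapply(rnames, function(nm) {
    cbind(response = nm, accuracy[[nm]]$predictions)
  }))
  .write_table_full(loo_tab, file.path(cfg$outdir, "loocv_predictions.csv"),
                    comment = paste("config_hash:", hash))
  log_line("loocv", paste(sprintf("%s r=%.4f", acc_tab$response, acc_tab$r),
                          collapse = ", "))

  # -- optimization ---------------------------------------------------
  spec <- objective_spec(cfg$goals, cfg$weights,
                         method = cfg$objective_method)
  optimum <- tryCatch(
    find_optimum(surfaces, spec, resolution = cfg$resolution),
    error = function(e) .pipeline_fail("optimize", e))
  jsonlite::write_json(list(
    config_hash = hash,
    par = as.list(optimum$par),
    predicted_transformed = as.list(optimum$predicted),
    predicted_response = as.list(optimum$predicted_response),
    objective = optimum$objective
  ), file.path(cfg$outdir, "optimum.json"), auto_unbox = TRUE, digits = NA,
  pretty = TRUE)
  log_line("optimize", paste(sprintf("%s=%.4f", names(optimum$par),
                                     optimum$par), collapse = ", "))

  # -- bootstrap ------------------------------------------------------
  boots <- tryCatch({
    lapply(cfg$bootstrap_B, function(B) {
      bootstrap_optimum(design, responses, spec, B = B, seed = cfg$seed,
                        transforms = cfg$transforms, lambda = cfg$lambda,
                        resolution = cfg$bootstrap_resolution)
    })
  }, error = function(e) .pipeline_fail("bootstrap", e))
  names(boots) <- paste0("B", cfg$bootstrap_B)
  boot_tab <- do.call(rbind, lapply(boots, function(s) {
    row <- c(B = s$B, s$mean,
             stats::setNames(s$sd, paste0("sd_", names(s$sd))),
             n_redrawn = s$n_redrawn)
    as.data.frame(as.list(row))
  }))
  rownames(boot_tab) <- NULL
  .write_table_full(boot_tab, file.path(cfg$outdir, "bootstrap.csv"),
                    comment = paste("config_hash:", hash))
  log_line("bootstrap", sprintf("B in {%s}",
                                paste(cfg$bootstrap_B, collapse = ", ")))

  # -- stability ------------------------------------------------------
  stability <- if (length(boots) >= 2L) {
    tryCatch(bootstrap_stability(boots,
                                 threshold = cfg$stability_threshold),
             error = function(e) .pipeline_fail("stability", e))
  } else NULL
  if (!is.null(stability)) {
    .write_table_full(as.data.frame(stability),
                      file.path(cfg$outdir, "stability.csv"),
                      comment = paste("config_hash:", hash))
    log_line("stability",
             if (attr(stability, "stable")) "stable" else "not stable")
  }

  manifest <- list(
    config_hash = hash,
    seed = cfg$seed,
    files = sort(setdiff(list.files(cfg$outdir), "log.txt")))
  jsonlite::write_json(manifest, file.path(cfg$outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  list(design = design, responses = responses, surfaces = surfaces,
       accuracy = accuracy, optimum = optimum, bootstrap = boots,
       stability = stability, truth = truth, hash = hash,
       outdir = cfg$outdir)
}
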