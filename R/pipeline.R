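# Orchestration: one structured config drives synthetic-world generation,
# demand projection, suitability training, scenario allocation, habitat
# scoring and the cross-scenario summaries, writing every artifact plus a
# checksummed manifest so a run is re-derivable from its config and seeds.

#' Default pipeline configuration
#'
#' @param seed Master seed; stage seeds are small fixed offsets from it.
#' @param output_dir Where artifacts are written (`NULL` = keep in memory).
#' @return Nested configuration list.
#' @export
default_config <- function(seed = 42L, output_dir = NULL) {
  list(
    seed = as.integer(seed),
    output_dir = output_dir,
    synth = list(shape = c(120L, 120L), cell_size = 100, smoothness = 6,
                 class_prevalence = c(0.40, 0.22, 0.27, 0.02, 0.06, 0.03)),
    scenarios = c("natural", "cultivated_protection",
                  "ecological_protection"),
    steps = 3L,
    suitability = list(n_train = 3000L, hidden_units = 12L, epochs = 300L),
    ca = list(tol_frac = 0.002, max_iter = 300L),
    habitat = list(k = 0.5, beta = 1))
}

#' Read a pipeline configuration from YAML
#'
#' Scalars present in the file override [default_config]; everything else
#' keeps its default.
#'
#' @param path YAML file path.
#' @return Configuration list.
#' @export
read_run_config <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- default_config()
  merge_in <- function(base, upd) {
    for (nm in names(upd)) {
      base[[nm]] <- if (is.list(base[[nm]]) && is.list(upd[[nm]]))
        merge_in(base[[nm]], upd[[nm]]) else upd[[nm]]
    }
    base
  }
  merge_in(cfg, user)
}

#' Validate a pipeline configuration
#'
#' All checks run; problems are aggregated rather than thrown one at a
#' time.
#'
#' @param config Configuration list.
#' @return Data frame with columns `field` and `message` (zero rows when
#'   valid).
#' @export
validate_config <- function(config) {
  errs <- list()
  add <- function(field, msg) errs[[length(errs) + 1L]] <<-
    data.frame(field = field, message = msg)
  if (is.null(config$seed) || config$seed != as.integer(config$seed))
    add("seed", "seed must be an integer")
  sh <- config$synth$shape
  if (is.null(sh) || length(sh) != 2L || any(sh < 3))
    add("synth.shape", "shape must be two dimensions >= 3")
  pv <- config$synth$class_prevalence
  if (is.null(pv) || length(pv) != 6L || abs(sum(pv) - 1) > 1e-9)
    add("synth.class_prevalence", "six prevalences summing to 1 required")
  known <- c("natural", "cultivated_protection", "ecological_protection")
  bad <- setdiff(config$scenarios, known)
  if (length(bad) > 0L)
    add("scenarios", paste0("unknown scenario name(s): ",
                            paste(bad, collapse = ", ")))
  if (!is.null(config$steps) && config$steps < 1)
    add("steps", "steps must be >= 1")
  k <- config$habitat$k
  if (is.null(k) || !is.numeric(k) || k <= 0)
    add("habitat.k", "half-saturation k must be > 0")
  if (!is.null(config$ca$tol_frac) &&
      (config$ca$tol_frac <= 0 || config$ca$tol_frac >= 1))
    add("ca.tol_frac", "tol_frac must lie in (0, 1)")
  if (!is.null(config$suitability$hidden_units) &&
      config$suitability$hidden_units < 2)
    add("suitability.hidden_units", "hidden_units must be >= 2")
  if (length(errs) == 0L)
    data.frame(field = character(0), message = character(0))
  else do.call(rbind, errs)
}

#' Run the full simulation pipeline
#'
#' Synthetic world -> transition estimation -> per-scenario demand,
#' suitability, allocation and habitat scoring -> cross-scenario
#' comparison. With `output_dir` set, every raster (ESRI ASCII), table
#' (CSV) and a manifest (YAML with md5 checksums of every artifact) is
#' written; identical config and seed reproduce identical checksums.
#'
#' @param config Configuration list (see [default_config]); validated
#'   before any compute.
#' @return A run manifest (list): parameters, per-scenario results
#'   (`maps`, `habitat`, `mean_quality`), `comparison`, `checksums`.
#' @export
run_pipeline <- function(config = default_config()) {
  problems <- validate_config(config)
  if (nrow(problems) > 0L)
    stop("invalid config:\n", paste0("  - ", problems$field, ": ",
                                     problems$message, collapse = "\n"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  out <- config$output_dir
  if (!is.null(out)) dir.create(out, recursive = TRUE, showWarnings = FALSE)
  sc <- stage("synth", synth_config(
    shape = config$synth$shape, cell_size = config$synth$cell_size,
    seed = config$seed, smoothness = config$synth$smoothness,
    class_prevalence = config$synth$class_prevalence))
  world <- stage("synth", gen_world(sc))
  if (!is.null(out)) {                 # partial outputs retained on failure
    write_raster(world$lu_t0, file.path(out, "landuse_t0.asc"))
    write_raster(world$lu_t1, file.path(out, "landuse_t1.asc"))
  }
  transition <- stage("demand",
                      estimate_transition(world$lu_t0, world$lu_t1,
                                          period_years = 10L))
  if (!is.null(out))
    write_transition_csv(transition, file.path(out, "transition.csv"))
  surface <- stage("suitability", {
    train <- sample_training(world$lu_t1, world$drivers,
                             config$suitability$n_train,
                             seed = config$seed + 11L)
    model <- fit_suitability(train, config$suitability$hidden_units,
                             seed = config$seed + 12L,
                             epochs = config$suitability$epochs)
    predict_suitability(model, world$drivers)
  })
  cacfg <- ca_config(tol_frac = config$ca$tol_frac,
                     max_iter = config$ca$max_iter)
  results <- list()
  for (nm in config$scenarios) {
    spec <- builtin_scenario(nm)
    lu <- stage(paste0("allocate:", nm),
                simulate_landuse(world$lu_t1, world$drivers, spec,
                                 steps = config$steps, seed = config$seed,
                                 transition = transition, surface = surface,
                                 cfg = cacfg))
    hq <- stage(paste0("habitat:", nm),
                assess_habitat(lu, world$roads, k = config$habitat$k,
                               beta = config$habitat$beta))
    if (!is.null(out)) {
      write_raster(lu, file.path(out, paste0("landuse_2035_", nm, ".asc")))
      write_raster(hq$quality, file.path(out, paste0("quality_", nm, ".asc")))
    }
    results[[nm]] <- list(map = lu, habitat = hq,
                          mean_quality =
                            summarize_quality(hq$quality)$mean_quality)
  }
  base_hq <- stage("habitat:base",
                   assess_habitat(world$lu_t1, world$roads,
                                  k = config$habitat$k,
                                  beta = config$habitat$beta))
  comparison <- stage("changes",
                      compare_scenarios(world$lu_t1,
                                        lapply(results, `[[`, "map")))
  manifest <- list(
    config = config[setdiff(names(config), "output_dir")],
    transition = transition$probs,
    demand_base = as.list(class_counts(world$lu_t1)),
    mean_quality = c(base = summarize_quality(base_hq$quality)$mean_quality,
                     vapply(results, `[[`, 0, "mean_quality")),
    scenarios = results, comparison = comparison,
    world = world)
  if (!is.null(out)) {
    utils::write.csv(comparison, file.path(out, "scenario_comparison.csv"),
                     row.names = FALSE)
    files <- list.files(out, full.names = TRUE)
    files <- files[basename(files) != "manifest.yaml"]
    checksums <- tools::md5sum(files)
    names(checksums) <- basename(files)
    manifest$checksums <- as.list(checksums)
    yaml::write_yaml(list(seed = config$seed,
                          mean_quality = as.list(manifest$mean_quality),
                          checksums = manifest$checksums),
                     file.path(out, "manifest.yaml"))
  }
  invisible(manifest)
}
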