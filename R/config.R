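# Configuration files, run manifests and CSV emitters.

config_blocks <- c("morphometry", "gases", "blood", "mechanics", "solver",
                   "ventilation", "scenario", "output_dir", "seed")

#' Default run configuration
#'
#' The full configuration with every parameter at its reference value, as a
#' nested list matching the YAML schema read by [load_config()].
#'
#' @return named list of configuration blocks.
#' @export
default_config <- function() {
  list(
    morphometry = list(trachea_radius_m = 0.01, homothety_ratio = 0.7937,
                       conductive_generations = 17L, acinar_generations = 6L),
    gases = list(
      o2 = list(D_air = 0.2e-4, D_water = 3.3e-9, sigma_blood = 1.34e-3,
                henry = 2.592e-2, P_air_mmHg = 150),
      co2 = list(D_air = 0.14e-4, D_water = 2.505e-9, sigma_blood = 3.07e-2,
                 henry = 0.594, P_air_mmHg = 0.3)
    ),
    blood = list(Z0 = 9.93, v_s = 5e-4, pH = 7.4, pK = 6.09072, tau = 1e-6,
                 Pa_o2_mmHg = 40, Pa_co2_mmHg = 47, Pa_o2_eff_mmHg = 88),
    mechanics = list(R = 2e5, C = 5e-7),
    solver = list(nodes_per_branch = 10L, steps_per_cycle = 200L,
                  max_cycles = 50L, periodicity_tol = 1e-6),
    ventilation = list(amplitude_m_per_s = 1, period_s = 5),
    scenario = NULL,
    output_dir = "ventopt-output",
    seed = 1L
  )
}

#' Load and validate a run configuration
#'
#' Reads a YAML configuration, rejects unknown keys, checks ranges, and fills
#' every omitted field with its reference default.
#'
#' @param path path to a YAML file.
#' @return validated configuration list (class `ventopt_config`).
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("configuration file not found: ", path)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg)) cfg <- list()
  validate_config(cfg)
}

#' @rdname load_config
#' @param cfg a configuration list (possibly partial).
#' @export
validate_config <- function(cfg) {
  unknown <- setdiff(names(cfg), config_blocks)
  if (length(unknown))
    stop("unknown configuration block(s): ", paste(unknown, collapse = ", "))
  def <- default_config()
  merged <- utils::modifyList(def, cfg, keep.null = TRUE)
  for (block in c("morphometry", "blood", "mechanics", "solver",
                  "ventilation")) {
    extra <- setdiff(names(merged[[block]]), names(def[[block]]))
    if (length(extra))
      stop("unknown key(s) in block '", block, "': ",
           paste(extra, collapse = ", "))
  }
  for (g in c("o2", "co2")) {
    extra <- setdiff(names(merged$gases[[g]]), names(def$gases[[g]]))
    if (length(extra))
      stop("unknown key(s) in gases$", g, ": ", paste(extra, collapse = ", "))
  }
  mo <- merged$morphometry
  if (mo$homothety_ratio <= 0 || mo$homothety_ratio > 1)
    stop("morphometry$homothety_ratio must lie in (0, 1], got ",
         mo$homothety_ratio)
  if (mo$trachea_radius_m <= 0)
    stop("morphometry$trachea_radius_m must be positive")
  if (merged$ventilation$amplitude_m_per_s < 0 ||
      merged$ventilation$period_s <= 0)
    stop("ventilation amplitude must be >= 0 and period > 0")
  structure(merged, class = c("ventopt_config", "list"))
}

#' Build a lung model from a configuration
#'
#' @param cfg a validated configuration from [load_config()] or
#'   [default_config()].
#' @return a [lung_model()].
#' @export
config_to_model <- function(cfg) {
  if (!inherits(cfg, "ventopt_config")) cfg <- validate_config(cfg)
  mo <- cfg$morphometry
  tree <- airway_tree(mo$trachea_radius_m, mo$homothety_ratio,
                      mo$conductive_generations, mo$acinar_generations)
  g <- cfg$gases
  o2 <- gas_species("O2", g$o2$D_air, g$o2$D_water, g$o2$sigma_blood,
                    g$o2$henry, g$o2$P_air_mmHg)
  co2 <- gas_species("CO2", g$co2$D_air, g$co2$D_water, g$co2$sigma_blood,
                     g$co2$henry, g$co2$P_air_mmHg)
  b <- cfg$blood
  blood <- blood_params(Z0 = b$Z0, v_s = b$v_s, pH = b$pH, pK = b$pK,
                        tau = b$tau, Pa_o2 = b$Pa_o2_mmHg,
                        Pa_co2 = b$Pa_co2_mmHg,
                        Pa_o2_eff = b$Pa_o2_eff_mmHg)
  s <- cfg$solver
  solver <- solver_control(nodes_per_branch = s$nodes_per_branch,
                           steps_per_cycle = s$steps_per_cycle,
                           max_cycles = s$max_cycles,
                           periodicity_tol = s$periodicity_tol)
  lung_model(tree = tree, o2 = o2, co2 = co2, blood = blood,
             mechanics = mechanics_params(cfg$mechanics$R, cfg$mechanics$C),
             solver = solver)
}

#' Write result tables and a run manifest
#'
#' Writes each table as a CSV (fixed column order, units embedded in column
#' names, full-precision locale-independent numbers) and a JSON manifest with
#' the configuration snapshot, its hash, software version, timings and the
#' file inventory. Re-running the manifest's configuration reproduces the
#' files byte for byte (the core model is deterministic).
#'
#' @param tables named list of data frames.
#' @param cfg the configuration the tables were produced from.
#' @param outdir output directory (created if missing).
#' @param timings optional named numeric vector of per-stage timings (s).
#' @return invisibly, the manifest list.
#' @export
write_results <- function(tables, cfg, outdir, timings = NULL) {
  if (!is.list(tables) || is.null(names(tables)) || any(names(tables) == ""))
    stop("tables must be a named list of data frames")
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  for (nm in names(tables)) {
    path <- file.path(outdir, paste0(nm, ".csv"))
    utils::write.csv(format(tables[[nm]], digits = 15, scientific = TRUE,
                            trim = TRUE),
                     path, row.names = FALSE, quote = FALSE)
    files <- c(files, path)
  }
  cfg_json <- jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, digits = NA,
                               null = "null")
  tmp <- tempfile()
  writeLines(cfg_json, tmp)
  manifest <- list(
    config = unclass(cfg),
    config_md5 = unname(tools::md5sum(tmp)),
    package_version = as.character(utils::packageVersion("ventopt")),
    timings_s = as.list(timings),
    files = basename(files)
  )
  unlink(tmp)
  manifest_path <- file.path(outdir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(manifest)
}
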