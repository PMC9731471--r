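## Configuration files, figure-scenario fixtures and result writers.
##
## Configs are YAML documents with a `type` key ("ode", "gillespie" or
## "abm").  ABM scenario fixtures may additionally carry `figure`,
## `description`, `sweep_parameter` and `sweep_values` keys describing a
## one-parameter sweep over the base config.

ode_config_defaults <- list(
  valency = 1, k_on = 1e6, k_off = 1, alpha_plus = NULL, alpha_minus = NULL,
  ligand_total = 1e-6, receptor_total = 1e-6, ligand_excess = TRUE,
  grid_min = NULL, grid_max = NULL, grid_n = 61
)

gillespie_config_defaults <- list(
  valency = 1, k_on = 1e6, k_off = 1,
  ligand_total = 1e-6, receptor_total = 1e-6, ligand_excess = TRUE,
  n_receptors = 100, t_max = 10, replicates = 1000, seed = 1,
  volume = 1e-15, quantiles = c(0.05, 0.95)
)

abm_scenario_keys <- c("figure", "description", "sweep_parameter",
                       "sweep_values")

#' Load and validate a configuration file
#'
#' Reads a YAML config, applies defaults, normalises concentration units
#' (strings such as `"1 uM"` are accepted wherever a concentration is
#' expected) and validates every field; unknown keys are an error that names
#' the offending key.
#'
#' @param path path to a YAML config file.
#' @return for `type: abm`, an [abm_config()] (with any scenario sweep
#'   attached as attribute `"sweep"`); for `type: ode` / `type: gillespie`,
#'   a validated named list with class `ode_config` / `gillespie_config`.
#' @export
load_config <- function(path) {
  doc <- yaml::read_yaml(path)
  if (is.null(doc)) doc <- list()
  type <- doc$type %||% "abm"
  doc$type <- NULL
  switch(
    type,
    abm = load_abm_config(doc),
    ode = load_flat_config(doc, ode_config_defaults, "ode_config"),
    gillespie = load_flat_config(doc, gillespie_config_defaults,
                                 "gillespie_config"),
    stop("validation error: unknown config type '", type, "'")
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

load_flat_config <- function(doc, defaults, cls) {
  unknown <- setdiff(names(doc), names(defaults))
  if (length(unknown)) {
    stop("validation error: unknown key '", unknown[1], "'")
  }
  cfg <- utils::modifyList(defaults, doc)
  for (f in intersect(names(cfg),
                      c("ligand_total", "receptor_total", "grid_min",
                        "grid_max", "k_on", "k_off"))) {
    if (is.character(cfg[[f]])) cfg[[f]] <- parse_conc(cfg[[f]])
  }
  if (!is.null(cfg$valency) && !cfg$valency %in% c(1, 2, 4)) {
    stop("validation error: valency must be 1, 2 or 4")
  }
  structure(cfg, class = cls)
}

load_abm_config <- function(doc) {
  sweep <- doc[abm_scenario_keys]
  names(sweep) <- abm_scenario_keys
  doc <- doc[setdiff(names(doc), abm_scenario_keys)]
  allowed <- names(formals(abm_config))
  unknown <- setdiff(names(doc), allowed)
  if (length(unknown)) {
    stop("validation error: unknown key '", unknown[1], "'")
  }
  cfg <- do.call(abm_config, doc)
  if (!is.null(sweep$sweep_parameter)) {
    if (!sweep$sweep_parameter %in% allowed) {
      stop("validation error: unknown sweep_parameter '",
           sweep$sweep_parameter, "'")
    }
    attr(cfg, "sweep") <- sweep
  } else if (!is.null(sweep$figure)) {
    attr(cfg, "sweep") <- sweep[c("figure", "description")]
  }
  cfg
}

#' Save a configuration as YAML (round-trips through [load_config()])
#'
#' @param config an `abm_config`, `ode_config` or `gillespie_config`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  type <- if (inherits(config, "abm_config")) "abm"
  else if (inherits(config, "ode_config")) "ode"
  else if (inherits(config, "gillespie_config")) "gillespie"
  else stop("unsupported config class")
  doc <- unclass(config)
  sweep <- attr(config, "sweep", exact = TRUE)
  attr(doc, "sweep") <- NULL
  doc <- c(list(type = type), doc, sweep)
  doc <- doc[!vapply(doc, is.null, TRUE)]
  yaml::write_yaml(doc, path)
  invisible(path)
}

#' Built-in figure scenario configurations
#'
#' The simulation experiments of the clustering study as ready-made ABM
#' scenario configs, one per figure panel: receptor-number and
#' dimerisation-rate sweeps (fig5A-C), high-affinity crosslinker experiments
#' (fig6A-E), divalent-ligand experiments (fig7A-C) and the
#' moderate-affinity analogues of the crosslinker experiments (figS4A-E).
#' Sweep values follow the panel captions where printed (counts varied
#' 25-200); rate sweep values are fixture choices documented in each
#' description.
#'
#' @return a named list of [abm_config()] objects, each carrying a `"sweep"`
#'   attribute with `figure`, `description`, `sweep_parameter` and
#'   `sweep_values`.
#' @export
figure_scenarios <- function() {
  base <- function(...) abm_config(...)
  sweep <- function(cfg, figure, description, parameter = NULL,
                    values = NULL) {
    attr(cfg, "sweep") <- list(figure = figure, description = description,
                               sweep_parameter = parameter,
                               sweep_values = values)
    cfg
  }
  xl_off <- list(n_crosslinkers = 0L, n_ligands = 0L)
  high <- list(crosslinker_affinity = "high")
  scenarios <- list(
    fig5A = sweep(base(n_crosslinkers = 0, n_ligands = 0),
                  "fig5A", "receptor-number sweep, no ligand/crosslinker",
                  "n_receptors", c(25, 50, 100, 200)),
    fig5B = sweep(base(n_crosslinkers = 0, n_ligands = 0),
                  "fig5B", "dimerisation on-rate sweep (fixture values)",
                  "p_dim_on", c(0.00075, 0.0015, 0.003, 0.006, 0.012)),
    fig5C = sweep(base(n_crosslinkers = 0, n_ligands = 0),
                  "fig5C", "dimerisation off-rate sweep (fixture values)",
                  "p_dim_off", c(0.025, 0.05, 0.10, 0.20, 0.40)),
    fig6A = sweep(base(p_dim_on = 0, n_ligands = 0,
                       crosslinker_affinity = "high"),
                  "fig6A", "non-dimerising receptor, high-affinity crosslinker count sweep",
                  "n_crosslinkers", c(25, 50, 100, 200)),
    fig6B = sweep(base(n_ligands = 0, crosslinker_affinity = "high"),
                  "fig6B", "basal dimerisation, high-affinity crosslinker count sweep",
                  "n_crosslinkers", c(25, 50, 100, 200)),
    fig6C = sweep(base(n_ligands = 0, crosslinker_affinity = "high"),
                  "fig6C", "phosphorylation on-rate sweep, 100 high-affinity crosslinkers (highest value targets ~80% phosphorylation)",
                  "p_phos_on", c(0.01, 0.04, 0.09, 0.18, 0.36)),
    fig6D = sweep(base(n_ligands = 0, crosslinker_affinity = "high"),
                  "fig6D", "dimerisation on-rate sweep, 100 high-affinity crosslinkers (highest value targets ~75% dimerisation)",
                  "p_dim_on", c(0.003, 0.012, 0.05, 0.10, 0.19)),
    fig6E = sweep(base(n_ligands = 0, crosslinker_affinity = "high",
                       p_phos_on = 0.36, p_dim_on = 0.19),
                  "fig6E", "high phosphorylation + high dimerisation, high-affinity crosslinker count sweep",
                  "n_crosslinkers", c(25, 50, 100, 200)),
    fig7A = sweep(base(p_dim_on = 0, crosslinker_affinity = "moderate"),
                  "fig7A", "non-dimerising receptor + moderate crosslinker, divalent ligand sweep",
                  "n_ligands", c(25, 50, 100, 200)),
    fig7B = sweep(base(n_crosslinkers = 0),
                  "fig7B", "basal dimerisation, no crosslinker, divalent ligand sweep",
                  "n_ligands", c(25, 50, 100, 200)),
    fig7C = sweep(base(crosslinker_affinity = "moderate"),
                  "fig7C", "basal dimerisation (10%) + moderate crosslinker, divalent ligand sweep",
                  "n_ligands", c(25, 50, 100, 200))
  )
  moderate_analogue <- function(cfg, fig) {
    cfg$crosslinker_affinity <- "moderate"
    preset <- crosslinker_preset("moderate")
    cfg$p_xl_on <- unname(preset["p_on"])
    cfg$p_xl_off <- unname(preset["p_off"])
    sw <- attr(cfg, "sweep")
    sw$figure <- fig
    sw$description <- paste("moderate-affinity analogue:", sw$description)
    attr(cfg, "sweep") <- sw
    cfg
  }
  s4 <- Map(moderate_analogue,
            scenarios[c("fig6A", "fig6B", "fig6C", "fig6D", "fig6E")],
            c("figS4A", "figS4B", "figS4C", "figS4D", "figS4E"))
  names(s4) <- c("figS4A", "figS4B", "figS4C", "figS4D", "figS4E")
  c(scenarios, s4)
}

#' Write the figure scenario configs to a directory
#'
#' Emits one YAML file per [figure_scenarios()] entry (fig5A.yaml, ...),
#' each annotated with its figure label and sweep description.
#'
#' @param out_dir writable output directory (created if missing).
#' @return character vector of written file paths, invisibly.
#' @export
generate_fixtures <- function(out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  scenarios <- figure_scenarios()
  paths <- vapply(names(scenarios), function(nm) {
    p <- file.path(out_dir, paste0(nm, ".yaml"))
    save_config(scenarios[[nm]], p)
    p
  }, "")
  invisible(unname(paths))
}

#' Run manifest
#'
#' Provenance record written next to every result set: command, fully
#' resolved config, seed(s), package version, output files and wall time.
#'
#' @param command character label of the command that produced the results.
#' @param config the resolved config object.
#' @param seed seed(s) used.
#' @param files character vector of result files.
#' @param wall_time elapsed seconds.
#' @return a list of class `run_manifest`.
#' @export
run_manifest <- function(command, config, seed, files = character(),
                         wall_time = NA_real_) {
  structure(
    list(command = command,
         config = unclass(config),
         seed = seed,
         version = as.character(utils::packageVersion("receptorclust")),
         files = as.character(files),
         wall_time = wall_time),
    class = "run_manifest"
  )
}

#' Write result tables and their manifest
#'
#' Writes each table as a UTF-8, "."-decimal, LF-terminated TSV (one row per
#' grid/time point, one column per quantity; an empty table yields a
#' header-only file) and the manifest as a JSON sidecar referencing every
#' written file.  Identical inputs produce byte-identical files.
#'
#' @param tables named list of `data.frame`s.
#' @param manifest a [run_manifest()].
#' @param out_dir writable output directory (created if missing).
#' @return character vector of all written paths (tables, then manifest),
#'   invisibly.
#' @export
write_results <- function(tables, manifest, out_dir) {
  stopifnot(is.list(tables), !is.null(names(tables)),
            inherits(manifest, "run_manifest"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- vapply(names(tables), function(nm) {
    p <- file.path(out_dir, paste0(nm, ".tsv"))
    utils::write.table(tables[[nm]], p, sep = "\t", quote = FALSE,
                       row.names = FALSE, eol = "\n",
                       fileEncoding = "UTF-8")
    p
  }, "")
  manifest$files <- unname(paths)
  mpath <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(unclass(manifest), mpath, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  invisible(c(unname(paths), mpath))
}
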