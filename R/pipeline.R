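# Orchestration: run the assessment stages over a campaign (read or
# synthesised), writing every artifact with a checksummed manifest so a run
# is reproducible end to end from its seed.

#' Pipeline run configuration
#'
#' @param input Path to a campaign CSV, or `NULL` to synthesise one from
#'   `campaign` (a [campaign_config()]).
#' @param campaign A [campaign_config()] used when `input` is `NULL`.
#' @param authority Standards authority for the index stage.
#' @param cohorts Cohorts for the risk stage.
#' @param stages Subset of
#'   `c("simulate", "indices", "risk", "mc", "stats", "map")`.
#' @param mc_metal,mc_n_iter Monte Carlo settings.
#' @param map_index Column of the per-sample index table to interpolate
#'   (e.g. `"mpi"`, `"npi"`).
#' @param map_n_hidden,map_n_particles,map_n_iterations MLGI settings.
#' @param out_dir Output directory (created if missing).
#' @param seed Integer seed recorded in every output's provenance.
#' @return List of class `"run_config"`.
#' @export
run_config <- function(input = NULL, campaign = campaign_config(),
                       authority = "PNSDW", cohorts = c("adult", "child"),
                       stages = c("simulate", "indices", "risk", "mc",
                                  "stats", "map"),
                       mc_metal = "As", mc_n_iter = 10000L,
                       map_index = "mpi", map_n_hidden = 6L,
                       map_n_particles = 30L, map_n_iterations = 200L,
                       out_dir = tempfile("aquarisk_run_"), seed = 1L) {
  stages <- match.arg(stages, several.ok = TRUE)
  if (length(stages) == 0L) stop("at least one stage must be enabled", call. = FALSE)
  structure(list(
    input = input, campaign = campaign, authority = authority,
    cohorts = cohorts, stages = stages, mc_metal = mc_metal,
    mc_n_iter = mc_n_iter, map_index = map_index,
    map_n_hidden = map_n_hidden, map_n_particles = map_n_particles,
    map_n_iterations = map_n_iterations,
    out_dir = out_dir, seed = as.integer(seed)
  ), class = "run_config")
}

.provenance_header <- function(config) {
  c(paste0("# aquarisk ", as.character(utils::packageVersion("aquarisk"))),
    paste0("# seed: ", config$seed),
    paste0("# config_hash: ", .config_hash(config)))
}

.config_hash <- function(config) {
  # stable content hash of the configuration via its serialised text form;
  # the output directory is excluded so identical runs hash identically
  # wherever they land
  hashed <- config
  hashed$out_dir <- NULL
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(utils::capture.output(utils::str(hashed)), tmp)
  unname(tools::md5sum(tmp))
}

.write_with_provenance <- function(df, path, config) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(.provenance_header(config), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Read a CSV written with a provenance header
#'
#' @param path File written by the pipeline (comment lines prefixed `#`).
#' @return Data frame.
#' @export
read_pipeline_csv <- function(path) {
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Run the assessment pipeline
#'
#' Executes the enabled stages in order over the input (or synthetic)
#' campaign, writing each stage's artifacts under `config$out_dir` and
#' returning a manifest of every file with its MD5 checksum. A stage failure
#' is recorded in the manifest and independent later stages still run.
#'
#' @param config A [run_config()].
#' @return Data frame manifest: `stage, file, md5, status` (invisibly also
#'   written to `manifest.csv`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list()
  note <- function(stage, file, status = "ok") {
    manifest[[length(manifest) + 1L]] <<- data.frame(
      stage = stage, file = basename(file),
      md5 = if (file.exists(file)) unname(tools::md5sum(file)) else NA_character_,
      status = status, stringsAsFactors = FALSE)
  }
  run_stage <- function(stage, fun) {
    if (!stage %in% config$stages) return(invisible(NULL))
    tryCatch(fun(), error = function(e) {
      note(stage, file.path(config$out_dir, paste0(stage, ".failed")),
           status = paste0("error: ", conditionMessage(e)))
    })
  }
  out <- function(name) file.path(config$out_dir, name)

  # input: read, or synthesise (the simulate stage also persists the table)
  samples <- if (!is.null(config$input)) {
    read_campaign(config$input)
  } else {
    cc <- config$campaign
    cc$seed <- config$seed
    generate_campaign(cc)
  }

  run_stage("simulate", function() {
    f <- out("campaign.csv")
    write_campaign(samples, f)
    note("simulate", f); note("simulate", paste0(f, ".meta.json"))
  })
  run_stage("indices", function() {
    f <- out("indices.csv")
    .write_with_provenance(index_table(samples, config$authority), f, config)
    note("indices", f)
    g <- out("indices_by_group.csv")
    .write_with_provenance(group_indices(samples, authority = config$authority),
                           g, config)
    note("indices", g)
  })
  run_stage("risk", function() {
    for (co in config$cohorts) {
      f <- out(paste0("risk_", co, ".csv"))
      .write_with_provenance(risk_table(samples, co), f, config)
      note("risk", f)
    }
  })
  run_stage("mc", function() {
    specs <- fit_input_distributions(samples, config$mc_metal, config$cohorts[1])
    mc <- run_mc(specs, config$mc_metal, config$cohorts[1],
                 n_iter = config$mc_n_iter, seed = config$seed)
    f <- out("mc_report.json")
    write_mc_report(mc, f, histogram_path = out("mc_histogram.csv"))
    note("mc", f); note("mc", out("mc_histogram.csv"))
  })
  run_stage("stats", function() {
    f <- out("descriptives.csv")
    .write_with_provenance(describe(samples, by = "source_type"), f, config)
    note("stats", f)
    cm <- correlation_matrix(samples)
    g <- out("correlations.csv")
    .write_with_provenance(correlation_long(cm), g, config)
    note("stats", g)
    cl <- cluster_metals(samples)
    h <- out("linkage.csv")
    write_linkage(cl, h)
    note("stats", h)
  })
  run_stage("map", function() {
    idx <- index_table(samples, config$authority)
    sites <- data.frame(x = samples$x, y = samples$y,
                        value = idx[[config$map_index]])
    surf <- build_surface(sites, n_hidden = config$map_n_hidden,
                          n_particles = config$map_n_particles,
                          n_iterations = config$map_n_iterations,
                          seed = config$seed)
    f <- out("surface.csv")
    write_surface_csv(surf, f)
    note("map", f)
    g <- out("surface.geojson")
    write_surface_geojson(surf, g)
    note("map", g)
    h <- out("train_report.csv")
    .write_with_provenance(surf$report, h, config)
    note("map", h)
  })

  m <- do.call(rbind, manifest)
  utils::write.csv(m, file.path(config$out_dir, "manifest.csv"),
                   row.names = FALSE)
  m
}
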