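#' Default pipeline run configuration
#'
#' Paths may point at existing inputs; when `simulate = TRUE` (default) all
#' inputs are generated by the synthetic cohort generator first. Stage
#' parameter blocks mirror the stage functions' defaults.
#'
#' @param outdir output directory.
#' @param seed master seed.
#' @param simulate generate synthetic inputs (otherwise all input paths must
#'   exist).
#' @param ... overrides for any config field (alpha, ic50_max, r2_min,
#'   inhibition_min, p_max, min_impact, evidence_mode, specimen, sim --
#'   a [sim_config()] --, counts, groups, mutations, gmt, targets,
#'   dose_response).
#' @return a `run_config` list.
#' @export
run_config <- function(outdir = "osintegrate_out", seed = 1L,
                       simulate = TRUE, ...) {
  sim_from_partial <- NULL
  if (inherits(simulate, "sim_config")) {
    # guard against R partially matching `sim = ...` to the `simulate` formal
    sim_from_partial <- simulate
    simulate <- TRUE
  }
  cfg <- list(outdir = outdir, seed = as.integer(seed), simulate = simulate,
              alpha = 0.05, ic50_max = 1000, r2_min = 0.6,
              inhibition_min = 50, p_max = 0.05, min_impact = "moderate",
              evidence_mode = "union", specimen = NULL,
              sim = NULL, counts = NULL, groups = NULL, mutations = NULL,
              gmt = NULL, targets = NULL, dose_response = NULL)
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown))
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  if (!is.null(sim_from_partial) && is.null(cfg$sim))
    cfg$sim <- sim_from_partial
  structure(cfg, class = "run_config")
}

#' Load a run configuration from YAML or JSON
#'
#' @param path config file; `.yaml`/`.yml` (needs the yaml package) or
#'   `.json`.
#' @return a `run_config`.
#' @export
load_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("the 'yaml' package is required for YAML configs")
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  sim <- NULL
  if (!is.null(raw$sim)) {
    sim <- do.call(sim_config, raw$sim)
    raw$sim <- NULL
  }
  cfg <- do.call(run_config, raw)
  cfg$sim <- sim
  cfg
}

pipeline_log <- function(stage, ...) {
  message(sprintf("[osintegrate] %s: %s", stage, sprintf(...)))
}

#' Run the full integration pipeline
#'
#' Stages run in order simulate (optional) -> differential expression ->
#' mutation aggregation and set algebra -> drug screen (fits, efficacy,
#' target deconvolution) -> pathway integration. Every output is written
#' under `config$outdir` together with a `manifest.json` recording input
#' hashes, parameters, the seed and per-stage record counts. The first
#' failing stage aborts with its error.
#'
#' @param config a [run_config()] or a path accepted by
#'   [load_run_config()].
#' @return (invisibly) list with `status = 0`, the manifest, and the main
#'   in-memory results (de, sets, efficacy, target_scores, ranked).
#' @export
run_pipeline <- function(config = run_config()) {
  if (is.character(config)) config <- load_run_config(config)
  stopifnot(inherits(config, "run_config"))
  outdir <- config$outdir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package_version = as.character(packageVersion("osintegrate")),
                   seed = config$seed,
                   parameters = config[c("alpha", "ic50_max", "r2_min",
                                         "inhibition_min", "p_max",
                                         "min_impact", "evidence_mode")],
                   inputs = list(), stages = list(), outputs = character(0))
  emit <- function(name) {
    manifest$outputs <<- c(manifest$outputs, name)
    file.path(outdir, name)
  }

  # -- stage 1: inputs ------------------------------------------------------
  if (isTRUE(config$simulate)) {
    sim <- config$sim
    if (is.null(sim)) sim <- sim_config(seed = config$seed)
    cohort <- simulate_cohort(sim)
    m <- cohort$counts
    muts_tab <- cohort$mutations
    pw <- cohort$pathways
    tm <- cohort$targets
    dr <- cohort$dose_response
    write_counts(m, emit("counts.tsv"))
    write_groups(m, emit("groups.tsv"))
    write_mutations(muts_tab, emit("mutations.tsv"))
    write_gmt(pw, emit("pathways.gmt"))
    write_target_matrix(tm, emit("targets.tsv"))
    write_dose_response(dr, emit("dose_response.csv"))
    write_truth(cohort$truth, emit("truth.json"))
    manifest$stages$simulate <- list(n_genes = nrow(m$counts),
                                     n_samples = ncol(m$counts),
                                     n_variants = nrow(muts_tab),
                                     n_pathways = length(pw$sets),
                                     n_compounds = nrow(tm))
    pipeline_log("simulate", "%d genes, %d variants, %d pathways, %d compounds",
                 nrow(m$counts), nrow(muts_tab), length(pw$sets), nrow(tm))
  } else {
    for (f in c("counts", "groups", "mutations", "gmt", "targets",
                "dose_response")) {
      if (is.null(config[[f]]) || !file.exists(config[[f]]))
        stop("required input missing: ", f, " (",
             if (is.null(config[[f]])) "unset" else config[[f]], ")")
      manifest$inputs[[f]] <- list(path = config[[f]],
                                   md5 = unname(tools::md5sum(config[[f]])))
    }
    m <- read_counts(config$counts, config$groups)
    muts_tab <- read_mutations(config$mutations)
    pw <- read_gmt(config$gmt)
    tm <- read_target_matrix(config$targets)
    dr <- read_dose_response(config$dose_response)
  }

  # -- stage 2: differential expression ------------------------------------
  d <- estimate_dispersion(m)
  de <- call_de(exact_test(m, d, "common"), exact_test(m, d, "tagwise"),
                alpha = config$alpha)
  write.table(de, emit("de_results.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  manifest$stages$de <- list(n_genes = nrow(de),
                             n_significant = sum(de$significant),
                             mode = de$mode_used[1],
                             common_dispersion = d$common)
  pipeline_log("de", "%d/%d significant (%s)", sum(de$significant),
               nrow(de), de$mode_used[1])

  # -- stage 3: mutations --------------------------------------------------
  gm <- aggregate_mutations(muts_tab)
  phen <- setNames(as.character(m$groups), colnames(m$counts))
  phen[!phen %in% c("aggressive", "curable")] <- "curable"
  sets <- phenotype_sets(gm, phen, min_impact = "modifier")
  write.table(as.data.frame(unclass(gm)), emit("gene_mutation_matrix.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  venn <- data.frame(region = names(sets$region_counts),
                     n_genes = as.integer(sets$region_counts),
                     stringsAsFactors = FALSE)
  write.table(venn, emit("venn_regions.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  fam <- family_clusters(sets$all_mutated)
  write.table(fam, emit("family_clusters.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  manifest$stages$mutations <- list(n_mutated_genes = length(sets$all_mutated),
                                    n_aggressive_only =
                                      length(sets$aggressive_only))
  pipeline_log("mutations", "%d mutated genes, %d aggressive-only",
               length(sets$all_mutated), length(sets$aggressive_only))

  # -- stage 4: drug screen ------------------------------------------------
  eff <- screen_efficacy(dr, ic50_max = config$ic50_max,
                         r2_min = config$r2_min)
  write_fits(eff, emit("fits.tsv"))
  ts <- target_deconvolution(eff, tm, inhibition_min = config$inhibition_min)
  write.table(ts, emit("target_scores.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  manifest$stages$screen <- list(n_compounds = length(unique(eff$compound)),
                                 n_effective = sum(eff$effective),
                                 top_target = if (nrow(ts)) ts$kinase[1]
                                 else NA_character_)
  pipeline_log("screen", "%d effective compounds of %d; top target %s",
               sum(eff$effective), length(unique(eff$compound)),
               if (nrow(ts)) ts$kinase[1] else "<none>")

  # -- stage 5: pathway integration ----------------------------------------
  specimen <- config$specimen
  if (is.null(specimen)) {
    agg <- names(phen)[phen == "aggressive"]
    specimen <- if (length(agg)) agg[1] else names(phen)[1]
  }
  ev <- build_evidence(de, gm, ts, specimen,
                       min_impact = config$min_impact)
  enr <- enrich_pathways(ev, pw, evidence_mode = config$evidence_mode)
  ranked <- prioritize_pathways(enr, p_max = config$p_max)
  write.table(ranked, emit("pathways_ranked.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  ann <- lapply(ranked$pathway_id, function(id)
    annotate_nodes(pw$sets[[id]], ev, gm))
  names(ann) <- ranked$pathway_id
  jsonlite::write_json(ann, emit("node_annotations.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  manifest$stages$integrate <- list(specimen = specimen,
                                    n_pathways_tested = nrow(enr),
                                    n_prioritized = nrow(ranked),
                                    top_pathway = if (nrow(ranked))
                                      ranked$pathway_id[1] else NA_character_)
  pipeline_log("integrate", "%d pathways tested, %d prioritized; top: %s",
               nrow(enr), nrow(ranked),
               if (nrow(ranked)) ranked$pathway_id[1] else "<none>")

  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(status = 0L, manifest = manifest, de = de, sets = sets,
                 efficacy = eff, target_scores = ts, ranked = ranked,
                 evidence = ev))
}

#' Command-line entry point
#'
#' Implements `osintegrate simulate|de|mutations|screen|integrate|all`
#' (see `exec/osintegrate`). `all` runs [run_pipeline()]; the single-stage
#' subcommands run the same pipeline but are thin wrappers kept for script
#' compatibility.
#'
#' @param args character vector of command-line arguments.
#' @return exit status (0 on success), invisibly.
#' @export
cli_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: osintegrate <simulate|de|mutations|screen|integrate|all>",
    "[--config cfg.yaml] [--outdir DIR] [--seed N]")
  if (length(args) == 0 || args[1] %in% c("-h", "--help")) {
    message(usage)
    return(invisible(0L))
  }
  if (args[1] == "--version") {
    message("osintegrate ", packageVersion("osintegrate"))
    return(invisible(0L))
  }
  cmd <- args[1]
  rest <- args[-1]
  getopt <- function(flag, default = NULL) {
    i <- which(rest == flag)
    if (length(i) == 1 && i < length(rest)) rest[i + 1] else default
  }
  status <- tryCatch({
    cfgpath <- getopt("--config")
    cfg <- if (!is.null(cfgpath)) load_run_config(cfgpath) else run_config()
    outdir <- getopt("--outdir")
    if (!is.null(outdir)) cfg$outdir <- outdir
    seed <- getopt("--seed")
    if (!is.null(seed)) cfg$seed <- as.integer(seed)
    if (!cmd %in% c("simulate", "de", "mutations", "screen", "integrate",
                    "all"))
      stop("unknown subcommand '", cmd, "'\n", usage)
    run_pipeline(cfg)
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(status)
}
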