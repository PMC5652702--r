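#' Simulation configuration
#'
#' Bundles every tunable of the synthetic cohort generator. Defaults describe
#' a small two-arm cohort with RNA-seq-like negative-binomial counts
#' (variance = mu + phi * mu^2), a background somatic mutation load with the
#' four SnpEff-style impact classes, a pathway collection containing one
#' spiked "driver" pathway, and a kinase-inhibitor panel screened at four
#' log-spaced concentrations in triplicate.
#'
#' @param n_genes number of genes in the simulated universe.
#' @param n_samples_per_group samples (= specimens) per phenotype arm.
#' @param baseline_mean expected count per gene at nominal library size.
#' @param dispersion NB dispersion phi (variance = mu + phi mu^2); 0 gives
#'   Poisson counts.
#' @param de_fraction fraction of genes truly differentially expressed.
#' @param de_log2fc absolute log2 fold change applied to true-DE genes in the
#'   aggressive arm (half up, half down).
#' @param libsize_range uniform range of per-sample library-size factors
#'   relative to nominal.
#' @param n_pathways total number of pathways emitted, including the driver
#'   pathway (so `n_pathways - 1` decoys).
#' @param pathway_size_range integer range of decoy pathway sizes.
#' @param driver_pathway_size number of genes in the driver pathway.
#' @param driver_enrichment_fraction fraction (>= 0.6 recommended) of
#'   non-kinase driver-pathway slots filled with true-DE or driver-mutated
#'   genes.
#' @param n_driver_mutated number of driver genes receiving high/moderate
#'   mutations in every aggressive specimen.
#' @param background_mutations expected background variants per specimen
#'   (Poisson), spread uniformly over the gene universe.
#' @param impact_prior categorical prior over impact classes for background
#'   variants, in the order high, moderate, low, modifier.
#' @param n_compounds,n_kinases size of the inhibitor panel and of the kinase
#'   space (kinases are genes of the simulated universe).
#' @param effective_fraction fraction of compounds that are truly effective
#'   (IC50 below 1000 nM); all of them inhibit the driver kinase.
#' @param cv_noise coefficient of variation of multiplicative Gaussian
#'   viability noise.
#' @param concentrations_nM tested concentrations (nM); at least 2 distinct.
#' @param n_replicates replicates per concentration.
#' @param seed integer master seed; every generator derives its own child
#'   seed from it, so stages are independently reproducible.
#'
#' @return object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_genes = 2000L,
                       n_samples_per_group = 5L,
                       baseline_mean = 100,
                       dispersion = 0.2,
                       de_fraction = 0.05,
                       de_log2fc = 2,
                       libsize_range = c(0.5, 1.5),
                       n_pathways = 51L,
                       pathway_size_range = c(10L, 40L),
                       driver_pathway_size = 20L,
                       driver_enrichment_fraction = 0.8,
                       n_driver_mutated = 20L,
                       background_mutations = 50,
                       impact_prior = c(high = 0.02, moderate = 0.18,
                                        low = 0.30, modifier = 0.50),
                       n_compounds = 50L,
                       n_kinases = 30L,
                       effective_fraction = 0.1,
                       cv_noise = 0.05,
                       concentrations_nM = c(1, 10, 100, 1000),
                       n_replicates = 3L,
                       seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes),
              n_samples_per_group = as.integer(n_samples_per_group),
              baseline_mean = baseline_mean,
              dispersion = dispersion,
              de_fraction = de_fraction,
              de_log2fc = de_log2fc,
              libsize_range = libsize_range,
              n_pathways = as.integer(n_pathways),
              pathway_size_range = as.integer(pathway_size_range),
              driver_pathway_size = as.integer(driver_pathway_size),
              driver_enrichment_fraction = driver_enrichment_fraction,
              n_driver_mutated = as.integer(n_driver_mutated),
              background_mutations = background_mutations,
              impact_prior = impact_prior,
              n_compounds = as.integer(n_compounds),
              n_kinases = as.integer(n_kinases),
              effective_fraction = effective_fraction,
              cv_noise = cv_noise,
              concentrations_nM = concentrations_nM,
              n_replicates = as.integer(n_replicates),
              seed = as.integer(seed))

  counts <- c("n_genes", "n_samples_per_group", "n_pathways",
              "driver_pathway_size", "n_compounds", "n_kinases",
              "n_replicates")
  for (f in counts) {
    if (length(cfg[[f]]) != 1L || is.na(cfg[[f]]) || cfg[[f]] < 1L)
      stop("'", f, "' must be a count >= 1")
  }
  props <- c("de_fraction", "effective_fraction", "cv_noise",
             "driver_enrichment_fraction")
  for (f in props) {
    if (!is.finite(cfg[[f]]) || cfg[[f]] < 0 || cfg[[f]] > 1)
      stop("'", f, "' must be a proportion in [0, 1]")
  }
  if (!is.finite(cfg$dispersion) || cfg$dispersion < 0)
    stop("'dispersion' must be a finite non-negative real")
  if (!is.finite(cfg$baseline_mean) || cfg$baseline_mean <= 0)
    stop("'baseline_mean' must be a finite positive real")
  if (!is.finite(cfg$de_log2fc))
    stop("'de_log2fc' must be finite")
  if (length(cfg$pathway_size_range) != 2L ||
      any(cfg$pathway_size_range < 1L) ||
      cfg$pathway_size_range[1] > cfg$pathway_size_range[2])
    stop("'pathway_size_range' must be an increasing integer interval")
  if (length(cfg$concentrations_nM) < 2L ||
      length(unique(cfg$concentrations_nM)) < 2L)
    stop("at least 2 distinct concentrations are required")
  if (any(cfg$concentrations_nM <= 0))
    stop("concentrations must be positive")
  if (abs(sum(cfg$impact_prior) - 1) > 1e-8 || any(cfg$impact_prior < 0))
    stop("'impact_prior' must be a probability vector over the 4 classes")
  if (!setequal(names(cfg$impact_prior), IMPACT_LEVELS))
    stop("'impact_prior' must be named high, moderate, low, modifier")
  if (is.na(cfg$seed)) stop("'seed' must be an integer")
  structure(cfg, class = "sim_config")
}

# deterministic child seed per stage, < 2^31
stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 48271 + h * 2654435) %% (2^31 - 1))
}

#' Simulate a two-arm RNA-seq count matrix with ground truth
#'
#' Counts are negative binomial with variance `mu + phi mu^2`; a fixed
#' fraction of genes receives a +/- `de_log2fc` group effect in the
#' aggressive arm. Library sizes vary uniformly within `libsize_range`.
#' The returned ground truth also pre-registers the driver-gene sets used by
#' the downstream generators (driver-mutated genes, the driver kinase and the
#' driver pathway id), so each generator stays independently reproducible.
#'
#' @param config a [sim_config()].
#' @return list with elements `counts` (a [count_matrix()]) and `truth`
#'   (class `ground_truth`: `de_genes` named by gene with signed log2 fold
#'   changes, `mutated_driver_genes`, `driver_pathway_id`, `driver_kinase`,
#'   `effective_compounds` -- filled by [simulate_drug_panel()]).
#' @export
simulate_counts <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(stage_seed(config$seed, "counts"))
  G <- config$n_genes
  S <- config$n_samples_per_group
  genes <- sprintf("g%05d", seq_len(G))
  samples <- c(sprintf("AGG%02d", seq_len(S)), sprintf("CUR%02d", seq_len(S)))
  groups <- rep(c("aggressive", "curable"), each = S)

  n_de <- round(config$de_fraction * G)
  de_idx <- if (n_de > 0) sort(sample.int(G, n_de)) else integer(0)
  sign_vec <- rep_len(c(1, -1), n_de)
  lfc <- numeric(G)
  lfc[de_idx] <- sign_vec * config$de_log2fc

  lib_factor <- runif(2L * S, config$libsize_range[1], config$libsize_range[2])
  mu <- outer(config$baseline_mean * 2^(lfc * 0), lib_factor) # G x 2S baseline
  agg_cols <- which(groups == "aggressive")
  mu[, agg_cols] <- mu[, agg_cols] * 2^lfc

  counts <- matrix(0L, G, 2L * S, dimnames = list(genes, samples))
  if (config$dispersion > 0) {
    counts[] <- rnbinom(length(mu), mu = mu, size = 1 / config$dispersion)
  } else {
    counts[] <- rpois(length(mu), lambda = mu)
  }
  storage.mode(counts) <- "integer"

  # driver-gene bookkeeping for the downstream generators
  n_drv <- min(config$n_driver_mutated, G)
  driver_mut <- sort(sample(genes, n_drv))
  taken <- union(genes[de_idx], driver_mut)
  free <- setdiff(genes, taken)
  driver_kinase <- if (length(free)) free[[1]] else genes[[G]]

  truth <- structure(list(
    de_genes = setNames(lfc[de_idx], genes[de_idx]),
    mutated_driver_genes = driver_mut,
    driver_pathway_id = "DRIVER",
    driver_kinase = driver_kinase,
    effective_compounds = character(0),
    gene_universe = genes,
    specimens = setNames(groups, samples)
  ), class = "ground_truth")

  list(counts = count_matrix(counts, groups), truth = truth)
}

#' Simulate an impact-annotated somatic mutation table
#'
#' Every specimen receives a Poisson number of background variants placed
#' uniformly over the gene universe (a gene may be hit more than once), with
#' impact classes drawn from `config$impact_prior`. Each driver gene
#' additionally receives one high- or moderate-impact variant in every
#' aggressive specimen.
#'
#' @param config a [sim_config()].
#' @param truth ground truth from [simulate_counts()].
#' @return data.frame with columns specimen, gene, variant_id, impact.
#' @export
simulate_mutations <- function(config, truth) {
  stopifnot(inherits(config, "sim_config"), inherits(truth, "ground_truth"))
  set.seed(stage_seed(config$seed, "mutations"))
  genes <- truth$gene_universe
  specimens <- names(truth$specimens)
  rows <- vector("list", length(specimens) + 1L)
  prior <- config$impact_prior[IMPACT_LEVELS]
  for (i in seq_along(specimens)) {
    n_bg <- rpois(1L, config$background_mutations)
    if (n_bg > 0) {
      rows[[i]] <- data.frame(
        specimen = specimens[i],
        gene = sample(genes, n_bg, replace = TRUE),
        impact = sample(IMPACT_LEVELS, n_bg, replace = TRUE, prob = prior),
        stringsAsFactors = FALSE)
    }
  }
  agg <- specimens[truth$specimens == "aggressive"]
  drv <- truth$mutated_driver_genes
  if (length(agg) && length(drv)) {
    rows[[length(specimens) + 1L]] <- data.frame(
      specimen = rep(agg, each = length(drv)),
      gene = rep(drv, times = length(agg)),
      impact = sample(c("high", "moderate"), length(agg) * length(drv),
                      replace = TRUE, prob = c(0.3, 0.7)),
      stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(tab)) {
    tab <- data.frame(specimen = character(0), gene = character(0),
                      impact = character(0), stringsAsFactors = FALSE)
  }
  tab$variant_id <- sprintf("v%06d", seq_len(nrow(tab)))
  tab <- tab[, c("specimen", "gene", "variant_id", "impact")]
  rownames(tab) <- NULL
  tab
}

#' Simulate a pathway collection with a spiked driver pathway
#'
#' Decoy pathways sample genes uniformly without replacement. The driver
#' pathway reserves one slot for the driver kinase and fills
#' `driver_enrichment_fraction` of the remaining slots with true-DE and/or
#' driver-mutated genes, the rest with unrelated genes.
#'
#' @param config a [sim_config()].
#' @param truth ground truth from [simulate_counts()].
#' @return a [pathway_collection()].
#' @export
simulate_pathways <- function(config, truth) {
  stopifnot(inherits(config, "sim_config"), inherits(truth, "ground_truth"))
  set.seed(stage_seed(config$seed, "pathways"))
  genes <- truth$gene_universe
  if (max(config$pathway_size_range) > length(genes) ||
      config$driver_pathway_size > length(genes))
    stop("pathway size exceeds gene universe")

  n_decoy <- config$n_pathways - 1L
  sets <- list()
  if (n_decoy > 0) {
    sizes <- sample(seq(config$pathway_size_range[1],
                        config$pathway_size_range[2]), n_decoy, replace = TRUE)
    for (i in seq_len(n_decoy)) {
      sets[[sprintf("PW%03d", i)]] <- sample(genes, sizes[i])
    }
  }

  kin <- truth$driver_kinase
  pool <- setdiff(union(names(truth$de_genes), truth$mutated_driver_genes), kin)
  n_slots <- config$driver_pathway_size - 1L
  n_evid <- min(round(config$driver_enrichment_fraction * n_slots),
                length(pool))
  evid <- if (n_evid > 0) sample(pool, n_evid) else character(0)
  filler_pool <- setdiff(genes, c(pool, kin))
  filler <- if (n_slots - n_evid > 0) sample(filler_pool, n_slots - n_evid)
            else character(0)
  sets[[truth$driver_pathway_id]] <- c(kin, evid, filler)

  desc <- setNames(rep("decoy pathway", length(sets)), names(sets))
  desc[truth$driver_pathway_id] <- "spiked driver pathway"
  pathway_collection(sets, descriptions = desc, universe = genes)
}

#' Simulate a compound-target panel and dose-response screen
#'
#' Builds a compound x kinase graded inhibition matrix (percent inhibition,
#' 0-100) in which every effective compound strongly inhibits the driver
#' kinase, and generates CellTiterGlo-style viability measurements from a
#' four-parameter logistic curve with known IC50 (effective compounds:
#' IC50 in 10-500 nM; others: 10-100 uM) under multiplicative Gaussian noise.
#'
#' @param config a [sim_config()].
#' @param truth ground truth from [simulate_counts()].
#' @param culture culture label attached to the viability records.
#' @return list with `targets` (compound x kinase matrix), `dose_response`
#'   (long data.frame: compound, culture, concentration_nM, replicate,
#'   viability), `true_ic50` (named vector, nM) and the updated `truth`
#'   (with `effective_compounds` filled in).
#' @export
simulate_drug_panel <- function(config, truth, culture = "CULT1") {
  stopifnot(inherits(config, "sim_config"), inherits(truth, "ground_truth"))
  if (length(config$concentrations_nM) < 2L)
    stop("at least 2 distinct concentrations are required")
  set.seed(stage_seed(config$seed, "drugs"))
  genes <- truth$gene_universe
  compounds <- sprintf("CMP%03d", seq_len(config$n_compounds))
  kinases <- c(truth$driver_kinase,
               sample(setdiff(genes, truth$driver_kinase),
                      config$n_kinases - 1L))

  n_eff <- round(config$effective_fraction * config$n_compounds)
  effective <- sort(sample(compounds, n_eff))

  tm <- matrix(0, config$n_compounds, config$n_kinases,
               dimnames = list(compounds, kinases))
  for (cmp in compounds) {
    hit <- sample(kinases, min(3L, config$n_kinases))
    tm[cmp, hit] <- runif(length(hit), 0, 100)
  }
  tm[effective, truth$driver_kinase] <- runif(n_eff, 85, 100)

  ic50 <- numeric(config$n_compounds)
  names(ic50) <- compounds
  is_eff <- compounds %in% effective
  ic50[is_eff] <- 10^runif(sum(is_eff), 1, log10(500))
  ic50[!is_eff] <- 10^runif(sum(!is_eff), 4, 5)

  conc <- sort(config$concentrations_nM)
  grid <- expand.grid(replicate = seq_len(config$n_replicates),
                      concentration_nM = conc,
                      compound = compounds,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  v_true <- fourpl(grid$concentration_nM, top = 1, bottom = 0, hill = 1,
                   ic50 = ic50[grid$compound])
  noise <- if (config$cv_noise > 0)
    1 + rnorm(nrow(grid), 0, config$cv_noise) else 1
  dr <- data.frame(compound = grid$compound,
                   culture = culture,
                   concentration_nM = grid$concentration_nM,
                   replicate = grid$replicate,
                   viability = pmax(v_true * noise, 0),
                   stringsAsFactors = FALSE)

  truth$effective_compounds <- effective
  list(targets = tm, dose_response = dr, true_ic50 = ic50, truth = truth)
}

#' Simulate a full synthetic cohort
#'
#' Convenience wrapper running all four generators off one config.
#'
#' @param config a [sim_config()].
#' @return list with counts, mutations, pathways, targets, dose_response,
#'   true_ic50 and truth.
#' @export
simulate_cohort <- function(config) {
  cm <- simulate_counts(config)
  muts <- simulate_mutations(config, cm$truth)
  pw <- simulate_pathways(config, cm$truth)
  panel <- simulate_drug_panel(config, cm$truth)
  list(counts = cm$counts, mutations = muts, pathways = pw,
       targets = panel$targets, dose_response = panel$dose_response,
       true_ic50 = panel$true_ic50, truth = panel$truth)
}
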