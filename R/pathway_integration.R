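#' Construct a pathway collection
#'
#' @param sets named list of character gene vectors (duplicates within a set
#'   are removed).
#' @param descriptions optional named character vector of descriptions.
#' @param universe background gene universe; defaults to the union of all
#'   pathway genes. Pathway genes outside a supplied universe are an error.
#' @return object of class `pathway_collection`.
#' @export
pathway_collection <- function(sets, descriptions = NULL, universe = NULL) {
  if (length(sets) == 0) stop("empty pathway collection")
  if (is.null(names(sets)) || any(names(sets) == ""))
    stop("every pathway needs an id")
  sets <- lapply(sets, function(g) unique(as.character(g)))
  if (any(vapply(sets, length, integer(1)) == 0))
    stop("empty pathways are not allowed")
  if (is.null(universe)) universe <- sort(unique(unlist(sets)))
  extra <- setdiff(unlist(sets), universe)
  if (length(extra))
    stop("pathway genes outside the universe: ",
         paste(utils::head(extra, 5), collapse = ", "))
  if (is.null(descriptions))
    descriptions <- setNames(rep("", length(sets)), names(sets))
  structure(list(sets = sets,
                 descriptions = descriptions[names(sets)],
                 universe = universe),
            class = "pathway_collection")
}

#' @export
print.pathway_collection <- function(x, ...) {
  cat(sprintf("pathway_collection: %d pathways over %d universe genes\n",
              length(x$sets), length(x$universe)))
  invisible(x)
}

#' Assemble the per-specimen evidence set
#'
#' Collects, in one harmonized gene namespace: significant DE genes,
#' "aberrant" genes (fold change above 2, i.e. |log2FC| > 1, but not
#' significant -- annotation only), genes mutated at or above `min_impact`
#' in the specimen, and the kinase targets of compounds effective in vitro.
#'
#' @param de a [call_de()] result.
#' @param muts a [aggregate_mutations()] result.
#' @param targets a [target_deconvolution()] result (kinases hit by at least
#'   one effective compound become drug-target genes), or a character vector
#'   of target genes.
#' @param specimen specimen id for the mutation evidence.
#' @param min_impact least impact class counting as mutation evidence
#'   (default "moderate").
#' @param cnv optional named character vector gene -> "amplified" /
#'   "deleted" / "neutral".
#' @return object of class `evidence_set`.
#' @export
build_evidence <- function(de, muts, targets, specimen,
                           min_impact = "moderate", cnv = NULL) {
  stopifnot(inherits(de, "de_result"),
            inherits(muts, "gene_mutation_matrix"))
  de_genes <- de$gene[de$significant]
  aberrant <- de$gene[!de$significant & abs(de$log2_fold_change) > 1]
  if (!specimen %in% muts$specimen) {
    warning("specimen '", specimen, "' absent from the mutation matrix; ",
            "mutation evidence is empty")
    mutated <- character(0)
  } else {
    mutated <- mutated_genes_for(muts, specimen, min_impact)
  }
  drug_targets <- if (is.character(targets)) {
    unique(targets)
  } else if (inherits(targets, "target_score")) {
    targets$kinase[targets$n_effective_hitting >= 1]
  } else stop("'targets' must be a target_score table or a character vector")
  direction <- setNames(de$log2_fold_change, de$gene)
  structure(list(specimen = specimen,
                 de_genes = sort(unique(de_genes)),
                 aberrant_genes = sort(unique(aberrant)),
                 mutated_genes = mutated,
                 drug_target_genes = sort(unique(drug_targets)),
                 de_direction = direction,
                 min_impact = min_impact,
                 cnv = cnv),
            class = "evidence_set")
}

#' Hypergeometric pathway over-representation
#'
#' The tested evidence gene set is the union (default) or intersection of
#' significant-DE and mutated genes; aberrant genes never enter the test.
#' For each pathway the upper-tail hypergeometric p of the overlap `k` given
#' pathway size `K`, evidence size `n` and universe size `N` is computed
#' (`k = 0` gives p = 1). Results are sorted by p, then pathway size, then
#' id; druggability (at least one effective-drug target in the pathway) is
#' annotated but not filtered here -- see [prioritize_pathways()].
#'
#' @param ev a [build_evidence()] result.
#' @param pw a [pathway_collection()].
#' @param evidence_mode `"union"` (default) or `"intersection"` of mutated
#'   and DE evidence.
#' @param universe optional explicit background; defaults to the
#'   collection's universe.
#' @return data.frame of class `prioritized_pathways` with columns
#'   pathway_id, overlap_k, pathway_size_K, evidence_n, universe_N, p,
#'   druggable, n_drug_targets, drug_targets. Evidence genes outside the
#'   universe are dropped and reported in attribute `"dropped_evidence"`.
#' @export
enrich_pathways <- function(ev, pw, evidence_mode = c("union", "intersection"),
                            universe = NULL) {
  stopifnot(inherits(ev, "evidence_set"), inherits(pw, "pathway_collection"))
  evidence_mode <- match.arg(evidence_mode)
  if (is.null(universe)) universe <- pw$universe
  evidence <- if (evidence_mode == "union") {
    union(ev$de_genes, ev$mutated_genes)
  } else {
    intersect(ev$de_genes, ev$mutated_genes)
  }
  dropped <- setdiff(evidence, universe)
  evidence <- intersect(evidence, universe)
  N <- length(universe)
  n <- length(evidence)
  rows <- lapply(names(pw$sets), function(id) {
    genes <- intersect(pw$sets[[id]], universe)
    K <- length(genes)
    k <- length(intersect(genes, evidence))
    p <- if (k == 0) 1 else
      phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    dt <- intersect(genes, ev$drug_target_genes)
    data.frame(pathway_id = id, overlap_k = k, pathway_size_K = K,
               evidence_n = n, universe_N = N, p = min(p, 1),
               druggable = length(dt) >= 1, n_drug_targets = length(dt),
               drug_targets = paste(sort(dt), collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$p, out$pathway_size_K, out$pathway_id), ]
  rownames(out) <- NULL
  attr(out, "dropped_evidence") <- dropped
  class(out) <- c("prioritized_pathways", "data.frame")
  out
}

#' Filter and rank enriched pathways by the druggability rule
#'
#' Keeps pathways with unadjusted `p < p_max` (strict) that contain at least
#' one target of an effective drug, and assigns dense ranks in the existing
#' deterministic order (p, then pathway size, then id). A BH-adjusted column
#' is added for transparency but never used for filtering.
#'
#' @param results an [enrich_pathways()] result.
#' @param p_max unadjusted p-value cutoff (default 0.05).
#' @return filtered data.frame with a `rank` column; may be empty.
#' @export
prioritize_pathways <- function(results, p_max = 0.05) {
  stopifnot(inherits(results, "prioritized_pathways"))
  results$p_bh <- p.adjust(results$p, method = "BH")
  keep <- results$p < p_max & results$druggable
  out <- results[keep, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  class(out) <- c("prioritized_pathways", "data.frame")
  out
}

#' Annotate the genes of one pathway with per-gene evidence
#'
#' Categories follow the precedence drug_target > mutated > de_under /
#' de_over > aberrant > none; mutation multiplicity per impact class is
#' preserved and an optional copy-number direction is attached.
#'
#' @param pathway_genes character vector of the pathway's genes.
#' @param ev a [build_evidence()] result.
#' @param muts a [aggregate_mutations()] result (multiplicities for the
#'   evidence specimen).
#' @return data.frame: gene, category, n_high, n_moderate, n_low,
#'   n_modifier, cnv.
#' @export
annotate_nodes <- function(pathway_genes, ev, muts) {
  stopifnot(inherits(ev, "evidence_set"),
            inherits(muts, "gene_mutation_matrix"))
  genes <- unique(pathway_genes)
  category <- vapply(genes, function(g) {
    if (g %in% ev$drug_target_genes) "drug_target"
    else if (g %in% ev$mutated_genes) "mutated"
    else if (g %in% ev$de_genes) {
      if (!is.na(ev$de_direction[g]) && ev$de_direction[g] < 0) "de_under"
      else "de_over"
    }
    else if (g %in% ev$aberrant_genes) "aberrant"
    else "none"
  }, character(1))
  mm <- muts[muts$specimen == ev$specimen, , drop = FALSE]
  idx <- match(genes, mm$gene)
  getn <- function(col) ifelse(is.na(idx), 0L, mm[[col]][idx])
  cnv <- if (is.null(ev$cnv)) rep(NA_character_, length(genes)) else {
    out <- unname(ev$cnv[genes])
    out
  }
  data.frame(gene = genes, category = unname(category),
             n_high = getn("n_high"), n_moderate = getn("n_moderate"),
             n_low = getn("n_low"), n_modifier = getn("n_modifier"),
             cnv = cnv, stringsAsFactors = FALSE)
}
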