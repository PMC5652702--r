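#' Aggregate impact-annotated variants to gene level per specimen
#'
#' Each record is one variant (specimen, gene, variant_id, impact). A gene
#' may carry several variants of different impacts; counts are kept per
#' impact class and `max_impact` uses the severity ordering
#' high > moderate > low > modifier.
#'
#' @param records data.frame with columns specimen, gene, variant_id, impact.
#' @return data.frame of class `gene_mutation_matrix`: specimen, gene,
#'   n_high, n_moderate, n_low, n_modifier, n_total, max_impact.
#' @export
aggregate_mutations <- function(records) {
  need <- c("specimen", "gene", "variant_id", "impact")
  if (!all(need %in% names(records)))
    stop("records need columns: ", paste(need, collapse = ", "))
  if (nrow(records) == 0) {
    out <- data.frame(specimen = character(0), gene = character(0),
                      n_high = integer(0), n_moderate = integer(0),
                      n_low = integer(0), n_modifier = integer(0),
                      n_total = integer(0), max_impact = character(0),
                      stringsAsFactors = FALSE)
    class(out) <- c("gene_mutation_matrix", "data.frame")
    return(out)
  }
  bad <- which(!records$impact %in% IMPACT_LEVELS)
  if (length(bad))
    stop("unknown impact label '", records$impact[bad[1]],
         "' at row ", bad[1])
  dup <- duplicated(records[, c("specimen", "variant_id")])
  if (any(dup))
    stop("duplicate variant_id within a specimen at row ", which(dup)[1])

  key <- interaction(records$specimen, records$gene, drop = TRUE, sep = "\r")
  tab <- table(key, factor(records$impact, levels = IMPACT_LEVELS))
  parts <- do.call(rbind, strsplit(rownames(tab), "\r", fixed = TRUE))
  cnt <- matrix(as.integer(tab), nrow = nrow(tab),
                dimnames = list(NULL, colnames(tab)))
  max_imp <- IMPACT_LEVELS[apply(cnt > 0, 1, function(z) max(which(z)))]
  out <- data.frame(specimen = parts[, 1], gene = parts[, 2],
                    n_high = cnt[, "high"], n_moderate = cnt[, "moderate"],
                    n_low = cnt[, "low"], n_modifier = cnt[, "modifier"],
                    n_total = rowSums(cnt), max_impact = max_imp,
                    stringsAsFactors = FALSE)
  out <- out[order(out$specimen, out$gene), ]
  rownames(out) <- NULL
  class(out) <- c("gene_mutation_matrix", "data.frame")
  out
}

# genes with max_impact >= min_impact for one specimen
mutated_genes_for <- function(gm, specimen, min_impact = "modifier") {
  sel <- gm$specimen == specimen &
    impact_rank(gm$max_impact) >= impact_rank(min_impact)
  sort(unique(gm$gene[sel]))
}

#' Cross-specimen mutated-gene set algebra
#'
#' Filters genes to `max_impact >= min_impact`, then computes every Venn
#' region over specimens together with the phenotype-level sets. In
#' `"all"` membership mode (default) a gene belongs to a phenotype only when
#' mutated in every specimen of that phenotype; `"any"` requires one.
#' `aggressive_only` excludes genes mutated in any curable specimen;
#' `shared_all` contains genes mutated in all specimens (mode `"all"`) or in
#' both phenotypes (mode `"any"`).
#'
#' @param gm a [aggregate_mutations()] result.
#' @param phenotypes named character vector specimen -> "aggressive" /
#'   "curable".
#' @param min_impact least severe impact class that still counts as mutated
#'   (default "modifier", i.e. all classes).
#' @param mode membership mode within a phenotype: `"all"` or `"any"`.
#' @return object of class `set_partition`: `aggressive_only`,
#'   `curable_only`, `shared_all`, `regions` (named list of gene sets, one
#'   per non-empty specimen combination), `region_counts`, `mode`,
#'   `min_impact`, `all_mutated`.
#' @export
phenotype_sets <- function(gm, phenotypes, min_impact = "modifier",
                           mode = c("all", "any")) {
  stopifnot(inherits(gm, "gene_mutation_matrix"))
  mode <- match.arg(mode)
  impact_rank(min_impact)
  specimens <- names(phenotypes)
  if (is.null(specimens) || !all(unique(gm$specimen) %in% specimens))
    stop("every specimen in the matrix must be labeled in 'phenotypes'")
  if (!all(phenotypes %in% c("aggressive", "curable")))
    stop("phenotype labels must be 'aggressive' or 'curable'")
  for (ph in c("aggressive", "curable")) {
    if (!any(phenotypes == ph))
      warning("phenotype '", ph, "' has zero specimens; its regions are empty")
  }

  sets <- lapply(specimens,
                 function(sp) mutated_genes_for(gm, sp, min_impact))
  names(sets) <- specimens
  all_mut <- sort(unique(unlist(sets)))
  member <- vapply(sets, function(s) all_mut %in% s,
                   logical(length(all_mut)))
  if (length(all_mut) == 1L) member <- matrix(member, nrow = 1L,
                                              dimnames = list(NULL, specimens))
  if (length(all_mut) == 0L)
    member <- matrix(logical(0), 0, length(specimens),
                     dimnames = list(NULL, specimens))

  pattern <- apply(member, 1, function(z)
    paste(specimens[z], collapse = "&"))
  regions <- split(all_mut, pattern)
  region_counts <- vapply(regions, length, integer(1))

  agg_sp <- specimens[phenotypes == "aggressive"]
  cur_sp <- specimens[phenotypes == "curable"]
  in_pheno <- function(sp) {
    if (length(sp) == 0L) return(rep(FALSE, length(all_mut)))
    mm <- member[, sp, drop = FALSE]
    if (mode == "all") rowSums(mm) == length(sp) else rowSums(mm) > 0
  }
  in_any <- function(sp) {
    if (length(sp) == 0L) return(rep(FALSE, length(all_mut)))
    rowSums(member[, sp, drop = FALSE]) > 0
  }
  agg_only <- all_mut[in_pheno(agg_sp) & !in_any(cur_sp)]
  cur_only <- all_mut[in_pheno(cur_sp) & !in_any(agg_sp)]
  shared <- if (mode == "all") {
    all_mut[rowSums(member) == length(specimens)]
  } else {
    all_mut[in_any(agg_sp) & in_any(cur_sp)]
  }

  structure(list(aggressive_only = agg_only, curable_only = cur_only,
                 shared_all = shared, regions = regions,
                 region_counts = region_counts, mode = mode,
                 min_impact = min_impact, all_mutated = all_mut),
            class = "set_partition")
}

#' @export
print.set_partition <- function(x, ...) {
  cat(sprintf(paste0("set_partition (%s mode, impact >= %s): %d mutated ",
                     "genes, %d aggressive-only, %d shared by all\n"),
              x$mode, x$min_impact, length(x$all_mutated),
              length(x$aggressive_only), length(x$shared_all)))
  invisible(x)
}

#' Cluster a gene set into symbol families
#'
#' Without an explicit map, family names are derived by stripping a trailing
#' numeric suffix (optionally followed by one letter) from the symbol, so
#' NBPF10 -> NBPF, BAGE2 -> BAGE, TUBA4A -> TUBA. With a (possibly partial)
#' map, unmapped genes each form a singleton family of themselves.
#'
#' @param genes character vector of gene symbols.
#' @param family_map optional named character vector gene -> family.
#' @return data.frame (family, n, members) sorted by count descending, then
#'   family name.
#' @export
family_clusters <- function(genes, family_map = NULL) {
  genes <- unique(genes)
  if (length(genes) == 0)
    return(data.frame(family = character(0), n = integer(0),
                      members = character(0), stringsAsFactors = FALSE))
  if (is.null(family_map)) {
    fam <- sub("[0-9]+[A-Za-z]?$", "", genes)
    fam[fam == ""] <- genes[fam == ""]
  } else {
    fam <- unname(family_map[genes])
    fam[is.na(fam)] <- genes[is.na(fam)]
  }
  spl <- split(genes, fam)
  out <- data.frame(family = names(spl),
                    n = vapply(spl, length, integer(1)),
                    members = vapply(spl, function(m)
                      paste(sort(m), collapse = ","), character(1)),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$n, out$family), ]
  rownames(out) <- NULL
  out
}
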