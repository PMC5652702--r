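make_de <- function(genes, p, lfc, sig) {
  out <- data.frame(gene = genes, log2_fold_change = lfc,
                    p_common = p, p_tagwise = p, fdr_common = p,
                    fdr_tagwise = p, significant = sig,
                    mode_used = "dual_fdr", stringsAsFactors = FALSE)
  class(out) <- c("de_result", "data.frame")
  out
}

test_that("build_evidence separates significant, aberrant and mutated genes", {
  genes <- c("A", "B", "C", "D", "E")
  de <- make_de(genes, p = c(0.001, 0.2, 0.3, 0.5, 0.9),
                lfc = c(-2, 1.5, 0.3, 3, 0),
                sig = c(TRUE, FALSE, FALSE, FALSE, FALSE))
  muts <- aggregate_mutations(mut_records("SP1", c("C", "A"),
                                          c("moderate", "modifier")))
  ev <- build_evidence(de, muts, targets = "E", specimen = "SP1")
  expect_identical(ev$de_genes, "A")
  # |log2FC| > 1 and not significant -> aberrant (annotation only)
  expect_setequal(ev$aberrant_genes, c("B", "D"))
  # modifier-impact A is below the default min_impact = moderate
  expect_identical(ev$mutated_genes, "C")
  expect_identical(ev$drug_target_genes, "E")
  expect_length(intersect(ev$de_genes, ev$aberrant_genes), 0)

  # gene both mutated and DE enters the union evidence once
  muts2 <- aggregate_mutations(mut_records("SP1", "A", "high"))
  ev2 <- build_evidence(de, muts2, targets = character(0), specimen = "SP1")
  pw <- pathway_collection(list(P1 = genes), universe = genes)
  enr <- enrich_pathways(ev2, pw)
  expect_equal(enr$evidence_n, 1L)

  expect_warning(build_evidence(de, muts, targets = "E",
                                specimen = "MISSING"), "absent")
})

test_that("empty evidence gives p = 1 for every pathway", {
  genes <- sprintf("G%02d", 1:30)
  de <- make_de(genes, p = rep(0.9, 30), lfc = rep(0, 30),
                sig = rep(FALSE, 30))
  muts <- aggregate_mutations(mut_records(character(0), character(0),
                                          character(0)))
  ev <- suppressWarnings(build_evidence(de, muts, targets = character(0),
                                        specimen = "SP1"))
  pw <- pathway_collection(list(P1 = genes[1:5], P2 = genes[6:20]),
                           universe = genes)
  enr <- enrich_pathways(ev, pw)
  expect_true(all(enr$p == 1))
  expect_true(all(enr$overlap_k == 0))
})

test_that("enrichment p matches exhaustive enumeration", {
  # N = 20, K = 5, n = 5, k = 5 -> 1 / C(20,5)
  genes <- sprintf("G%02d", 1:20)
  ev <- fake_evidence(genes[1:5])
  pw <- pathway_collection(list(P = genes[1:5]), universe = genes)
  enr <- enrich_pathways(ev, pw)
  expect_equal(enr$p, 1 / choose(20, 5), tolerance = 1e-12)

  # random small configurations against the enumeration oracle
  set.seed(17)
  for (i in 1:20) {
    N <- sample(5:30, 1)
    uni <- sprintf("G%02d", seq_len(N))
    K <- sample(seq_len(N), 1)
    n <- sample(seq_len(N), 1)
    k <- sample(0:min(K, n), 1)
    if (n - k > N - K) next
    pwy <- uni[seq_len(K)]
    evd <- c(uni[seq_len(k)], if (n - k > 0) uni[K + seq_len(n - k)])
    enr <- enrich_pathways(fake_evidence(evd),
                           pathway_collection(list(P = pwy), universe = uni))
    expect_equal(enr$p, oracle_hyper_upper(N, K, n, k), tolerance = 1e-10,
                 label = sprintf("N=%d K=%d n=%d k=%d", N, K, n, k))
  }
})

test_that("enrichment p is monotone decreasing in the overlap", {
  uni <- sprintf("G%02d", 1:25)
  pwy <- uni[1:8]
  last <- 1.01
  for (k in 1:8) {
    evd <- c(uni[seq_len(k)], uni[8 + seq_len(8 - k)])
    enr <- enrich_pathways(fake_evidence(evd),
                           pathway_collection(list(P = pwy), universe = uni))
    expect_lt(enr$p, last)
    last <- enr$p
  }
})

test_that("prioritize applies the strict p cutoff and druggability filter", {
  uni <- sprintf("G%02d", 1:40)
  ev <- fake_evidence(uni[1:8], drug_targets = "G01")
  pw <- pathway_collection(list(
    BEST_NOT_DRUGGABLE = uni[5:8],          # full overlap, no drug target
    DRUGGABLE = c("G01", "G02", "G03", uni[20]),  # contains a drug target
    WEAK = uni[30:35]), universe = uni)
  enr <- enrich_pathways(ev, pw)
  ranked <- prioritize_pathways(enr)
  expect_identical(ranked$pathway_id, "DRUGGABLE")
  expect_identical(ranked$rank, 1L)
  expect_true(all(c("BEST_NOT_DRUGGABLE", "WEAK") %in% enr$pathway_id))
  expect_lt(enr$p[enr$pathway_id == "BEST_NOT_DRUGGABLE"],
            enr$p[enr$pathway_id == "DRUGGABLE"])

  # boundary: p exactly at p_max is excluded (strict inequality)
  fake <- enr
  fake$p[fake$pathway_id == "DRUGGABLE"] <- 0.05
  expect_equal(nrow(prioritize_pathways(fake, p_max = 0.05)), 0L)

  # filter/score separation: dropping druggability changes membership only
  all_kept <- prioritize_pathways(enr, p_max = 1.000001)
  expect_equal(
    enr$p[match(all_kept$pathway_id, enr$pathway_id)], all_kept$p)
})

test_that("node annotation applies category precedence and multiplicity", {
  genes <- c("DT", "MUT", "UP", "DOWN", "ABER", "NONE")
  de <- make_de(genes, p = c(0.001, 0.5, 0.001, 0.001, 0.2, 0.9),
                lfc = c(2, 0, 1.2, -1.2, 1.4, 0.1),
                sig = c(TRUE, FALSE, TRUE, TRUE, FALSE, FALSE))
  muts <- aggregate_mutations(
    mut_records("SP1", c(rep("MUT", 4), "NONE"),
                c(rep("moderate", 4), "modifier")))
  ev <- build_evidence(de, muts, targets = "DT", specimen = "SP1")
  ann <- annotate_nodes(genes, ev, muts)
  got <- setNames(ann$category, ann$gene)
  expect_identical(got[["DT"]], "drug_target")   # precedence over DE
  expect_identical(got[["MUT"]], "mutated")
  expect_identical(got[["UP"]], "de_over")
  expect_identical(got[["DOWN"]], "de_under")
  expect_identical(got[["ABER"]], "aberrant")
  expect_identical(got[["NONE"]], "none")
  expect_equal(ann$n_moderate[ann$gene == "MUT"], 4L)
  expect_equal(ann$n_modifier[ann$gene == "NONE"], 1L)

  # CNV direction attached when provided
  ev2 <- build_evidence(de, muts, targets = "DT", specimen = "SP1",
                        cnv = c(UP = "amplified", DOWN = "deleted"))
  ann2 <- annotate_nodes(genes, ev2, muts)
  expect_identical(ann2$cnv[ann2$gene == "UP"], "amplified")
  expect_true(is.na(ann2$cnv[ann2$gene == "NONE"]))
})

test_that("evidence mode union vs intersection behaves as set algebra", {
  genes <- sprintf("G%02d", 1:20)
  de <- make_de(genes, p = rep(0.001, 20), lfc = rep(2, 20),
                sig = genes %in% genes[1:6])
  muts <- aggregate_mutations(mut_records("SP1", genes[4:9], rep("high", 6)))
  ev <- build_evidence(de, muts, targets = character(0), specimen = "SP1")
  pw <- pathway_collection(list(P = genes[1:10]), universe = genes)
  u <- enrich_pathways(ev, pw, evidence_mode = "union")
  i <- enrich_pathways(ev, pw, evidence_mode = "intersection")
  expect_equal(u$evidence_n, 9L)   # 1:6 union 4:9
  expect_equal(i$evidence_n, 3L)   # 4:6
})
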