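# Small in-code fixtures shared across test files.

# count matrix with one informative gene at user-chosen group counts,
# equal (overridden) library sizes
toy_split_matrix <- function(z1, z2, s1 = 1, s2 = 1, filler = 0L) {
  counts <- matrix(filler, nrow = 1, ncol = s1 + s2,
                   dimnames = list("gene1",
                                   c(sprintf("a%d", seq_len(s1)),
                                     sprintf("c%d", seq_len(s2)))))
  counts[1, 1] <- z1
  counts[1, s1 + 1] <- z2
  count_matrix(counts, rep(c("aggressive", "curable"), c(s1, s2)),
               lib_sizes = rep(100, s1 + s2))
}

# mutation record data.frame builder
mut_records <- function(specimen, gene, impact) {
  data.frame(specimen = specimen, gene = gene,
             variant_id = sprintf("v%04d", seq_along(gene)),
             impact = impact, stringsAsFactors = FALSE)
}

# noiseless 4PL dose-response records
dr_records <- function(ic50, top = 1, bottom = 0, hill = 1,
                       conc = c(1, 10, 100, 1000), reps = 3,
                       compound = "CMP", culture = "CU", noise_cv = 0,
                       seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  grid <- expand.grid(replicate = seq_len(reps), concentration_nM = conc)
  v <- fourpl(grid$concentration_nM, top, bottom, hill, ic50)
  if (noise_cv > 0) v <- pmax(v * (1 + rnorm(length(v), 0, noise_cv)), 0)
  data.frame(compound = compound, culture = culture,
             concentration_nM = grid$concentration_nM,
             replicate = grid$replicate, viability = v,
             stringsAsFactors = FALSE)
}

# viability records following the median-effect model exactly:
# fa/(1-fa) = (D/Dm)^m
me_records <- function(Dm, m, compound = "CMP", culture = "CU",
                       conc = c(10, 50, 100, 500, 1000)) {
  fa <- (conc / Dm)^m / (1 + (conc / Dm)^m)
  data.frame(compound = compound, culture = culture,
             concentration_nM = conc, replicate = 1L, viability = 1 - fa,
             stringsAsFactors = FALSE)
}
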