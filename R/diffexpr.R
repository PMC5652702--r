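#' Construct a labelled count matrix
#'
#' @param counts integer matrix, genes x samples, with dimnames.
#' @param groups character/factor of length `ncol(counts)` with exactly two
#'   levels (e.g. "aggressive" and "curable").
#' @param aggressive_level which group label is the phenotype of interest
#'   (numerator of fold changes). Defaults to `"aggressive"` when present,
#'   otherwise the second level.
#' @param lib_sizes optional per-sample library sizes; defaults to column
#'   sums.
#' @return object of class `count_matrix`.
#' @export
count_matrix <- function(counts, groups, aggressive_level = NULL,
                         lib_sizes = NULL) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("negative counts are not allowed")
  if (is.null(rownames(counts)))
    rownames(counts) <- sprintf("g%05d", seq_len(nrow(counts)))
  if (is.null(colnames(counts)))
    colnames(counts) <- sprintf("s%02d", seq_len(ncol(counts)))
  groups <- as.character(groups)
  if (length(groups) != ncol(counts))
    stop("every sample needs a group label")
  lev <- sort(unique(groups))
  if (length(lev) != 2L) stop("exactly two groups are required")
  if (is.null(aggressive_level))
    aggressive_level <- if ("aggressive" %in% lev) "aggressive" else lev[2]
  if (!aggressive_level %in% lev)
    stop("'aggressive_level' not among group labels")
  comparator <- setdiff(lev, aggressive_level)
  groups <- factor(groups, levels = c(comparator, aggressive_level))
  if (any(table(groups) < 1L)) stop("each group needs >= 1 sample")
  lib_override <- !is.null(lib_sizes)
  if (!lib_override) lib_sizes <- colSums(counts)
  if (any(lib_sizes <= 0)) stop("library sizes must be positive")
  structure(list(counts = counts, groups = groups,
                 aggressive = aggressive_level, comparator = comparator,
                 lib_sizes = setNames(as.numeric(lib_sizes),
                                      colnames(counts)),
                 lib_override = lib_override),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d genes x %d samples (%s: %d vs %s: %d)\n",
              nrow(x$counts), ncol(x$counts),
              x$aggressive, sum(x$groups == x$aggressive),
              x$comparator, sum(x$groups == x$comparator)))
  invisible(x)
}

#' Median-of-ratios effective library sizes
#'
#' Size factors are per-sample medians of count ratios to the geometric-mean
#' pseudo-reference (rows with a positive count in every sample), rescaled to
#' geometric mean 1. Effective library sizes put the factors back on the raw
#' sequencing-depth scale: `factor * geometric mean of the column sums`.
#'
#' @param m a [count_matrix()].
#' @return named numeric vector of effective library sizes, with the
#'   geometric-mean-1 scale factors in attribute `"scale_factors"`.
#' @export
normalize_libsizes <- function(m) {
  stopifnot(inherits(m, "count_matrix"))
  x <- m$counts
  if (all(x == 0)) stop("all-zero count matrix cannot be normalized")
  if (ncol(x) == 1L) {
    out <- setNames(sum(x), colnames(x))
    attr(out, "scale_factors") <- setNames(1, colnames(x))
    return(out)
  }
  usable <- rowSums(x > 0) == ncol(x)
  if (!any(usable)) {
    warning("no gene observed in every sample; falling back to column sums")
    sf <- colSums(x)
  } else {
    logref <- rowMeans(log(x[usable, , drop = FALSE]))
    sf <- apply(log(x[usable, , drop = FALSE]) - logref, 2,
                function(lr) exp(median(lr)))
  }
  sf <- sf / exp(mean(log(sf)))
  eff <- sf * exp(mean(log(colSums(x))))
  out <- setNames(as.numeric(eff), colnames(x))
  attr(out, "scale_factors") <- setNames(as.numeric(sf), colnames(x))
  out
}

# counts scaled to a common (geometric-mean) effective library size and
# rounded -- the quantile-adjustment approximation used by the conditional
# dispersion and exact-test machinery.
pseudo_counts <- function(m) {
  eff <- if (isTRUE(m$lib_override)) m$lib_sizes else normalize_libsizes(m)
  target <- exp(mean(log(eff)))
  pseudo <- round(sweep(m$counts, 2, target / eff, `*`))
  storage.mode(pseudo) <- "double"
  list(pseudo = pseudo, target = target, eff = eff)
}

# conditional NB log-likelihood (given per-group totals) for each gene at
# each phi in `phis`; groups with < 2 samples carry no information and are
# skipped. Returns genes x length(phis) matrix (constants dropped).
cond_ll_matrix <- function(pseudo, groups, phis) {
  G <- nrow(pseudo)
  out <- matrix(0, G, length(phis))
  for (lev in levels(groups)) {
    cols <- which(groups == lev)
    s <- length(cols)
    if (s < 2L) next
    y <- pseudo[, cols, drop = FALSE]
    z <- rowSums(y)
    for (j in seq_along(phis)) {
      phi <- phis[j]
      if (phi < 1e-10) phi <- 1e-10
      r <- 1 / phi
      ll <- rowSums(lgamma(y + r)) - s * lgamma(r) -
        (lgamma(z + s * r) - lgamma(s * r))
      out[, j] <- out[, j] + ll
    }
  }
  out
}

#' Estimate common and tagwise NB dispersions
#'
#' The common dispersion maximizes the conditional negative-binomial
#' log-likelihood (given per-group totals of counts adjusted to equal
#' effective library sizes) summed over genes. Tagwise dispersions maximize
#' the per-gene conditional likelihood augmented with `shrinkage_weight`
#' pseudo-genes carrying the cohort-average likelihood, shrinking each gene
#' toward the common value; `shrinkage_weight = Inf` returns the common value
#' for every gene.
#'
#' @param m a [count_matrix()].
#' @param shrinkage_weight number of pseudo-genes used for shrinkage
#'   (default 10).
#' @return object of class `dispersion_estimate` with elements `common`,
#'   `tagwise` (named by gene) and `shrinkage_weight`.
#' @export
estimate_dispersion <- function(m, shrinkage_weight = 10) {
  stopifnot(inherits(m, "count_matrix"))
  if (all(table(m$groups) < 2L))
    stop("dispersion is not estimable from a single-replicate-everywhere ",
         "design; supply a fixed value with dispersion_estimate()")
  pc <- pseudo_counts(m)

  total_ll <- function(logphi) {
    sum(cond_ll_matrix(pc$pseudo, m$groups, exp(logphi)))
  }
  opt <- optimize(total_ll, interval = c(log(1e-6), log(10)), maximum = TRUE,
                  tol = 1e-4)
  common <- exp(opt$maximum)
  if (common < 2e-6) common <- 0

  if (is.infinite(shrinkage_weight)) {
    tagwise <- setNames(rep(common, nrow(pc$pseudo)), rownames(pc$pseudo))
  } else {
    grid <- exp(seq(log(1e-4), log(10), length.out = 31))
    ll <- cond_ll_matrix(pc$pseudo, m$groups, grid)
    lbar <- colMeans(ll)
    score <- ll + shrinkage_weight * rep(lbar, each = nrow(ll))
    idx <- max.col(score, ties.method = "first")
    # quadratic interpolation in log-phi around the grid maximum
    logphi <- log(grid)
    tw <- numeric(nrow(ll))
    for (g in seq_len(nrow(ll))) {
      i <- idx[g]
      if (i == 1L || i == length(grid)) { tw[g] <- logphi[i]; next }
      y0 <- score[g, i - 1L]; y1 <- score[g, i]; y2 <- score[g, i + 1L]
      denom <- y0 - 2 * y1 + y2
      shift <- if (abs(denom) > 1e-12) 0.5 * (y0 - y2) / denom else 0
      shift <- max(min(shift, 1), -1)
      tw[g] <- logphi[i] + shift * (logphi[2] - logphi[1])
    }
    tagwise <- setNames(exp(tw), rownames(pc$pseudo))
    tagwise[tagwise < 2e-6] <- 0
  }
  dispersion_estimate(common, tagwise, shrinkage_weight)
}

#' Assemble a dispersion estimate (e.g. a user-supplied fixed value)
#'
#' @param common non-negative common dispersion.
#' @param tagwise optional named per-gene dispersions; defaults to the common
#'   value for every gene at use time.
#' @param shrinkage_weight shrinkage pseudo-gene count used (bookkeeping).
#' @return object of class `dispersion_estimate`.
#' @export
dispersion_estimate <- function(common, tagwise = NULL,
                                shrinkage_weight = NA_real_) {
  if (!is.finite(common) || common < 0)
    stop("'common' dispersion must be finite and >= 0")
  if (!is.null(tagwise) && (any(!is.finite(tagwise)) || any(tagwise < 0)))
    stop("'tagwise' dispersions must be finite and >= 0")
  structure(list(common = common, tagwise = tagwise,
                 shrinkage_weight = shrinkage_weight),
            class = "dispersion_estimate")
}

# two-sided minimum-likelihood p for one gene: observed split (z1, z2) of
# per-group pseudo-count totals between groups of s1 and s2 samples, NB
# dispersion phi. Sum of s iid NB(mu, 1/phi) is NB(s mu, s/phi), so the
# split conditional on the total is free of mu (negative hypergeometric;
# binomial in the Poisson limit).
exact_test_gene <- function(z1, z2, s1, s2, phi) {
  t <- z1 + z2
  if (t == 0) return(1)
  y <- 0:t
  if (phi < 1e-10) {
    logp <- dbinom(y, t, s1 / (s1 + s2), log = TRUE)
  } else {
    r1 <- s1 / phi
    r2 <- s2 / phi
    logw <- lgamma(y + r1) - lgamma(y + 1) +
      lgamma(t - y + r2) - lgamma(t - y + 1)
    logw <- logw - max(logw)
    logp <- logw - log(sum(exp(logw)))
  }
  obs <- logp[z1 + 1L]
  p <- sum(exp(logp[logp <= obs + 1e-10]))
  min(p, 1)
}

#' Negative-binomial exact test between the two phenotype groups
#'
#' Counts are adjusted to equal effective library sizes, summed within each
#' group, and the observed split of each gene's total is tested against its
#' conditional distribution under a common mean (negative hypergeometric with
#' the chosen dispersion; binomial at dispersion zero). Two-sided p-values
#' sum the probabilities of all splits no more likely than the observed one
#' (minimum-likelihood method). Fold changes are aggressive vs comparator on
#' normalized group means with a 0.5 pseudo-count.
#'
#' @param m a [count_matrix()].
#' @param d a [dispersion_estimate()] (or a single numeric dispersion).
#' @param which use the `"common"` or the `"tagwise"` dispersion.
#' @return data.frame: gene, p, log2_fold_change.
#' @export
exact_test <- function(m, d, which = c("common", "tagwise")) {
  stopifnot(inherits(m, "count_matrix"))
  which <- match.arg(which)
  if (is.numeric(d)) d <- dispersion_estimate(d)
  stopifnot(inherits(d, "dispersion_estimate"))
  pc <- pseudo_counts(m)
  agg <- m$groups == m$aggressive
  s1 <- sum(agg)
  s2 <- sum(!agg)
  z1 <- rowSums(pc$pseudo[, agg, drop = FALSE])
  z2 <- rowSums(pc$pseudo[, !agg, drop = FALSE])

  phi <- if (which == "common" || is.null(d$tagwise)) {
    rep(d$common, nrow(pc$pseudo))
  } else {
    as.numeric(d$tagwise[rownames(pc$pseudo)])
  }
  if (anyNA(phi)) stop("tagwise dispersion missing for some genes")

  p <- vapply(seq_along(z1),
              function(g) exact_test_gene(z1[g], z2[g], s1, s2, phi[g]),
              numeric(1))
  m1 <- z1 / s1
  m2 <- z2 / s2
  lfc <- log2((m1 + 0.5) / (m2 + 0.5))
  lfc[z1 + z2 == 0] <- 0
  data.frame(gene = rownames(pc$pseudo), p = p, log2_fold_change = lfc,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Call differential expression with the dual-dispersion FDR rule
#'
#' Benjamini-Hochberg adjusts the common-dispersion and tagwise-dispersion
#' p-value vectors separately; a gene is significant when both FDRs fall
#' below `alpha`. If no gene passes, the entire run switches to the fallback
#' rule -- both unadjusted p-values below `alpha` -- and records
#' `mode_used = "unadjusted_fallback"`. The fallback is all-or-nothing per
#' run, never per gene.
#'
#' @param r_common,r_tagwise results of [exact_test()] under the common and
#'   tagwise dispersions (same genes, same order not required).
#' @param alpha significance threshold (default 0.05).
#' @return data.frame of class `de_result`: gene, log2_fold_change,
#'   p_common, p_tagwise, fdr_common, fdr_tagwise, significant, mode_used.
#' @export
call_de <- function(r_common, r_tagwise, alpha = 0.05) {
  if (!setequal(r_common$gene, r_tagwise$gene) ||
      anyDuplicated(r_common$gene))
    stop("common and tagwise results must cover the same gene set")
  r_tagwise <- r_tagwise[match(r_common$gene, r_tagwise$gene), ]
  fdr_c <- p.adjust(r_common$p, method = "BH")
  fdr_t <- p.adjust(r_tagwise$p, method = "BH")
  sig <- fdr_c < alpha & fdr_t < alpha
  mode <- "dual_fdr"
  if (!any(sig)) {
    sig <- r_common$p < alpha & r_tagwise$p < alpha
    mode <- "unadjusted_fallback"
  }
  out <- data.frame(gene = r_common$gene,
                    log2_fold_change = r_common$log2_fold_change,
                    p_common = r_common$p, p_tagwise = r_tagwise$p,
                    fdr_common = fdr_c, fdr_tagwise = fdr_t,
                    significant = sig, mode_used = mode,
                    row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- c("de_result", "data.frame")
  out
}

#' Pearson correlation between two transcriptomes
#'
#' Computed on log2(CPM + 1) of two count vectors over the same genes.
#'
#' @param a,b non-negative count vectors in the same gene order.
#' @param transform apply the log2(CPM + 1) transform (set `FALSE` when the
#'   vectors are already on a log expression scale).
#' @return Pearson correlation coefficient in `[-1, 1]`.
#' @export
transcriptome_correlation <- function(a, b, transform = TRUE) {
  if (length(a) != length(b)) stop("vectors must share the same gene order")
  if (transform) {
    la <- log2(a / sum(a) * 1e6 + 1)
    lb <- log2(b / sum(b) * 1e6 + 1)
  } else {
    la <- a
    lb <- b
  }
  if (stats::sd(la) == 0 || stats::sd(lb) == 0)
    stop("correlation undefined for a zero-variance transcriptome")
  cor(la, lb)
}
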