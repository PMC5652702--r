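#' Read / write the pipeline table formats
#'
#' Gene-keyed tables are TSV with a header row, dose-response data is CSV,
#' pathway collections use the GMT dialect (id TAB description TAB
#' genes...), ground truth and manifests are JSON. All files are UTF-8 with
#' Unix newlines; every writer emits a header and every reader verifies it.
#'
#' @name table_io
NULL

check_header <- function(df, need, path) {
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("file '", path, "' lacks required column(s): ",
         paste(miss, collapse = ", "))
}

#' @rdname table_io
#' @param m a [count_matrix()]; `path` a file path.
#' @export
write_counts <- function(m, path) {
  stopifnot(inherits(m, "count_matrix"))
  df <- data.frame(gene = rownames(m$counts), m$counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname table_io
#' @param groups_path labels TSV (columns sample, group) written/read next
#'   to the counts.
#' @export
write_groups <- function(m, groups_path) {
  stopifnot(inherits(m, "count_matrix"))
  df <- data.frame(sample = colnames(m$counts),
                   group = as.character(m$groups), stringsAsFactors = FALSE)
  write.table(df, groups_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(groups_path)
}

#' @rdname table_io
#' @param path counts TSV (first column `gene`).
#' @param aggressive_level passed to [count_matrix()].
#' @export
read_counts <- function(path, groups_path, aggressive_level = NULL) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  check_header(df, "gene", path)
  counts <- as.matrix(df[, -1, drop = FALSE])
  rownames(counts) <- df$gene
  gr <- read.delim(groups_path, stringsAsFactors = FALSE)
  check_header(gr, c("sample", "group"), groups_path)
  if (!setequal(gr$sample, colnames(counts)))
    stop("samples in '", groups_path, "' do not match the count matrix")
  groups <- gr$group[match(colnames(counts), gr$sample)]
  count_matrix(counts, groups, aggressive_level = aggressive_level)
}

#' @rdname table_io
#' @param records mutation table (specimen, gene, variant_id, impact).
#' @export
write_mutations <- function(records, path) {
  write.table(records, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname table_io
#' @export
read_mutations <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  check_header(df, c("specimen", "gene", "variant_id", "impact"), path)
  df
}

#' Read a GMT pathway file
#'
#' Tab-separated: field 1 pathway id, field 2 description, fields 3+ member
#' genes. Duplicate genes within a pathway are de-duplicated with a warning;
#' lines with fewer than 3 fields are an error naming the line.
#'
#' @param path GMT file path.
#' @param universe optional background universe passed to
#'   [pathway_collection()].
#' @return a [pathway_collection()].
#' @export
read_gmt <- function(path, universe = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) stop("empty GMT file: ", path)
  sets <- list()
  desc <- character(0)
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3)
      stop("GMT line ", i, " has fewer than 3 fields")
    genes <- f[-(1:2)]
    genes <- genes[nzchar(genes)]
    if (anyDuplicated(genes)) {
      warning("duplicate genes in pathway '", f[1], "' de-duplicated")
      genes <- unique(genes)
    }
    sets[[f[1]]] <- genes
    desc[f[1]] <- f[2]
  }
  pathway_collection(sets, descriptions = desc, universe = universe)
}

#' @rdname table_io
#' @param pw a [pathway_collection()].
#' @export
write_gmt <- function(pw, path) {
  stopifnot(inherits(pw, "pathway_collection"))
  lines <- vapply(names(pw$sets), function(id) {
    paste(c(id, pw$descriptions[[id]], pw$sets[[id]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname table_io
#' @param tm compound x kinase inhibition matrix; written long (compound,
#'   kinase, inhibition).
#' @export
write_target_matrix <- function(tm, path) {
  df <- data.frame(compound = rep(rownames(tm), times = ncol(tm)),
                   kinase = rep(colnames(tm), each = nrow(tm)),
                   inhibition = as.vector(tm), stringsAsFactors = FALSE)
  df <- df[order(df$compound, df$kinase), ]
  rownames(df) <- NULL
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname table_io
#' @export
read_target_matrix <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  check_header(df, c("compound", "kinase", "inhibition"), path)
  compounds <- sort(unique(df$compound))
  kinases <- sort(unique(df$kinase))
  tm <- matrix(0, length(compounds), length(kinases),
               dimnames = list(compounds, kinases))
  tm[cbind(match(df$compound, compounds), match(df$kinase, kinases))] <-
    df$inhibition
  tm
}

#' @rdname table_io
#' @param dr dose-response long data.frame (compound, culture,
#'   concentration_nM, replicate, viability); CSV on disk.
#' @export
write_dose_response <- function(dr, path) {
  write.csv(dr, path, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname table_io
#' @export
read_dose_response <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  check_header(df, c("compound", "culture", "concentration_nM",
                     "replicate", "viability"), path)
  df
}

#' @rdname table_io
#' @param fits a [screen_efficacy()] table; censored IC50s are serialized as
#'   `"> <cmax>"` strings in the `ic50_nM` column.
#' @export
write_fits <- function(fits, path) {
  out <- fits
  out$ic50_nM <- ifelse(out$censored, sprintf("> %g", out$cmax),
                        sprintf("%.6g", out$ic50_nM))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname table_io
#' @param truth a `ground_truth` object; JSON on disk.
#' @export
write_truth <- function(truth, path) {
  t <- unclass(truth)
  # named vectors serialize as JSON objects only when they are lists
  t$de_genes <- as.list(t$de_genes)
  t$specimens <- as.list(t$specimens)
  jsonlite::write_json(t, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname table_io
#' @export
read_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$de_genes <- unlist(x$de_genes)
  x$specimens <- unlist(x$specimens)
  structure(x, class = "ground_truth")
}
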