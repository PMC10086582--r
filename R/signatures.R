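#' Classify a 5'UTR as a TOP-mRNA
#'
#' A transcript is a 5' terminal oligopyrimidine (TOP) mRNA when its first
#' transcribed base is a cytidine and it is followed by an uninterrupted
#' stretch of 4 to 14 pyrimidines (C/T, with U read as T). `N` interrupts a
#' run. A stretch of 15 or more pyrimidines after the initial C does not
#' qualify: the maximal run length must lie within `[4, 14]`.
#'
#' @param sequences Character vector of 5'UTR sequences (5' to 3', first base
#'   = first transcribed base after the cap). Alphabet `A, C, G, T, U, N`,
#'   case-insensitive.
#'
#' @return Logical vector, one element per sequence.
#' @export
#' @examples
#' classify_top_mrna(c("CTTTTGGA", "CTTTGA", "GTTTTTA"))
classify_top_mrna <- function(sequences) {
  if (!length(sequences)) return(logical(0))
  s <- toupper(as.character(sequences))
  if (any(is.na(s) | nchar(s) == 0)) {
    stop("sequences must be non-empty strings")
  }
  if (any(grepl("[^ACGTUN]", s))) {
    stop("sequences may only contain A, C, G, T, U, N")
  }
  s <- gsub("U", "T", s, fixed = TRUE)
  first_c <- substr(s, 1, 1) == "C"
  # maximal pyrimidine run starting at position 2 (N breaks the run)
  rest <- substr(s, 2, nchar(s))
  m <- regexpr("^[CT]*", rest)
  run_len <- attr(m, "match.length")
  first_c & run_len >= 4 & run_len <= 14
}

#' Select the top-n most significant upregulated genes
#'
#' Rank-selection step used to define a gene signature from a precomputed
#' differential-expression table: the `n` upregulated genes with the smallest
#' adjusted p-values, with ties broken lexicographically by gene id.
#'
#' @param de_table Data frame with columns `gene`, `padj` and either a
#'   logical `up` or a character `direction` (`"up"`/`"down"`).
#' @param n Number of genes to select (default 300).
#'
#' @return Character vector of gene ids, sorted by ascending adjusted
#'   p-value. If fewer than `n` genes qualify, all are returned, a warning is
#'   raised, and the attribute `short_list` is set to `TRUE`.
#' @export
select_top_n <- function(de_table, n = 300) {
  if (!all(c("gene", "padj") %in% names(de_table))) {
    stop("'de_table' needs columns 'gene' and 'padj'")
  }
  up <- if (!is.null(de_table$up)) {
    as.logical(de_table$up)
  } else if (!is.null(de_table$direction)) {
    de_table$direction == "up"
  } else {
    stop("'de_table' needs an 'up' (logical) or 'direction' column")
  }
  cand <- de_table[up & !is.na(de_table$padj), , drop = FALSE]
  cand <- cand[order(cand$padj, cand$gene), , drop = FALSE]
  short <- nrow(cand) < n
  if (short) {
    warning("only ", nrow(cand), " qualifying genes for a top-", n,
            " selection; returning all of them")
  }
  out <- utils::head(cand$gene, n)
  attr(out, "short_list") <- short
  out
}

#' Per-cell gene-set scores on a count matrix
#'
#' For each cell, counts are normalised to a total of 1,000,000, transformed
#' with `log1p` (natural logarithm), and summed over the genes of the set.
#' This normalisation target belongs to the scoring step and is deliberately
#' distinct from the (out-of-scope) embedding preprocessing, which uses
#' 10,000. Genes of the set absent from the matrix contribute 0 (reported via
#' a message); a cell with zero total counts scores 0 with a warning.
#'
#' @param counts Non-negative gene-by-cell count matrix with gene ids as row
#'   names (a base matrix or any Matrix-like object supporting `colSums` and
#'   row indexing).
#' @param gene_set Character vector of gene ids.
#' @param target_sum Per-cell normalisation total (default 1e6).
#'
#' @return Named numeric vector of per-cell scores.
#' @export
#' @examples
#' toy <- generate_toy_counts(n_genes = 20, n_cells = 5, seed = 1)
#' score_gene_set(toy$counts, toy$gene_set)
score_gene_set <- function(counts, gene_set, target_sum = 1e6) {
  if (is.null(rownames(counts))) stop("'counts' must have gene row names")
  if (any(counts < 0)) stop("'counts' must be non-negative")
  gene_set <- unique(as.character(gene_set))
  missing <- setdiff(gene_set, rownames(counts))
  if (length(missing)) {
    message(length(missing), " gene(s) of the set absent from the matrix; ",
            "they contribute 0")
  }
  present <- intersect(gene_set, rownames(counts))
  totals <- colSums(counts)
  zero <- totals == 0
  if (any(zero)) {
    warning(sum(zero), " cell(s) with zero total counts scored 0")
  }
  if (!length(present)) {
    return(stats::setNames(numeric(ncol(counts)), colnames(counts)))
  }
  sub <- counts[present, , drop = FALSE]
  denom <- ifelse(zero, 1, totals)
  norm <- sweep(as.matrix(sub), 2, denom, `/`) * target_sum
  norm[, zero] <- 0
  scores <- colSums(log1p(norm))
  stats::setNames(as.numeric(scores), colnames(counts))
}

#' Group means of per-cell scores
#'
#' @param scores Named numeric vector of per-cell scores.
#' @param labels Group label per cell (e.g. an interaction of cell type, age
#'   and genotype), same length/order as `scores`.
#'
#' @return Named numeric vector of group means. Factor levels without cells
#'   are omitted with a warning.
#' @export
group_mean_scores <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  labels <- as.factor(labels)
  empty <- setdiff(levels(labels), unique(as.character(labels)))
  if (length(empty)) {
    warning("empty group(s) omitted: ", paste(empty, collapse = ", "))
  }
  means <- tapply(scores, droplevels(labels), mean)
  stats::setNames(as.numeric(means), names(means))
}
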