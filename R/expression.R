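# Library-size normalized expression from read-count tables:
# RPKM = C * 1e9 / (N * L) and RPM = C * 1e6 / N, with replicate summaries.

#' Read-count matrix with library sizes and gene lengths
#'
#' @param counts Genes x samples matrix of non-negative integer read counts,
#'   with row and column names.
#' @param lib_sizes Per-sample total mapped reads (N); supplied, not
#'   recomputed, and must be at least the column sum of the counts.
#' @param gene_lengths Per-gene length in base pairs (summed exon length),
#'   all >= 1.
#' @return An object of class `count_matrix`.
#' @export
count_matrix <- function(counts, lib_sizes, gene_lengths) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("counts must have gene row names and sample column names")
  }
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers")
  }
  lib_sizes <- as.numeric(lib_sizes)
  gene_lengths <- as.numeric(gene_lengths)
  if (length(lib_sizes) != ncol(counts)) {
    stop("need one library size per sample")
  }
  if (length(gene_lengths) != nrow(counts)) {
    stop("need one gene length per gene")
  }
  if (any(lib_sizes <= 0)) stop("library sizes must be positive")
  if (any(gene_lengths < 1)) stop("gene lengths must be >= 1 bp")
  short <- lib_sizes < colSums(counts)
  if (any(short)) {
    stop("library size smaller than the column sum for sample(s): ",
         paste(colnames(counts)[short], collapse = ", "))
  }
  structure(list(counts = counts,
                 lib_sizes = stats::setNames(lib_sizes, colnames(counts)),
                 gene_lengths = stats::setNames(gene_lengths, rownames(counts))),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat("Count matrix: ", nrow(x$counts), " gene(s) x ", ncol(x$counts),
      " sample(s); library sizes ",
      paste(format(x$lib_sizes, big.mark = ","), collapse = ", "), "\n",
      sep = "")
  invisible(x)
}

#' Read a count matrix from counts + samples TSV
#'
#' `counts_file`: columns `gene_id`, `length_bp`, then one column per sample.
#' `samples_file`: columns `sample_id`, `total_mapped_reads` and optionally
#' `group`.
#'
#' @param counts_file,samples_file Paths.
#' @return A `count_matrix`; any `group` column is kept as attribute
#'   `groups` (named by sample).
#' @export
read_count_matrix <- function(counts_file, samples_file) {
  ct <- utils::read.table(counts_file, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE)
  sm <- utils::read.table(samples_file, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  samples <- setdiff(names(ct), c("gene_id", "length_bp"))
  m <- as.matrix(ct[, samples, drop = FALSE])
  rownames(m) <- ct$gene_id
  idx <- match(samples, sm$sample_id)
  if (anyNA(idx)) stop("samples TSV is missing sample(s): ",
                       paste(samples[is.na(idx)], collapse = ", "))
  cm <- count_matrix(m, sm$total_mapped_reads[idx], ct$length_bp)
  if ("group" %in% names(sm)) {
    attr(cm, "groups") <- stats::setNames(sm$group[idx], samples)
  }
  cm
}

expression_table <- function(values, metric, plus_one = FALSE) {
  structure(values, metric = metric, plus_one = plus_one,
            class = c("expression_table", class(values)))
}

#' Reads per kilobase per million mapped reads
#'
#' `RPKM[g, s] = C[g, s] * 1e9 / (N[s] * L[g])`, correcting read counts for
#' both sequencing depth and gene length. Invariant under joint scaling of
#' all counts and library sizes.
#'
#' @param cm A `count_matrix`.
#' @param plus_one If TRUE, add 1 to every value (export convenience for
#'   log-scale heatmaps; statistics should use raw RPKM).
#' @return Genes x samples matrix of class `expression_table`.
#' @export
compute_rpkm <- function(cm, plus_one = FALSE) {
  stopifnot(inherits(cm, "count_matrix"))
  v <- cm$counts * 1e9 /
    outer(as.numeric(cm$gene_lengths), as.numeric(cm$lib_sizes))
  if (plus_one) v <- v + 1
  expression_table(v, "rpkm", plus_one)
}

#' Reads per million mapped reads
#'
#' `RPM[g, s] = C[g, s] * 1e6 / N[s]`; depth normalization only, no gene
#' length correction.
#'
#' @inheritParams compute_rpkm
#' @return Genes x samples matrix of class `expression_table`.
#' @export
compute_rpm <- function(cm, plus_one = FALSE) {
  stopifnot(inherits(cm, "count_matrix"))
  v <- sweep(cm$counts * 1e6, 2L, as.numeric(cm$lib_sizes), "/")
  if (plus_one) v <- v + 1
  expression_table(v, "rpm", plus_one)
}

#' Replicate summary and expression ranking
#'
#' Per-gene mean over replicate columns, coefficient of variation
#' (CV% = 100 * sd / mean, sample sd with n - 1; reported as `NA` when the
#' mean is 0), descending rank by mean (ties broken in row order so the
#' ranking is a permutation) and an `expressed` flag (mean > 0).
#'
#' @param et An `expression_table` (or plain matrix) whose columns are
#'   replicates.
#' @return Data frame with columns `gene_id`, `mean`, `cv_pct`, `rank`,
#'   `expressed`, in input gene order.
#' @export
replicate_stats <- function(et) {
  m <- unclass(et)
  mu <- rowMeans(m)
  sdv <- apply(m, 1L, stats::sd)
  cv <- ifelse(mu == 0, NA_real_, 100 * sdv / mu)
  if (ncol(m) < 2L) cv <- rep(NA_real_, nrow(m))
  data.frame(gene_id = rownames(m),
             mean = mu,
             cv_pct = cv,
             rank = rank(-mu, ties.method = "first"),
             expressed = mu > 0,
             row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Group-wise RPM/RPKM comparison with a fold-change annotation
#'
#' Compares per-gene mean expression between two sample groups and flags
#' genes whose control/treated ratio exceeds a threshold as strongly
#' repressed (and the converse as strongly induced). This is a report
#' annotation, not an inferential test.
#'
#' @param et An `expression_table`.
#' @param control,treated Column names (or indices) of the two groups.
#' @param ratio_threshold Fold-change flag threshold, default 5.
#' @return Data frame with per-gene group means, `ratio`
#'   (control / treated; `Inf` when treated is 0 and control positive,
#'   `NA` when both are 0), `strongly_repressed`, `strongly_induced`.
#' @export
compare_groups <- function(et, control, treated, ratio_threshold = 5) {
  m <- unclass(et)
  mc <- rowMeans(m[, control, drop = FALSE])
  mt <- rowMeans(m[, treated, drop = FALSE])
  ratio <- ifelse(mc == 0 & mt == 0, NA_real_, mc / mt)
  data.frame(gene_id = rownames(m),
             mean_control = mc,
             mean_treated = mt,
             ratio = ratio,
             strongly_repressed = !is.na(ratio) & ratio > ratio_threshold,
             strongly_induced = !is.na(ratio) & ratio < 1 / ratio_threshold,
             row.names = NULL,
             stringsAsFactors = FALSE)
}
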