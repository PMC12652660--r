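# PWM scanning with exact p-value calibration.
#
# Scores are discretized onto an integer grid (grid_scale units per bit) and
# the full null distribution of the discretized score of a random background
# word is computed by position-wise convolution. Cutoffs derived from that
# distribution make "hit" exactly equivalent to "word p-value < threshold" at
# grid resolution, for both strands.

#' Dual stringency thresholds for a scan
#'
#' @param lenient_p Lenient motif p-value threshold (default 1e-4). A hit
#'   exists wherever the word p-value is strictly below this.
#' @param stringent_p Stringent threshold (default 1e-5); must be smaller
#'   than `lenient_p`. Hits passing it are tiered `stringent`, the rest
#'   `lenient-only`.
#' @return An object of class `scan_thresholds`.
#' @export
scan_thresholds <- function(lenient_p = 1e-4, stringent_p = 1e-5) {
  stopifnot(is.numeric(lenient_p), is.numeric(stringent_p))
  if (!(lenient_p > 0 && lenient_p <= 1) || !(stringent_p > 0 && stringent_p <= 1)) {
    stop("p-value thresholds must lie in (0, 1]")
  }
  if (!(stringent_p < lenient_p)) {
    stop("stringent_p must be < lenient_p")
  }
  structure(list(lenient_p = lenient_p, stringent_p = stringent_p),
            class = "scan_thresholds")
}

#' Reverse-complement a DNA string
#'
#' @param x Character vector of DNA strings over A/C/G/T/N.
#' @return The reverse complement of each element.
#' @export
reverse_complement <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(chartr("ACGTN", "TGCAN", toupper(s)), "",
                       fixed = TRUE)[[1L]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

base_codes <- function(s) {
  match(strsplit(toupper(s), "", fixed = TRUE)[[1L]], DNA_BASES)
}

int_weights <- function(pwm, grid_scale) {
  w <- round(pwm$weights * grid_scale)
  storage.mode(w) <- "double"  # values can exceed .Machine$integer.max sums
  w
}

#' Score one word with a PWM
#'
#' Sum of per-position weights in bits. For strand `-` the word is
#' reverse-complemented before scoring, so `score_window(pwm, w, "-")` equals
#' `score_window(pwm, reverse_complement(w), "+")`.
#'
#' @param pwm A `pwm`.
#' @param word DNA word of exactly the motif length.
#' @param strand `"+"` or `"-"`.
#' @return Score in bits, or `NA` if the word contains `N` (unscorable; the
#'   scanner skips such windows).
#' @export
score_window <- function(pwm, word, strand = "+") {
  stopifnot(inherits(pwm, "pwm"))
  strand <- match.arg(strand, c("+", "-"))
  L <- ncol(pwm$weights)
  if (nchar(word) != L) {
    stop("word length ", nchar(word), " does not match motif length ", L)
  }
  if (strand == "-") word <- reverse_complement(word)
  codes <- base_codes(word)
  if (anyNA(codes)) return(NA_real_)
  sum(pwm$weights[cbind(codes, seq_len(L))])
}

#' Exact null distribution of the discretized PWM score
#'
#' Computes, by position-wise convolution, the exact probability distribution
#' of the integer-discretized score of a random word of the motif length with
#' independent bases drawn from the PWM's background model. This is the basis
#' for exact motif p-values and threshold cutoffs.
#'
#' @param pwm A `pwm` (its `background` is the null model).
#' @param grid_scale Integer score units per bit (default 10000). Higher
#'   values refine p-values at linearly growing cost; any p-value moves by at
#'   most the mass of one grid cell when the grid is refined.
#' @return An object of class `score_distribution` with elements
#'   `grid_scale`, `min_score` (integer grid origin), `probs` (probability of
#'   each grid score from `min_score` upward) and `tail` (upper-tail
#'   probabilities `P(S >= s)`).
#' @export
score_distribution <- function(pwm, grid_scale = 10000L) {
  stopifnot(inherits(pwm, "pwm"))
  grid_scale <- as.integer(grid_scale)
  if (is.na(grid_scale) || grid_scale < 1L) stop("grid_scale must be >= 1")
  W <- int_weights(pwm, grid_scale)
  bg <- as.numeric(pwm$background)
  L <- ncol(W)
  col_min <- apply(W, 2L, min)
  p <- 1
  for (j in seq_len(L)) {
    off <- W[, j] - col_min[j]
    newlen <- length(p) + max(off)
    acc <- numeric(newlen)
    for (b in 1:4) {
      i0 <- off[b]
      idx <- (1L + i0):(length(p) + i0)
      acc[idx] <- acc[idx] + bg[b] * p
    }
    p <- acc
  }
  if (abs(sum(p) - 1) > 1e-9) {
    stop("score distribution probabilities do not sum to 1 (numerical failure)")
  }
  structure(list(matrix_id = pwm$matrix_id,
                 grid_scale = grid_scale,
                 min_score = sum(col_min),
                 probs = p,
                 tail = rev(cumsum(rev(p)))),
            class = "score_distribution")
}

#' @export
print.score_distribution <- function(x, ...) {
  sup <- score_support(x)
  cat("Exact score distribution for ", x$matrix_id, ": ", nrow(sup),
      " support points on [", min(sup$score), ", ", max(sup$score),
      "] bits (grid ", x$grid_scale, "/bit)\n", sep = "")
  invisible(x)
}

#' Support of a score distribution
#'
#' @param dist A `score_distribution`.
#' @return Data frame with columns `score` (bits), `prob`, `pvalue`
#'   (upper tail), restricted to grid points with positive probability.
#' @export
score_support <- function(dist) {
  stopifnot(inherits(dist, "score_distribution"))
  keep <- dist$probs > 0
  data.frame(score = (dist$min_score + which(keep) - 1L) / dist$grid_scale,
             prob = dist$probs[keep],
             pvalue = dist$tail[keep])
}

# Upper tail P(S >= s_int) at integer grid score(s); exact lookup.
tail_at_int <- function(dist, s_int) {
  n <- length(dist$probs)
  idx <- s_int - dist$min_score + 1
  out <- numeric(length(idx))
  out[idx <= 0] <- 1
  out[idx > n] <- 0
  inb <- idx >= 1 & idx <= n
  out[inb] <- dist$tail[idx[inb]]
  out
}

#' Exact motif p-value of a score
#'
#' `P(S >= score)` for a random background word, at grid resolution: the
#' score (in bits) is mapped to its nearest integer grid value first.
#' Scores reported by the scanner (and those in [score_support()]) are exact
#' grid multiples, so their lookup is exact; a score summed from unrounded
#' weights can sit up to half a grid unit per position away from its
#' discretized counterpart -- use [word_pvalue()] for a word-level query that
#' shares the scanner's discretization exactly.
#'
#' @param dist A `score_distribution`.
#' @param score Score(s) in bits.
#' @return Upper-tail probabilities.
#' @export
pvalue_of_score <- function(dist, score) {
  stopifnot(inherits(dist, "score_distribution"))
  tail_at_int(dist, round(score * dist$grid_scale))
}

#' Exact p-value of a word under a PWM
#'
#' Scores the word on the same rounded-weight integer grid the score
#' distribution is built on, then looks up the exact upper tail, so the
#' result agrees exactly with the scanner's hit calibration.
#'
#' @param pwm A `pwm`.
#' @param word DNA word of the motif length (strand `+`; reverse-complement
#'   first for the other strand).
#' @param dist Optional precomputed [score_distribution()] for `pwm`.
#' @param grid_scale Used when `dist` is not supplied.
#' @return The word's exact motif p-value, or `NA` if the word contains `N`.
#' @export
word_pvalue <- function(pwm, word, dist = NULL, grid_scale = 10000L) {
  stopifnot(inherits(pwm, "pwm"))
  if (is.null(dist)) dist <- score_distribution(pwm, grid_scale)
  codes <- base_codes(word)
  L <- ncol(pwm$weights)
  if (length(codes) != L) stop("word length does not match motif length")
  if (anyNA(codes)) return(NA_real_)
  W <- int_weights(pwm, dist$grid_scale)
  tail_at_int(dist, sum(W[cbind(codes, seq_len(L))]))
}

cutoff_int <- function(dist, p) {
  if (!is.numeric(p) || length(p) != 1L || p <= 0 || p > 1) {
    stop("p must lie in (0, 1]")
  }
  idx <- which(dist$tail < p)
  if (length(idx) == 0L) {
    dist$min_score + length(dist$probs)  # one grid unit above the max score
  } else {
    dist$min_score + idx[1L] - 1
  }
}

#' Score cutoff achieving a p-value threshold
#'
#' The smallest discretized score `s` with `P(S >= s) < p` (strict, matching
#' the "p < threshold" definition of a hit). Scanning with this cutoff yields
#' exactly the words whose p-value is below `p` at grid resolution.
#'
#' @param dist A `score_distribution`.
#' @param p Threshold in (0, 1].
#' @return Cutoff in bits (integer grid value divided by `grid_scale`).
#' @export
score_cutoff <- function(dist, p) {
  stopifnot(inherits(dist, "score_distribution"))
  cutoff_int(dist, p) / dist$grid_scale
}

#' Validate hit-table consistency against thresholds
#'
#' Checks the contract every hit table must satisfy, whether scanned or
#' fabricated: all p-values strictly below the lenient threshold, tier
#' `stringent` exactly when the p-value is below the stringent threshold
#' (nesting), and no duplicate (matrix_id, gene_id, start, strand) tuples.
#'
#' @param hits A `hit_table` (or plain data frame with the hit columns).
#' @param thresholds A `scan_thresholds`.
#' @return Invisibly TRUE; stops with a message on the first violation.
#' @export
validate_hits <- function(hits, thresholds = scan_thresholds()) {
  if (any(hits$pvalue >= thresholds$lenient_p)) {
    stop("hit(s) with p-value >= lenient threshold ", thresholds$lenient_p)
  }
  should_str <- hits$pvalue < thresholds$stringent_p
  if (any(should_str != (hits$tier == "stringent"))) {
    stop("tier nesting violated: 'stringent' must hold exactly when ",
         "p-value < ", thresholds$stringent_p)
  }
  key <- paste(hits$matrix_id, hits$gene_id, hits$start, hits$strand)
  if (anyDuplicated(key)) stop("duplicate (matrix_id, gene_id, start, strand) hits")
  invisible(TRUE)
}

hit_columns <- c("matrix_id", "tf_name", "gene_id", "start", "end",
                 "strand", "score_bits", "pvalue", "tier")

empty_hits <- function() {
  data.frame(matrix_id = character(0), tf_name = character(0),
             gene_id = character(0), start = integer(0), end = integer(0),
             strand = character(0), score_bits = numeric(0),
             pvalue = numeric(0), tier = character(0),
             stringsAsFactors = FALSE)
}

as_hit_table <- function(hits, provenance = NULL) {
  rownames(hits) <- NULL
  key <- paste(hits$matrix_id, hits$gene_id, hits$start, hits$strand)
  if (anyDuplicated(key)) stop("duplicate (matrix_id, gene_id, start, strand) hits")
  structure(hits, provenance = provenance,
            class = c("hit_table", "data.frame"))
}

#' @export
print.hit_table <- function(x, ...) {
  pv <- attr(x, "provenance")
  cat("Motif hit table: ", nrow(x), " hit(s), ",
      sum(x$tier == "stringent"), " stringent\n", sep = "")
  if (!is.null(pv)) {
    cat("  window ", pv$window[1L], "..+", pv$window[2L],
        ", thresholds p<", pv$thresholds$lenient_p, " / p<",
        pv$thresholds$stringent_p, ", ", length(pv$matrix_ids),
        " matrices, ", pv$n_masked, " masked window(s)\n", sep = "")
  }
  print(utils::head(as.data.frame(x), 10L))
  if (nrow(x) > 10L) cat("  ... ", nrow(x) - 10L, " more row(s)\n", sep = "")
  invisible(x)
}

# Core per-(pwm, promoter) scan; dist may be precomputed by scan_collection.
scan_one <- function(pwm, gene_id, sequence, window_start, window_end,
                     thresholds, grid_scale, dist = NULL) {
  L <- ncol(pwm$weights)
  n <- nchar(sequence)
  if (n < L) {
    warning("promoter window for ", gene_id, " (", n,
            " nt) is shorter than motif ", pwm$matrix_id, " (", L, " nt)")
    return(list(hits = empty_hits(), n_masked = 0L))
  }
  if (is.null(dist)) dist <- score_distribution(pwm, grid_scale)
  cut_len <- cutoff_int(dist, thresholds$lenient_p)
  cut_str <- cutoff_int(dist, thresholds$stringent_p)

  codes <- base_codes(sequence)
  W <- int_weights(pwm, dist$grid_scale)
  W_rc <- W[4:1, L:1, drop = FALSE]  # complement rows, reversed columns
  npos <- n - L + 1L
  fwd <- numeric(npos)
  rev_ <- numeric(npos)
  for (j in seq_len(L)) {
    cj <- codes[j:(j + npos - 1L)]
    fwd <- fwd + W[cbind(cj, j)]
    rev_ <- rev_ + W_rc[cbind(cj, j)]
  }
  n_masked <- sum(is.na(fwd))

  collect <- function(scores, strand) {
    idx <- which(!is.na(scores) & scores >= cut_len)
    if (length(idx) == 0L) return(empty_hits())
    s_int <- scores[idx]
    data.frame(matrix_id = pwm$matrix_id, tf_name = pwm$tf_name,
               gene_id = gene_id,
               start = tss_position(idx, window_start),
               end = tss_position(idx + L - 1L, window_start),
               strand = strand,
               score_bits = s_int / dist$grid_scale,
               pvalue = tail_at_int(dist, s_int),
               tier = ifelse(s_int >= cut_str, "stringent", "lenient-only"),
               stringsAsFactors = FALSE)
  }
  hits <- rbind(collect(fwd, "+"), collect(rev_, "-"))
  list(hits = hits, n_masked = n_masked)
}

#' Scan one promoter with one PWM
#'
#' Every window position on both strands is scored; positions whose word
#' p-value falls strictly below the lenient threshold become hits, tiered
#' `stringent` when they also pass the stringent threshold. Hit coordinates
#' are TSS-relative (no position 0) and anchored at the 5'-most base of the
#' matched window in forward-strand space for both strands. Windows
#' containing `N` are skipped and counted as masked.
#'
#' @param pwm A `pwm`.
#' @param promoter A one-row `promoter_set`.
#' @param thresholds A `scan_thresholds` (default p<1e-4 / p<1e-5).
#' @param grid_scale Score discretization, units per bit.
#' @return A `hit_table` (data frame, one row per hit) with a `provenance`
#'   attribute recording window, background, pseudocount, thresholds, grid
#'   and masked-window tally.
#' @export
scan_promoter <- function(pwm, promoter, thresholds = scan_thresholds(),
                          grid_scale = 10000L) {
  stopifnot(inherits(pwm, "pwm"), inherits(promoter, "promoter_set"))
  if (nrow(promoter) != 1L) {
    stop("scan_promoter expects a single promoter; use scan_collection")
  }
  scan_collection(list(pwm), promoter, thresholds, grid_scale)
}

#' Scan a promoter collection with a matrix library
#'
#' Batch driver: scans every (matrix, promoter) pair, concatenates the hits
#' and sorts them by (gene_id, matrix_id, start, strand).
#'
#' @param pwms List of `pwm` objects with unique matrix ids.
#' @param promoters A `promoter_set`.
#' @param thresholds A `scan_thresholds`.
#' @param grid_scale Score discretization, units per bit.
#' @return A `hit_table` covering all pairs.
#' @export
scan_collection <- function(pwms, promoters, thresholds = scan_thresholds(),
                            grid_scale = 10000L) {
  if (inherits(pwms, "pwm")) pwms <- list(pwms)
  stopifnot(length(pwms) >= 0, inherits(promoters, "promoter_set"),
            inherits(thresholds, "scan_thresholds"))
  ids <- vapply(pwms, function(p) p$matrix_id, character(1))
  if (anyDuplicated(ids)) {
    stop("duplicate matrix_id in library: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  ws <- attr(promoters, "window_start")
  we <- attr(promoters, "window_end")
  pieces <- list()
  n_masked <- 0L
  max_scores <- numeric(0)
  for (pwm in pwms) {
    dist <- score_distribution(pwm, grid_scale)
    max_scores[pwm$matrix_id] <- sum(apply(pwm$weights, 2L, max))
    for (i in seq_len(nrow(promoters))) {
      res <- scan_one(pwm, promoters$gene_id[i], promoters$sequence[i],
                      ws, we, thresholds, grid_scale, dist = dist)
      n_masked <- n_masked + res$n_masked
      if (nrow(res$hits)) pieces[[length(pieces) + 1L]] <- res$hits
    }
  }
  hits <- if (length(pieces)) do.call(rbind, pieces) else empty_hits()
  hits <- hits[order(hits$gene_id, hits$matrix_id, hits$start, hits$strand), ]
  pv <- list(window = c(ws, we),
             background = if (length(pwms)) pwms[[1L]]$background else background_model(),
             pseudocount_total = if (length(pwms)) pwms[[1L]]$pseudocount_total else NA,
             thresholds = thresholds,
             grid_scale = as.integer(grid_scale),
             matrix_ids = ids,
             max_scores = max_scores,
             library_checksum = round(sum(vapply(pwms, function(p) sum(p$weights),
                                                 numeric(1))), 6),
             n_masked = n_masked)
  as_hit_table(hits, pv)
}

#' Write / read a hit table as TSV
#'
#' Plain nine-column TSV (`matrix_id`, `tf_name`, `gene_id`, `start`, `end`,
#' `strand`, `score_bits`, `pvalue`, `tier`); provenance is not serialized.
#'
#' @param hits A `hit_table`.
#' @param file Path.
#' @export
write_hits_tsv <- function(hits, file) {
  stopifnot(inherits(hits, "hit_table"))
  utils::write.table(as.data.frame(hits)[, hit_columns], file, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname write_hits_tsv
#' @export
read_hits_tsv <- function(file) {
  df <- utils::read.table(file, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE,
                          colClasses = c(matrix_id = "character",
                                         tf_name = "character",
                                         gene_id = "character",
                                         start = "integer", end = "integer",
                                         strand = "character",
                                         score_bits = "numeric",
                                         pvalue = "numeric",
                                         tier = "character"))
  as_hit_table(df[, hit_columns])
}

#' Export hits as BED6
#'
#' Coordinates are 0-based half-open within the scanned window (absolute
#' window offsets, not TSS-relative); `name` is the matrix id and `score` is
#' `round(1000 * min(1, score_bits / max_score))` using the per-matrix
#' maximum score recorded in the provenance.
#'
#' @param hits A `hit_table` produced by [scan_collection()].
#' @param file Path.
#' @export
hits_to_bed <- function(hits, file) {
  stopifnot(inherits(hits, "hit_table"))
  pv <- attr(hits, "provenance")
  if (is.null(pv)) stop("BED export needs scan provenance (window, max scores)")
  start0 <- seq_index(hits$start, pv$window[1L]) - 1L
  ms <- pv$max_scores[hits$matrix_id]
  bed <- data.frame(chrom = hits$gene_id,
                    start = start0,
                    end = start0 + (seq_index(hits$end, pv$window[1L]) - 1L -
                                      start0) + 1L,
                    name = hits$matrix_id,
                    score = round(1000 * pmin(1, hits$score_bits / ms)),
                    strand = hits$strand)
  utils::write.table(bed, file, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(file)
}
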