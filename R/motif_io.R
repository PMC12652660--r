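#' @importFrom stats setNames
NULL

DNA_BASES <- c("A", "C", "G", "T")

#' Nucleotide background model
#'
#' A background model is the independent per-base null distribution used both
#' to build log likelihood-ratio weights and to calibrate motif p-values.
#'
#' @param freqs Numeric vector of four frequencies for A, C, G, T. Must be
#'   strictly positive and sum to 1 (within 1e-9). Default is uniform.
#' @return A named numeric vector of class `background_model`.
#' @examples
#' background_model()                       # uniform
#' background_model(c(0.3, 0.2, 0.2, 0.3))  # A/T-rich, promoter-like
#' @export
background_model <- function(freqs = rep(0.25, 4)) {
  freqs <- as.numeric(freqs)
  if (length(freqs) != 4L) {
    stop("background model needs exactly 4 frequencies (A, C, G, T)")
  }
  if (any(!is.finite(freqs)) || any(freqs <= 0)) {
    stop("background frequencies must all be > 0")
  }
  if (abs(sum(freqs) - 1) > 1e-9) {
    stop("background frequencies must sum to 1 (got ", sum(freqs), ")")
  }
  structure(setNames(freqs, DNA_BASES), class = "background_model")
}

#' Estimate a background model from promoter sequences
#'
#' Pools all promoter sequences and uses the observed A/C/G/T frequencies
#' (N bases are ignored) as the background.
#'
#' @param promoters A `promoter_set`, see [read_promoters_fasta()].
#' @return A `background_model`.
#' @export
background_from_promoters <- function(promoters) {
  stopifnot(inherits(promoters, "promoter_set"))
  chars <- unlist(strsplit(promoters$sequence, "", fixed = TRUE), use.names = FALSE)
  counts <- vapply(DNA_BASES, function(b) sum(chars == b), numeric(1))
  if (sum(counts) == 0) stop("no A/C/G/T bases found in promoter set")
  background_model(counts / sum(counts))
}

#' Construct a position frequency matrix
#'
#' @param matrix_id Text identifier (e.g. a JASPAR accession).
#' @param tf_name Transcription factor name.
#' @param counts 4 x L non-negative count matrix, rows in A, C, G, T order;
#'   every column needs at least one positive count.
#' @return An object of class `pfm`.
#' @export
pfm <- function(matrix_id, tf_name, counts) {
  new_pfm(matrix_id, tf_name, counts)
}

new_pfm <- function(matrix_id, tf_name, counts) {
  counts <- as.matrix(counts)
  if (nrow(counts) != 4L) {
    stop("PFM '", matrix_id, "': counts must have 4 rows (A, C, G, T)")
  }
  rownames(counts) <- DNA_BASES
  if (ncol(counts) < 1L) stop("PFM '", matrix_id, "': motif length must be >= 1")
  if (any(!is.finite(counts)) || any(counts < 0)) {
    stop("PFM '", matrix_id, "': counts must be finite and non-negative")
  }
  if (any(colSums(counts) == 0)) {
    stop("PFM '", matrix_id, "': every column needs at least one positive count")
  }
  structure(list(matrix_id = as.character(matrix_id),
                 tf_name = as.character(tf_name),
                 counts = counts),
            class = "pfm")
}

#' @export
print.pfm <- function(x, ...) {
  cat("Position frequency matrix ", x$matrix_id, " (", x$tf_name, "), length ",
      ncol(x$counts), "\n", sep = "")
  print(x$counts)
  invisible(x)
}

#' Read JASPAR-format position frequency matrices
#'
#' Parses the JASPAR 2016+ plain-text PFM dialect: a `>ID NAME` header line
#' followed by four base rows of the form `A  [ 4 19 0 ... ]`. Base rows may
#' appear in any order; they are remapped to the fixed internal A, C, G, T
#' order by their row label.
#'
#' @param file Path to a PFM file, or a connection.
#' @return A list of `pfm` objects, one per record, in file order.
#' @seealso [write_jaspar_pfm()], [pfm_to_pwm()]
#' @export
read_jaspar_pfm <- function(file) {
  lines <- readLines(file)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) return(list())
  is_header <- startsWith(lines, ">")
  if (!is_header[1L]) stop("JASPAR PFM stream must start with a '>' header")
  rec_id <- cumsum(is_header)
  headers <- lines[is_header]
  out <- vector("list", length(headers))
  for (r in seq_along(headers)) {
    hdr_tokens <- strsplit(sub("^>", "", headers[r]), "[ \t]+")[[1L]]
    matrix_id <- hdr_tokens[1L]
    tf_name <- if (length(hdr_tokens) >= 2L) {
      paste(hdr_tokens[-1L], collapse = " ")
    } else {
      matrix_id
    }
    body <- lines[rec_id == r & !is_header]
    rows <- list()
    for (ln in body) {
      base <- toupper(substr(ln, 1L, 1L))
      if (!base %in% DNA_BASES) {
        stop("PFM '", matrix_id, "': unrecognised base row '", ln, "'")
      }
      nums <- gsub("[][]", " ", substr(ln, 2L, nchar(ln)))
      vals <- suppressWarnings(as.numeric(strsplit(trimws(nums), "[ \t]+")[[1L]]))
      if (anyNA(vals)) {
        stop("PFM '", matrix_id, "': non-numeric counts in row ", base)
      }
      rows[[base]] <- vals
    }
    missing <- setdiff(DNA_BASES, names(rows))
    if (length(missing)) {
      stop("PFM '", matrix_id, "': missing base row(s) ",
           paste(missing, collapse = ", "))
    }
    lens <- lengths(rows[DNA_BASES])
    if (length(unique(lens)) != 1L) {
      stop("PFM '", matrix_id, "': ragged rows (column counts ",
           paste(lens, collapse = "/"), " across A/C/G/T)")
    }
    out[[r]] <- new_pfm(matrix_id, tf_name,
                        do.call(rbind, rows[DNA_BASES]))
  }
  out
}

#' Write position frequency matrices in JASPAR format
#'
#' @param pfms A list of `pfm` objects (or a single one).
#' @param file Path or connection to write to.
#' @export
write_jaspar_pfm <- function(pfms, file) {
  if (inherits(pfms, "pfm")) pfms <- list(pfms)
  lines <- unlist(lapply(pfms, function(p) {
    c(paste0(">", p$matrix_id, " ", p$tf_name),
      vapply(DNA_BASES, function(b) {
        paste0(b, "  [ ", paste(format(p$counts[b, ], trim = TRUE),
                                collapse = " "), " ]")
      }, character(1)))
  }))
  writeLines(lines, file)
  invisible(file)
}

#' Consensus word of a frequency matrix
#'
#' Per column, the base with the highest count (ties broken in A, C, G, T
#' order). Used e.g. as the planted word by the promoter simulator.
#'
#' @param pfm A `pfm`.
#' @return A character scalar of the motif length.
#' @export
pfm_consensus <- function(pfm) {
  stopifnot(inherits(pfm, "pfm"))
  paste(DNA_BASES[apply(pfm$counts, 2L, which.max)], collapse = "")
}

#' Build a position weight matrix from a frequency matrix
#'
#' Converts base counts into per-position log2 likelihood-ratio weights
#' against a background model:
#' `weight[b, j] = log2(((counts[b, j] + bg[b] * pc) / (colsum[j] + pc)) / bg[b])`
#' where `pc` is the total pseudocount per column, distributed across bases
#' proportionally to the background. The score of a word is the sum of its
#' per-position weights (in bits); a word drawn from the matrix model scores
#' high, a background-typical word scores near or below zero.
#'
#' @param pfm A `pfm`.
#' @param background A `background_model`; default uniform.
#' @param pseudocount_total Total pseudocount added per column (default 1).
#'   May be 0 only when every count is positive, otherwise weights would be
#'   infinite.
#' @return An object of class `pwm`: list with `matrix_id`, `tf_name`,
#'   `weights` (4 x L, bits), `background`, `pseudocount_total`.
#' @examples
#' p <- new_pfm_example <- read_jaspar_pfm(textConnection(c(
#'   ">MX0001.1 TOY", "A [ 12 0 ]", "C [ 0 12 ]", "G [ 0 0 ]", "T [ 0 0 ]")))[[1]]
#' pfm_to_pwm(p)$weights
#' @export
pfm_to_pwm <- function(pfm, background = background_model(),
                       pseudocount_total = 1) {
  stopifnot(inherits(pfm, "pfm"))
  if (!inherits(background, "background_model")) {
    background <- background_model(background)
  }
  if (!is.numeric(pseudocount_total) || length(pseudocount_total) != 1L ||
      pseudocount_total < 0) {
    stop("pseudocount_total must be a single non-negative number")
  }
  counts <- pfm$counts
  if (pseudocount_total == 0 && any(counts == 0)) {
    stop("PFM '", pfm$matrix_id,
         "' has zero counts; a positive pseudocount_total is required")
  }
  colsum <- colSums(counts)
  freq <- sweep(counts + outer(as.numeric(background), rep(pseudocount_total, ncol(counts))),
                2L, colsum + pseudocount_total, "/")
  weights <- log2(sweep(freq, 1L, as.numeric(background), "/"))
  rownames(weights) <- DNA_BASES
  structure(list(matrix_id = pfm$matrix_id,
                 tf_name = pfm$tf_name,
                 weights = weights,
                 background = background,
                 pseudocount_total = pseudocount_total),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat("Position weight matrix ", x$matrix_id, " (", x$tf_name, "), length ",
      ncol(x$weights), ", max score ", round(sum(apply(x$weights, 2, max)), 3),
      " bits\n", sep = "")
  print(round(x$weights, 3))
  invisible(x)
}

# ---- TSS-relative coordinates ----------------------------------------------
# EPD-style convention: there is no position 0; -1 is the base immediately
# upstream of the TSS and +1 the first transcribed base. A window
# (window_start, window_end) with window_start < 0 < window_end therefore
# spans window_end - window_start bases.

#' Convert 1-based sequence indices to TSS-relative positions
#'
#' @param idx 1-based indices into the window sequence.
#' @param window_start Negative TSS-relative window start (e.g. -5000).
#' @return Integer TSS-relative positions (never 0).
#' @export
tss_position <- function(idx, window_start) {
  u <- -as.integer(window_start)
  idx <- as.integer(idx)
  ifelse(idx <= u, idx - 1L - u, idx - u)
}

#' Convert TSS-relative positions to 1-based sequence indices
#'
#' @param pos TSS-relative positions (no 0).
#' @param window_start Negative TSS-relative window start.
#' @export
seq_index <- function(pos, window_start) {
  pos <- as.integer(pos)
  if (any(pos == 0L)) stop("position 0 does not exist in TSS-relative coordinates")
  u <- -as.integer(window_start)
  ifelse(pos < 0L, pos + u + 1L, pos + u)
}

window_length <- function(window_start, window_end) {
  as.integer(window_end) - as.integer(window_start)
}

new_promoter_set <- function(gene_id, gene_symbol, sequence,
                             window_start, window_end) {
  window_start <- as.integer(window_start)
  window_end <- as.integer(window_end)
  if (!(window_start < 0L && window_end > 0L)) {
    stop("promoter window must satisfy window_start < 0 < window_end")
  }
  if (anyDuplicated(gene_id)) {
    stop("duplicate gene_id in promoter set: ",
         paste(unique(gene_id[duplicated(gene_id)]), collapse = ", "))
  }
  sequence <- toupper(sequence)
  bad <- grepl("[^ACGTN]", sequence)
  if (any(bad)) {
    stop("promoter sequence for ", paste(gene_id[bad], collapse = ", "),
         " contains characters outside A/C/G/T/N")
  }
  want <- window_length(window_start, window_end)
  lens <- nchar(sequence)
  if (any(lens != want)) {
    off <- which(lens != want)
    stop("promoter sequence length mismatch for ",
         paste0(gene_id[off], " (", lens[off], " nt, expected ", want, ")",
                collapse = "; "))
  }
  structure(data.frame(gene_id = as.character(gene_id),
                       gene_symbol = as.character(gene_symbol),
                       sequence = sequence,
                       stringsAsFactors = FALSE),
            window_start = window_start,
            window_end = window_end,
            class = c("promoter_set", "data.frame"))
}

#' Read TSS-anchored promoter sequences from FASTA
#'
#' Headers follow the grammar `gene_id|gene_symbol`; when no `|` is present
#' the first whitespace-delimited token is taken as the gene id and also used
#' as the symbol (permissive fallback for externally exported FASTA). Every
#' sequence must have exactly `window_end - window_start` bases (there is no
#' position 0 in TSS-relative coordinates); `N` is allowed and windows
#' containing it are later skipped by the scanner.
#'
#' @param file FASTA path.
#' @param window_start,window_end TSS-relative window, default -5000..+1000.
#' @return A `promoter_set`: data frame with columns `gene_id`, `gene_symbol`,
#'   `sequence` and attributes `window_start`, `window_end`.
#' @export
read_promoters_fasta <- function(file, window_start = -5000, window_end = 1000) {
  seqs <- Biostrings::readDNAStringSet(file)
  headers <- names(seqs)
  first_tok <- vapply(strsplit(headers, "[ \t]+"), `[`, character(1), 1L)
  parts <- strsplit(first_tok, "|", fixed = TRUE)
  gene_id <- vapply(parts, `[`, character(1), 1L)
  gene_symbol <- vapply(parts, function(p) {
    if (length(p) >= 2L && nzchar(p[2L])) p[2L] else p[1L]
  }, character(1))
  new_promoter_set(gene_id, gene_symbol, as.character(seqs),
                   window_start, window_end)
}

#' Write a promoter set as FASTA
#'
#' @param promoters A `promoter_set`.
#' @param file Output path.
#' @param width Line width for sequence wrapping.
#' @export
write_promoters_fasta <- function(promoters, file, width = 70L) {
  stopifnot(inherits(promoters, "promoter_set"))
  con <- base::file(file, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(promoters))) {
    writeLines(paste0(">", promoters$gene_id[i], "|", promoters$gene_symbol[i]),
               con)
    s <- promoters$sequence[i]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(file)
}

#' @export
`[.promoter_set` <- function(x, i, ...) {
  out <- NextMethod()
  if (is.data.frame(out) && "sequence" %in% names(out)) {
    attr(out, "window_start") <- attr(x, "window_start")
    attr(out, "window_end") <- attr(x, "window_end")
    class(out) <- c("promoter_set", "data.frame")
  }
  out
}

#' @export
print.promoter_set <- function(x, ...) {
  cat("Promoter set: ", nrow(x), " gene(s), window ",
      attr(x, "window_start"), "..+", attr(x, "window_end"),
      " (", window_length(attr(x, "window_start"), attr(x, "window_end")),
      " nt, no position 0)\n", sep = "")
  print(data.frame(gene_id = x$gene_id, gene_symbol = x$gene_symbol,
                   length = nchar(x$sequence)))
  invisible(x)
}

#' Map transcription factors to their own genes
#'
#' Needed for autoregulation detection and binding-derived network edges:
#' records which scanned promoter belongs to the gene encoding each TF.
#'
#' @param tf Character vector of TF names (or matrix ids).
#' @param gene_id Character vector, same length, of promoter gene ids.
#' @return A validated data frame of class `tf_gene_map`.
#' @export
tf_gene_map <- function(tf, gene_id) {
  stopifnot(length(tf) == length(gene_id))
  df <- unique(data.frame(tf = as.character(tf),
                          gene_id = as.character(gene_id),
                          stringsAsFactors = FALSE))
  dup <- duplicated(df$tf)
  if (any(dup)) {
    stop("TF(s) mapped to more than one gene: ",
         paste(unique(df$tf[dup]), collapse = ", "))
  }
  structure(df, class = c("tf_gene_map", "data.frame"))
}

#' Read a two-column TF-to-gene map from TSV
#'
#' @param file Path to a headerless two-column TSV (tf, gene_id).
#' @export
read_tf_gene_map <- function(file) {
  df <- utils::read.table(file, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE,
                          col.names = c("tf", "gene_id"))
  tf_gene_map(df$tf, df$gene_id)
}
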