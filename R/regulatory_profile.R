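# Analytical products derived from hit tables: upstream/downstream count
# profiles at two stringency tiers, master-regulator sets, gene-specific TF
# sets, proximal-window profiles, autoregulatory-site reports and CArG-box
# matching.

#' Classify a hit as upstream or downstream of the TSS
#'
#' Upstream iff the TSS-relative start is <= -1, downstream iff >= +1 (there
#' is no position 0). Hits whose window spans the TSS are classified by their
#' 5' start.
#'
#' @param start Integer TSS-relative start position(s).
#' @return Character vector, `"upstream"` or `"downstream"`.
#' @export
classify_region <- function(start) {
  start <- as.integer(start)
  if (any(start == 0L)) stop("TSS-relative position 0 does not exist")
  ifelse(start <= -1L, "upstream", "downstream")
}

tier_levels <- c("lenient", "stringent")

# Rows of `hits` contributing to a tier: lenient = all hits (stringent hits
# are lenient hits too), stringent = stringent tier only.
tier_rows <- function(hits, tier) {
  if (tier == "lenient") rep(TRUE, nrow(hits)) else hits$tier == "stringent"
}

#' Per-gene upstream/downstream hit counts at both tiers
#'
#' Counts hit events (matrix, position, strand) per gene, split by region and
#' stringency tier, within a window. The `lenient` rows count all hits, the
#' `stringent` rows only stringent-tier hits, so stringent counts can never
#' exceed lenient counts.
#'
#' @param hits A `hit_table`.
#' @param window Length-2 integer window (start, end), default the full
#'   -5000..+1000 scan window.
#' @param gene_ids Optional character vector of all analyzed genes; genes
#'   without hits get zero rows, and hits for genes outside this set raise an
#'   error.
#' @return Data frame of class `profile_table` with columns `gene_id`,
#'   `tier`, `upstream`, `downstream`, plus a distinct-TF summary in
#'   attribute `n_distinct_tfs`.
#' @export
count_by_region <- function(hits, window = c(-5000L, 1000L), gene_ids = NULL) {
  stopifnot(inherits(hits, "data.frame"))
  if (is.null(gene_ids)) {
    gene_ids <- sort(unique(hits$gene_id))
  } else {
    extra <- setdiff(unique(hits$gene_id), gene_ids)
    if (length(extra)) {
      stop("hits reference gene(s) absent from the promoter set: ",
           paste(extra, collapse = ", "))
    }
  }
  inw <- hits$start >= window[1L] & hits$start <= window[2L]
  region <- classify_region(hits$start)
  out <- expand.grid(gene_id = gene_ids, tier = tier_levels,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out$upstream <- 0L
  out$downstream <- 0L
  ntf <- integer(nrow(out))
  for (r in seq_len(nrow(out))) {
    sel <- inw & hits$gene_id == out$gene_id[r] & tier_rows(hits, out$tier[r])
    out$upstream[r] <- sum(sel & region == "upstream")
    out$downstream[r] <- sum(sel & region == "downstream")
    ntf[r] <- length(unique(hits$tf_name[sel]))
  }
  structure(out, n_distinct_tfs = ntf,
            class = c("profile_table", "data.frame"))
}

agg_column <- function(hits, aggregation) {
  aggregation <- match.arg(aggregation, c("tf_name", "matrix_id"))
  hits[[aggregation]]
}

#' Identify master regulatory transcription factors
#'
#' A TF is a master regulator (MRTF) at a tier when it has at least one hit
#' of that tier in *every* analyzed promoter, regardless of binding position.
#' The core set is the intersection of the lenient and stringent MRTF sets;
#' for tiers taken from a single scan nesting makes the core equal to the
#' stringent set, but the intersection is kept general so hit tables from
#' different scans can be combined.
#'
#' @param hits A `hit_table`.
#' @param gene_ids Non-empty character vector of all analyzed promoters.
#' @param aggregation `"tf_name"` (a TF binds if any of its matrices hits,
#'   the default) or `"matrix_id"`.
#' @return List of class `mrtf_report` with sets `mrtf_lenient`,
#'   `mrtf_stringent`, `core`.
#' @export
find_mrtfs <- function(hits, gene_ids, aggregation = "tf_name") {
  stopifnot(length(gene_ids) >= 1L)
  tfs <- agg_column(hits, aggregation)
  set_at <- function(tier) {
    keep <- tier_rows(hits, tier)
    tab <- unique(data.frame(tf = tfs[keep], gene = hits$gene_id[keep]))
    tab <- tab[tab$gene %in% gene_ids, ]
    cover <- table(tab$tf)
    sort(names(cover)[cover == length(unique(gene_ids))])
  }
  len <- set_at("lenient")
  str <- set_at("stringent")
  structure(list(mrtf_lenient = len, mrtf_stringent = str,
                 core = intersect(len, str)),
            class = "mrtf_report")
}

#' @export
print.mrtf_report <- function(x, ...) {
  cat("Master regulator report:\n",
      "  lenient tier:   ", length(x$mrtf_lenient), " TF(s)\n",
      "  stringent tier: ", length(x$mrtf_stringent), " TF(s)\n",
      "  core (both):    ", paste(x$core, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Identify gene-specific transcription factors
#'
#' A TF is gene-specific when every one of its hits falls in a single
#' analyzed promoter (and it has at least one hit). Computed on the lenient
#' tier only: all hits count, whatever their stringency, and a TF with both a
#' lenient-only and a stringent hit in the same gene is listed once.
#'
#' @inheritParams find_mrtfs
#' @return Named list of class `gene_specific_report`: one element per gene
#'   (genes with no exclusive binder are omitted), each a sorted character
#'   vector of TF names. Sets are pairwise disjoint by construction.
#' @export
find_gene_specific <- function(hits, gene_ids, aggregation = "tf_name") {
  stopifnot(length(gene_ids) >= 1L)
  tfs <- agg_column(hits, aggregation)
  keep <- hits$gene_id %in% gene_ids
  tab <- unique(data.frame(tf = tfs[keep], gene = hits$gene_id[keep],
                           stringsAsFactors = FALSE))
  cover <- table(tab$tf)
  exclusive <- names(cover)[cover == 1L]
  tab <- tab[tab$tf %in% exclusive, ]
  out <- lapply(split(tab$tf, tab$gene), function(v) sort(unique(v)))
  structure(out[order(names(out))], class = "gene_specific_report")
}

#' @export
print.gene_specific_report <- function(x, ...) {
  cat("Gene-specific TF report (", sum(lengths(x)), " exclusive TF(s) over ",
      length(x), " gene(s)):\n", sep = "")
  for (g in names(x)) {
    cat("  ", g, ": ", paste(x[[g]], collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Detect autoregulatory binding sites
#'
#' For every TF with a mapped own gene, collects its hits inside its own
#' promoter (sorted by position) and flags TFs with at least one
#' stringent-tier own-promoter site.
#'
#' @param hits A `hit_table`.
#' @param map A `tf_gene_map` linking TF names to their own promoter
#'   gene ids; every mapped gene must be in `gene_ids`.
#' @param gene_ids Character vector of scanned promoter gene ids.
#' @return List of class `autoreg_report`: `sites`, a data frame with
#'   columns `tf`, `gene_id`, `start`, `strand`, `pvalue`, `tier`; and
#'   `summary` with per-TF site counts and `has_high_stringency_site`.
#' @export
detect_autoregulation <- function(hits, map, gene_ids) {
  stopifnot(inherits(map, "tf_gene_map"))
  missing <- !(map$gene_id %in% gene_ids)
  if (any(missing)) {
    stop("own gene not in the scanned promoter set for TF(s): ",
         paste(map$tf[missing], collapse = ", "))
  }
  own <- merge(hits, map, by.x = c("tf_name", "gene_id"),
               by.y = c("tf", "gene_id"))
  own <- own[order(own$tf_name, own$start), ]
  sites <- data.frame(tf = own$tf_name, gene_id = own$gene_id,
                      start = own$start, strand = own$strand,
                      pvalue = own$pvalue, tier = own$tier,
                      stringsAsFactors = FALSE)
  rownames(sites) <- NULL
  summary <- data.frame(tf = map$tf, gene_id = map$gene_id,
                        n_sites = vapply(map$tf, function(f)
                          sum(sites$tf == f), integer(1)),
                        has_high_stringency_site = vapply(map$tf, function(f)
                          any(sites$tf == f & sites$tier == "stringent"),
                          logical(1)),
                        stringsAsFactors = FALSE)
  rownames(summary) <- NULL
  structure(list(sites = sites, summary = summary), class = "autoreg_report")
}

#' @export
print.autoreg_report <- function(x, ...) {
  cat("Autoregulation report:\n")
  print(x$summary)
  invisible(x)
}

#' Proximal-window positions of selected TFs
#'
#' Restricts hits of a TF subset to a central promoter window (default
#' -500..+200) and returns their positions per TF and gene, for inspecting
#' TSS-proximal clustering.
#'
#' @param hits A `hit_table`.
#' @param tf_subset Character vector of TF names (default: all).
#' @param window Length-2 window, default `c(-500, 200)`.
#' @return Data frame with columns `tf_name`, `gene_id`, `start`, `strand`,
#'   `tier`, sorted by TF, gene and position.
#' @export
proximal_profile <- function(hits, tf_subset = NULL, window = c(-500L, 200L)) {
  keep <- hits$start >= window[1L] & hits$start <= window[2L]
  if (!is.null(tf_subset)) keep <- keep & hits$tf_name %in% tf_subset
  out <- hits[keep, c("tf_name", "gene_id", "start", "strand", "tier")]
  out <- out[order(out$tf_name, out$gene_id, out$start), ]
  rownames(out) <- NULL
  as.data.frame(out)
}

#' Match canonical CArG-boxes
#'
#' Finds all occurrences of the MADS-domain consensus `CC(A/T)6GG` on the
#' forward strand. The pattern equals its own reverse complement, so a
#' forward search covers both strands; matches cannot overlap.
#'
#' @param sequence DNA string over A/C/G/T/N.
#' @param window_start Optional negative window start; when given, reported
#'   positions are TSS-relative (position of the first base of the match),
#'   otherwise 1-based string offsets.
#' @return Data frame with columns `position`, `word`.
#' @examples
#' match_carg("CCAATTAAGG")  # one match at position 1
#' @export
match_carg <- function(sequence, window_start = NULL) {
  sequence <- toupper(sequence)
  m <- gregexpr("CC[AT]{6}GG", sequence)[[1L]]
  if (m[1L] == -1L) {
    return(data.frame(position = integer(0), word = character(0)))
  }
  pos <- as.integer(m)
  word <- substring(sequence, pos, pos + 9L)
  if (!is.null(window_start)) pos <- tss_position(pos, window_start)
  data.frame(position = pos, word = word, stringsAsFactors = FALSE)
}

#' Write profile reports as TSV
#'
#' Small serializers for the report objects: profile tables (`gene_id`,
#' `tier`, `upstream`, `downstream`), gene-specific reports (`gene_id`, `tf`)
#' and autoregulation reports (site rows).
#'
#' @param x A `profile_table`, `gene_specific_report` or `autoreg_report`.
#' @param file Path.
#' @export
write_report_tsv <- function(x, file) {
  df <- if (inherits(x, "gene_specific_report")) {
    data.frame(gene_id = rep(names(x), lengths(x)),
               tf = unlist(x, use.names = FALSE))
  } else if (inherits(x, "autoreg_report")) {
    x$sites
  } else {
    as.data.frame(x)
  }
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
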