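# Seeded generators with known ground truth: matrix libraries of controlled
# sharpness, promoter windows with planted motifs, fabricated hit tables for
# fast profiling tests, and replicate count matrices. All generators are pure
# functions of (seed, configuration): the same call yields identical output.

#' Simulate a library of position frequency matrices
#'
#' Each column places `sharpness` of the probability mass on one consensus
#' base (drawn at random) and splits the remainder as evenly as possible
#' across the other three, so the per-column maximum probability is
#' approximately `sharpness` exactly by construction. `sharpness = 1` gives a
#' single positive count per column.
#'
#' @param n Number of matrices.
#' @param motif_length Length-2 range (min, max) of motif lengths, sampled
#'   uniformly; a single value fixes the length.
#' @param sharpness Target per-column maximum probability, in (0.25, 1].
#' @param counts_per_column Total count per column (default 100).
#' @param seed Integer seed; the generator is deterministic given it.
#' @param id_prefix Matrix id prefix; ids are `<prefix>001` ... and TF names
#'   `TF001` ...
#' @return List of `pfm` objects.
#' @export
simulate_pwms <- function(n, motif_length = c(10L, 10L), sharpness = 0.97,
                          counts_per_column = 100L, seed = NULL,
                          id_prefix = "SYN") {
  if (!is.numeric(sharpness) || sharpness <= 0.25 || sharpness > 1) {
    stop("sharpness must lie in (0.25, 1]: a column maximum below 0.25 ",
         "cannot be the maximum of four probabilities")
  }
  if (length(motif_length) == 1L) motif_length <- rep(motif_length, 2L)
  if (!is.null(seed)) set.seed(seed)
  lapply(seq_len(n), function(k) {
    L <- if (motif_length[1L] == motif_length[2L]) {
      as.integer(motif_length[1L])
    } else {
      sample(seq(motif_length[1L], motif_length[2L]), 1L)
    }
    counts <- matrix(0, 4L, L)
    cons <- sample.int(4L, L, replace = TRUE)
    for (j in seq_len(L)) {
      top <- round(sharpness * counts_per_column)
      rest <- counts_per_column - top
      others <- setdiff(1:4, cons[j])
      share <- rep(rest %/% 3L, 3L)
      extra <- rest %% 3L
      if (extra > 0L) share[seq_len(extra)] <- share[seq_len(extra)] + 1L
      counts[cons[j], j] <- top
      counts[others, j] <- share
    }
    new_pfm(sprintf("%s%03d", id_prefix, k), sprintf("TF%03d", k), counts)
  })
}

#' Simulate promoter windows with planted motifs
#'
#' Background bases are drawn i.i.d. from `composition`; each planted motif
#' overwrites the background with the matrix consensus at the stated
#' TSS-relative position and strand (for strand `-`, the reverse complement
#' of the consensus is written on the forward strand), so window lengths are
#' invariant and ground truth exact. Overlapping plants are rejected with an
#' error naming the colliding pair rather than silently shifted.
#'
#' @param n_genes Number of promoters; gene ids are `gene01` ...
#' @param pwms List of `pfm` or `pwm` objects referenced by the plant plan
#'   (consensus is taken from counts for `pfm`s, from weights for `pwm`s).
#' @param plant_plan Data frame with columns `gene_id`, `matrix_id`,
#'   `position` (TSS-relative 5' start), `strand`; NULL plants nothing.
#' @param window TSS-relative window, default -5000..+1000.
#' @param composition Background base probabilities (A, C, G, T).
#' @param seed Integer seed.
#' @return List with `promoters` (a `promoter_set`) and `truth` (the plant
#'   plan augmented with the planted forward-strand word).
#' @export
simulate_promoters <- function(n_genes, pwms = list(), plant_plan = NULL,
                               window = c(-5000L, 1000L),
                               composition = rep(0.25, 4), seed = NULL) {
  composition <- as.numeric(composition)
  if (length(composition) != 4L || any(composition < 0) ||
      abs(sum(composition) - 1) > 1e-9) {
    stop("composition must be 4 non-negative probabilities summing to 1")
  }
  ws <- as.integer(window[1L]); we <- as.integer(window[2L])
  len <- window_length(ws, we)
  if (!is.null(seed)) set.seed(seed)
  gene_id <- sprintf("gene%02d", seq_len(n_genes))
  seqs <- vapply(seq_len(n_genes), function(i) {
    paste(sample(DNA_BASES, len, replace = TRUE, prob = composition),
          collapse = "")
  }, character(1))

  truth <- data.frame(gene_id = character(0), matrix_id = character(0),
                      position = integer(0), strand = character(0),
                      word = character(0), stringsAsFactors = FALSE)
  if (!is.null(plant_plan) && nrow(plant_plan)) {
    cons_of <- function(id) {
      for (p in pwms) {
        if (p$matrix_id == id) {
          if (inherits(p, "pfm")) return(pfm_consensus(p))
          return(paste(DNA_BASES[apply(p$weights, 2L, which.max)],
                       collapse = ""))
        }
      }
      stop("plant plan references unknown matrix_id '", id, "'")
    }
    plant_plan$word <- NA_character_
    plant_plan$.from <- NA_integer_
    plant_plan$.to <- NA_integer_
    for (r in seq_len(nrow(plant_plan))) {
      word <- cons_of(plant_plan$matrix_id[r])
      if (plant_plan$strand[r] == "-") word <- reverse_complement(word)
      from <- seq_index(plant_plan$position[r], ws)
      to <- from + nchar(word) - 1L
      if (from < 1L || to > len) {
        stop("plant of ", plant_plan$matrix_id[r], " at ",
             plant_plan$position[r], " in ", plant_plan$gene_id[r],
             " does not fit inside the window")
      }
      plant_plan$word[r] <- word
      plant_plan$.from[r] <- from
      plant_plan$.to[r] <- to
    }
    # collision check per gene, then overwrite background
    for (g in unique(plant_plan$gene_id)) {
      rows <- which(plant_plan$gene_id == g)
      if (length(rows) > 1L) {
        for (a in seq_along(rows)) for (b in seq_along(rows)) {
          if (a < b) {
            ra <- rows[a]; rb <- rows[b]
            if (plant_plan$.from[ra] <= plant_plan$.to[rb] &&
                plant_plan$.from[rb] <= plant_plan$.to[ra]) {
              stop("overlapping plants in ", g, ": ",
                   plant_plan$matrix_id[ra], " at ", plant_plan$position[ra],
                   " and ", plant_plan$matrix_id[rb], " at ",
                   plant_plan$position[rb])
            }
          }
        }
      }
      gi <- match(g, gene_id)
      if (is.na(gi)) stop("plant plan references unknown gene '", g, "'")
      for (r in rows) {
        substr(seqs[gi], plant_plan$.from[r], plant_plan$.to[r]) <-
          plant_plan$word[r]
      }
    }
    truth <- plant_plan[, c("gene_id", "matrix_id", "position", "strand", "word")]
  }
  list(promoters = new_promoter_set(gene_id, gene_id, seqs, ws, we),
       truth = truth)
}

#' Fabricate a hit table with known profiling answers
#'
#' Builds a `hit_table` directly (bypassing scanning) with designated master
#' regulators hitting every gene at both tiers and designated exclusive TFs
#' hitting exactly one gene each, for fast unit tests of the profiling
#' operations. Tier nesting is enforced by construction (stringent hits carry
#' p-values below the stringent threshold, lenient-only hits between the two
#' thresholds).
#'
#' @param n_genes Number of genes (>= 2: with a single gene every binding TF
#'   would be both "all genes" and "one gene", so the generator refuses).
#' @param n_mrtfs Number of designated master regulators.
#' @param n_specific Number of designated gene-specific TFs, spread
#'   round-robin over the genes.
#' @param thresholds A `scan_thresholds`.
#' @param window TSS-relative window for fabricated positions.
#' @param seed Integer seed (positions and strands are random).
#' @return List with `hits`, `gene_ids`, `mrtfs` (designated names),
#'   `gene_specific` (named list gene -> TF names) and `profile` (the
#'   expected per-gene/tier upstream/downstream counts).
#' @export
make_profile_fixture <- function(n_genes = 18L, n_mrtfs = 3L,
                                 n_specific = 96L,
                                 thresholds = scan_thresholds(),
                                 window = c(-5000L, 1000L), seed = NULL) {
  if (n_genes < 2L) {
    stop("a single gene makes 'binds all genes' and 'binds one gene' ",
         "coincide; use n_genes >= 2")
  }
  if (!is.null(seed)) set.seed(seed)
  gene_ids <- sprintf("gene%02d", seq_len(n_genes))
  mrtfs <- sprintf("MRTF%02d", seq_len(n_mrtfs))
  specifics <- sprintf("SPEC%03d", seq_len(n_specific))
  if (length(intersect(mrtfs, specifics))) {
    stop("a TF cannot be both a master regulator and gene-specific")
  }
  p_len <- thresholds$lenient_p / 2 + thresholds$stringent_p / 2
  p_str <- thresholds$stringent_p / 2
  rand_pos <- function(n) {
    p <- sample(setdiff(seq(window[1L], window[2L] - 10L), 0L), n)
    as.integer(p)
  }
  rows <- list()
  add <- function(tf, gene, tier) {
    pos <- rand_pos(1L)
    rows[[length(rows) + 1L]] <<- data.frame(
      matrix_id = paste0("MX_", tf), tf_name = tf, gene_id = gene,
      start = pos, end = pos + 9L + (pos < 0 && pos + 9L >= 0),
      strand = sample(c("+", "-"), 1L),
      score_bits = 10, pvalue = if (tier == "stringent") p_str else p_len,
      tier = tier, stringsAsFactors = FALSE)
  }
  for (tf in mrtfs) for (g in gene_ids) {
    add(tf, g, "stringent")   # stringent in every gene -> core MRTF
    add(tf, g, "lenient-only")
  }
  spec_gene <- gene_ids[(seq_len(n_specific) - 1L) %% n_genes + 1L]
  for (k in seq_len(n_specific)) add(specifics[k], spec_gene[k], "lenient-only")
  hits <- do.call(rbind, rows)
  dup <- duplicated(paste(hits$matrix_id, hits$gene_id, hits$start, hits$strand))
  hits <- hits[!dup, ]
  expected <- count_by_region(
    structure(hits, class = c("hit_table", "data.frame")),
    window = window, gene_ids = gene_ids)
  validate_hits(hits, thresholds)
  list(hits = as_hit_table(hits),
       gene_ids = gene_ids,
       mrtfs = mrtfs,
       gene_specific = lapply(split(specifics, spec_gene), sort),
       profile = expected)
}

#' Simulate a replicate count matrix
#'
#' Per-gene counts are drawn from a negative binomial with mean
#' `rate * lib_size / 1e6` (so `rate` is the expected RPM) and variance
#' `mu + dispersion * mu^2`; `dispersion = 0` gives Poisson draws. Library
#' sizes are inputs, as in real pipelines where they come from the aligner.
#'
#' @param rates Named numeric vector of per-gene expected RPM (>= 0).
#' @param lib_sizes Named numeric vector of per-sample total mapped reads.
#' @param gene_lengths Per-gene length in bp (default 1000, making the
#'   analytic RPKM equal to the RPM rate).
#' @param dispersion Negative binomial dispersion (>= 0).
#' @param seed Integer seed.
#' @return List with `cm` (a `count_matrix`) and `rates`.
#' @export
simulate_counts <- function(rates, lib_sizes, gene_lengths = 1000,
                            dispersion = 0.1, seed = NULL) {
  if (dispersion < 0) stop("dispersion must be >= 0")
  if (any(rates < 0)) stop("rates must be >= 0")
  if (is.null(names(rates))) names(rates) <- sprintf("gene%02d", seq_along(rates))
  if (is.null(names(lib_sizes))) {
    names(lib_sizes) <- sprintf("sample%d", seq_along(lib_sizes))
  }
  if (length(gene_lengths) == 1L) gene_lengths <- rep(gene_lengths, length(rates))
  if (!is.null(seed)) set.seed(seed)
  mu <- outer(rates, lib_sizes) / 1e6
  draw <- if (dispersion == 0) {
    function(m) stats::rpois(length(m), m)
  } else {
    function(m) stats::rnbinom(length(m), mu = m, size = 1 / dispersion)
  }
  counts <- matrix(draw(mu), nrow = length(rates),
                   dimnames = list(names(rates), names(lib_sizes)))
  counts[rates == 0, ] <- 0L
  lib <- pmax(lib_sizes, colSums(counts))
  list(cm = count_matrix(counts, lib, gene_lengths), rates = rates)
}

#' Planted-motif recovery experiment
#'
#' Assembles the package's reference synthetic study: `n_genes` uniform
#' promoters over the full window, a library of `n_matrices` sharp motifs, of
#' which the first three are planted (as consensus) in every gene, and two
#' further matrices are each planted in exactly one gene -- one of them on
#' the forward strand at position -1024, mirroring a biologically notable
#' upstream autoregulatory site position. The collection is scanned at the
#' default dual thresholds and profiled.
#'
#' @param seed Integer seed driving both the matrix and promoter generators.
#' @param n_genes,n_matrices,motif_length,sharpness,window,composition Study
#'   conditions; defaults are the reference configuration.
#' @return List with the inputs (`pwms`, `promoters`, `truth`, `plan`), the
#'   scan (`hits`), the derived reports (`mrtf_report`,
#'   `gene_specific_report`) and the designated ground truth (`mrtf_truth`,
#'   `specific_truth`).
#' @export
planted_motif_experiment <- function(seed = 42L, n_genes = 18L,
                                     n_matrices = 20L, motif_length = 10L,
                                     sharpness = 0.97,
                                     window = c(-5000L, 1000L),
                                     composition = rep(0.25, 4)) {
  pfms <- simulate_pwms(n_matrices, motif_length, sharpness, seed = seed)
  ids <- vapply(pfms, function(p) p$matrix_id, character(1))
  tfs <- vapply(pfms, function(p) p$tf_name, character(1))
  gene_ids <- sprintf("gene%02d", seq_len(n_genes))

  mrtf_ids <- ids[1:3]
  excl_ids <- ids[4:5]
  plan <- rbind(
    expand.grid(gene_id = gene_ids, matrix_id = mrtf_ids,
                KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE),
    data.frame(gene_id = gene_ids[c(1L, 2L)], matrix_id = excl_ids,
               stringsAsFactors = FALSE))
  plan$position <- c(rep(c(-4500L, -3000L, 500L), each = n_genes),
                     -1024L, -2000L)
  plan$strand <- c(rep("+", 3L * n_genes), "+", "-")

  sim <- simulate_promoters(n_genes, pfms, plan, window, composition,
                            seed = seed + 1L)
  pwms <- lapply(pfms, pfm_to_pwm)
  hits <- scan_collection(pwms, sim$promoters)
  list(pwms = pwms, promoters = sim$promoters, truth = sim$truth, plan = plan,
       hits = hits,
       mrtf_report = find_mrtfs(hits, gene_ids),
       gene_specific_report = find_gene_specific(hits, gene_ids),
       mrtf_truth = sort(tfs[1:3]),
       specific_truth = list(gene01 = tfs[4L], gene02 = tfs[5L]))
}
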