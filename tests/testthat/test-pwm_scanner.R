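test_that("word scoring is additive, strand-symmetric and N-aware", {
  zero <- pfm_to_pwm(pfm("Z", "Z", matrix(1, 4, 4)))  # all weights 0
  expect_equal(score_window(zero, "ACGT"), 0)
  expect_equal(score_window(zero, "TTTT"), 0)

  sharp <- pfm_to_pwm(sharp_pfm("ACGTTGCA"))
  expect_equal(score_window(sharp, "ACGTTGCA"),
               sum(apply(sharp$weights, 2, max)))

  set.seed(101)
  for (i in 1:20) {
    word <- paste(sample(c("A", "C", "G", "T"), 8, replace = TRUE),
                  collapse = "")
    expect_equal(score_window(sharp, word, "-"),
                 score_window(sharp, reverse_complement(word), "+"))
  }
  expect_true(is.na(score_window(sharp, "ACGTNGCA")))
  expect_error(score_window(sharp, "ACGT"), "length")
})

test_that("exact score distribution equals brute-force enumeration", {
  # degenerate: L = 1, all-zero weights -> single mass point at 0
  d0 <- score_distribution(pfm_to_pwm(pfm("Z", "Z", matrix(1, 4, 1))))
  sup0 <- score_support(d0)
  expect_equal(nrow(sup0), 1L)
  expect_equal(sup0$score, 0)
  expect_equal(sup0$prob, 1)

  # L = 2 with distinct columns, plus random PWMs with a non-uniform
  # background, against full enumeration of all 4^L words
  set.seed(7)
  cases <- c(list(pfm_to_pwm(pfm("T2", "T2",
                                 matrix(c(8, 1, 1, 0, 2, 2, 5, 1), 4, 2)))),
             lapply(c(1L, 3L, 4L, 6L), function(L)
               random_pwm(L, background_model(c(0.3, 0.2, 0.2, 0.3)))))
  for (pwm in cases) {
    d <- score_distribution(pwm)
    bf <- brute_force_dist(pwm)
    keep <- d$probs > 0
    expect_equal(d$min_score + which(keep) - 1, bf$score)
    expect_equal(d$probs[keep], bf$prob, tolerance = 1e-12)
    expect_equal(d$tail[keep], rev(cumsum(rev(bf$prob))), tolerance = 1e-12)
  }

  # conservation of probability over many random matrices
  set.seed(8)
  for (i in 1:50) {
    d <- score_distribution(random_pwm(sample(1:8, 1)))
    expect_equal(sum(d$probs), 1, tolerance = 1e-9)
  }
})

test_that("p-value and cutoff semantics honour strict inequality", {
  zero <- pfm_to_pwm(pfm("Z", "Z", matrix(1, 4, 2)))
  d <- score_distribution(zero)
  # P(S >= 0) = 1, which is not < 1: cutoff(1) is one grid unit above 0
  # and no word can ever pass
  expect_equal(score_cutoff(d, 1), 1 / d$grid_scale)
  expect_equal(pvalue_of_score(d, 0), 1)
  expect_error(score_cutoff(d, 0), "\\(0, 1\\]")
  expect_error(score_cutoff(d, 1.5), "\\(0, 1\\]")

  # unique-maximum tail of a sharp 10-mer: consensus p-value is 4^-10,
  # passing both default thresholds
  sharp <- pfm_to_pwm(sharp_pfm("ACGTACGTAC", 0.97))
  ds <- score_distribution(sharp)
  pmax_ <- word_pvalue(sharp, "ACGTACGTAC", ds)
  expect_equal(pmax_, 4^-10, tolerance = 1e-12)
  expect_lt(pmax_, 1e-5)

  # cutoff at p = 0.1 for random L = 4 PWMs agrees with enumeration
  set.seed(9)
  for (i in 1:5) {
    pwm <- random_pwm(4L)
    d4 <- score_distribution(pwm)
    bf <- brute_force_dist(pwm)
    for (p in c(0.1, 1e-2, 1e-4)) {
      expect_equal(score_cutoff(d4, p) * d4$grid_scale,
                   brute_force_cutoff(bf, p))
    }
  }
})

test_that("scanning recovers a planted consensus at its TSS-relative start", {
  cons <- "GCGTAACGTC"
  pfm_sharp <- sharp_pfm(cons, 0.97, matrix_id = "PL1")
  sim <- simulate_promoters(
    1L, list(pfm_sharp),
    data.frame(gene_id = "gene01", matrix_id = "PL1",
               position = -1024L, strand = "+"),
    seed = 500)
  hits <- scan_promoter(pfm_to_pwm(pfm_sharp), sim$promoters)
  at <- hits[hits$start == -1024L, ]
  expect_equal(nrow(at), 1L)
  expect_equal(at$strand, "+")
  expect_equal(at$tier, "stringent")
  expect_equal(at$end, -1015L)
  expect_lt(at$pvalue, 1e-5)

  # determinism: an identical rescan yields a byte-identical table
  hits2 <- scan_promoter(pfm_to_pwm(pfm_sharp), sim$promoters)
  expect_identical(as.data.frame(hits), as.data.frame(hits2))
})

test_that("stringent hits equal a fresh scan at the stringent threshold", {
  set.seed(21)
  pfms <- simulate_pwms(4, 10L, 0.9, seed = 21)
  pwms <- lapply(pfms, pfm_to_pwm)
  plan <- data.frame(gene_id = c("gene01", "gene02"),
                     matrix_id = c("SYN001", "SYN002"),
                     position = c(-150L, 80L), strand = c("+", "-"))
  prom <- simulate_promoters(3L, pfms, plan, window = c(-1000L, 500L),
                             seed = 22)$promoters
  full <- scan_collection(pwms, prom)
  expect_true(all(full$pvalue < 1e-4))
  expect_equal(full$tier == "stringent", full$pvalue < 1e-5)

  restr <- scan_collection(pwms, prom,
                           scan_thresholds(lenient_p = 1e-5,
                                           stringent_p = 1e-6))
  key <- function(h) paste(h$matrix_id, h$gene_id, h$start, h$strand)
  expect_setequal(key(full[full$tier == "stringent", ]), key(restr))
  # nesting: stringent hit set is a subset of the lenient hit set
  expect_true(all(key(restr) %in% key(full)))
})

test_that("reverse-complementing promoters mirrors the hit set", {
  set.seed(33)
  pfms <- simulate_pwms(2, 8L, 0.92, seed = 33)
  pwms <- lapply(pfms, pfm_to_pwm)
  th <- scan_thresholds(1e-2, 1e-3)  # permissive: keep the mirrored sets non-empty
  for (rep in 1:10) {
    prom <- random_promoter_set(1L, c(-300L, 300L))
    hits <- scan_collection(pwms, prom, th)
    rc <- prom
    rc$sequence <- reverse_complement(prom$sequence)
    hits_rc <- scan_collection(pwms, rc, th)
    expect_gt(nrow(hits), 0L)
    # index-space mirror: a hit starting at index i (1-based, length L)
    # maps to index n - (i + L - 1) + 1 on the flipped strand
    n <- nchar(prom$sequence)
    mirror_start <- tss_position(
      n - seq_index(hits$end, -300L) + 1L, -300L)
    expect_setequal(
      paste(hits$matrix_id, mirror_start, ifelse(hits$strand == "+", "-", "+"),
            round(hits$score_bits, 6)),
      paste(hits_rc$matrix_id, hits_rc$start, hits_rc$strand,
            round(hits_rc$score_bits, 6)))
  }
})

test_that("N-containing windows are skipped and tallied, not scored", {
  prom <- simulate_promoters(1L, window = c(-50L, 50L), seed = 4)$promoters
  s <- prom$sequence
  substr(s, 40, 40) <- "N"
  prom$sequence <- s
  hits <- scan_collection(list(pfm_to_pwm(sharp_pfm("ACGTACGT", 0.97))), prom)
  expect_false(any(is.na(hits$score_bits)))
  expect_equal(attr(hits, "provenance")$n_masked, 8L)  # 8 windows cover pos 40
})

test_that("collection scans compose, sort stably and validate the library", {
  pfms <- simulate_pwms(2, 7L, 0.95, seed = 51)
  pwms <- lapply(pfms, pfm_to_pwm)
  plan <- expand.grid(gene_id = sprintf("gene%02d", 1:3),
                      matrix_id = c("SYN001", "SYN002"),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  plan$position <- c(-90L, -60L, -30L, 20L, 50L, 80L)
  plan$strand <- "+"
  prom <- simulate_promoters(3L, pfms, plan, window = c(-150L, 150L),
                             seed = 52)$promoters
  all_hits <- scan_collection(pwms, prom)
  # per-pair subsets equal individual scans
  for (m in 1:2) for (g in 1:3) {
    single <- scan_promoter(pwms[[m]], prom[g, ])
    sub <- all_hits[all_hits$matrix_id == pwms[[m]]$matrix_id &
                      all_hits$gene_id == prom$gene_id[g], ]
    expect_equal(as.data.frame(sub)[order(sub$start, sub$strand), ],
                 as.data.frame(single)[order(single$start, single$strand), ],
                 ignore_attr = TRUE)
  }
  expect_error(scan_collection(c(pwms, pwms[1]), prom), "duplicate matrix_id")
  expect_equal(nrow(scan_collection(list(), prom)), 0L)

  # TSV round-trip preserves hits
  f <- withr::local_tempfile(fileext = ".tsv")
  write_hits_tsv(all_hits, f)
  expect_equal(as.data.frame(read_hits_tsv(f)), as.data.frame(all_hits),
               ignore_attr = TRUE)

  # BED export: 0-based half-open, within-window coordinates
  fb <- withr::local_tempfile(fileext = ".bed")
  hits_to_bed(all_hits, fb)
  bed <- read.table(fb, sep = "\t")
  expect_equal(nrow(bed), nrow(all_hits))
  expect_true(all(bed$V3 - bed$V2 == 7L))
  expect_true(all(bed$V2 >= 0 & bed$V3 <= 300))
  expect_true(all(bed$V5 >= 0 & bed$V5 <= 1000))
})

test_that("grid refinement moves p-values by at most one grid cell's mass", {
  set.seed(61)
  pwm <- random_pwm(5L)
  d_lo <- score_distribution(pwm, grid_scale = 1000L)
  d_hi <- score_distribution(pwm, grid_scale = 10000L)
  words <- replicate(25, paste(sample(c("A", "C", "G", "T"), 5, replace = TRUE),
                               collapse = ""))
  for (w in words) {
    p_lo <- word_pvalue(pwm, w, d_lo)
    p_hi <- word_pvalue(pwm, w, d_hi)
    cell <- max(d_lo$probs)
    expect_lte(abs(p_lo - p_hi), cell + 1e-12)
  }
})

test_that("windows shorter than the motif warn and yield no hits", {
  pwm <- pfm_to_pwm(sharp_pfm("ACGTACGTAC"))
  prom <- simulate_promoters(1L, window = c(-4L, 4L), seed = 2)$promoters
  expect_warning(h <- scan_promoter(pwm, prom), "shorter than motif")
  expect_equal(nrow(h), 0L)
})
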