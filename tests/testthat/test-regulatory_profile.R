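mk_hits <- function(df) {
  df$matrix_id <- paste0("MX_", df$tf_name)
  df$end <- df$start + 9L
  df$score_bits <- 10
  df$pvalue <- ifelse(df$tier == "stringent", 5e-6, 5e-5)
  structure(df, class = c("hit_table", "data.frame"))
}

test_that("region classification splits at the missing position 0", {
  expect_equal(classify_region(-1L), "upstream")
  expect_equal(classify_region(1L), "downstream")
  # a hit starting at -3 spans the TSS but is classified by its 5' start
  expect_equal(classify_region(-3L), "upstream")
  expect_error(classify_region(0L), "position 0")
})

test_that("upstream/downstream counts split by tier without double counting", {
  h <- mk_hits(data.frame(
    tf_name = c("A", "A", "B", "C", "C"),
    gene_id = "g1",
    start = c(-300L, -200L, -100L, 10L, 20L),
    strand = "+",
    tier = c("stringent", "lenient-only", "lenient-only",
             "lenient-only", "lenient-only"),
    stringsAsFactors = FALSE))
  pt <- count_by_region(h, window = c(-5000L, 1000L))
  len <- pt[pt$tier == "lenient", ]
  str <- pt[pt$tier == "stringent", ]
  expect_equal(c(len$upstream, len$downstream), c(3L, 2L))
  expect_equal(c(str$upstream, str$downstream), c(1L, 0L))

  # empty table -> all-zero rows for the declared genes
  empty <- count_by_region(h[0, ], gene_ids = c("g1", "g2"))
  expect_equal(sum(empty$upstream + empty$downstream), 0L)
  expect_equal(nrow(empty), 4L)

  expect_error(count_by_region(h, gene_ids = "other"), "absent")
})

test_that("count additivity holds on a fabricated fixture", {
  fx <- make_profile_fixture(n_genes = 6, n_mrtfs = 3, n_specific = 12,
                             seed = 71)
  pt <- fx$profile
  for (g in fx$gene_ids) for (tier in c("lenient", "stringent")) {
    row <- pt[pt$gene_id == g & pt$tier == tier, ]
    inw <- fx$hits$gene_id == g &
      fx$hits$start >= -5000L & fx$hits$start <= 1000L
    if (tier == "stringent") inw <- inw & fx$hits$tier == "stringent"
    expect_equal(row$upstream + row$downstream, sum(inw))
  }
  # stringent counts never exceed lenient counts per cell
  len <- pt[pt$tier == "lenient", c("upstream", "downstream")]
  str <- pt[pt$tier == "stringent", c("upstream", "downstream")]
  expect_true(all(str <= len))
})

test_that("master regulators are TFs hitting every promoter", {
  h <- mk_hits(data.frame(
    tf_name = c("A", "A", "A", "B", "B", "C"),
    gene_id = c("g1", "g2", "g3", "g1", "g2", "g2"),
    start = c(-10L, -20L, -30L, -40L, -50L, -60L),
    strand = "+",
    tier = c("stringent", "stringent", "stringent",
             "lenient-only", "lenient-only", "lenient-only"),
    stringsAsFactors = FALSE))
  rep_ <- find_mrtfs(h, c("g1", "g2", "g3"))
  expect_equal(rep_$mrtf_lenient, "A")
  expect_equal(rep_$mrtf_stringent, "A")
  expect_equal(rep_$core, "A")
  # nesting: with tiers from one scan the stringent set is within the lenient
  expect_true(all(rep_$mrtf_stringent %in% rep_$mrtf_lenient))
})

test_that("gene-specific TFs bind exactly one promoter, lenient tier only", {
  h <- mk_hits(data.frame(
    tf_name = c("A", "A", "A", "C", "C", "D"),
    gene_id = c("g1", "g2", "g3", "g2", "g2", "g3"),
    start = c(-10L, -20L, -30L, -40L, -45L, 15L),
    strand = "+",
    tier = c("lenient-only", "lenient-only", "lenient-only",
             "lenient-only", "stringent", "lenient-only"),
    stringsAsFactors = FALSE))
  gs <- find_gene_specific(h, c("g1", "g2", "g3"))
  # C has a lenient and a stringent hit, both in g2: listed once, under g2
  expect_equal(gs$g2, "C")
  expect_equal(gs$g3, "D")
  # the all-gene binder A is listed nowhere
  expect_false("A" %in% unlist(gs))
  # disjointness of the per-gene sets
  expect_equal(anyDuplicated(unlist(gs)), 0L)
  # MRTF and gene-specific sets cannot intersect with >= 2 genes
  expect_length(intersect(unlist(gs),
                          find_mrtfs(h, c("g1", "g2", "g3"))$mrtf_lenient), 0L)
})

test_that("autoregulation report lists own-promoter sites sorted, with flags", {
  pos <- c(-3851L, -2567L, -2495L, -1287L, -1024L, -971L)
  h <- mk_hits(data.frame(
    tf_name = "PI",
    gene_id = "AT5G20240",
    start = sample(pos),  # deliberately unsorted input
    strand = "+",
    tier = "lenient-only",
    stringsAsFactors = FALSE))
  h$tier[h$start == -1024L] <- "stringent"
  h$pvalue <- ifelse(h$tier == "stringent", 5e-6, 5e-5)
  h2 <- mk_hits(data.frame(
    tf_name = "SEP3", gene_id = "AT1G24260", start = 466L, strand = "+",
    tier = "stringent", stringsAsFactors = FALSE))
  hits <- structure(rbind(h, h2), class = c("hit_table", "data.frame"))
  map <- tf_gene_map(c("PI", "SEP3", "LFY"),
                     c("AT5G20240", "AT1G24260", "AT5G61850"))
  rep_ <- detect_autoregulation(hits, map,
                                c("AT5G20240", "AT1G24260", "AT5G61850"))
  pi_sites <- rep_$sites[rep_$sites$tf == "PI", ]
  expect_equal(pi_sites$start, sort(pos))
  expect_equal(nrow(pi_sites), 6L)
  s <- rep_$summary
  expect_true(s$has_high_stringency_site[s$tf == "PI"])
  expect_equal(pi_sites$start[pi_sites$tier == "stringent"], -1024L)
  expect_true(s$has_high_stringency_site[s$tf == "SEP3"])
  expect_equal(s$n_sites[s$tf == "LFY"], 0L)
  expect_false(s$has_high_stringency_site[s$tf == "LFY"])
  expect_error(
    detect_autoregulation(hits, tf_gene_map("AP1", "AT1G69120"),
                          c("AT5G20240")),
    "AP1")
})

test_that("proximal profiles keep the -500..+200 window inclusively", {
  bpc1 <- c(-62L, -50L, -35L, -14L, -6L, 2L, 16L, 18L, 20L, 25L, 39L, 40L,
            53L, 57L, 69L, 94L, 102L, 110L, 112L)
  h <- mk_hits(data.frame(
    tf_name = c(rep("BPC1", length(bpc1)), "OBP3", "OBP3", "OBP3", "OBP3"),
    gene_id = "g1",
    start = c(bpc1, -424L, -501L, 200L, 201L),
    strand = "+",
    tier = "lenient-only",
    stringsAsFactors = FALSE))
  px <- proximal_profile(h, c("BPC1", "OBP3"))
  expect_equal(sort(px$start[px$tf_name == "BPC1"]), bpc1)
  expect_true(-424L %in% px$start)
  expect_true(200L %in% px$start)
  expect_false(-501L %in% px$start)
  expect_false(201L %in% px$start)
  expect_equal(nrow(proximal_profile(h, character(0))), 0L)
})

test_that("CArG matcher finds CC(A/T)6GG and agrees with enumeration", {
  one <- match_carg("CCAATTAAGG")
  expect_equal(one$position, 1L)
  expect_equal(one$word, "CCAATTAAGG")
  expect_equal(nrow(match_carg("CCAATTACGG")), 0L)  # C inside the A/T core

  # the pattern is its own reverse complement
  seqs <- c("TTCCAAATTTGGAT", "CCAATTAAGGCCTTTTTTGG", "GGGGAAAACCCC")
  for (s in seqs) {
    fwd <- match_carg(s)$position
    expect_equal(fwd, brute_force_carg(s))
    rcpos <- match_carg(reverse_complement(s))$position
    expect_equal(length(fwd), length(rcpos))
  }

  # TSS-relative reporting
  m <- match_carg("TTCCAAATTTGGAT", window_start = -5L)
  expect_equal(m$position, -3L)

  set.seed(91)
  for (i in 1:20) {
    s <- paste(sample(c("A", "C", "G", "T"), 60, replace = TRUE,
                      prob = c(0.3, 0.2, 0.2, 0.3)), collapse = "")
    expect_equal(match_carg(s)$position, brute_force_carg(s))
  }
})

test_that("report serializers write readable TSV", {
  fx <- make_profile_fixture(n_genes = 4, n_mrtfs = 2, n_specific = 6,
                             seed = 75)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_report_tsv(fx$profile, f)
  back <- read.table(f, header = TRUE, sep = "\t")
  expect_equal(nrow(back), 8L)
  gs <- find_gene_specific(fx$hits, fx$gene_ids)
  write_report_tsv(gs, f)
  back2 <- read.table(f, header = TRUE, sep = "\t")
  expect_equal(sort(back2$tf), sort(unlist(fx$gene_specific)),
               ignore_attr = TRUE)
})
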