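# Independent oracles used across the suite. These deliberately avoid the
# package's own computational paths: the score-distribution oracle enumerates
# every word, the clustering oracle counts triangles directly, and the
# CArG oracle slides a window with per-character checks.

# Exact null score distribution by exhaustive enumeration of all 4^L words,
# on the same summed-rounded-weights integer grid as the package DP.
brute_force_dist <- function(pwm, grid_scale = 10000L) {
  W <- round(pwm$weights * grid_scale)
  bg <- as.numeric(pwm$background)
  L <- ncol(W)
  words <- as.matrix(expand.grid(rep(list(1:4), L), KEEP.OUT.ATTRS = FALSE))
  scores <- numeric(nrow(words))
  probs <- rep(1, nrow(words))
  for (j in seq_len(L)) {
    scores <- scores + W[cbind(words[, j], j)]
    probs <- probs * bg[words[, j]]
  }
  agg <- tapply(probs, scores, sum)
  score <- as.numeric(names(agg))
  o <- order(score)
  list(score = score[o], prob = as.numeric(agg)[o])
}

brute_force_tail <- function(bf, s) {
  vapply(s, function(si) sum(bf$prob[bf$score >= si]), numeric(1))
}

# Smallest integer score with upper tail strictly below p.
brute_force_cutoff <- function(bf, p) {
  tails <- rev(cumsum(rev(bf$prob)))
  i <- which(tails < p)
  if (length(i) == 0L) bf$score[length(bf$score)] + 1 else bf$score[i[1L] - 1L] + 1
}

# Random PFM/PWM generator for property-style tests.
random_pwm <- function(L, background = promscan::background_model(),
                       pseudocount_total = 1) {
  repeat {
    counts <- matrix(sample(0:20, 4L * L, replace = TRUE), 4L, L)
    if (all(colSums(counts) > 0)) break
  }
  promscan::pfm_to_pwm(promscan::pfm("RND", "RND", counts), background,
                       pseudocount_total)
}

# Sharp single-consensus PFM: `sharpness` of the column mass on a given base.
sharp_pfm <- function(consensus, sharpness = 0.97, total = 100L,
                      matrix_id = "SHARP", tf_name = matrix_id) {
  bases <- strsplit(consensus, "")[[1L]]
  counts <- matrix(0, 4L, length(bases))
  for (j in seq_along(bases)) {
    b <- match(bases[j], c("A", "C", "G", "T"))
    top <- round(sharpness * total)
    counts[, j] <- rep((total - top) / 3, 4L)
    counts[b, j] <- top
  }
  promscan::pfm(matrix_id, tf_name, counts)
}

# Local clustering coefficients by explicit triangle counting on the
# undirected simple projection (self-loops and directions dropped).
brute_force_clustering <- function(edges, nodes) {
  adj <- matrix(FALSE, length(nodes), length(nodes),
                dimnames = list(nodes, nodes))
  for (r in seq_len(nrow(edges))) {
    a <- edges$regulator[r]; b <- edges$target[r]
    if (a != b) adj[a, b] <- adj[b, a] <- TRUE
  }
  vapply(nodes, function(v) {
    nb <- nodes[adj[v, ]]
    k <- length(nb)
    if (k < 2L) return(0)
    links <- 0L
    for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
      if (adj[nb[i], nb[j]]) links <- links + 1L
    }
    2 * links / (k * (k - 1))
  }, numeric(1))
}

# All CArG-box (CC[A/T]x6 GG) start positions by per-character checks.
brute_force_carg <- function(sequence) {
  s <- strsplit(toupper(sequence), "")[[1L]]
  n <- length(s)
  hits <- integer(0)
  if (n >= 10L) {
    for (i in seq_len(n - 9L)) {
      w <- s[i:(i + 9L)]
      if (w[1] == "C" && w[2] == "C" && all(w[3:8] %in% c("A", "T")) &&
          w[9] == "G" && w[10] == "G") {
        hits <- c(hits, i)
      }
    }
  }
  hits
}

# Random promoter set of a given window (uses the current RNG state).
random_promoter_set <- function(n_genes, window = c(-200L, 100L)) {
  promscan::simulate_promoters(n_genes, window = window)$promoters
}
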