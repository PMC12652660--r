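# Directed gene regulatory network with self-loops, plus topology metrics.
# Degrees honour a configurable self-loop policy; local clustering
# coefficients are computed on the undirected simple projection.

new_regulatory_network <- function(edges, nodes = NULL) {
  stopifnot(is.data.frame(edges))
  if (!all(c("regulator", "target") %in% names(edges))) {
    stop("edges need 'regulator' and 'target' columns")
  }
  if (!"provenance" %in% names(edges)) edges$provenance <- "curated"
  edges <- unique(edges[, c("regulator", "target", "provenance")])
  key <- paste(edges$regulator, edges$target)
  if (anyDuplicated(key)) {
    stop("edge(s) listed with conflicting provenance: ",
         paste(unique(key[duplicated(key)]), collapse = "; "))
  }
  nodes <- sort(unique(c(nodes, edges$regulator, edges$target)))
  rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges),
            class = "regulatory_network")
}

#' Build a regulatory network from an edge data frame
#'
#' @param edges Data frame with columns `regulator`, `target` and optionally
#'   `provenance` (`curated`, `putative`, `binding-derived`, ...). Duplicate
#'   rows are collapsed; self-loops (regulator == target) are allowed and
#'   mark autoregulation.
#' @param nodes Optional extra (isolated) node names.
#' @return An object of class `regulatory_network`.
#' @export
regulatory_network <- function(edges, nodes = NULL) {
  new_regulatory_network(edges, nodes)
}

#' @export
print.regulatory_network <- function(x, ...) {
  loops <- sum(x$edges$regulator == x$edges$target)
  cat("Regulatory network: ", length(x$nodes), " node(s), ",
      nrow(x$edges), " directed edge(s), ", loops, " self-loop(s)\n", sep = "")
  invisible(x)
}

#' Read a directed edge list from TSV
#'
#' Two columns regulator, target, plus an optional third provenance column;
#' no header. Duplicate rows collapse to a single edge; nodes are created for
#' any name appearing in either column.
#'
#' @param file Path.
#' @return A `regulatory_network`.
#' @export
read_edge_list <- function(file) {
  lines <- readLines(file)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  if (length(lines) == 0L) {
    return(new_regulatory_network(
      data.frame(regulator = character(0), target = character(0),
                 provenance = character(0))))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nfield <- lengths(parts)
  bad <- which(nfield < 2L)
  if (length(bad)) {
    stop("malformed edge row at line ", bad[1L], ": '", lines[bad[1L]], "'")
  }
  edges <- data.frame(
    regulator = vapply(parts, `[`, character(1), 1L),
    target = vapply(parts, `[`, character(1), 2L),
    provenance = vapply(parts, function(p)
      if (length(p) >= 3L && nzchar(p[3L])) p[3L] else "curated", character(1)),
    stringsAsFactors = FALSE)
  new_regulatory_network(edges)
}

#' Write an edge list as TSV
#'
#' @param net A `regulatory_network`.
#' @param file Path.
#' @export
write_edge_list <- function(net, file) {
  stopifnot(inherits(net, "regulatory_network"))
  utils::write.table(net$edges, file, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(file)
}

#' Node degrees under a self-loop policy
#'
#' Out-degree counts outgoing edges and in-degree incoming edges, with
#' self-loops handled per policy: `out_only` (default) counts a self-loop in
#' the out-degree only, `both` counts it once in each, `none` ignores it.
#' Under `out_only` the out-degrees sum to the number of edges and the
#' in-degrees to edges minus self-loops.
#'
#' @param net A `regulatory_network`.
#' @param selfloop_policy `"out_only"`, `"both"` or `"none"`.
#' @return Data frame with columns `node`, `in_degree`, `out_degree`,
#'   `autoregulatory`.
#' @export
degree_metrics <- function(net, selfloop_policy = c("out_only", "both", "none")) {
  stopifnot(inherits(net, "regulatory_network"))
  selfloop_policy <- match.arg(selfloop_policy)
  e <- net$edges
  loop <- e$regulator == e$target
  count_out <- if (selfloop_policy == "none") e[!loop, ] else e
  count_in <- if (selfloop_policy == "both") e else e[!loop, ]
  tab <- function(v) {
    t <- table(factor(v, levels = net$nodes))
    as.integer(t)
  }
  data.frame(node = net$nodes,
             in_degree = tab(count_in$target),
             out_degree = tab(count_out$regulator),
             autoregulatory = net$nodes %in% e$regulator[loop],
             stringsAsFactors = FALSE)
}

undirected_simple_igraph <- function(net) {
  g <- igraph::graph_from_data_frame(net$edges[, c("regulator", "target")],
                                     directed = FALSE,
                                     vertices = net$nodes)
  igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
}

#' Local clustering coefficients
#'
#' Computed on the undirected simple projection of the network (directions
#' and self-loops dropped): the fraction of a node's neighbour pairs that are
#' themselves connected. Nodes with fewer than two neighbours get 0.
#'
#' @param net A `regulatory_network`.
#' @return Named numeric vector in `[0, 1]`, one value per node.
#' @export
clustering_coefficients <- function(net) {
  stopifnot(inherits(net, "regulatory_network"))
  g <- undirected_simple_igraph(net)
  cc <- igraph::transitivity(g, type = "local", isolates = "zero")
  cc[is.nan(cc)] <- 0
  stats::setNames(cc, igraph::V(g)$name)[net$nodes]
}

#' Full topology metric table
#'
#' Degrees (under the chosen self-loop policy) joined with local clustering
#' coefficients.
#'
#' @inheritParams degree_metrics
#' @return Data frame with columns `node`, `in_degree`, `out_degree`,
#'   `clustering`, `autoregulatory`.
#' @export
topology_metrics <- function(net, selfloop_policy = "out_only") {
  d <- degree_metrics(net, selfloop_policy)
  d$clustering <- as.numeric(clustering_coefficients(net)[d$node])
  d[, c("node", "in_degree", "out_degree", "clustering", "autoregulatory")]
}

#' Derive network edges from a motif hit table
#'
#' Adds an edge `TF's own gene -> target gene` for every (TF, promoter) pair
#' with at least one hit, tagged `binding-derived`; a hit of a TF in its own
#' promoter yields a self-loop. TFs without a mapped own gene contribute no
#' edges.
#'
#' @param hits A `hit_table`.
#' @param map A `tf_gene_map`.
#' @param symbols Optional named character vector translating gene ids to
#'   display symbols for the node names.
#' @return Edge data frame suitable for [regulatory_network()].
#' @export
derive_binding_edges <- function(hits, map, symbols = NULL) {
  stopifnot(inherits(map, "tf_gene_map"))
  pairs <- unique(data.frame(tf = hits$tf_name, target = hits$gene_id,
                             stringsAsFactors = FALSE))
  pairs <- merge(pairs, map, by = "tf")  # gene_id = TF's own gene
  lab <- function(g) {
    if (is.null(symbols)) g else ifelse(is.na(symbols[g]), g, symbols[g])
  }
  out <- data.frame(regulator = lab(pairs$gene_id),
                    target = lab(pairs$target),
                    provenance = "binding-derived",
                    stringsAsFactors = FALSE)
  unique(out[order(out$regulator, out$target), ])
}

#' Export a network as JSON
#'
#' Whole-network JSON (nodes, edges with provenance) for plotting tools.
#' Requires the jsonlite package.
#'
#' @param net A `regulatory_network`.
#' @param file Path.
#' @export
network_to_json <- function(net, file) {
  stopifnot(inherits(net, "regulatory_network"))
  if (!requireNamespace("jsonlite", quietly = TRUE)) {
    stop("network_to_json requires the 'jsonlite' package")
  }
  jsonlite::write_json(list(nodes = net$nodes, edges = net$edges),
                       file, auto_unbox = TRUE, digits = NA)
  invisible(file)
}

#' Packaged curated floral regulatory edge fixture
#'
#' Path to the literature-derived edge list for the Arabidopsis floral
#' MADS-box network shipped with the package: PI and SEP3 self-activation,
#' the mutual PI/AP3 activation of the B-function dimer, reciprocal SEP3
#' edges with SEP1/SEP2/SEP4/AG, and LFY activating AP1, AG, SOC1 plus
#' putative targets AGL24, SVP, FUL (13 nodes, 18 directed edges).
#'
#' @return File path of the TSV edge list.
#' @export
floral_network_edges <- function() {
  system.file("extdata", "floral_network_edges.tsv", package = "promscan",
              mustWork = TRUE)
}
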