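# Protein-protein interaction projection of TRN genes: edge enrichment
# against a global-density binomial null, integration (within-subgraph
# degree) ranking, and extraction of the hub-centred core regulatory
# circuit (the hub plus its single-nearest neighbours).

#' Construct a PPI graph
#'
#' Undirected simple graph. Self-loops and duplicate edges are removed with
#' a warning. The background node/edge counts define the global density used
#' by the enrichment null; they default to the graph's own counts.
#'
#' @param edges data.frame with columns gene_a, gene_b and optional score.
#' @param nodes optional character vector of nodes (isolated nodes allowed).
#' @param background_n_nodes,background_n_edges background universe counts.
#' @param min_score optional minimum edge confidence filter.
#' @return list of class \code{ppi_graph}: graph (igraph), nodes, edges,
#'   background_n_nodes, background_n_edges.
#' @export
ppi_graph <- function(edges, nodes = NULL, background_n_nodes = NULL,
                      background_n_edges = NULL, min_score = NULL) {
  stopifnot(all(c("gene_a", "gene_b") %in% names(edges)))
  if (!"score" %in% names(edges)) edges$score <- rep(NA_real_, nrow(edges))
  if (!is.null(min_score)) edges <- edges[!is.na(edges$score) &
                                            edges$score >= min_score, ]
  loops <- edges$gene_a == edges$gene_b
  if (any(loops)) {
    warning(sprintf("ppi_graph: dropped %d self-loop(s)", sum(loops)))
    edges <- edges[!loops, , drop = FALSE]
  }
  a <- pmin(edges$gene_a, edges$gene_b)
  b <- pmax(edges$gene_a, edges$gene_b)
  key <- paste(a, b, sep = "\r")
  dup <- duplicated(key)
  if (any(dup)) {
    warning(sprintf("ppi_graph: dropped %d duplicate edge(s)", sum(dup)))
    a <- a[!dup]; b <- b[!dup]
    edges <- edges[!dup, , drop = FALSE]
  }
  edges$gene_a <- a; edges$gene_b <- b
  verts <- sort(unique(c(a, b, nodes)))
  g <- igraph::graph_from_data_frame(
    data.frame(from = a, to = b, stringsAsFactors = FALSE),
    directed = FALSE, vertices = verts)
  structure(list(
    graph = g, nodes = verts, edges = edges,
    background_n_nodes = if (is.null(background_n_nodes)) length(verts)
      else background_n_nodes,
    background_n_edges = if (is.null(background_n_edges)) nrow(edges)
      else background_n_edges
  ), class = "ppi_graph")
}

#' @export
print.ppi_graph <- function(x, ...) {
  cat(sprintf("ppi_graph: %d nodes, %d edges (background %d / %d)\n",
              length(x$nodes), nrow(x$edges), x$background_n_nodes,
              x$background_n_edges))
  invisible(x)
}

#' Read a PPI edge list
#'
#' Tab-separated with header: gene_a, gene_b, optional score.
#'
#' @param path file path.
#' @param ... passed to \code{ppi_graph}.
#' @return \code{ppi_graph}.
#' @export
read_ppi <- function(path, ...) {
  tab <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  if (!all(c("gene_a", "gene_b") %in% names(tab)))
    stop("PPI edge list must have columns gene_a, gene_b")
  ppi_graph(tab, ...)
}

#' Induce a PPI subgraph on a gene set
#'
#' Nodes are the intersection of the gene set with the graph's nodes; edges
#' are the background edges with both endpoints retained. Background counts
#' are inherited so enrichment can still be tested against the full graph.
#'
#' @param ppi \code{ppi_graph}.
#' @param genes character vector.
#' @return \code{ppi_graph} induced subgraph.
#' @export
ppi_induced_subgraph <- function(ppi, genes) {
  keep <- intersect(ppi$nodes, genes)
  e <- ppi$edges[ppi$edges$gene_a %in% keep & ppi$edges$gene_b %in% keep, ,
                 drop = FALSE]
  rownames(e) <- NULL
  out <- ppi_graph(e, nodes = keep,
                   background_n_nodes = ppi$background_n_nodes,
                   background_n_edges = ppi$background_n_edges)
  out
}

#' Edge enrichment of a gene set against the background density
#'
#' Null model: each of the C(n, 2) possible pairs among the n selected nodes
#' is an edge independently with the background density
#' rho = background_edges / C(background_nodes, 2). Reports the observed
#' edge count m, its expectation rho * C(n, 2), and the binomial upper tail
#' P(X >= m).
#'
#' @param ppi background \code{ppi_graph}.
#' @param genes gene set (>= 2 present in the graph).
#' @return list(n_nodes, observed_edges, expected, rho, p).
#' @export
edge_enrichment <- function(ppi, genes) {
  sub <- ppi_induced_subgraph(ppi, genes)
  n <- length(sub$nodes)
  if (n < 2) stop("edge_enrichment: fewer than 2 selected genes in graph")
  m <- nrow(sub$edges)
  pairs <- choose(n, 2)
  rho <- ppi$background_n_edges / choose(ppi$background_n_nodes, 2)
  if (rho == 0) {
    p <- if (m > 0) 0 else 1
    return(list(n_nodes = n, observed_edges = m, expected = 0, rho = 0,
                p = p, inconsistent_background = m > 0))
  }
  p <- stats::pbinom(m - 1, pairs, rho, lower.tail = FALSE)
  list(n_nodes = n, observed_edges = m, expected = rho * pairs, rho = rho,
       p = p, inconsistent_background = FALSE)
}

#' Rank nodes by integration (within-subgraph degree)
#'
#' Integration of a node is its number of direct interactions with other
#' members of the network. Ties are broken lexicographically by node id.
#'
#' @param sub \code{ppi_graph} (typically an induced subgraph).
#' @return data.frame (node, degree, rank) sorted by decreasing degree.
#' @export
integration_rank <- function(sub) {
  if (length(sub$nodes) == 0)
    return(data.frame(node = character(), degree = integer(),
                      rank = integer(), stringsAsFactors = FALSE))
  deg <- igraph::degree(sub$graph)
  out <- data.frame(node = names(deg), degree = as.integer(deg),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$degree, out$node), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Extract the hub-centred core regulatory circuit
#'
#' The CRC is the hub plus its single-nearest (direct) neighbours within the
#' subgraph, with the induced sub-subgraph on those members.
#'
#' @param sub \code{ppi_graph}.
#' @param hub node id; must be present in the subgraph.
#' @return list of class \code{circuit_graph}: hub, crc_members (sorted,
#'   includes hub), subgraph (induced \code{ppi_graph} on members),
#'   integration (degree table of \code{sub}).
#' @export
extract_crc <- function(sub, hub) {
  if (!hub %in% sub$nodes)
    stop("extract_crc: hub node '", hub, "' not in subgraph")
  nb <- names(igraph::neighbors(sub$graph, hub))
  members <- sort(unique(c(hub, nb)))
  structure(list(hub = hub, crc_members = members,
                 subgraph = ppi_induced_subgraph(sub, members),
                 integration = integration_rank(sub)),
            class = "circuit_graph")
}

#' @export
print.circuit_graph <- function(x, ...) {
  cat(sprintf("circuit_graph: hub %s + %d neighbours (%d edges)\n", x$hub,
              length(x$crc_members) - 1, nrow(x$subgraph$edges)))
  invisible(x)
}

#' Conservation of a core circuit between models
#'
#' Upper-tail hypergeometric probability of the observed overlap between two
#' CRC member sets drawn from a common universe.
#'
#' @param crc_a,crc_b character node sets (subsets of \code{universe}).
#' @param universe character vector of background genes.
#' @return list(overlap, p).
#' @export
crc_conservation <- function(crc_a, crc_b, universe) {
  universe <- unique(universe)
  if (length(universe) == 0) stop("crc_conservation: empty universe")
  a <- unique(crc_a); b <- unique(crc_b)
  stopifnot(all(a %in% universe), all(b %in% universe))
  k <- length(intersect(a, b))
  p <- stats::phyper(k - 1, length(a), length(universe) - length(a),
                     length(b), lower.tail = FALSE)
  list(overlap = k, p = p)
}
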