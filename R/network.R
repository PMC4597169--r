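#' Construct a weighted bipartite HLA-peptide binding network
#'
#' One side holds HLA alleles, the other peptides; each binding record becomes
#' an edge weighted 2 (positive binding) or 1 (negative binding). Records must
#' be deduplicated first: a repeated (HLA, peptide) key is an error, because
#' aggregation is a separate, earlier step.
#'
#' Internally the two node sets are indexed separately, so a peptide string can
#' never collide with an allele name. Adjacency lists, degrees and weight sums
#' are precomputed once; downstream per-edge computations (similarities, means
#' with one edge excluded) reuse them without copying the graph.
#'
#' @param records Data frame with columns `hla`, `peptide` and either `label`
#'   (`"positive"`/`"negative"`) or `weight` (2/1).
#' @return An object of class `"binding_network"`.
#' @export
binding_network <- function(records) {
  stopifnot(is.data.frame(records), all(c("hla", "peptide") %in% names(records)))
  w <- if ("weight" %in% names(records)) as.integer(records$weight)
       else if ("label" %in% names(records)) ifelse(records$label == "positive", 2L, 1L)
       else stop("records need a 'label' or 'weight' column")
  if (nrow(records) > 0L && !all(w %in% c(1L, 2L)))
    stop("edge weights must be 1 (negative) or 2 (positive)")
  hla_names <- sort(unique(records$hla))
  pep_names <- sort(unique(records$peptide))
  h <- match(records$hla, hla_names)
  p <- match(records$peptide, pep_names)
  if (anyDuplicated(paste(h, p))) {
    stop("duplicate (hla, peptide) pairs: aggregate records before building the network")
  }
  nh <- length(hla_names); np <- length(pep_names)
  net <- structure(list(
    hla = hla_names, peptide = pep_names,
    edge_h = h, edge_p = p, edge_w = w,
    h_nbr = NULL, h_w = NULL, p_nbr = NULL, p_w = NULL,
    h_deg = NULL, p_deg = NULL, h_wsum = NULL, p_wsum = NULL
  ), class = "binding_network")
  .index_network(net)
}

# (Re)build adjacency lists and per-node degree / weight-sum caches.
.index_network <- function(net) {
  nh <- length(net$hla); np <- length(net$peptide)
  h <- net$edge_h; p <- net$edge_p; w <- net$edge_w
  net$h_nbr <- unname(split(p, factor(h, levels = seq_len(nh))))
  net$h_w   <- unname(split(w, factor(h, levels = seq_len(nh))))
  net$p_nbr <- unname(split(h, factor(p, levels = seq_len(np))))
  net$p_w   <- unname(split(w, factor(p, levels = seq_len(np))))
  net$h_deg <- lengths(net$h_nbr)
  net$p_deg <- lengths(net$p_nbr)
  net$h_wsum <- vapply(net$h_w, sum, numeric(1))
  net$p_wsum <- vapply(net$p_w, sum, numeric(1))
  net
}

#' @export
print.binding_network <- function(x, ...) {
  npos <- sum(x$edge_w == 2L)
  cat("Weighted bipartite HLA-peptide binding network\n")
  cat(sprintf("  %d HLA alleles, %d peptides, %d edges (%.1f%% positive)\n",
              length(x$hla), length(x$peptide), length(x$edge_w),
              if (length(x$edge_w)) 100 * npos / length(x$edge_w) else NA_real_))
  invisible(x)
}

# Resolve a user-supplied node name to (side, index); side "hla" or "peptide".
.resolve_node <- function(net, node, type = c("auto", "hla", "peptide")) {
  type <- match.arg(type)
  ih <- if (type != "peptide") match(node, net$hla) else NA_integer_
  ip <- if (type != "hla") match(node, net$peptide) else NA_integer_
  if (!is.na(ih) && !is.na(ip))
    stop("node '", node, "' names both an HLA and a peptide; pass type=")
  if (!is.na(ih)) return(list(side = "hla", idx = ih))
  if (!is.na(ip)) return(list(side = "peptide", idx = ip))
  stop("unknown node: ", node)
}

#' Opposite-side neighbors of a node
#'
#' @param net A [binding_network()].
#' @param node Node name (allele or peptide sequence).
#' @param type `"auto"` resolves the side by lookup; force with `"hla"` or
#'   `"peptide"` if a name could occur on both sides.
#' @return Character vector of the opposite-side node names sharing an edge
#'   with `node`.
#' @export
node_neighbors <- function(net, node, type = "auto") {
  r <- .resolve_node(net, node, type)
  if (r$side == "hla") net$peptide[net$h_nbr[[r$idx]]] else net$hla[net$p_nbr[[r$idx]]]
}

#' Mean incident edge weight of a node, optionally excluding one edge
#'
#' The node mean used throughout the neighbor-edge predictor: the arithmetic
#' mean over all edges incident to the node, with the edge under prediction
#' removed when `exclude` is given. Exclusion is a parameter, not a graph
#' mutation, so leave-one-out never copies the network.
#'
#' @param net A [binding_network()].
#' @param node Node name.
#' @param exclude Optional length-2 character vector `c(hla, peptide)` naming
#'   one edge to leave out of the mean.
#' @param type Side resolution as in [node_neighbors()].
#' @return The mean weight, or `NA` (with a warning) when no edges remain,
#'   leaving the fallback decision to the caller.
#' @export
node_mean_weight <- function(net, node, exclude = NULL, type = "auto") {
  r <- .resolve_node(net, node, type)
  if (r$side == "hla") { ws <- net$h_wsum[r$idx]; d <- net$h_deg[r$idx] }
  else { ws <- net$p_wsum[r$idx]; d <- net$p_deg[r$idx] }
  if (!is.null(exclude)) {
    stopifnot(length(exclude) == 2L)
    eh <- match(exclude[[1]], net$hla); ep <- match(exclude[[2]], net$peptide)
    if (!is.na(eh) && !is.na(ep)) {
      hit <- which(net$edge_h == eh & net$edge_p == ep)
      if (length(hit) == 1L &&
          ((r$side == "hla" && eh == r$idx) || (r$side == "peptide" && ep == r$idx))) {
        ws <- ws - net$edge_w[hit]; d <- d - 1L
      }
    }
  }
  if (d == 0L) { warning("mean weight undefined: node '", node, "' has no remaining edges")
    return(NA_real_) }
  ws / d
}

#' Export a network as an edge-list TSV
#'
#' Columns `hla`, `peptide`, `weight`; re-importing with [read_network_tsv()]
#' reproduces identical edges and weights.
#' @param net A [binding_network()].
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_network_tsv <- function(net, path) {
  utils::write.table(
    data.frame(hla = net$hla[net$edge_h], peptide = net$peptide[net$edge_p],
               weight = net$edge_w),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Import a network from an edge-list TSV
#' @param path Path written by [write_network_tsv()] (or any 3-column
#'   hla/peptide/weight TSV).
#' @return A [binding_network()].
#' @export
read_network_tsv <- function(path) {
  df <- utils::read.delim(path, colClasses = c("character", "character", "integer"))
  names(df)[1:3] <- c("hla", "peptide", "weight")
  binding_network(df)
}

#' Export a network as GraphML for external viewers
#'
#' Thin wrapper over igraph's GraphML writer; node attribute `type` marks the
#' side, edge attribute `weight` the binding label code.
#' @param net A [binding_network()].
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_network_graphml <- function(net, path) {
  igraph::write_graph(as_igraph(net), path, format = "graphml")
  invisible(path)
}

#' Convert a binding network to an igraph object
#'
#' Vertices are the HLA nodes followed by the peptide nodes, with logical
#' vertex attribute `type` (`TRUE` for peptides, igraph's bipartite
#' convention) and the allele/sequence as `name`; edge attribute `weight`.
#' @param net A [binding_network()].
#' @param weights Attach the 1/2 weights as edge weights (default `TRUE`).
#' @return An igraph graph.
#' @export
as_igraph <- function(net, weights = TRUE) {
  nh <- length(net$hla); np <- length(net$peptide)
  g <- igraph::make_empty_graph(n = nh + np, directed = FALSE)
  g <- igraph::add_edges(g, rbind(net$edge_h, nh + net$edge_p))
  igraph::V(g)$type <- c(rep(FALSE, nh), rep(TRUE, np))
  igraph::V(g)$name <- c(net$hla, net$peptide)
  if (weights) igraph::E(g)$weight <- net$edge_w
  g
}
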