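#' Newman-Girvan modularity of a node partition
#'
#' Computes Q = sum_c (e_c - a_c^2), where e_c is the fraction of (weighted)
#' edge weight falling inside community c and a_c the fraction of (weighted)
#' degree attached to c. The general unipartite form is applied to the
#' bipartite graph, matching the behaviour of igraph's community routines on
#' such graphs. With every node in one community Q is exactly 0.
#'
#' @param net A [binding_network()].
#' @param partition A `module_partition` (from [fast_greedy_modules()]) or a
#'   list with named integer vectors `hla_module` and `peptide_module`
#'   covering every node.
#' @param weighted Use the 1/2 edge weights (default `TRUE`); otherwise each
#'   edge counts 1.
#' @return Modularity Q in \[-1, 1\].
#' @export
modularity_q <- function(net, partition, weighted = TRUE) {
  hm <- partition$hla_module[net$hla]
  pm <- partition$peptide_module[net$peptide]
  if (anyNA(hm) || anyNA(pm)) {
    miss <- c(net$hla[is.na(hm)], net$peptide[is.na(pm)])
    stop("partition does not cover node(s): ", paste(utils::head(miss, 5), collapse = ", "))
  }
  w <- if (weighted) as.numeric(net$edge_w) else rep(1, length(net$edge_w))
  m <- sum(w)
  if (m == 0) stop("modularity undefined on an empty network")
  ch <- hm[net$edge_h]; cp <- pm[net$edge_p]
  e_within <- sum(w[ch == cp]) / m
  comms <- sort(unique(c(hm, pm)))
  # weighted degree per community: each edge contributes w to both endpoints
  deg_c <- vapply(comms, function(cc) sum(w[ch == cc]) + sum(w[cp == cc]), numeric(1))
  e_within - sum((deg_c / (2 * m))^2)
}

#' Identify binding modules by fast greedy modularity optimization
#'
#' Runs the Clauset-Newman-Moore agglomerative algorithm (via igraph) on the
#' bipartite binding network and cuts the merge dendrogram at maximum
#' modularity. The reported modularity is recomputed independently with
#' [modularity_q()] from the returned assignment.
#'
#' @param net A [binding_network()].
#' @param weighted Use the 1/2 binding weights (default `TRUE`).
#' @return An object of class `"module_partition"`: list with `hla_module`
#'   and `peptide_module` (named integer vectors, module ids 1..M),
#'   `n_modules`, `modularity`, and `weighted`.
#' @export
fast_greedy_modules <- function(net, weighted = TRUE) {
  if (length(net$edge_w) == 0L) stop("cannot detect modules in an empty network")
  g <- as_igraph(net, weights = FALSE)
  cl <- igraph::cluster_fast_greedy(
    g, weights = if (weighted) as.numeric(net$edge_w) else NULL)
  memb <- igraph::membership(cl)
  nh <- length(net$hla)
  part <- structure(list(
    hla_module = stats::setNames(as.integer(memb[seq_len(nh)]), net$hla),
    peptide_module = stats::setNames(as.integer(memb[nh + seq_along(net$peptide)]),
                                     net$peptide),
    n_modules = length(unique(as.integer(memb))),
    modularity = NA_real_,
    weighted = weighted
  ), class = "module_partition")
  part$modularity <- modularity_q(net, part, weighted = weighted)
  part
}

#' @export
print.module_partition <- function(x, ...) {
  cat(sprintf("Module partition: %d modules, modularity Q = %.4f (%s)\n",
              x$n_modules, x$modularity,
              if (x$weighted) "weighted" else "unweighted"))
  tab <- table(module = c(x$hla_module, x$peptide_module))
  print(tab)
  invisible(x)
}

#' Write a partition as a two-column TSV (node, module_id)
#' @param partition A `module_partition`.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_partition_tsv <- function(partition, path) {
  df <- data.frame(
    node = c(names(partition$hla_module), names(partition$peptide_module)),
    type = rep(c("hla", "peptide"),
               c(length(partition$hla_module), length(partition$peptide_module))),
    module_id = c(partition$hla_module, partition$peptide_module))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Shuffle edge weights, preserving topology and weight counts
#'
#' Produces a random network for the permutation null: nodes and edges are
#' untouched; only the positive/negative weights are permuted uniformly at
#' random over the edges, so the counts of 1s and 2s are conserved exactly.
#'
#' @param net A [binding_network()].
#' @param seed Integer seed (mandatory, for a reproducible null).
#' @return A new `binding_network` with permuted weights.
#' @export
shuffle_weights <- function(net, seed) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  set.seed(as.integer(seed))
  net$edge_w <- sample(net$edge_w)
  .index_network(net)
}

#' Rewire edges preserving node counts and weight counts
#'
#' Alternative, harsher null model: edges are re-drawn uniformly among all
#' HLA-peptide pairs (no duplicates), keeping the number of nodes, edges,
#' positives and negatives. Not the default null; the primary analysis
#' shuffles weights only.
#'
#' @inheritParams shuffle_weights
#' @return A new `binding_network`.
#' @export
rewire_edges <- function(net, seed) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  set.seed(as.integer(seed))
  nh <- length(net$hla); np <- length(net$peptide); ne <- length(net$edge_w)
  if (as.double(nh) * np < ne) stop("not enough node pairs to place edges")
  cells <- sample.int(nh * np, ne)   # unique pairs
  net$edge_h <- ((cells - 1L) %% nh) + 1L
  net$edge_p <- ((cells - 1L) %/% nh) + 1L
  net$edge_w <- sample(net$edge_w)
  .index_network(net)
}

#' Weight-permutation null distribution of modularity
#'
#' For each replicate, shuffles the edge weights ([shuffle_weights()]) and
#' reruns fast greedy module detection with the same parameters as the real
#' network, collecting the resulting modularity values. Replicate i uses seed
#' `base_seed + i`, recorded in the result. The empirical p-value is
#' `(1 + #\{null >= real\}) / (1 + replicates)`.
#'
#' @param net A [binding_network()].
#' @param replicates Number of random networks (>= 1), default 1000.
#' @param base_seed Integer; replicate i is seeded with `base_seed + i`.
#' @param weighted Passed to [fast_greedy_modules()] and [modularity_q()].
#' @param mode `"weights"` (default, shuffle weights on fixed topology) or
#'   `"rewire"` (draw new edges, same node and weight counts).
#' @return Object of class `"null_distribution"`: list with `values`
#'   (numeric, length `replicates`), `real` (modularity of `net`),
#'   `empirical_p`, `seeds`, `mode`.
#' @export
permutation_null <- function(net, replicates = 1000L, base_seed = 1L,
                             weighted = TRUE, mode = c("weights", "rewire")) {
  mode <- match.arg(mode)
  stopifnot(replicates >= 1L)
  real_part <- fast_greedy_modules(net, weighted = weighted)
  seeds <- as.integer(base_seed) + seq_len(replicates)
  g <- as_igraph(net, weights = FALSE)   # topology reused across replicates
  vals <- vapply(seeds, function(s) {
    if (mode == "weights") {
      set.seed(s)
      w <- sample(net$edge_w)
      cl <- igraph::cluster_fast_greedy(g, weights = if (weighted) as.numeric(w) else NULL)
      memb <- as.integer(igraph::membership(cl))
      .modularity_fast(net$edge_h, net$edge_p, if (weighted) w else rep(1L, length(w)),
                       memb, length(net$hla))
    } else {
      rnet <- rewire_edges(net, s)
      fast_greedy_modules(rnet, weighted = weighted)$modularity
    }
  }, numeric(1))
  structure(list(
    values = vals,
    real = real_part$modularity,
    real_partition = real_part,
    empirical_p = (1 + sum(vals >= real_part$modularity)) / (1 + replicates),
    seeds = seeds,
    replicates = replicates,
    mode = mode,
    weighted = weighted
  ), class = "null_distribution")
}

# Modularity from raw edge indices and an integer membership over
# (hla nodes, then peptide nodes); avoids name lookups in the null loop.
.modularity_fast <- function(eh, ep, w, memb, nh) {
  w <- as.numeric(w)
  m <- sum(w)
  ch <- memb[eh]; cp <- memb[nh + ep]
  e_within <- sum(w[ch == cp]) / m
  deg_c <- rowsum(c(w, w), c(ch, cp))
  e_within - sum((deg_c / (2 * m))^2)
}

#' @export
print.null_distribution <- function(x, ...) {
  cat(sprintf("Permutation null (%s, %d replicates): real Q = %.4f\n",
              x$mode, x$replicates, x$real))
  cat(sprintf("  null Q: mean %.4f, sd %.4f, range [%.4f, %.4f]\n",
              mean(x$values), stats::sd(x$values), min(x$values), max(x$values)))
  cat(sprintf("  empirical p = %.4g (%d of %d null values >= real)\n",
              x$empirical_p, sum(x$values >= x$real), x$replicates))
  invisible(x)
}

#' Summarize a null distribution as a JSON-ready list
#' @param x A `null_distribution`.
#' @return List with `real`, `mean`, `sd`, `min`, `max`, `empirical_p`.
#' @export
null_summary <- function(x) {
  stopifnot(inherits(x, "null_distribution"))
  list(real = x$real, mean = mean(x$values), sd = stats::sd(x$values),
       min = min(x$values), max = max(x$values), empirical_p = x$empirical_p)
}
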