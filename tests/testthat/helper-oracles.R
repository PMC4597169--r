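# Independent oracles, deliberately sharing no code with the package:
# dense-matrix / brute-force re-derivations of each contract.

# Random small bipartite weight matrix (0 = no edge, 1/2 = labels), every
# row and column guaranteed at least one edge.
random_weight_matrix <- function(nh, np, p_edge = 0.6) {
  W <- matrix(sample(0:2, nh * np, replace = TRUE,
                     prob = c(1 - p_edge, p_edge / 2, p_edge / 2)), nh, np)
  for (r in seq_len(nh)) if (all(W[r, ] == 0)) W[r, sample.int(np, 1)] <- sample(1:2, 1)
  for (c in seq_len(np)) if (all(W[, c] == 0)) W[sample.int(nh, 1), c] <- sample(1:2, 1)
  W
}

records_from_matrix <- function(W) {
  idx <- which(W > 0, arr.ind = TRUE)
  data.frame(hla = paste0("H", idx[, 1]), peptide = paste0("pep", idx[, 2]),
             weight = W[idx], stringsAsFactors = FALSE)
}

# Naive from-scratch evaluation of the neighbor-edge predictor: node means
# over all incident edges, Pearson similarity over the shared profile with
# those means, neighbor sum divided by the similarity sum (or its absolute
# sum), fallback to the node mean on empty/degenerate denominators, final
# score the mean of the defined sides, global mean when neither is defined.
naive_nebula <- function(W, i, x, exclude, denom = "literal", eps = 1e-12) {
  if (exclude) W[i, x] <- 0
  mean_h <- function(h) { w <- W[h, ][W[h, ] > 0]; if (!length(w)) NA_real_ else mean(w) }
  mean_p <- function(p) { w <- W[, p][W[, p] > 0]; if (!length(w)) NA_real_ else mean(w) }
  S_pair <- function(wa, wb, ma, mb) {
    shared <- which(wa > 0 & wb > 0)
    if (!length(shared)) return(0)
    da <- wa[shared] - ma; db <- wb[shared] - mb
    den <- sqrt(sum(da^2) * sum(db^2))
    if (den < eps) return(0)
    sum(da * db) / den
  }
  side <- function(vec_i, m_i, others, w_others, m_others, S) {
    if (is.na(m_i)) return(NA_real_)
    if (!length(others)) return(m_i)
    D <- if (denom == "absolute") sum(abs(S)) else sum(S)
    if (abs(D) < eps) return(m_i)
    m_i + sum((w_others - m_others) * S) / D
  }
  J <- setdiff(which(W[, x] > 0), i)
  S_h <- vapply(J, function(j) S_pair(W[i, ], W[j, ], mean_h(i), mean_h(j)), numeric(1))
  P_h <- side(W[i, ], mean_h(i), J, W[J, x], vapply(J, mean_h, numeric(1)), S_h)
  K <- setdiff(which(W[i, ] > 0), x)
  S_p <- vapply(K, function(k) S_pair(W[, x], W[, k], mean_p(x), mean_p(k)), numeric(1))
  P_p <- side(W[, x], mean_p(x), K, W[i, K], vapply(K, mean_p, numeric(1)), S_p)
  if (!is.na(P_h) && !is.na(P_p)) (P_h + P_p) / 2
  else if (!is.na(P_h)) P_h
  else if (!is.na(P_p)) P_p
  else mean(W[W > 0])
}

# Brute-force repeated deletion: drop any record touching an under-connected
# node, one full sweep at a time, until stable.
brute_kcore <- function(records, min_count = 2L) {
  repeat {
    if (nrow(records) == 0L) return(records)
    h <- table(records$hla); p <- table(records$peptide)
    drop <- h[records$hla] < min_count | p[records$peptide] < min_count
    if (!any(drop)) return(records)
    records <- records[!drop, , drop = FALSE]
  }
}

# AUC by exhaustive concordant/discordant/tied pair counting.
pair_count_auc <- function(scores, positive) {
  ip <- which(positive); ineg <- which(!positive)
  tot <- 0
  for (a in ip) for (b in ineg) {
    tot <- tot + (scores[a] > scores[b]) + 0.5 * (scores[a] == scores[b])
  }
  tot / (length(ip) * length(ineg))
}

# Exhaustive search over all set partitions of <= 10 nodes for the maximum
# Newman-Girvan modularity of an undirected (possibly weighted) edge list.
# edges: data.frame(a, b, w) with integer node ids 1..n.
exhaustive_best_modularity <- function(edges, n) {
  m <- sum(edges$w)
  deg <- numeric(n)
  for (r in seq_len(nrow(edges))) {
    deg[edges$a[r]] <- deg[edges$a[r]] + edges$w[r]
    deg[edges$b[r]] <- deg[edges$b[r]] + edges$w[r]
  }
  q_of <- function(memb) {
    within <- sum(edges$w[memb[edges$a] == memb[edges$b]]) / m
    within - sum((tapply(deg, memb, sum) / (2 * m))^2)
  }
  best <- -Inf
  # enumerate partitions via restricted growth strings
  rgs <- integer(n)
  recurse <- function(i, maxv) {
    if (i > n) { best <<- max(best, q_of(rgs[seq_len(n)])); return(invisible()) }
    for (v in seq_len(maxv + 1L)) {
      rgs[i] <<- v
      recurse(i + 1L, max(maxv, v))
    }
  }
  recurse(1L, 0L)
  best
}

# Tiny fixed network used across tests: 4 HLAs x 4 peptides, hand-assigned
# weights with a mix of positives and negatives.
toy_4x4 <- function() {
  W <- matrix(c(2, 2, 1, 0,
                2, 1, 1, 2,
                0, 2, 2, 1,
                1, 0, 2, 2), nrow = 4, byrow = TRUE)
  rownames(W) <- paste0("H", 1:4); colnames(W) <- paste0("pep", 1:4)
  W
}
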