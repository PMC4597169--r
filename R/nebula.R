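#' Fit a Nebula neighbor-edge collaborative-filtering predictor
#'
#' Nebula (neighbor-edges based and unbiased leverage algorithm) predicts the
#' qualitative label of an HLA-peptide edge from the edges neighboring it in
#' the weighted bipartite binding network (weights 2 = positive binding,
#' 1 = negative). For a queried pair (h, p) it forms two side predictions:
#'
#' \deqn{P_{h,p} = \bar w_h + \frac{\sum_j (w_{j,p} - \bar w_j)\, S_{h,j}}
#'                                 {\sum_j S_{h,j}}}
#'
#' where j runs over the HLAs connected to p, \eqn{\bar w} is a node's mean
#' weight over all its incident edges, and \eqn{S_{h,j}} is the Pearson
#' correlation of the two HLAs' weights over their shared peptides (0 when no
#' peptide is shared or the shared weights are degenerate). The mirrored
#' expression over the peptides connected to h gives \eqn{P_{p,h}}; the final
#' score is their arithmetic mean \eqn{F = (P_{h,p} + P_{p,h}) / 2}, and the
#' categorical call is positive when F is at or above the unbiased leverage
#' (UL), the midpoint 1.5 of the two weight codes.
#'
#' This is a memory-based model: fitting stores the indexed training network
#' and configuration; all computation happens at prediction time.
#'
#' @param x A [binding_network()], or a record data frame accepted by it.
#' @param ul Unbiased leverage, the decision threshold on F (default 1.5,
#'   the midpoint of weights 1 and 2); the comparison is inclusive
#'   (F >= UL is called positive).
#' @param denominator `"literal"` (default) divides the neighbor sum by
#'   \eqn{\sum_j S} exactly as written above; `"absolute"` divides by
#'   \eqn{\sum_j |S|}, the classical Resnick collaborative-filtering
#'   convention, which cannot cancel to zero or flip sign.
#' @param epsilon Magnitude below which a denominator is treated as zero and
#'   the side prediction falls back to the node mean (default 1e-12).
#' @return An object of class `"nebula"`.
#' @seealso [predict.nebula()], [loo_validate()], [kfold_validate()]
#' @export
nebula <- function(x, ul = 1.5, denominator = c("literal", "absolute"),
                   epsilon = 1e-12) {
  denominator <- match.arg(denominator)
  net <- if (inherits(x, "binding_network")) x else binding_network(x)
  stopifnot(ul > 1, ul < 2)
  structure(list(
    network = net,
    ul = ul,
    denominator = denominator,
    epsilon = epsilon,
    global_mean = if (length(net$edge_w)) mean(net$edge_w) else NA_real_
  ), class = "nebula")
}

#' @export
print.nebula <- function(x, ...) {
  cat("Nebula neighbor-edge binding predictor\n")
  cat(sprintf("  training network: %d HLAs x %d peptides, %d edges\n",
              length(x$network$hla), length(x$network$peptide),
              length(x$network$edge_w)))
  cat(sprintf("  unbiased leverage %.2f, %s denominator\n", x$ul, x$denominator))
  invisible(x)
}

#' @export
summary.nebula <- function(object, ...) {
  net <- object$network
  out <- list(
    n_hla = length(net$hla), n_peptide = length(net$peptide),
    n_edges = length(net$edge_w),
    positive_fraction = mean(net$edge_w == 2L),
    hla_degree = summary(net$h_deg), peptide_degree = summary(net$p_deg),
    ul = object$ul, denominator = object$denominator)
  class(out) <- "summary.nebula"
  out
}

#' @export
print.summary.nebula <- function(x, ...) {
  cat(sprintf("Nebula fit on %d edges (%d HLAs, %d peptides), %.1f%% positive\n",
              x$n_edges, x$n_hla, x$n_peptide, 100 * x$positive_fraction))
  cat("  HLA degree: "); print(x$hla_degree)
  cat("  peptide degree: "); print(x$peptide_degree)
  cat(sprintf("  UL = %.2f, denominator = %s\n", x$ul, x$denominator))
  invisible(x)
}

# One side prediction: predict edge (i, x) from the side of node i.
# Arguments are the adjacency caches of the "i" side (A_*) and the opposite
# side (B_*); with swap=TRUE the caller passes peptide caches as A_*.
# exclude_w: weight of the excluded edge (i,x) or NA when nothing is excluded.
# Returns c(value, defined, fallback).
.nebula_side <- function(i, x, A_nbr, A_w, A_deg, A_wsum,
                         B_nbr, B_w, exclude_w, denominator, eps) {
  deg_i <- A_deg[i]; wsum_i <- A_wsum[i]
  if (!is.na(exclude_w)) { deg_i <- deg_i - 1L; wsum_i <- wsum_i - exclude_w }
  if (deg_i <= 0L) return(c(NA_real_, 0, 0))      # side undefined
  m_i <- wsum_i / deg_i
  J <- B_nbr[[x]]; wJx <- B_w[[x]]
  if (!is.na(exclude_w)) { keep <- J != i; J <- J[keep]; wJx <- wJx[keep] }
  if (length(J) == 0L) return(c(m_i, 1, 1))       # no neighboring edges: node mean
  Ai <- A_nbr[[i]]; Awi <- A_w[[i]]
  if (!is.na(exclude_w)) { keep <- Ai != x; Ai <- Ai[keep]; Awi <- Awi[keep] }
  devI <- Awi - m_i
  mJ <- A_wsum[J] / A_deg[J]
  S <- numeric(length(J))
  for (t in seq_along(J)) {
    Bj <- A_nbr[[J[t]]]
    pos <- match(Ai, Bj)
    sel <- which(!is.na(pos))
    if (length(sel) == 0L) next
    a <- devI[sel]
    b <- A_w[[J[t]]][pos[sel]] - mJ[t]
    den <- sqrt(sum(a * a) * sum(b * b))
    if (den > eps) S[t] <- sum(a * b) / den
  }
  D <- if (denominator == "absolute") sum(abs(S)) else sum(S)
  if (abs(D) < eps) return(c(m_i, 1, 1))          # cancelled/empty denominator
  c(m_i + sum((wJx - mJ) * S) / D, 1, 0)
}

# Core scorer for one (hla index, peptide index) pair. idx_* may be NA for
# nodes absent from the training network. leave_out drops the training edge
# (i, x), if present, from every mean, similarity and neighbor sum.
.nebula_score_one <- function(fit, ih, ip, leave_out) {
  net <- fit$network
  exclude_w <- NA_integer_
  if (leave_out && !is.na(ih) && !is.na(ip)) {
    hit <- net$h_nbr[[ih]] == ip
    if (any(hit)) exclude_w <- net$h_w[[ih]][which(hit)[1]]
  }
  side_h <- .nebula_side(ih, ip, net$h_nbr, net$h_w, net$h_deg, net$h_wsum,
                         net$p_nbr, net$p_w, exclude_w, fit$denominator, fit$epsilon)
  side_p <- .nebula_side(ip, ih, net$p_nbr, net$p_w, net$p_deg, net$p_wsum,
                         net$h_nbr, net$h_w, exclude_w, fit$denominator, fit$epsilon)
  h_def <- side_h[2] == 1; p_def <- side_p[2] == 1
  if (h_def && p_def) {
    f <- (side_h[1] + side_p[1]) / 2
    fb <- if (side_h[3] == 1 || side_p[3] == 1) "side_mean" else "none"
  } else if (h_def) { f <- side_h[1]; fb <- "hla_side_only"
  } else if (p_def) { f <- side_p[1]; fb <- "peptide_side_only"
  } else {
    g <- if (is.na(exclude_w)) fit$global_mean else
      (fit$global_mean * length(net$edge_w) - exclude_w) / (length(net$edge_w) - 1L)
    f <- g; fb <- "global_mean"
  }
  list(F = f, P_hla = side_h[1], P_peptide = side_p[1],
       hla_defined = h_def, pep_defined = p_def, fallback = fb)
}

#' Predict HLA-peptide binding with a fitted Nebula model
#'
#' Scores each queried (HLA, peptide) pair with the continuous prediction F
#' and the categorical call C (positive when `F >= UL`). Pairs involving
#' nodes unknown to the training network, or whose side sums are empty or
#' degenerate, are resolved by a fallback cascade (node mean, single defined
#' side, global training mean); every fallback is flagged in the output so
#' validation can report coverage.
#'
#' @param object A fitted [nebula()] model.
#' @param newdata Data frame with columns `hla` and `peptide`; defaults to the
#'   training edges.
#' @param leave_out If `TRUE`, each queried pair that is a training edge is
#'   predicted with that edge excluded from all means, similarities and
#'   neighbor sums (leave-one-out semantics). Default `FALSE`.
#' @param ... Unused.
#' @return A data frame with one row per query: `hla`, `peptide`, `F`, `C`
#'   (`"positive"`/`"negative"`), `P_hla`, `P_peptide`, `hla_defined`,
#'   `pep_defined`, `fallback` (one of `"none"`, `"side_mean"`,
#'   `"hla_side_only"`, `"peptide_side_only"`, `"global_mean"`).
#' @export
predict.nebula <- function(object, newdata = NULL, leave_out = FALSE, ...) {
  net <- object$network
  if (is.null(newdata)) {
    newdata <- data.frame(hla = net$hla[net$edge_h],
                          peptide = net$peptide[net$edge_p],
                          stringsAsFactors = FALSE)
  }
  stopifnot(all(c("hla", "peptide") %in% names(newdata)))
  ih <- match(newdata$hla, net$hla)
  ip <- match(newdata$peptide, net$peptide)
  n <- nrow(newdata)
  Fv <- Ph <- Pp <- numeric(n)
  hd <- pd <- logical(n)
  fb <- character(n)
  for (r in seq_len(n)) {
    if (!is.na(ih[r]) && is.na(ip[r])) {
      s <- .nebula_side_nomate(object, ih[r], side = "hla")
    } else if (is.na(ih[r]) && !is.na(ip[r])) {
      s <- .nebula_side_nomate(object, ip[r], side = "peptide")
    } else if (is.na(ih[r]) && is.na(ip[r])) {
      s <- list(F = object$global_mean, P_hla = NA_real_, P_peptide = NA_real_,
                hla_defined = FALSE, pep_defined = FALSE, fallback = "global_mean")
    } else {
      s <- .nebula_score_one(object, ih[r], ip[r], leave_out)
    }
    Fv[r] <- s$F; Ph[r] <- s$P_hla; Pp[r] <- s$P_peptide
    hd[r] <- s$hla_defined; pd[r] <- s$pep_defined; fb[r] <- s$fallback
  }
  data.frame(hla = newdata$hla, peptide = newdata$peptide,
             F = Fv, C = ifelse(Fv >= object$ul, "positive", "negative"),
             P_hla = Ph, P_peptide = Pp,
             hla_defined = hd, pep_defined = pd, fallback = fb,
             stringsAsFactors = FALSE)
}

# One known node, opposite endpoint unknown: the neighbor sum is empty on the
# known side (the unknown node has no edges), so the side value is the node
# mean; the other side is undefined.
.nebula_side_nomate <- function(fit, idx, side) {
  net <- fit$network
  m <- if (side == "hla") net$h_wsum[idx] / net$h_deg[idx]
       else net$p_wsum[idx] / net$p_deg[idx]
  list(F = m,
       P_hla = if (side == "hla") m else NA_real_,
       P_peptide = if (side == "peptide") m else NA_real_,
       hla_defined = side == "hla", pep_defined = side == "peptide",
       fallback = if (side == "hla") "hla_side_only" else "peptide_side_only")
}

#' Pearson similarity between two HLAs over their shared peptides
#'
#' The correlation of the two alleles' edge weights across peptides connected
#' to both, centering each allele's weights at its mean over all its incident
#' edges. Returns 0 when no peptide is shared or when either allele's shared
#' weights are degenerate (zero variance around its mean). When `exclude`
#' names an edge, that edge is removed from the means and the shared set.
#'
#' @param net A [binding_network()].
#' @param hla_a,hla_b Allele names.
#' @param exclude Optional `c(hla, peptide)` edge to leave out.
#' @param epsilon Degeneracy threshold on the denominator.
#' @return Similarity in \[-1, 1\].
#' @export
similarity_hla <- function(net, hla_a, hla_b, exclude = NULL, epsilon = 1e-12) {
  .similarity(net, match(hla_a, net$hla), match(hla_b, net$hla), "hla",
              exclude, epsilon)
}

#' Pearson similarity between two peptides over their shared HLAs
#'
#' Mirror of [similarity_hla()] with the sides swapped.
#' @param net A [binding_network()].
#' @param pep_a,pep_b Peptide sequences.
#' @inheritParams similarity_hla
#' @return Similarity in \[-1, 1\].
#' @export
similarity_peptide <- function(net, pep_a, pep_b, exclude = NULL, epsilon = 1e-12) {
  .similarity(net, match(pep_a, net$peptide), match(pep_b, net$peptide),
              "peptide", exclude, epsilon)
}

.similarity <- function(net, ia, ib, side, exclude, epsilon) {
  if (is.na(ia) || is.na(ib)) stop("unknown node in similarity query")
  if (side == "hla") {
    nbr <- net$h_nbr; wts <- net$h_w; deg <- net$h_deg; wsum <- net$h_wsum
  } else {
    nbr <- net$p_nbr; wts <- net$p_w; deg <- net$p_deg; wsum <- net$p_wsum
  }
  Aa <- nbr[[ia]]; Wa <- wts[[ia]]; da <- deg[ia]; sa <- wsum[ia]
  Ab <- nbr[[ib]]; Wb <- wts[[ib]]; db <- deg[ib]; sb <- wsum[ib]
  if (!is.null(exclude)) {
    eh <- match(exclude[[1]], net$hla); ep <- match(exclude[[2]], net$peptide)
    eidx <- if (side == "hla") c(eh, ep) else c(ep, eh)  # (this-side node, mate)
    if (!is.na(eidx[1]) && !is.na(eidx[2])) {
      for (who in c("a", "b")) {
        i <- if (who == "a") ia else ib
        if (eidx[1] == i) {
          if (who == "a") { k <- Aa != eidx[2]
            if (any(!k)) { sa <- sa - Wa[!k]; da <- da - 1L; Aa <- Aa[k]; Wa <- Wa[k] }
          } else { k <- Ab != eidx[2]
            if (any(!k)) { sb <- sb - Wb[!k]; db <- db - 1L; Ab <- Ab[k]; Wb <- Wb[k] }
          }
        }
      }
    }
  }
  if (da == 0L || db == 0L) return(0)
  ma <- sa / da; mb <- sb / db
  pos <- match(Aa, Ab)
  sel <- which(!is.na(pos))
  if (length(sel) == 0L) return(0)
  a <- Wa[sel] - ma
  b <- Wb[pos[sel]] - mb
  den <- sqrt(sum(a * a) * sum(b * b))
  if (den < epsilon) return(0)
  sum(a * b) / den
}
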