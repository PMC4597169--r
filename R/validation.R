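#' Rank-based ROC AUC with midranks for ties
#'
#' Computes the area under the ROC curve via the Mann-Whitney formulation:
#' tied scores receive midranks, so ties contribute half a concordance. This
#' makes the AUC invariant under any strictly monotone transform of the
#' scores, and exactly 0.5 when all scores are identical.
#'
#' @param scores Numeric prediction scores (higher = more positive).
#' @param labels Binary true labels: logical, `"positive"`/`"negative"`, or
#'   weight codes 2/1.
#' @return AUC in \[0, 1\], or `NA` (with a warning) when only one class is
#'   present.
#' @export
roc_auc <- function(scores, labels) {
  pos <- .as_positive(labels)
  stopifnot(length(scores) == length(pos))
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L) {
    warning("AUC undefined: only one class present")
    return(NA_real_)
  }
  r <- rank(scores)          # midranks
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

.as_positive <- function(labels) {
  if (is.logical(labels)) return(labels)
  if (is.numeric(labels)) return(labels == 2)
  labels == "positive"
}

#' ROC curve points
#'
#' True/false positive rates at every distinct score threshold (descending),
#' for plotting the ROC curve whose area [roc_auc()] reports.
#'
#' @inheritParams roc_auc
#' @return Data frame with columns `threshold`, `fpr`, `tpr`.
#' @export
roc_points <- function(scores, labels) {
  pos <- .as_positive(labels)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; p <- pos[ord]
  keep <- !duplicated(s, fromLast = TRUE)   # last index of each tied block
  tp <- cumsum(p)[keep]; fp <- cumsum(!p)[keep]
  out <- rbind(data.frame(threshold = Inf, fpr = 0, tpr = 0),
               data.frame(threshold = s[keep],
                          fpr = fp / max(sum(!pos), 1),
                          tpr = tp / max(sum(pos), 1)))
  rownames(out) <- NULL
  out
}

#' Confusion-matrix metrics for categorical binding calls
#'
#' Sensitivity TP/(TP+FN), specificity TN/(TN+FP) and accuracy
#' (TP+TN)/total, with "positive" meaning binder.
#'
#' @param calls Predicted categories (same encodings as `labels`).
#' @param labels True categories.
#' @return Named list with `sensitivity`, `specificity`, `accuracy` and the
#'   counts `tp`, `fp`, `tn`, `fn`.
#' @export
confusion_metrics <- function(calls, labels) {
  pc <- .as_positive(calls); pl <- .as_positive(labels)
  stopifnot(length(pc) == length(pl))
  tp <- sum(pc & pl); fp <- sum(pc & !pl)
  tn <- sum(!pc & !pl); fn <- sum(!pc & pl)
  list(sensitivity = tp / (tp + fn), specificity = tn / (tn + fp),
       accuracy = (tp + tn) / length(pc), tp = tp, fp = fp, tn = tn, fn = fn)
}

.make_report <- function(edges_df, method, extra = list()) {
  cm <- confusion_metrics(edges_df$C, edges_df$label)
  structure(c(list(
    edges = edges_df,
    sensitivity = cm$sensitivity, specificity = cm$specificity,
    accuracy = cm$accuracy,
    auc = roc_auc(edges_df$F, edges_df$label),
    counts = cm[c("tp", "fp", "tn", "fn")],
    n_fallback_global = sum(edges_df$fallback == "global_mean"),
    method = method), extra),
    class = "validation_report")
}

#' Leave-one-out validation of a Nebula fit
#'
#' Takes each training edge out one at a time and predicts it from the
#' remaining network (exclusion removes the edge from every mean, similarity
#' and neighbor sum), then aggregates sensitivity, specificity, accuracy and
#' rank-based AUC over all edges. Edges resolved purely by the global-mean
#' fallback are included in the metrics and counted separately.
#'
#' @param fit A [nebula()] model.
#' @return Object of class `"validation_report"` with per-edge predictions
#'   (`$edges`) and aggregate metrics.
#' @export
loo_validate <- function(fit) {
  net <- fit$network
  if (any(net$h_deg < 2L) || any(net$p_deg < 2L)) {
    warning("nodes with a single edge present; their left-out edges are ",
            "predicted via the fallback cascade")
  }
  pred <- predict(fit, leave_out = TRUE)
  pred$label <- ifelse(net$edge_w == 2L, "positive", "negative")
  .make_report(pred, "loo")
}

#' Repeated k-fold cross-validation of a Nebula fit
#'
#' Each iteration splits the edges uniformly at random into k near-equal
#' folds (sizes differing by at most one); each fold is predicted from a
#' model trained on the union of the others. Splitting is by edges, so a node
#' may appear in several folds; test edges whose endpoints lose all training
#' edges are resolved by the fallback cascade and flagged. Iteration i uses
#' seed `base_seed + i`, making the whole run reproducible. With
#' `k = number of edges` and one iteration this reduces exactly to
#' [loo_validate()].
#'
#' @param fit A [nebula()] model.
#' @param k Number of folds (default 2, the paper-style even split).
#' @param iterations Number of random repetitions (default 100).
#' @param base_seed Integer seed base.
#' @return Object of class `"cv_report"`: list with `iterations` (data frame
#'   of per-iteration sensitivity/specificity/accuracy/auc), `mean`, `sd`,
#'   `reports` (per-iteration `validation_report`s), `k`, `seeds`.
#' @export
kfold_validate <- function(fit, k = 2L, iterations = 100L, base_seed = 1L) {
  net <- fit$network
  ne <- length(net$edge_w)
  stopifnot(k >= 2L, ne >= k)
  edge_df <- data.frame(hla = net$hla[net$edge_h],
                        peptide = net$peptide[net$edge_p],
                        weight = net$edge_w, stringsAsFactors = FALSE)
  seeds <- as.integer(base_seed) + seq_len(iterations)
  reports <- vector("list", iterations)
  for (it in seq_len(iterations)) {
    set.seed(seeds[it])
    fold <- sample(rep_len(seq_len(k), ne))
    preds <- vector("list", k)
    for (f in seq_len(k)) {
      train <- edge_df[fold != f, , drop = FALSE]
      test <- edge_df[fold == f, , drop = FALSE]
      sub_fit <- nebula(binding_network(train), ul = fit$ul,
                        denominator = fit$denominator, epsilon = fit$epsilon)
      p <- predict(sub_fit, newdata = test[c("hla", "peptide")])
      p$label <- ifelse(test$weight == 2L, "positive", "negative")
      preds[[f]] <- p
    }
    reports[[it]] <- .make_report(do.call(rbind, preds), "kfold",
                                  list(k = k, seed = seeds[it]))
  }
  metrics <- data.frame(
    iteration = seq_len(iterations),
    sensitivity = vapply(reports, `[[`, numeric(1), "sensitivity"),
    specificity = vapply(reports, `[[`, numeric(1), "specificity"),
    accuracy = vapply(reports, `[[`, numeric(1), "accuracy"),
    auc = vapply(reports, `[[`, numeric(1), "auc"))
  structure(list(
    iterations = metrics,
    mean = colMeans(metrics[-1]),
    sd = vapply(metrics[-1], stats::sd, numeric(1)),
    reports = reports, k = k, seeds = seeds), class = "cv_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("%s validation over %d edges\n",
              if (x$method == "loo") "Leave-one-out" else "Fold", nrow(x$edges)))
  cat(sprintf("  sensitivity %.3f, specificity %.3f, accuracy %.3f, AUC %.3f\n",
              x$sensitivity, x$specificity, x$accuracy, x$auc))
  if (x$n_fallback_global > 0)
    cat(sprintf("  %d edge(s) predicted by global-mean fallback\n",
                x$n_fallback_global))
  invisible(x)
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("%d-fold cross-validation, %d iterations\n",
              x$k, nrow(x$iterations)))
  for (m in c("sensitivity", "specificity", "accuracy", "auc")) {
    cat(sprintf("  %s: %.4f +/- %.4f\n", m, x$mean[[m]], x$sd[[m]]))
  }
  invisible(x)
}

#' Serialize a validation report to JSON (metrics) and TSV (per-edge)
#'
#' @param report A `validation_report`.
#' @param json_path,tsv_path Output paths; either may be `NULL` to skip.
#' @return Invisibly, the metric list written to JSON.
#' @export
write_validation_report <- function(report, json_path = NULL, tsv_path = NULL) {
  metrics <- list(method = report$method,
                  n_edges = nrow(report$edges),
                  sensitivity = report$sensitivity,
                  specificity = report$specificity,
                  accuracy = report$accuracy, auc = report$auc,
                  counts = report$counts,
                  n_fallback_global = report$n_fallback_global)
  if (!is.null(json_path))
    jsonlite::write_json(metrics, json_path, auto_unbox = TRUE, digits = NA)
  if (!is.null(tsv_path))
    utils::write.table(report$edges, tsv_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  invisible(metrics)
}
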