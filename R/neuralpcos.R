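#' Fit a neuralPCOS diagnostic scoring model
#'
#' The full training pipeline in one call: (1) log2 transform (counts ->
#' log2(CPM+1)); (2) moderated-t differential expression with the
#' p < `p_cut`, |logFC| > `lfc_cut`, bottom-`low_expr_quantile`
#' expression screen; (3) random-forest tuning (mtry sweep by OOB error,
#' ntree by the stability rule) and gene selection at the
#' MeanDecreaseGini >= `gini_threshold` cut; (4) min-max normalization and
#' training of a d-`n_hidden`-2 logistic network on the selected genes;
#' (5) extraction of the per-gene network weights defining the linear
#' diagnostic score sum(expression_norm * weight).
#'
#' @param train an [expression_matrix()] of training samples (log2 or
#'   counts scale) with both classes present.
#' @param p_cut,lfc_cut,low_expr_quantile DEG screen thresholds (defaults
#'   0.01, 0.26, 0.25).
#' @param mtry_max,ntree_probe,ntree_max,stability_eps,gini_threshold
#'   random-forest tuning parameters (defaults 2000, 500, 3000, 0.005,
#'   0.15).
#' @param ntree_min floor on the trees of the final importance forest
#'   (default 500). The stability rule can legitimately settle on a very
#'   small ntree when the out-of-bag error trace is flat (e.g. strongly
#'   separable classes), but importance estimates are averages over trees
#'   and need a real ensemble; the final forest uses
#'   `max(chosen_ntree, ntree_min)`.
#' @param n_hidden hidden units of the network (default 3).
#' @param max_genes optional cap on the number of selected genes passed to
#'   the network (top of the Gini ranking); `NULL` passes all selected
#'   genes.
#' @param seed one integer seed; stage seeds are derived from it
#'   deterministically.
#' @return An object of class `"neuralpcos"`: a list with `deg_table`,
#'   `deg_genes` (up/down calls), `mtry` and `ntree` sweeps, `rf`
#'   (the [importance_and_select()] result), `score_model`, `seed` and
#'   `call`. Methods: [print.neuralpcos()], [summary.neuralpcos()],
#'   [coef.neuralpcos()] (gene weights), [predict.neuralpcos()]
#'   (scores for new data), [plot.neuralpcos()].
#' @examples
#' sim <- simulate_expression(sim_config(n_genes = 300, n_de = 20, seed = 1))
#' fit <- neuralpcos(sim$matrix, mtry_max = 30, ntree_max = 500, seed = 1)
#' fit
#' val <- simulate_expression(sim_config(n_genes = 300, n_de = 20, seed = 2))
#' roc_auc(predict(fit, val$matrix), val$matrix$class_labels)
#' @export
neuralpcos <- function(train, p_cut = 0.01, lfc_cut = 0.26,
                       low_expr_quantile = 0.25, mtry_max = 2000,
                       ntree_probe = 500, ntree_max = 3000,
                       stability_eps = 0.005, ntree_min = 500,
                       gini_threshold = 0.15,
                       n_hidden = 3, max_genes = NULL, seed = 1) {
  stopifnot(inherits(train, "expr_matrix"))
  cl <- match.call()
  train <- to_log2(train)

  deg_tab <- filter_degs(moderated_t(train), p_cut = p_cut,
                         lfc_cut = lfc_cut,
                         low_expr_quantile = low_expr_quantile)
  calls <- deg_calls(deg_tab)
  if (nrow(calls) < 2)
    stop("fewer than 2 genes pass the DEG screen; nothing to model")

  X <- t(train$values[calls$gene_id, , drop = FALSE])
  y <- train$class_labels
  s_rf <- stage_seed(seed, "rf_select")
  mt <- tune_mtry(X, y, mtry_max = mtry_max, ntree_probe = ntree_probe,
                  seed = s_rf)
  nt <- tune_ntree(X, y, mt$chosen_mtry, ntree_max = ntree_max,
                   stability_eps = stability_eps, seed = s_rf)
  rf <- importance_and_select(X, y, mt$chosen_mtry,
                              max(nt$chosen_ntree, ntree_min),
                              gini_threshold = gini_threshold, seed = s_rf)
  genes <- rf$selected_genes
  if (length(genes) == 0)
    stop("no gene reaches the Gini importance threshold; cannot train a score")
  if (!is.null(max_genes)) genes <- utils::head(genes, max_genes)

  sm <- build_score_model(train, genes, n_hidden = n_hidden,
                          seed = stage_seed(seed, "ann_score"))
  structure(
    list(deg_table = deg_tab, deg_genes = calls,
         mtry = mt, ntree = nt, rf = rf, score_model = sm,
         seed = as.integer(seed), call = cl),
    class = "neuralpcos"
  )
}

#' @export
print.neuralpcos <- function(x, ...) {
  cnt <- attr(x$deg_table, "counts")
  cat("neuralPCOS diagnostic score model\n")
  cat(sprintf("  DEG screen : %d up + %d down of %d genes\n",
              cnt["up"], cnt["down"], nrow(x$deg_table)))
  cat(sprintf("  RF         : mtry=%d, ntree=%d, OOB error %.3f\n",
              x$rf$chosen_mtry, x$rf$chosen_ntree, x$rf$oob_error))
  cat(sprintf("  selection  : %d genes at MeanDecreaseGini >= %g\n",
              length(x$rf$selected_genes), x$rf$gini_threshold))
  cat(sprintf("  network    : %d-%d-2, %s\n",
              length(x$score_model$gene_ids),
              x$score_model$provenance$n_hidden,
              if (x$score_model$provenance$converged) "converged"
              else "stopped at epoch cap"))
  invisible(x)
}

#' @export
summary.neuralpcos <- function(object, ...) {
  print(object)
  cat("\nGene weights (descending |weight|):\n")
  w <- stats::setNames(object$score_model$weights, object$score_model$gene_ids)
  print(round(w[order(-abs(w))], 4))
  invisible(object)
}

#' @export
coef.neuralpcos <- function(object, ...) {
  stats::setNames(object$score_model$weights, object$score_model$gene_ids)
}

#' Score new samples with a fitted model
#'
#' @param object a `neuralpcos` fit.
#' @param newdata an `expr_matrix` containing all model genes.
#' @param ... unused.
#' @return Named numeric vector of per-sample diagnostic scores (higher =
#'   more case-like).
#' @export
predict.neuralpcos <- function(object, newdata, ...) {
  score_samples(newdata, object$score_model)
}

#' Diagnostic plots of a fitted model
#'
#' @param x a `neuralpcos` fit.
#' @param which `"mtry"` (OOB error over the mtry sweep), `"ntree"`
#'   (cumulative OOB error trace), `"importance"` (top MeanDecreaseGini),
#'   or `"weights"` (gene weights of the score).
#' @param n_top genes shown in the importance/weight panels.
#' @param ... passed to the underlying base-graphics call.
#' @export
plot.neuralpcos <- function(x, which = c("mtry", "ntree", "importance",
                                         "weights"), n_top = 12, ...) {
  which <- match.arg(which)
  switch(which,
    mtry = plot(x$mtry$sweep$mtry, x$mtry$sweep$oob_error, type = "b",
                xlab = "mtry", ylab = "OOB error", ...),
    ntree = plot(x$ntree$sweep$ntree, x$ntree$sweep$oob_error, type = "l",
                 xlab = "trees", ylab = "cumulative OOB error", ...),
    importance = {
      imp <- utils::head(x$rf$importance, n_top)
      graphics::barplot(rev(imp$mean_decrease_gini),
                        names.arg = rev(imp$gene_id), horiz = TRUE,
                        las = 1, xlab = "MeanDecreaseGini", ...)
      graphics::abline(v = x$rf$gini_threshold, lty = 2)
    },
    weights = {
      w <- stats::setNames(x$score_model$weights, x$score_model$gene_ids)
      w <- utils::head(w[order(-abs(w))], n_top)
      graphics::barplot(rev(w), names.arg = rev(names(w)), horiz = TRUE,
                        las = 1, xlab = "network gene weight", ...)
    })
  invisible(x)
}

# One global seed expands into reproducible per-stage seeds by hashing the
# stage name; kept below 2^31 so it is a valid R integer seed.
stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 2654435 + h) %% .Machine$integer.max)
}
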