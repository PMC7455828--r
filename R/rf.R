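#' Sweep mtry by out-of-bag error
#'
#' Fits one random forest per candidate mtry (number of variables tried at
#' each split) over 1..min(mtry_max, n_genes) with `ntree_probe` trees each
#' and records the out-of-bag (OOB) misclassification rate. The chosen
#' mtry minimises OOB error; ties go to the smallest (cheapest) mtry.
#'
#' @param X numeric matrix, samples x genes (e.g. the transposed DEG
#'   expression matrix).
#' @param y factor or character class labels (`case` / `control`).
#' @param mtry_max upper end of the sweep (capped at `ncol(X)`;
#'   default 2000).
#' @param ntree_probe trees per probe forest (default 500).
#' @param seed integer seed driving all bootstrap randomness.
#' @return A list with `sweep` (data.frame `mtry`, `oob_error`) and
#'   `chosen_mtry`.
#' @export
tune_mtry <- function(X, y, mtry_max = 2000, ntree_probe = 500, seed = 1) {
  y <- check_rf_input(X, y)
  grid <- seq_len(min(mtry_max, ncol(X)))
  set.seed(as.integer(seed))
  oob <- vapply(grid, function(mt) {
    fit <- randomForest::randomForest(x = X, y = y, mtry = mt,
                                      ntree = ntree_probe)
    fit$err.rate[ntree_probe, "OOB"]
  }, numeric(1))
  list(sweep = data.frame(mtry = grid, oob_error = oob),
       chosen_mtry = grid[which.min(oob)])
}

#' Choose ntree from the cumulative out-of-bag error trace
#'
#' Grows a single forest of `ntree_max` trees at the tuned mtry and reads
#' the cumulative OOB error as trees accumulate. The chosen ntree is the
#' smallest t whose error, and the error of every larger forest in the
#' trace, stays within `stability_eps` of the overall minimum — the
#' "lowest error and best stability" rule made operational.
#'
#' @inheritParams tune_mtry
#' @param chosen_mtry mtry to grow the forest with.
#' @param ntree_max trace length (default 3000).
#' @param stability_eps stability band around the minimum OOB error
#'   (default 0.005).
#' @return A list with `sweep` (data.frame `ntree`, `oob_error`) and
#'   `chosen_ntree`.
#' @export
tune_ntree <- function(X, y, chosen_mtry, ntree_max = 3000,
                       stability_eps = 0.005, seed = 1) {
  y <- check_rf_input(X, y)
  set.seed(as.integer(seed))
  fit <- randomForest::randomForest(x = X, y = y, mtry = chosen_mtry,
                                    ntree = ntree_max)
  trace <- fit$err.rate[, "OOB"]
  # the first few entries can be NaN before every sample has an OOB vote;
  # such forests cannot count as stable
  band <- min(trace, na.rm = TRUE) + stability_eps
  in_band <- !is.na(trace) & trace <= band
  stable_from <- rev(cumprod(rev(in_band)))  # 1 where all t' >= t in band
  chosen <- which(stable_from == 1)[1]
  # with few samples the OOB granularity (1/n) can exceed the band, so no
  # suffix may qualify; the full trace is then the most stable choice
  if (is.na(chosen)) chosen <- ntree_max
  list(sweep = data.frame(ntree = seq_len(ntree_max), oob_error = trace),
       chosen_ntree = chosen)
}

#' Fit the tuned forest, report dual importances, select genes by Gini
#'
#' Fits the final forest and reports, per gene, MeanDecreaseGini (total
#' Gini impurity decrease attributed to the gene, averaged over trees, on
#' the raw randomForest scale) and MeanDecreaseAccuracy (unscaled drop in
#' OOB accuracy when the gene's out-of-bag values are permuted). Genes with
#' MeanDecreaseGini at or above `gini_threshold` are selected, ranked by
#' decreasing Gini importance.
#'
#' @inheritParams tune_ntree
#' @param chosen_ntree trees in the final forest.
#' @param gini_threshold MeanDecreaseGini selection threshold
#'   (default 0.15).
#' @param normalize_importance report Gini importances rescaled to sum to
#'   one instead of the raw total-decrease scale (default `FALSE`; the
#'   default threshold is meaningful on the raw scale).
#' @return A list of class `"rf_selection"`: `importance` (data.frame
#'   `gene_id`, `mean_decrease_accuracy`, `mean_decrease_gini`, sorted by
#'   Gini), `selected_genes`, `gini_threshold`, `chosen_mtry`,
#'   `chosen_ntree`, `oob_error`, and the fitted `forest`.
#' @export
importance_and_select <- function(X, y, chosen_mtry, chosen_ntree,
                                  gini_threshold = 0.15, seed = 1,
                                  normalize_importance = FALSE) {
  y <- check_rf_input(X, y)
  set.seed(as.integer(seed))
  fit <- randomForest::randomForest(x = X, y = y, mtry = chosen_mtry,
                                    ntree = chosen_ntree, importance = TRUE)
  mda <- randomForest::importance(fit, type = 1, scale = FALSE)[, 1]
  gini <- randomForest::importance(fit, type = 2)[, 1]
  if (normalize_importance && sum(gini) > 0) gini <- gini / sum(gini)
  ord <- order(gini, decreasing = TRUE)
  imp <- data.frame(gene_id = colnames(X)[ord],
                    mean_decrease_accuracy = unname(mda[ord]),
                    mean_decrease_gini = unname(gini[ord]),
                    stringsAsFactors = FALSE)
  selected <- imp$gene_id[imp$mean_decrease_gini >= gini_threshold]
  if (length(selected) == 0)
    warning("no gene reaches the Gini importance threshold ",
            gini_threshold, "; selection is empty")
  structure(
    list(importance = imp, selected_genes = selected,
         gini_threshold = gini_threshold, chosen_mtry = chosen_mtry,
         chosen_ntree = chosen_ntree,
         oob_error = unname(fit$err.rate[chosen_ntree, "OOB"]),
         forest = fit),
    class = "rf_selection"
  )
}

#' @export
print.rf_selection <- function(x, ...) {
  cat(sprintf(
    "<rf_selection> mtry=%d ntree=%d OOB=%.3f; %d genes at Gini >= %g\n",
    x$chosen_mtry, x$chosen_ntree, x$oob_error,
    length(x$selected_genes), x$gini_threshold))
  invisible(x)
}

check_rf_input <- function(X, y) {
  if (!is.matrix(X) || !is.numeric(X)) stop("`X` must be a numeric matrix")
  y <- factor(as.character(y), levels = c("control", "case"))
  if (anyNA(y)) stop("class labels must be 'case' or 'control'")
  if (length(y) != nrow(X)) stop("one label per row of `X` required")
  if (nlevels(droplevels(y)) < 2) stop("both classes must be present")
  y
}
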