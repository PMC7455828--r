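#' Published comparator marker-gene sets
#'
#' The two literature gene panels the diagnostic score is benchmarked
#' against: `EC-PCOS`, three genes upregulated in endometrial cells of
#' PCOS (IGF1, PTEN, IGFBP1), and `GC-PCOS`, four genes upregulated in
#' granulosa cells (HSD3B2, STAR, INHBA, CYP19A1).
#'
#' @return Named list of character vectors.
#' @export
comparator_gene_sets <- function() {
  list(
    `EC-PCOS` = c("IGF1", "PTEN", "IGFBP1"),
    `GC-PCOS` = c("HSD3B2", "STAR", "INHBA", "CYP19A1")
  )
}

#' Unweighted comparator score of a gene panel
#'
#' The analogue of the neural score with all weights equal to one: per
#' sample, the sum of min-max-normalized log2 expression over the panel
#' genes present in the matrix. Panel genes absent from the matrix are
#' dropped with a warning; a panel with no genes present is an error.
#'
#' @param m an `expr_matrix` (counts are log2-CPM transformed first).
#' @param genes character vector of panel gene ids.
#' @param name optional panel name used in messages.
#' @return Named numeric vector of per-sample scores.
#' @export
comparator_score <- function(m, genes, name = "comparator") {
  stopifnot(inherits(m, "expr_matrix"))
  if (length(genes) == 0) stop("empty comparator gene set")
  m <- to_log2(m)
  present <- intersect(genes, rownames(m$values))
  if (length(present) == 0)
    stop("no gene of comparator set '", name, "' is present in the matrix")
  if (length(present) < length(genes))
    warning(sprintf("comparator '%s': dropping %d absent gene(s): %s",
                    name, length(genes) - length(present),
                    paste(setdiff(genes, present), collapse = ", ")))
  sub <- subset_expr(m, genes = present)
  norm <- minmax_normalize(sub)
  colSums(norm$matrix$values)
}

#' ROC curve, AUC and Youden-optimal threshold
#'
#' Sweeps the decision threshold over the unique score values (plus
#' infinite endpoints), calling a sample positive (case) when its score is
#' at or above the threshold. The AUC is the trapezoidal area under the
#' (1 - specificity, sensitivity) polyline, which for this sweep equals
#' the Mann-Whitney concordance probability with ties counted 1/2. The
#' optimal threshold maximises the Youden index J = sens + spec - 1 over
#' finite thresholds; ties go to the lower threshold.
#'
#' @param scores numeric vector, higher = more case-like.
#' @param labels class labels (`case` / `control`), both present.
#' @return A list of class `"roc_result"`: `model_name`, `points`
#'   (data.frame `threshold`, `sensitivity`, `specificity`), `auc`,
#'   `optimal_threshold`, `sens_at_opt`, `spec_at_opt`.
#' @param model_name label carried into the result.
#' @export
roc_auc <- function(scores, labels, model_name = "model") {
  labels <- as.character(labels)
  if (!all(labels %in% c("case", "control")))
    stop("labels must be 'case' or 'control'")
  if (length(scores) != length(labels) || length(scores) < 2)
    stop("need matching scores and labels for >= 2 samples")
  pos <- labels == "case"
  if (!any(pos) || all(pos)) stop("both classes must be present")
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE), -Inf)
  sens <- vapply(thr, function(t) mean(scores[pos] >= t), numeric(1))
  spec <- vapply(thr, function(t) mean(scores[!pos] < t), numeric(1))
  fpr <- 1 - spec
  auc <- sum(diff(fpr) * (utils::head(sens, -1) + utils::tail(sens, -1)) / 2)
  finite <- is.finite(thr)
  j <- sens + spec - 1
  j[!finite] <- -Inf
  best <- which(j == max(j[finite]))
  opt <- best[which.min(thr[best])]
  structure(
    list(model_name = model_name,
         points = data.frame(threshold = thr, sensitivity = sens,
                             specificity = spec),
         auc = auc, optimal_threshold = thr[opt],
         sens_at_opt = sens[opt], spec_at_opt = spec[opt]),
    class = "roc_result"
  )
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf(
    "<roc_result> %s: AUC %.4f; optimal threshold %.4g (sens %.1f%%, spec %.1f%%)\n",
    x$model_name, x$auc, x$optimal_threshold,
    100 * x$sens_at_opt, 100 * x$spec_at_opt))
  invisible(x)
}

#' @export
plot.roc_result <- function(x, add = FALSE, col = 1, ...) {
  fpr <- 1 - x$points$specificity
  if (!add) {
    plot(fpr, x$points$sensitivity, type = "l", col = col,
         xlab = "1 - specificity", ylab = "sensitivity",
         main = sprintf("%s (AUC %.3f)", x$model_name, x$auc), ...)
    graphics::abline(0, 1, lty = 3, col = "grey")
  } else {
    graphics::lines(fpr, x$points$sensitivity, col = col, ...)
  }
  invisible(x)
}

#' Benchmark the neural score against comparator panels on validation data
#'
#' Scores the validation matrix with the fitted score model and with each
#' comparator panel (unweighted normalized-expression sums), and evaluates
#' each by ROC/AUC. A comparator whose genes are all absent is reported as
#' a warning and skipped; the remaining models are still evaluated.
#'
#' @param validation an `expr_matrix` of held-out samples.
#' @param sm a `score_model`.
#' @param comparators named list of comparator gene vectors (default
#'   [comparator_gene_sets()]).
#' @return Named list of `roc_result`, first entry `"neuralPCOS"`, with a
#'   summary data.frame attached as attribute `"summary"` (`model`, `auc`,
#'   `optimal_threshold`, `sensitivity`, `specificity`).
#' @export
compare_models <- function(validation, sm,
                           comparators = comparator_gene_sets()) {
  stopifnot(inherits(validation, "expr_matrix"))
  results <- list(
    neuralPCOS = roc_auc(score_samples(validation, sm),
                         validation$class_labels, "neuralPCOS")
  )
  for (nm in names(comparators)) {
    res <- tryCatch(
      roc_auc(comparator_score(validation, comparators[[nm]], nm),
              validation$class_labels, nm),
      error = function(e) {
        warning(sprintf("comparator '%s' could not be scored: %s",
                        nm, conditionMessage(e)))
        NULL
      })
    if (!is.null(res)) results[[nm]] <- res
  }
  attr(results, "summary") <- data.frame(
    model = vapply(results, `[[`, character(1), "model_name"),
    auc = vapply(results, `[[`, numeric(1), "auc"),
    optimal_threshold = vapply(results, `[[`, numeric(1), "optimal_threshold"),
    sensitivity = vapply(results, `[[`, numeric(1), "sens_at_opt"),
    specificity = vapply(results, `[[`, numeric(1), "spec_at_opt"),
    row.names = NULL, stringsAsFactors = FALSE
  )
  results
}
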