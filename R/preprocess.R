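#' Convert raw counts to log2(CPM + 1)
#'
#' Counts are scaled per sample to counts-per-million and transformed as
#' log2(CPM + 1), so a zero count maps exactly to zero. Log2-scale input is
#' returned unchanged (the transform is idempotent).
#'
#' @param m an [expression_matrix()].
#' @return An `expr_matrix` on the log2 scale.
#' @export
to_log2 <- function(m) {
  stopifnot(inherits(m, "expr_matrix"))
  if (m$scale == "log2") return(m)
  if (any(m$values < 0)) stop("counts must be non-negative")
  lib <- colSums(m$values)
  if (any(lib == 0)) stop("sample with zero total counts")
  cpm <- sweep(m$values, 2, lib / 1e6, "/")
  expression_matrix(log2(cpm + 1), m$class_labels, m$batch_labels, "log2")
}

#' Merge expression datasets on their common genes
#'
#' Takes the intersection of gene ids across all inputs and concatenates
#' samples; each source dataset becomes one batch level (its position in the
#' list, or `names(ms)` when supplied), ready for [combat_adjust()].
#'
#' @param ms list of two or more log2-scale `expr_matrix` objects.
#' @return An `expr_matrix` on the common gene set.
#' @export
merge_datasets <- function(ms) {
  if (!is.list(ms) || length(ms) < 2) stop("need a list of >= 2 matrices")
  for (m in ms) {
    stopifnot(inherits(m, "expr_matrix"))
    if (m$scale != "log2") stop("all matrices must be on the log2 scale")
  }
  common <- Reduce(intersect, lapply(ms, function(m) rownames(m$values)))
  if (length(common) == 0) stop("empty gene intersection across datasets")
  labels <- names(ms)
  if (is.null(labels)) labels <- paste0("dataset", seq_along(ms))
  vals <- do.call(cbind, lapply(ms, function(m) m$values[common, , drop = FALSE]))
  if (anyDuplicated(colnames(vals))) stop("duplicate sample ids across datasets")
  cls <- unlist(lapply(ms, function(m) m$class_labels), use.names = FALSE)
  batch <- rep(labels, vapply(ms, function(m) ncol(m$values), integer(1)))
  expression_matrix(vals, cls, batch, "log2")
}

#' Empirical-Bayes batch adjustment (ComBat)
#'
#' Removes additive/multiplicative batch effects by the Johnson (2007)
#' location/scale model with empirical-Bayes shrinkage of the per-batch
#' parameters, protecting the case/control contrast as a model covariate.
#' The computation is delegated to \code{sva::ComBat}; `parametric = TRUE`
#' uses the normal / inverse-gamma priors, `FALSE` the non-parametric
#' (weighted Monte-Carlo) posterior means. Genes with zero variance across
#' samples carry no batch information and are passed through unadjusted.
#'
#' @param m an `expr_matrix` on the log2 scale with >= 2 batches, each with
#'   >= 2 samples.
#' @param parametric logical; prior family for the EB step.
#' @return A batch-adjusted `expr_matrix` with identical dimensions, gene
#'   order and metadata.
#' @export
combat_adjust <- function(m, parametric = TRUE) {
  stopifnot(inherits(m, "expr_matrix"))
  if (m$scale != "log2") stop("combat_adjust expects log2-scale data")
  tab <- table(m$batch_labels)
  if (length(tab) < 2) stop("need >= 2 batches")
  if (any(tab < 2)) stop("every batch must contain >= 2 samples")
  v <- m$values
  keep <- apply(v, 1, stats::var) > 0
  adj <- v
  if (any(keep)) {
    mod <- stats::model.matrix(~ factor(m$class_labels, c("control", "case")))
    adj[keep, ] <- suppressMessages(sva::ComBat(
      dat = v[keep, , drop = FALSE],
      batch = factor(m$batch_labels),
      mod = mod,
      par.prior = parametric
    ))
  }
  expression_matrix(adj, m$class_labels, m$batch_labels, "log2")
}

#' Per-gene min-max normalization to [0, 1]
#'
#' x' = (x - min_g) / (max_g - min_g), the normalization applied before
#' network training and scoring. With `ranges = NULL` the per-gene min/max
#' are computed from `m` itself (training mode) and returned; supplying a
#' previously computed `ranges` (validation mode) applies the training
#' statistics and clips the result into [0, 1] so scores stay bounded.
#' Constant genes map to 0.5, the centre of the range.
#'
#' @param m an `expr_matrix` on the log2 scale.
#' @param ranges optional `norm_ranges` from a previous call.
#' @return A list with elements `matrix` (normalized `expr_matrix`) and
#'   `ranges` (object of class `"norm_ranges"`: data.frame `gene_id`,
#'   `min`, `max`).
#' @export
minmax_normalize <- function(m, ranges = NULL) {
  stopifnot(inherits(m, "expr_matrix"))
  if (m$scale != "log2") stop("minmax_normalize expects log2-scale data")
  v <- m$values
  if (is.null(ranges)) {
    ranges <- norm_ranges(rownames(v),
                          apply(v, 1, min), apply(v, 1, max))
    clip <- FALSE
  } else {
    stopifnot(inherits(ranges, "norm_ranges"))
    idx <- match(rownames(v), ranges$gene_id)
    if (anyNA(idx))
      stop("`ranges` is missing genes present in the matrix")
    ranges <- ranges[idx, , drop = FALSE]
    class(ranges) <- c("norm_ranges", "data.frame")
    clip <- TRUE
  }
  span <- ranges$max - ranges$min
  out <- (v - ranges$min) / ifelse(span > 0, span, 1)
  out[span == 0, ] <- 0.5
  if (clip) out <- pmin(pmax(out, 0), 1)
  list(matrix = expression_matrix(out, m$class_labels, m$batch_labels, "log2"),
       ranges = ranges)
}

norm_ranges <- function(gene_id, min, max) {
  if (any(max < min)) stop("max < min in normalization ranges")
  structure(data.frame(gene_id = gene_id, min = min, max = max,
                       row.names = NULL, stringsAsFactors = FALSE),
            class = c("norm_ranges", "data.frame"))
}
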