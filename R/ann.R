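#' Train a d-H-2 feed-forward network on normalized expression
#'
#' A single hidden layer of `n_hidden` logistic units and two logistic
#' output units one-hot coding \{control, case\}, trained full-batch on the
#' sum-of-squared-error loss E = 1/2 sum (y - yhat)^2 with the iRprop-
#' resilient-backpropagation rule: each weight keeps its own step size,
#' multiplied by 1.2 while its gradient keeps sign and by 0.5 on a sign
#' flip (the flipped gradient is zeroed for one step). Training stops when
#' the sup-norm of the error gradient drops below `threshold` or after
#' `max_epochs` epochs, and the weights achieving the lowest loss seen are
#' returned, so the recorded error trace is non-increasing.
#'
#' Weights and biases are initialised i.i.d. Normal(0, 0.5^2) from `seed`;
#' the whole procedure is deterministic given the seed.
#'
#' @param X_norm numeric matrix, samples x genes, min-max normalized into
#'   [0, 1] (see [minmax_normalize()]); values outside [0, 1] beyond 1e-9
#'   are a contract violation.
#' @param y class labels (`case` / `control`), one per row.
#' @param n_hidden hidden units (default 3).
#' @param threshold stopping tolerance on the sup-norm of the gradient
#'   (default 0.01).
#' @param max_epochs epoch cap (default 1e5).
#' @param seed integer seed for the weight initialisation.
#' @return A list of class `"ann_model"`: `W1` (genes x hidden), `b1`,
#'   `W2` (hidden x 2, output order control then case), `b2`,
#'   `activation = "logistic"`, `training_error_trace` (best loss at each
#'   checkpoint), `converged`, `epochs`, `seed`, `gene_ids`,
#'   `class_levels = c("control", "case")`.
#' @export
train_ann <- function(X_norm, y, n_hidden = 3, threshold = 0.01,
                      max_epochs = 1e5, seed = 1) {
  if (!is.matrix(X_norm) || !is.numeric(X_norm))
    stop("`X_norm` must be a numeric matrix (samples x genes)")
  if (any(X_norm < -1e-9 | X_norm > 1 + 1e-9))
    stop("`X_norm` must be min-max normalized into [0, 1]")
  y <- factor(as.character(y), levels = c("control", "case"))
  if (anyNA(y)) stop("class labels must be 'case' or 'control'")
  if (length(y) != nrow(X_norm)) stop("one label per sample required")
  if (nlevels(droplevels(y)) < 2) stop("both classes must be present")
  d <- ncol(X_norm); H <- as.integer(n_hidden)
  Y <- cbind(control = as.numeric(y == "control"),
             case = as.numeric(y == "case"))

  set.seed(as.integer(seed))
  n_w <- d * H + H + H * 2 + 2
  w0 <- stats::rnorm(n_w, 0, 0.5)
  unpack <- function(w) {
    i <- 0
    W1 <- matrix(w[i + seq_len(d * H)], d, H); i <- i + d * H
    b1 <- w[i + seq_len(H)]; i <- i + H
    W2 <- matrix(w[i + seq_len(H * 2)], H, 2); i <- i + H * 2
    b2 <- w[i + 1:2]
    list(W1 = W1, b1 = b1, W2 = W2, b2 = b2)
  }
  loss_grad <- function(w) {
    p <- unpack(w)
    Hact <- stats::plogis(sweep(X_norm %*% p$W1, 2, p$b1, "+"))
    O <- stats::plogis(sweep(Hact %*% p$W2, 2, p$b2, "+"))
    err <- O - Y
    dO <- err * O * (1 - O)
    dH <- (dO %*% t(p$W2)) * Hact * (1 - Hact)
    list(loss = 0.5 * sum(err^2),
         grad = c(t(X_norm) %*% dH, colSums(dH),
                  t(Hact) %*% dO, colSums(dO)))
  }

  # iRprop- : per-weight adaptive steps
  w <- w0
  step <- rep(0.1, n_w)
  g_prev <- rep(0, n_w)
  lg <- loss_grad(w)
  best_w <- w; best_loss <- lg$loss
  trace <- best_loss
  converged <- FALSE
  epoch <- 0
  while (epoch < max_epochs) {
    epoch <- epoch + 1
    g <- lg$grad
    if (max(abs(g)) < threshold) { converged <- TRUE; break }
    sgn <- g * g_prev
    step <- pmin(pmax(ifelse(sgn > 0, step * 1.2,
                             ifelse(sgn < 0, step * 0.5, step)),
                      1e-6), 50)
    g[sgn < 0] <- 0                  # iRprop-: forget flipped gradients
    w <- w - sign(g) * step
    g_prev <- g
    lg <- loss_grad(w)
    if (lg$loss < best_loss) { best_loss <- lg$loss; best_w <- w }
    if (epoch %% 100 == 0) trace <- c(trace, best_loss)
  }
  trace <- c(trace, best_loss)
  p <- unpack(best_w)
  rownames(p$W1) <- colnames(X_norm)
  colnames(p$W2) <- c("control", "case")
  structure(
    list(W1 = p$W1, b1 = p$b1, W2 = p$W2, b2 = p$b2,
         activation = "logistic", training_error_trace = trace,
         converged = converged, epochs = epoch, seed = as.integer(seed),
         gene_ids = colnames(X_norm), class_levels = c("control", "case")),
    class = "ann_model"
  )
}

#' @export
print.ann_model <- function(x, ...) {
  cat(sprintf(
    "<ann_model> %d-%d-2 logistic network; %d epochs (%s), final SSE %.4g\n",
    nrow(x$W1), ncol(x$W1), x$epochs,
    if (x$converged) "converged" else "epoch cap",
    utils::tail(x$training_error_trace, 1)))
  invisible(x)
}

#' Forward pass of a trained network
#'
#' @param object an `ann_model`.
#' @param X_norm samples x genes matrix on the training normalization
#'   scale, columns ordered as `object$gene_ids`.
#' @param type `"response"` for the two output activations, `"class"` for
#'   the argmax label.
#' @param ... unused.
#' @return A samples x 2 matrix of output activations, or a character
#'   vector of predicted labels.
#' @export
predict.ann_model <- function(object, X_norm, type = c("response", "class"),
                              ...) {
  type <- match.arg(type)
  if (ncol(X_norm) != nrow(object$W1))
    stop("`X_norm` must have one column per model gene")
  Hact <- stats::plogis(sweep(X_norm %*% object$W1, 2, object$b1, "+"))
  O <- stats::plogis(sweep(Hact %*% object$W2, 2, object$b2, "+"))
  if (type == "response") return(O)
  object$class_levels[max.col(O, ties.method = "first")]
}

#' Linearized per-gene weights of a trained network
#'
#' The class-discriminative contribution of gene g through the hidden
#' layer: w_g = sum_h W1[g, h] * (W2[h, case] - W2[h, control]). It is
#' invariant to permuting hidden units, zero when the two output units
#' share weights, and equals the network's exact input-to-output map when
#' the activations are linear. These are the "neural network weights" of
#' the diagnostic score.
#'
#' @param model a trained `ann_model`.
#' @return Named numeric vector, one weight per gene.
#' @export
extract_gene_weights <- function(model) {
  if (!inherits(model, "ann_model")) stop("`model` must be an ann_model")
  drop(model$W1 %*% (model$W2[, "case"] - model$W2[, "control"]))
}

#' The neuralPCOS linear score of one normalized sample
#'
#' score = sum_g x_norm[g] * weight[g]: the expression of each model gene,
#' min-max normalized on the training ranges, multiplied by its
#' network-derived weight and summed. Exactly linear in the input.
#'
#' @param x_norm numeric vector of normalized expression ordered exactly as
#'   `sm$gene_ids` (names, when present, are checked).
#' @param sm a `score_model` from [build_score_model()].
#' @return A single numeric score.
#' @export
neural_score <- function(x_norm, sm) {
  stopifnot(inherits(sm, "score_model"))
  if (length(x_norm) != length(sm$gene_ids))
    stop("`x_norm` must have one value per model gene")
  if (!is.null(names(x_norm)) && !identical(names(x_norm), sm$gene_ids))
    stop("`x_norm` gene order does not match the model")
  sum(x_norm * sm$weights)
}

#' Build a complete scoring model from training data
#'
#' Subsets the training matrix to the selected genes, min-max normalizes
#' per gene (keeping the training min/max), trains the d-`n_hidden`-2
#' network and extracts the per-gene weights. The returned object carries
#' everything needed to score a new sample: gene order, weights and the
#' training normalization ranges.
#'
#' @param training an `expr_matrix` (counts are converted via [to_log2()]).
#' @param selected_genes character vector of model genes, all present in
#'   `training` (e.g. `selected_genes` of an [importance_and_select()]
#'   result); order is kept.
#' @param n_hidden hidden units (default 3).
#' @param seed integer seed for network initialisation.
#' @param ... further arguments to [train_ann()].
#' @return A list of class `"score_model"`: `gene_ids`, `weights`,
#'   `ranges` (training min/max per gene), `ann` (the fitted
#'   `ann_model`) and `provenance` (seed, topology, epochs, convergence).
#' @export
build_score_model <- function(training, selected_genes, n_hidden = 3,
                              seed = 1, ...) {
  stopifnot(inherits(training, "expr_matrix"))
  if (length(selected_genes) == 0) stop("`selected_genes` is empty")
  training <- to_log2(training)
  sub <- subset_expr(training, genes = selected_genes)
  norm <- minmax_normalize(sub)
  ann <- train_ann(t(norm$matrix$values), sub$class_labels,
                   n_hidden = n_hidden, seed = seed, ...)
  w <- extract_gene_weights(ann)
  structure(
    list(gene_ids = selected_genes, weights = unname(w),
         ranges = norm$ranges, ann = ann,
         provenance = list(seed = as.integer(seed),
                           n_hidden = as.integer(n_hidden),
                           epochs = ann$epochs, converged = ann$converged,
                           n_train = ncol(training$values))),
    class = "score_model"
  )
}

#' @export
print.score_model <- function(x, ...) {
  cat(sprintf("<score_model> %d genes, %d-%d-2 network (seed %d)\n",
              length(x$gene_ids), length(x$gene_ids),
              x$provenance$n_hidden, x$provenance$seed))
  w <- stats::setNames(round(x$weights, 4), x$gene_ids)
  print(utils::head(w[order(-abs(w))], 12))
  invisible(x)
}

#' Score every sample of an expression matrix
#'
#' Applies the model's training normalization (clipping to [0, 1]) and
#' Eq.-style linear scoring to each sample.
#'
#' @param m an `expr_matrix` containing all model genes (counts are
#'   log2-CPM transformed first).
#' @param sm a `score_model`.
#' @return Named numeric vector of per-sample scores.
#' @export
score_samples <- function(m, sm) {
  stopifnot(inherits(m, "expr_matrix"), inherits(sm, "score_model"))
  m <- to_log2(m)
  sub <- subset_expr(m, genes = sm$gene_ids)
  norm <- minmax_normalize(sub, ranges = sm$ranges)
  drop(crossprod(norm$matrix$values, sm$weights))
}

#' Serialize / restore a score model as JSON
#'
#' @param sm a `score_model`.
#' @param path output file.
#' @return `read_score_model` returns the restored `score_model` (the
#'   fitted network's matrices are preserved; round-trips bit-identically
#'   for the scoring fields).
#' @export
write_score_model <- function(sm, path) {
  stopifnot(inherits(sm, "score_model"))
  obj <- list(
    gene_ids = sm$gene_ids, weights = sm$weights,
    ranges = list(gene_id = sm$ranges$gene_id, min = sm$ranges$min,
                  max = sm$ranges$max),
    W1 = sm$ann$W1, b1 = sm$ann$b1, W2 = sm$ann$W2, b2 = sm$ann$b2,
    provenance = sm$provenance
  )
  jsonlite::write_json(obj, path, digits = I(17), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_score_model
#' @export
read_score_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  ranges <- norm_ranges(obj$ranges$gene_id, obj$ranges$min, obj$ranges$max)
  ann <- structure(
    list(W1 = as.matrix(obj$W1), b1 = obj$b1,
         W2 = matrix(unlist(obj$W2), ncol = 2,
                     dimnames = list(NULL, c("control", "case"))),
         b2 = obj$b2,
         activation = "logistic", training_error_trace = NA,
         converged = obj$provenance$converged,
         epochs = obj$provenance$epochs, seed = obj$provenance$seed,
         gene_ids = obj$gene_ids, class_levels = c("control", "case")),
    class = "ann_model"
  )
  rownames(ann$W1) <- obj$gene_ids
  structure(
    list(gene_ids = obj$gene_ids, weights = obj$weights, ranges = ranges,
         ann = ann, provenance = obj$provenance),
    class = "score_model"
  )
}
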