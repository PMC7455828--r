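#' Expression matrix with sample metadata
#'
#' The central container of the package: a numeric genes x samples matrix
#' together with per-sample class labels (\code{"case"} / \code{"control"}),
#' per-sample batch labels, and a scale flag saying whether values are
#' log2 intensities/log2(CPM+1) (\code{"log2"}) or raw RNA-seq counts
#' (\code{"counts"}).
#'
#' @param values numeric matrix, genes in rows, samples in columns. Row and
#'   column names are taken as gene and sample identifiers unless
#'   \code{gene_ids} / \code{sample_ids} are given.
#' @param class_labels character or factor of length \code{ncol(values)} with
#'   values \code{"case"} or \code{"control"}.
#' @param batch_labels optional character vector of batch assignments; a
#'   single batch \code{"b1"} is assumed when omitted.
#' @param scale \code{"log2"} or \code{"counts"}.
#' @param gene_ids,sample_ids optional identifier vectors overriding dimnames.
#' @return An object of class \code{"expr_matrix"}: a list with elements
#'   \code{values}, \code{class_labels}, \code{batch_labels}, \code{scale}.
#' @export
expression_matrix <- function(values, class_labels, batch_labels = NULL,
                              scale = c("log2", "counts"),
                              gene_ids = NULL, sample_ids = NULL) {
  scale <- match.arg(scale)
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("`values` must be a numeric matrix")
  if (!is.null(gene_ids)) rownames(values) <- gene_ids
  if (!is.null(sample_ids)) colnames(values) <- sample_ids
  if (is.null(rownames(values)))
    rownames(values) <- paste0("g", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- paste0("s", seq_len(ncol(values)))
  if (anyDuplicated(rownames(values))) stop("duplicate gene ids")
  if (anyDuplicated(colnames(values))) stop("duplicate sample ids")
  class_labels <- as.character(class_labels)
  if (length(class_labels) != ncol(values))
    stop("`class_labels` must have one entry per sample")
  if (!all(class_labels %in% c("case", "control")))
    stop("class labels must be 'case' or 'control'")
  if (is.null(batch_labels)) batch_labels <- rep("b1", ncol(values))
  batch_labels <- as.character(batch_labels)
  if (length(batch_labels) != ncol(values))
    stop("`batch_labels` must have one entry per sample")
  if (scale == "log2" && !all(is.finite(values)))
    stop("log2-scale values must be finite")
  if (scale == "counts") {
    if (any(values < 0)) stop("counts must be non-negative")
    if (!all(is.finite(values))) stop("counts must be finite")
  }
  structure(
    list(values = values, class_labels = class_labels,
         batch_labels = batch_labels, scale = scale),
    class = "expr_matrix"
  )
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("<expr_matrix> %d genes x %d samples [%s scale]\n",
              nrow(x$values), ncol(x$values), x$scale))
  cat(sprintf("  classes: %d case / %d control; batches: %s\n",
              sum(x$class_labels == "case"),
              sum(x$class_labels == "control"),
              paste(names(table(x$batch_labels)), table(x$batch_labels),
                    sep = "=", collapse = ", ")))
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

n_samples <- function(m) ncol(m$values)
gene_ids <- function(m) rownames(m$values)
sample_ids <- function(m) colnames(m$values)

#' Subset an expression matrix by genes and/or samples
#'
#' @param m an \code{expr_matrix}.
#' @param genes,samples character vectors of identifiers (or logical/integer
#'   indices); \code{NULL} keeps everything.
#' @return An \code{expr_matrix}.
#' @export
subset_expr <- function(m, genes = NULL, samples = NULL) {
  stopifnot(inherits(m, "expr_matrix"))
  gi <- if (is.null(genes)) seq_len(nrow(m$values)) else genes
  si <- if (is.null(samples)) seq_len(ncol(m$values)) else samples
  if (is.character(gi)) {
    missing <- setdiff(gi, rownames(m$values))
    if (length(missing))
      stop("genes not present in matrix: ", paste(missing, collapse = ", "))
  }
  v <- m$values[gi, , drop = FALSE][, si, drop = FALSE]
  keep <- match(colnames(v), colnames(m$values))
  expression_matrix(v, m$class_labels[keep], m$batch_labels[keep], m$scale)
}

#' Read / write expression matrices as TSV
#'
#' The on-disk layout is a plain TSV with a `gene_id` first column and one
#' column per sample, plus a companion sample sheet TSV with columns
#' `sample_id`, `class` (\code{case}/\code{control}) and `batch`.
#'
#' @param path path to the expression TSV.
#' @param sample_sheet path to the sample sheet TSV.
#' @param scale value scale of the stored matrix.
#' @return \code{read_expression_tsv} returns an \code{expr_matrix};
#'   \code{write_expression_tsv} returns its paths invisibly.
#' @export
read_expression_tsv <- function(path, sample_sheet, scale = c("log2", "counts")) {
  scale <- match.arg(scale)
  tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(tab)[1] != "gene_id") stop("first column must be `gene_id`")
  v <- as.matrix(tab[, -1, drop = FALSE])
  rownames(v) <- tab$gene_id
  ss <- utils::read.delim(sample_sheet, stringsAsFactors = FALSE)
  need <- c("sample_id", "class", "batch")
  if (!all(need %in% names(ss)))
    stop("sample sheet needs columns: ", paste(need, collapse = ", "))
  idx <- match(colnames(v), ss$sample_id)
  if (anyNA(idx)) stop("sample sheet is missing samples present in the matrix")
  expression_matrix(v, ss$class[idx], ss$batch[idx], scale)
}

#' @rdname read_expression_tsv
#' @param m an \code{expr_matrix} to write.
#' @export
write_expression_tsv <- function(m, path, sample_sheet) {
  stopifnot(inherits(m, "expr_matrix"))
  tab <- data.frame(gene_id = rownames(m$values), m$values,
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  ss <- data.frame(sample_id = colnames(m$values), class = m$class_labels,
                   batch = m$batch_labels, stringsAsFactors = FALSE)
  utils::write.table(ss, sample_sheet, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(path, sample_sheet))
}

#' Read / write gene-set annotations in GMT format
#'
#' @param path file path.
#' @return \code{read_gmt} returns a named list of character vectors
#'   (term id -> member gene ids).
#' @export
read_gmt <- function(path) {
  fgsea::gmtPathways(path)
}

#' @rdname read_gmt
#' @param sets named list of character vectors.
#' @param descriptions optional character vector of per-term descriptions
#'   (GMT column 2); term ids are reused when omitted.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(names(sets)) || any(names(sets) == ""))
    stop("`sets` must be a fully named list")
  if (is.null(descriptions)) descriptions <- names(sets)
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
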