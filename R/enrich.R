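#' Hypergeometric gene-set enrichment of a DEG list
#'
#' For each annotation term, tests over-representation of the DEG set by
#' the hypergeometric upper tail P(X >= k) where N is the universe size,
#' K the term size (restricted to the universe), n the DEG-set size and k
#' the overlap. P-values are Benjamini-Hochberg adjusted across all tested
#' terms. Each term also gets the GOplot-style direction z-score
#' z = (n_up - n_down) / sqrt(k) (0 when k = 0), used to order bubbles in
#' enrichment plots.
#'
#' @param deg_genes data.frame with columns `gene_id` and `sign` (+1 for
#'   up, -1 for down), e.g. the `up`/`down` rows of a filtered
#'   [moderated_t()] table; or a character vector (signs then unknown,
#'   z is reported as `NA`).
#' @param annotation named list term -> character vector of member genes.
#' @param universe character vector of all genes considered (the assayed
#'   genes); DEG and annotation genes outside it are dropped.
#' @param categories optional named character vector term -> category
#'   (`"BP"`, `"CC"`, `"MF"`, `"other"`).
#' @return A data.frame of class `"enrichment_table"`: `term_id`,
#'   `category`, `k`, `K`, `n`, `N`, `p`, `adj_p`, `z`, `pruned` (all
#'   `FALSE`; see [prune_redundant()]), plus a list-column `member_degs`
#'   of the DEG members of each term.
#' @export
enrich <- function(deg_genes, annotation, universe, categories = NULL) {
  if (is.character(deg_genes))
    deg_genes <- data.frame(gene_id = deg_genes, sign = NA_integer_,
                            stringsAsFactors = FALSE)
  if (length(universe) == 0) stop("`universe` must be non-empty")
  if (nrow(deg_genes) == 0) stop("`deg_genes` must be non-empty")
  if (is.null(names(annotation)) || length(annotation) == 0)
    stop("`annotation` must be a named list of terms")
  universe <- unique(universe)
  deg_genes <- deg_genes[deg_genes$gene_id %in% universe, , drop = FALSE]
  N <- length(universe)
  n <- nrow(deg_genes)
  sign_of <- stats::setNames(deg_genes$sign, deg_genes$gene_id)

  rows <- lapply(names(annotation), function(term) {
    members <- intersect(annotation[[term]], universe)
    hits <- intersect(members, deg_genes$gene_id)
    k <- length(hits); K <- length(members)
    p <- if (k == 0) 1 else
      stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    s <- sign_of[hits]
    z <- if (k == 0) 0 else if (anyNA(s)) NA_real_ else
      (sum(s == 1) - sum(s == -1)) / sqrt(k)
    list(term_id = term, k = k, K = K, p = p, z = z, hits = hits)
  })
  out <- data.frame(
    term_id = vapply(rows, `[[`, character(1), "term_id"),
    category = "other",
    k = vapply(rows, `[[`, integer(1), "k"),
    K = vapply(rows, `[[`, integer(1), "K"),
    n = n, N = N,
    p = vapply(rows, `[[`, numeric(1), "p"),
    stringsAsFactors = FALSE
  )
  if (!is.null(categories))
    out$category <- unname(categories[out$term_id])
  out$adj_p <- stats::p.adjust(out$p, method = "BH")
  out$z <- vapply(rows, `[[`, numeric(1), "z")
  out$member_degs <- I(lapply(rows, `[[`, "hits"))
  out$pruned <- FALSE
  class(out) <- c("enrichment_table", "data.frame")
  out
}

#' Prune redundant enriched terms by pairwise overlap
#'
#' Among significant terms (adjusted p below `adj_p_cut`), any pair whose
#' DEG-member overlap exceeds `overlap_frac` of the smaller term's
#' DEG-member count is redundant; the less significant term of the pair is
#' marked `pruned` (ties on adjusted p: the larger term is pruned, then the
#' lexicographically later id). The surviving significant set contains no
#' violating pair, so a second application is a no-op.
#'
#' @param tab an `enrichment_table` from [enrich()].
#' @param overlap_frac overlap fraction above which a pair is redundant
#'   (default 0.75).
#' @param adj_p_cut significance cut defining which terms compete
#'   (default 0.01).
#' @return The table with `pruned` filled in.
#' @export
prune_redundant <- function(tab, overlap_frac = 0.75, adj_p_cut = 0.01) {
  stopifnot(inherits(tab, "enrichment_table"))
  sig <- which(tab$adj_p < adj_p_cut & !tab$pruned)
  if (length(sig) < 2) return(tab)
  # keep-priority: stronger signal first, smaller term, then id
  ord <- sig[order(tab$adj_p[sig], tab$K[sig], tab$term_id[sig])]
  kept <- integer(0)
  pruned <- rep(FALSE, nrow(tab))
  for (i in ord) {
    mi <- tab$member_degs[[i]]
    clash <- FALSE
    for (j in kept) {
      mj <- tab$member_degs[[j]]
      denom <- min(length(mi), length(mj))
      if (denom > 0 &&
          length(intersect(mi, mj)) / denom > overlap_frac) {
        clash <- TRUE
        break
      }
    }
    if (clash) pruned[i] <- TRUE else kept <- c(kept, i)
  }
  tab$pruned <- tab$pruned | pruned
  tab
}
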