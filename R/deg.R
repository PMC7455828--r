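#' Moderated two-sample t differential expression
#'
#' Per gene, a pooled two-group linear model gives the log2 fold change
#' (case minus control) and residual variance s_g^2 on d_g = n1 + n2 - 2
#' degrees of freedom. An empirical-Bayes prior (d0, s0^2) for the gene
#' variances is estimated by closed-form moment matching on log s_g^2
#' (Smyth 2004) and each variance is shrunk to its posterior
#' s~_g^2 = (d0 s0^2 + d_g s_g^2) / (d0 + d_g). The moderated statistic
#' t = logFC / (s~_g sqrt(1/n1 + 1/n2)) is referred to a t distribution on
#' d0 + d_g degrees of freedom; p-values are BH-adjusted across genes.
#'
#' @param m an `expr_matrix` on the log2 scale with >= 2 samples per class.
#' @param shrink logical; `FALSE` forces the d0 -> 0 limit, i.e. the
#'   ordinary pooled two-sample t on d_g degrees of freedom (useful as a
#'   limiting-case check; no variance moderation).
#' @return A data.frame of class `"deg_table"` with one row per gene:
#'   `gene_id`, `logFC`, `aveExpr`, `s2` (residual variance), `t_mod`,
#'   `df_total`, `p`, `adj_p`, plus `status` and `low_expression` columns
#'   initialised by [filter_degs()] (all `"stable"` / `FALSE` here).
#'   The estimated prior is attached as attributes `d0` and `s0_2`.
#' @export
moderated_t <- function(m, shrink = TRUE) {
  stopifnot(inherits(m, "expr_matrix"))
  if (m$scale != "log2") stop("moderated_t expects log2-scale data")
  case <- m$class_labels == "case"
  n1 <- sum(case); n2 <- sum(!case)
  if (n1 < 2 || n2 < 2) stop("need >= 2 samples in each class")
  v <- m$values
  mean_case <- rowMeans(v[, case, drop = FALSE])
  mean_ctrl <- rowMeans(v[, !case, drop = FALSE])
  logFC <- mean_case - mean_ctrl
  aveExpr <- rowMeans(v)
  dg <- n1 + n2 - 2
  ss <- rowSums((v[, case, drop = FALSE] - mean_case)^2) +
    rowSums((v[, !case, drop = FALSE] - mean_ctrl)^2)
  s2 <- ss / dg

  if (shrink) {
    prior <- fit_variance_prior(s2, dg)
    d0 <- prior$d0; s0_2 <- prior$s0_2
  } else {
    d0 <- 0; s0_2 <- NA_real_
  }
  if (is.infinite(d0)) {
    s2_post <- rep(s0_2, length(s2))
    df_total <- rep(Inf, length(s2))
  } else if (d0 == 0) {
    s2_post <- s2
    df_total <- rep(dg, length(s2))
  } else {
    s2_post <- (d0 * s0_2 + dg * s2) / (d0 + dg)
    df_total <- rep(d0 + dg, length(s2))
  }
  se <- sqrt(s2_post * (1 / n1 + 1 / n2))
  t_mod <- ifelse(se > 0, logFC / se, ifelse(logFC == 0, 0, Inf * sign(logFC)))
  p <- 2 * stats::pt(-abs(t_mod), df = df_total)
  p[!is.finite(t_mod) & logFC != 0] <- 0
  p <- pmin(pmax(p, .Machine$double.xmin), 1)
  out <- data.frame(
    gene_id = rownames(v), logFC = logFC, aveExpr = aveExpr, s2 = s2,
    t_mod = t_mod, df_total = df_total, p = p,
    adj_p = stats::p.adjust(p, method = "BH"),
    status = "stable", low_expression = FALSE,
    row.names = NULL, stringsAsFactors = FALSE
  )
  attr(out, "d0") <- d0
  attr(out, "s0_2") <- s0_2
  attr(out, "n_per_class") <- c(case = n1, control = n2)
  class(out) <- c("deg_table", "data.frame")
  out
}

# Closed-form moment matching of the scaled-inverse-chi-square variance
# prior on z = log s_g^2 (Smyth 2004): after removing the known sampling
# moments digamma(d_g/2) - log(d_g/2) and trigamma(d_g/2), the residual
# mean and variance identify log s0^2 and trigamma(d0/2).
fit_variance_prior <- function(s2, dg) {
  ok <- is.finite(s2) & s2 > 0
  if (sum(ok) < 2) return(list(d0 = 0, s0_2 = stats::median(s2)))
  e <- log(s2[ok]) - digamma(dg / 2) + log(dg / 2)
  emean <- mean(e)
  evar <- stats::var(e) - trigamma(dg / 2)
  if (!is.finite(evar) || evar <= 0) {
    # no detectable spread beyond sampling noise: infinitely strong prior
    return(list(d0 = Inf, s0_2 = exp(emean)))
  }
  d0 <- 2 * trigamma_inverse(evar)
  s0_2 <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  list(d0 = d0, s0_2 = s0_2)
}

# Newton solve of trigamma(y) = x for y > 0 (monotone decreasing).
trigamma_inverse <- function(x) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:75) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, deriv = 2)
    y <- y + dif
    if (abs(dif / y) < 1e-10) break
  }
  y
}

#' Apply the significance / fold-change / low-expression screen
#'
#' Flags genes in the bottom `low_expr_quantile` of average expression as
#' `low_expression`; a gene is called `up` (`down`) when p < `p_cut`,
#' logFC > `lfc_cut` (< -`lfc_cut`) and it is not low-expressed. All other
#' genes are `stable`. The raw (not BH-adjusted) p drives the call. Both
#' the pre-filter and post-filter up/down counts are attached as the
#' attribute `counts`.
#'
#' @param tab a `deg_table` from [moderated_t()].
#' @param p_cut raw p-value threshold (default 0.01).
#' @param lfc_cut |log2 fold change| threshold (default 0.26).
#' @param low_expr_quantile quantile of `aveExpr` below which genes are
#'   discarded as low-expressed (default 0.25, i.e. the bottom quarter);
#'   must lie in (0, 1).
#' @return The `deg_table` with `status` and `low_expression` filled in.
#' @export
filter_degs <- function(tab, p_cut = 0.01, lfc_cut = 0.26,
                        low_expr_quantile = 0.25) {
  stopifnot(inherits(tab, "deg_table"))
  if (!is.finite(low_expr_quantile) || low_expr_quantile <= 0 ||
      low_expr_quantile >= 1)
    stop("`low_expr_quantile` must lie in (0, 1)")
  lo <- stats::quantile(tab$aveExpr, low_expr_quantile, names = FALSE)
  low <- tab$aveExpr < lo
  pass <- tab$p < p_cut & abs(tab$logFC) > lfc_cut
  status <- rep("stable", nrow(tab))
  status[pass & !low & tab$logFC > 0] <- "up"
  status[pass & !low & tab$logFC < 0] <- "down"
  tab$status <- status
  tab$low_expression <- low
  attr(tab, "counts") <- c(
    up_prefilter = sum(pass & tab$logFC > 0),
    down_prefilter = sum(pass & tab$logFC < 0),
    up = sum(status == "up"),
    down = sum(status == "down")
  )
  attr(tab, "cuts") <- c(p_cut = p_cut, lfc_cut = lfc_cut,
                         low_expr_quantile = low_expr_quantile)
  tab
}

# Genes called up/down, as a data.frame gene_id / sign (+1 up, -1 down).
deg_calls <- function(tab) {
  keep <- tab$status != "stable"
  data.frame(gene_id = tab$gene_id[keep],
             sign = ifelse(tab$status[keep] == "up", 1L, -1L),
             stringsAsFactors = FALSE)
}
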