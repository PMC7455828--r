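# Small in-code fixtures shared across test files.

# A tiny deterministic log2 expression matrix with labelled groups.
tiny_matrix <- function(n_genes = 10, n_case = 5, n_control = 5,
                        seed = 42, batch = NULL) {
  set.seed(seed)
  v <- matrix(rnorm(n_genes * (n_case + n_control), 7, 1),
              n_genes, n_case + n_control)
  expression_matrix(
    v,
    class_labels = c(rep("case", n_case), rep("control", n_control)),
    batch_labels = batch,
    scale = "log2",
    gene_ids = paste0("G", seq_len(n_genes)),
    sample_ids = paste0("S", seq_len(n_case + n_control))
  )
}

# Brute-force Benjamini-Hochberg by its definition: sort, p*m/rank,
# cumulative minimum from the largest rank down, restore order.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- (m / seq_len(m)) * p[o]
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# Exact hypergeometric upper-tail by direct summation of choose() terms.
hyper_tail_oracle <- function(k, K, n, N) {
  if (k == 0) return(1)
  i <- k:min(K, n)
  sum(exp(lchoose(K, i) + lchoose(N - K, n - i) - lchoose(N, n)))
}

# All-pairs Mann-Whitney concordance (ties counted 1/2).
auc_oracle <- function(scores, labels) {
  cs <- scores[labels == "case"]
  ct <- scores[labels == "control"]
  tot <- 0
  for (a in cs) tot <- tot + sum(a > ct) + 0.5 * sum(a == ct)
  tot / (length(cs) * length(ct))
}
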