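#' Configuration for the two-class expression simulator
#'
#' Collects, and validates, every knob of [simulate_expression()]. Defaults
#' describe a typical desk-scale two-group cohort: 2000 genes, 20 cases and
#' 20 controls, 50 planted differentially expressed (DE) genes with a log2
#' fold change of 2, a single batch, and a gene-level variance hierarchy
#' sigma_g^2 ~ scaled-inverse-chi-square(d0 = 4, s0^2 = 0.05) matching the
#' hierarchical model assumed by the moderated t screen.
#'
#' @param n_genes,n_case,n_control positive integers.
#' @param n_de number of planted DE genes (half up, half down).
#' @param effect_logfc planted |log2 fold change| (case minus control).
#' @param n_batches number of batches; samples are assigned round-robin so
#'   batches stay balanced across classes.
#' @param batch_shift_sd SD of the gene-wise additive batch offsets (log2
#'   units); 0 disables batch structure.
#' @param mode `"microarray"` (Gaussian log2 intensities) or `"rnaseq"`
#'   (negative-binomial counts).
#' @param var_prior_df,var_prior_scale prior df d0 and scale s0^2 of the
#'   gene-variance hierarchy.
#' @param nb_dispersion negative-binomial dispersion (rnaseq mode); the NB
#'   size parameter is `1/nb_dispersion`.
#' @param seed integer seed; all output is deterministic given the config.
#' @return A list of class `"sim_config"`.
#' @export
sim_config <- function(n_genes = 2000, n_case = 20, n_control = 20,
                       n_de = 50, effect_logfc = 2, n_batches = 1,
                       batch_shift_sd = 0, mode = c("microarray", "rnaseq"),
                       var_prior_df = 4, var_prior_scale = 0.05,
                       nb_dispersion = 0.1, seed = 1) {
  mode <- match.arg(mode)
  cfg <- list(n_genes = as.integer(n_genes), n_case = as.integer(n_case),
              n_control = as.integer(n_control), n_de = as.integer(n_de),
              effect_logfc = effect_logfc, n_batches = as.integer(n_batches),
              batch_shift_sd = batch_shift_sd, mode = mode,
              var_prior_df = var_prior_df, var_prior_scale = var_prior_scale,
              nb_dispersion = nb_dispersion, seed = as.integer(seed))
  with(cfg, {
    if (n_genes < 1 || n_case < 1 || n_control < 1 || n_batches < 1)
      stop("n_genes, n_case, n_control, n_batches must be positive")
    if (n_de < 0 || n_de > n_genes) stop("need 0 <= n_de <= n_genes")
    if (n_case + n_control < 4) stop("need at least 4 samples in total")
    if (!is.finite(effect_logfc) || effect_logfc < 0)
      stop("effect_logfc must be finite and >= 0")
    if (!is.finite(batch_shift_sd) || batch_shift_sd < 0)
      stop("batch_shift_sd must be finite and >= 0")
    if (!is.finite(var_prior_df) || var_prior_df <= 0 ||
        !is.finite(var_prior_scale) || var_prior_scale <= 0)
      stop("variance prior parameters must be finite and positive")
    if (!is.finite(nb_dispersion) || nb_dispersion <= 0)
      stop("nb_dispersion must be finite and positive")
  })
  structure(cfg, class = "sim_config")
}

#' Simulate a two-class, multi-batch expression matrix with planted signal
#'
#' Microarray mode draws gene baselines mu_g ~ N(7, 1.5^2) on the log2 scale
#' and gene variances from a scaled-inverse-chi-square(d0, s0^2) hierarchy;
#' case samples of planted genes are shifted by +/- `effect_logfc` (half of
#' the planted set up, half down) and each batch adds an independent
#' gene-wise N(0, batch_shift_sd^2) offset. RNA-seq mode converts the same
#' log2 mean structure to negative-binomial counts
#' (mean 2^mu, size 1/dispersion) and stores raw counts.
#'
#' Planted genes are sampled among genes whose baseline lies above the
#' cohort median: planted signal is meant to be detectable, and real
#' biomarker fold changes live above the expression floor rather than in
#' the bottom quartile that the screening stage discards.
#'
#' @param cfg a [sim_config()].
#' @param gene_params optional `gene_params` element of a previous
#'   `sim_result`: reuses its gene baselines, gene variances and planted
#'   DE genes so the new draw is an independent *sample* cohort (e.g. a
#'   validation set) measuring the same genes and the same condition;
#'   `cfg$seed` then only drives the sample-level noise. `n_genes`,
#'   `n_de` and `effect_logfc` must match the original config.
#' @return A list of class `"sim_result"` with elements
#'   \describe{
#'     \item{matrix}{an [expression_matrix()] (`log2` or `counts` scale);}
#'     \item{de_truth}{data.frame `gene_id`, `sign` (+1/-1), `logfc`;}
#'     \item{gene_params}{list `mu`, `sigma2`, `de_idx`, `sign` — the
#'       gene-level truth, reusable via the `gene_params` argument;}
#'     \item{annotation}{named list term -> gene ids (GMT-writable), built
#'       by [simulate_annotation()]; enriched terms draw from the planted
#'       set when `n_de > 0`.}
#'   }
#' @export
simulate_expression <- function(cfg, gene_params = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  ng <- cfg$n_genes
  n <- cfg$n_case + cfg$n_control
  genes <- sprintf("gene%04d", seq_len(ng))
  samples <- sprintf("sample%03d", seq_len(n))
  cls <- c(rep("case", cfg$n_case), rep("control", cfg$n_control))
  # round-robin within class keeps batches balanced across classes
  batch <- integer(n)
  batch[cls == "case"] <- (seq_len(cfg$n_case) - 1L) %% cfg$n_batches + 1L
  batch[cls == "control"] <- (seq_len(cfg$n_control) - 1L) %% cfg$n_batches + 1L
  batch <- paste0("b", batch)

  if (is.null(gene_params)) {
    mu <- stats::rnorm(ng, mean = 7, sd = 1.5)
    sigma2 <- cfg$var_prior_df * cfg$var_prior_scale /
      stats::rchisq(ng, df = cfg$var_prior_df)
    de_idx <- integer(0)
    sign_vec <- integer(0)
    if (cfg$n_de > 0) {
      eligible <- which(mu > stats::median(mu))
      if (length(eligible) < cfg$n_de) eligible <- seq_len(ng)
      de_idx <- sort(sample(eligible, cfg$n_de))
      n_up <- ceiling(cfg$n_de / 2)
      sign_vec <- sample(c(rep(1L, n_up), rep(-1L, cfg$n_de - n_up)))
    }
  } else {
    if (length(gene_params$mu) != ng || length(gene_params$de_idx) != cfg$n_de)
      stop("`gene_params` does not match n_genes / n_de of `cfg`")
    mu <- gene_params$mu
    sigma2 <- gene_params$sigma2
    de_idx <- gene_params$de_idx
    sign_vec <- gene_params$sign
  }
  shift <- matrix(0, ng, n)
  if (cfg$n_de > 0)
    shift[de_idx, cls == "case"] <- sign_vec * cfg$effect_logfc

  batch_off <- matrix(0, ng, n)
  if (cfg$batch_shift_sd > 0 && cfg$n_batches > 1) {
    offs <- matrix(stats::rnorm(ng * cfg$n_batches, 0, cfg$batch_shift_sd),
                   ng, cfg$n_batches)
    batch_off <- offs[, as.integer(sub("^b", "", batch)), drop = FALSE]
  }

  log2_mean <- mu + shift + batch_off
  if (cfg$mode == "microarray") {
    v <- log2_mean + matrix(stats::rnorm(ng * n, 0, rep(sqrt(sigma2), n)),
                            ng, n)
    m <- expression_matrix(v, cls, batch, scale = "log2",
                           gene_ids = genes, sample_ids = samples)
  } else {
    v <- matrix(stats::rnbinom(ng * n, mu = 2^log2_mean,
                               size = 1 / cfg$nb_dispersion), ng, n)
    m <- expression_matrix(v, cls, batch, scale = "counts",
                           gene_ids = genes, sample_ids = samples)
  }

  de_truth <- data.frame(
    gene_id = genes[de_idx],
    sign = sign_vec,
    logfc = sign_vec * cfg$effect_logfc,
    stringsAsFactors = FALSE
  )
  ann <- simulate_annotation(
    genes, n_terms = 50,
    enriched_term_fraction_of_de = if (cfg$n_de > 0) 0.6 else 0,
    de_genes = de_truth$gene_id,
    seed = (cfg$seed + 7919L) %% .Machine$integer.max
  )
  structure(list(matrix = m, de_truth = de_truth,
                 gene_params = list(mu = mu, sigma2 = sigma2,
                                    de_idx = de_idx, sign = sign_vec),
                 annotation = ann),
            class = "sim_result")
}

#' Simulate a gene -> term annotation with optional planted enrichment
#'
#' Builds `n_terms` gene sets of 10-200 members drawn from `genes`. The
#' first `n_enriched` terms are "enriched": the given fraction of their
#' members is drawn from `de_genes`, producing hypergeometric signal
#' against that set; the remainder (and all other terms) are drawn
#' uniformly from the universe.
#'
#' @param genes character vector, the gene universe.
#' @param n_terms number of terms (>= 1).
#' @param enriched_term_fraction_of_de fraction in `[0, 1]` of each enriched
#'   term's members drawn from `de_genes`; 0 means no planted enrichment.
#' @param de_genes character vector of planted DE gene ids.
#' @param n_enriched how many terms carry planted enrichment (default 5,
#'   capped at `n_terms`); ignored when the fraction is 0 or `de_genes`
#'   is empty.
#' @param seed integer seed.
#' @return Named list term id -> character vector of member genes.
#' @export
simulate_annotation <- function(genes, n_terms = 50,
                                enriched_term_fraction_of_de = 0,
                                de_genes = character(0), n_enriched = 5,
                                seed = 1) {
  if (length(genes) == 0) stop("`genes` must be non-empty")
  if (n_terms < 1) stop("`n_terms` must be >= 1")
  frac <- enriched_term_fraction_of_de
  if (!is.finite(frac) || frac < 0 || frac > 1)
    stop("`enriched_term_fraction_of_de` must be in [0, 1]")
  set.seed(as.integer(seed))
  de_genes <- intersect(de_genes, genes)
  if (frac == 0 || length(de_genes) == 0) n_enriched <- 0
  n_enriched <- min(n_enriched, n_terms)
  sizes <- sample(10:min(200, length(genes)), n_terms, replace = TRUE)
  ann <- vector("list", n_terms)
  names(ann) <- sprintf("TERM%03d", seq_len(n_terms))
  for (i in seq_len(n_terms)) {
    size <- sizes[i]
    if (i <= n_enriched) {
      k_de <- min(round(frac * size), length(de_genes))
      members <- c(sample(de_genes, k_de),
                   sample(setdiff(genes, de_genes), size - k_de))
    } else {
      members <- sample(genes, size)
    }
    ann[[i]] <- sort(members)
  }
  ann
}
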