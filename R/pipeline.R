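#' Assemble a pipeline configuration
#'
#' Collects every tunable of the pipeline with defaults equal to the
#' published protocol constants: DEG screen p < 0.01 and |logFC| > 0.26
#' with the bottom-25% expression filter; enrichment at adjusted p < 0.01
#' with 75% overlap pruning; random-forest sweeps over mtry 1..2000 and
#' 1..3000 trees with the Gini threshold 0.15; a 3-unit hidden layer.
#' Accepts overrides as arguments, or a YAML file with the same field
#' names via `yaml_file` (explicit arguments win).
#'
#' @param train_expression,train_sample_sheet paths of the training
#'   expression TSV and sample sheet (see [read_expression_tsv()]).
#' @param validation_expression,validation_sample_sheet optional paths of
#'   held-out data for the evaluation stage.
#' @param gmt optional annotation path for the enrichment stage.
#' @param scale input scale, `"log2"` or `"counts"`.
#' @param combat `"parametric"`, `"nonparametric"`, or `"off"` — batch
#'   adjustment of the training data before screening.
#' @param p_cut,lfc_cut,low_expr_quantile,adj_p_cut,overlap_frac,mtry_max,ntree_probe,ntree_max,stability_eps,gini_threshold,n_hidden,max_genes
#'   stage parameters as in [neuralpcos()], [enrich()] and
#'   [prune_redundant()].
#' @param seed one global integer seed.
#' @param yaml_file optional YAML file of overrides.
#' @return A list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(train_expression = NULL,
                            train_sample_sheet = NULL,
                            validation_expression = NULL,
                            validation_sample_sheet = NULL,
                            gmt = NULL, scale = "log2",
                            combat = c("off", "parametric", "nonparametric"),
                            p_cut = 0.01, lfc_cut = 0.26,
                            low_expr_quantile = 0.25, adj_p_cut = 0.01,
                            overlap_frac = 0.75, mtry_max = 2000,
                            ntree_probe = 500, ntree_max = 3000,
                            stability_eps = 0.005, gini_threshold = 0.15,
                            n_hidden = 3, max_genes = NULL, seed = 1,
                            yaml_file = NULL) {
  cfg <- as.list(environment())
  cfg$yaml_file <- NULL
  if (!is.null(yaml_file)) {
    over <- yaml::read_yaml(yaml_file)
    unknown <- setdiff(names(over), names(cfg))
    if (length(unknown))
      stop("unknown config field(s): ", paste(unknown, collapse = ", "))
    given <- names(as.list(match.call()))[-1]
    for (nm in setdiff(names(over), given)) cfg[[nm]] <- over[[nm]]
  }
  cfg$combat <- match.arg(cfg$combat, c("off", "parametric", "nonparametric"))
  cfg$scale <- match.arg(cfg$scale, c("log2", "counts"))
  if (is.null(cfg$train_expression) || is.null(cfg$train_sample_sheet))
    stop("config field `train_expression` / `train_sample_sheet` is required")
  structure(cfg, class = "pipeline_config")
}

#' Run the full pipeline into an output directory
#'
#' Executes, in order: load (+ optional batch adjustment) -> DEG screen ->
#' term enrichment (when a GMT is configured) -> random-forest selection ->
#' network scoring model -> ROC evaluation on the validation data (when
#' configured, against the published comparator panels). Every stage
#' writes a self-describing TSV/JSON into `out_dir`, and a `manifest.json`
#' records the package version, all parameter values, derived per-stage
#' seeds and md5 checksums of the inputs, so any stage can be re-run in
#' isolation. A failing stage halts the run with the stage named; outputs
#' of completed stages are retained.
#'
#' @param cfg a [pipeline_config()].
#' @param out_dir output directory (created if absent).
#' @return Invisibly, a list with the fitted `neuralpcos` object, the
#'   enrichment table (or `NULL`), the evaluation summary (or `NULL`) and
#'   the manifest.
#' @export
run_pipeline <- function(cfg, out_dir) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  inputs <- c(cfg$train_expression, cfg$train_sample_sheet,
              cfg$validation_expression, cfg$validation_sample_sheet,
              cfg$gmt)
  missing <- inputs[!file.exists(inputs)]
  if (length(missing))
    stop("input path(s) do not exist: ", paste(missing, collapse = ", "))

  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }
  tsv <- function(df, file) {
    utils::write.table(df, file.path(out_dir, file), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }

  train <- run_stage("load", {
    m <- read_expression_tsv(cfg$train_expression, cfg$train_sample_sheet,
                             scale = cfg$scale)
    m <- to_log2(m)
    if (cfg$combat != "off")
      m <- combat_adjust(m, parametric = cfg$combat == "parametric")
    m
  })

  fit <- run_stage("model", {
    neuralpcos(train, p_cut = cfg$p_cut, lfc_cut = cfg$lfc_cut,
               low_expr_quantile = cfg$low_expr_quantile,
               mtry_max = cfg$mtry_max, ntree_probe = cfg$ntree_probe,
               ntree_max = cfg$ntree_max, stability_eps = cfg$stability_eps,
               gini_threshold = cfg$gini_threshold, n_hidden = cfg$n_hidden,
               max_genes = cfg$max_genes, seed = cfg$seed)
  })
  tsv(fit$deg_table[, setdiff(names(fit$deg_table), "member_degs")],
      "deg_table.tsv")
  tsv(fit$mtry$sweep, "mtry_sweep.tsv")
  tsv(fit$ntree$sweep, "ntree_sweep.tsv")
  tsv(fit$rf$importance, "importance.tsv")
  tsv(data.frame(gene_id = fit$score_model$gene_ids,
                 weight = fit$score_model$weights), "gene_weights.tsv")
  write_score_model(fit$score_model, file.path(out_dir, "score_model.json"))

  enr <- NULL
  if (!is.null(cfg$gmt)) {
    enr <- run_stage("enrich", {
      ann <- read_gmt(cfg$gmt)
      tab <- enrich(fit$deg_genes, ann, universe = rownames(train$values))
      prune_redundant(tab, overlap_frac = cfg$overlap_frac,
                      adj_p_cut = cfg$adj_p_cut)
    })
    flat <- enr
    flat$member_degs <- vapply(enr$member_degs, paste, character(1),
                               collapse = ",")
    tsv(flat, "enrichment.tsv")
  }

  evaluation <- NULL
  if (!is.null(cfg$validation_expression)) {
    evaluation <- run_stage("evaluate", {
      val <- read_expression_tsv(cfg$validation_expression,
                                 cfg$validation_sample_sheet,
                                 scale = cfg$scale)
      rocs <- compare_models(val, fit$score_model)
      summ <- attr(rocs, "summary")
      tsv(summ, "evaluation_summary.tsv")
      pts <- do.call(rbind, lapply(rocs, function(r)
        cbind(model = r$model_name, r$points)))
      tsv(pts, "roc_points.tsv")
      summ
    })
  }

  manifest <- list(
    package = "neuralpcos",
    version = as.character(utils::packageVersion("neuralpcos")),
    parameters = unclass(cfg),
    stage_seeds = list(rf_select = stage_seed(cfg$seed, "rf_select"),
                       ann_score = stage_seed(cfg$seed, "ann_score")),
    input_md5 = as.list(tools::md5sum(inputs)),
    outputs = list.files(out_dir)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE, null = "null")
  invisible(list(fit = fit, enrichment = enr, evaluation = evaluation,
                 manifest = manifest))
}
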