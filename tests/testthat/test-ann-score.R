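# Linearly separable two-gene toy in [0,1] with a comfortable margin.
toy_xy <- function(n_per = 10, seed = 3) {
  set.seed(seed)
  x1 <- c(runif(n_per, 0.75, 1), runif(n_per, 0, 0.25))
  x2 <- runif(2 * n_per)
  X <- cbind(gA = x1, gB = x2)
  list(X = X, y = rep(c("case", "control"), each = n_per))
}

test_that("the network learns a separable toy to 100% training accuracy", {
  d <- toy_xy()
  fit <- train_ann(d$X, d$y, seed = 1)
  expect_identical(predict(fit, d$X, type = "class"), d$y)
  expect_true(fit$converged)
})

test_that("training is deterministic given the seed", {
  d <- toy_xy()
  a <- train_ann(d$X, d$y, seed = 7)
  b <- train_ann(d$X, d$y, seed = 7)
  expect_identical(a$W1, b$W1)
  expect_identical(a$W2, b$W2)
  expect_identical(a$training_error_trace, b$training_error_trace)
  c2 <- train_ann(d$X, d$y, seed = 8)
  expect_false(identical(a$W1, c2$W1))
})

test_that("the recorded error trace is non-increasing and below the start", {
  d <- toy_xy(n_per = 8)
  for (seed in 1:5) {
    fit <- train_ann(d$X, d$y, seed = seed)
    tr <- fit$training_error_trace
    expect_true(all(diff(tr) <= 0))
    expect_lte(tr[length(tr)], tr[1])
  }
})

test_that("input outside [0,1] violates the normalization contract", {
  d <- toy_xy()
  d$X[1, 1] <- 1.5
  expect_error(train_ann(d$X, d$y), "normalized")
})

test_that("gene-weight extraction matches the hand-computed formula", {
  d <- toy_xy()
  fit <- train_ann(d$X, d$y, n_hidden = 2, seed = 2)
  # hand-set a 2x2x2 network and verify sum_h W1[g,h] (W2[h,case]-W2[h,control])
  fit$W1 <- matrix(c(1, 0, 0, 2), 2, 2, dimnames = list(c("gA", "gB"), NULL))
  fit$W2 <- matrix(c(1, 0.5, -1, 0), 2, 2,
                   dimnames = list(NULL, c("control", "case")))
  w <- extract_gene_weights(fit)
  # gA: 1*(-1-1) + 0*(0-0.5) = -2 ; gB: 0*(-2) + 2*(-0.5) = -1
  expect_equal(unname(w), c(-2, -1))
  # symmetric output weights give all-zero gene weights
  fit$W2[, "case"] <- fit$W2[, "control"]
  expect_equal(unname(extract_gene_weights(fit)), c(0, 0))
})

test_that("gene weights are invariant to permuting hidden units", {
  d <- toy_xy()
  fit <- train_ann(d$X, d$y, n_hidden = 3, seed = 4)
  perm <- c(3, 1, 2)
  swapped <- fit
  swapped$W1 <- fit$W1[, perm]
  swapped$b1 <- fit$b1[perm]
  swapped$W2 <- fit$W2[perm, ]
  expect_equal(extract_gene_weights(swapped), extract_gene_weights(fit))
})

test_that("the score is the exact dot product and is linear", {
  sm <- structure(
    list(gene_ids = c("a", "b", "c"), weights = c(1, -2, 0.5),
         ranges = NULL, ann = NULL, provenance = list()),
    class = "score_model"
  )
  expect_equal(neural_score(c(0.5, 0.25, 1), sm), 0.5)
  expect_equal(neural_score(c(0, 0, 0), sm), 0)
  x <- c(0.2, 0.8, 0.4); y <- c(0.9, 0.1, 0.5); a <- 0.3
  expect_equal(neural_score(a * x + (1 - a) * y, sm),
               a * neural_score(x, sm) + (1 - a) * neural_score(y, sm))
  expect_error(neural_score(c(0.1, 0.2), sm), "one value per")
  expect_error(neural_score(stats::setNames(c(1, 1, 1), c("b", "a", "c")), sm),
               "order")
})

test_that("doubling the weights doubles scores and leaves the AUC alone", {
  sim <- simulate_expression(sim_config(n_genes = 100, n_de = 10,
                                        n_case = 10, n_control = 10,
                                        seed = 12))
  sm <- build_score_model(sim$matrix, sim$de_truth$gene_id, seed = 1)
  s1 <- score_samples(sim$matrix, sm)
  sm2 <- sm
  sm2$weights <- sm$weights * 2
  s2 <- score_samples(sim$matrix, sm2)
  expect_equal(s2, 2 * s1)
  labels <- sim$matrix$class_labels
  expect_equal(roc_auc(s1, labels)$auc, roc_auc(s2, labels)$auc)
})

test_that("build_score_model trains an end-to-end discriminative score", {
  aucs <- vapply(1:3, function(seed) {
    cfg <- sim_config(n_genes = 200, n_de = 12, effect_logfc = 2,
                      seed = seed)
    train <- simulate_expression(cfg)
    sm <- build_score_model(train$matrix, train$de_truth$gene_id,
                            seed = seed)
    val <- simulate_expression(
      sim_config(n_genes = 200, n_de = 12, effect_logfc = 2,
                 seed = seed + 500),
      gene_params = train$gene_params)
    roc_auc(score_samples(val$matrix, sm), val$matrix$class_labels)$auc
  }, numeric(1))
  expect_true(all(aucs >= 0.9))
})

test_that("extracted weight signs track the planted regulation direction", {
  agree <- vapply(1:3, function(seed) {
    cfg <- sim_config(n_genes = 200, n_de = 12, effect_logfc = 2,
                      seed = seed + 40)
    train <- simulate_expression(cfg)
    sm <- build_score_model(train$matrix, train$de_truth$gene_id,
                            seed = seed)
    mean(sign(sm$weights) == train$de_truth$sign)
  }, numeric(1))
  expect_gte(mean(agree), 0.8)
})

test_that("a score model round-trips through JSON bit-identically", {
  sim <- simulate_expression(sim_config(n_genes = 60, n_de = 6,
                                        n_case = 8, n_control = 8,
                                        seed = 33))
  sm <- build_score_model(sim$matrix, sim$de_truth$gene_id, seed = 2)
  f <- tempfile(fileext = ".json")
  write_score_model(sm, f)
  back <- read_score_model(f)
  expect_identical(back$gene_ids, sm$gene_ids)
  expect_identical(back$weights, sm$weights)
  expect_identical(back$ranges$min, sm$ranges$min)
  expect_identical(back$ranges$max, sm$ranges$max)
  expect_equal(unname(back$ann$W1), unname(sm$ann$W1))
  expect_equal(unname(back$ann$W2), unname(sm$ann$W2))
  # identical scores from the restored model
  expect_identical(score_samples(sim$matrix, back),
                   score_samples(sim$matrix, sm))
  expect_error(build_score_model(sim$matrix, c("absent_gene")), "absent")
})

test_that("null-data training generalizes at chance level", {
  correct <- 0; total <- 0
  for (seed in 1:5) {
    cfg <- sim_config(n_genes = 12, n_de = 0, n_case = 13, n_control = 13,
                      seed = seed + 60)
    train <- simulate_expression(cfg)
    test_set <- simulate_expression(
      sim_config(n_genes = 12, n_de = 0, n_case = 13, n_control = 13,
                 seed = seed + 160),
      gene_params = train$gene_params)
    norm <- minmax_normalize(train$matrix)
    fit <- train_ann(t(norm$matrix$values), train$matrix$class_labels,
                     seed = seed)
    vnorm <- minmax_normalize(test_set$matrix, ranges = norm$ranges)
    pred <- predict(fit, t(vnorm$matrix$values), type = "class")
    correct <- correct + sum(pred == test_set$matrix$class_labels)
    total <- total + length(pred)
  }
  acc <- correct / total
  ci <- 1.96 * sqrt(0.25 / total)
  expect_gt(acc, 0.5 - ci)
  expect_lt(acc, 0.5 + ci)
})
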