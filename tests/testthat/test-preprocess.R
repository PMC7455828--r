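test_that("to_log2 applies log2(CPM+1) and is idempotent", {
  counts <- matrix(c(0, 1024, 10, 500, 0, 3), nrow = 3)
  counts <- rbind(counts, 1e6 - colSums(counts))  # library size exactly 1e6
  m <- expression_matrix(counts, c("case", "control"), scale = "counts")
  lg <- to_log2(m)
  expect_identical(lg$scale, "log2")
  expect_equal(lg$values[1, 1], 0)                     # zero count -> 0
  expect_equal(lg$values[2, 1], log2(1025))            # CPM 1024 -> ~10.0014
  expect_equal(lg$values[2, 1], 10.0014, tolerance = 1e-4)
  expect_identical(to_log2(lg), lg)                    # idempotent
  neg <- m; neg$values[1, 1] <- -1
  expect_error(to_log2(neg), "non-negative")
})

test_that("merge_datasets intersects genes and tracks source batches", {
  a <- tiny_matrix(n_genes = 120, seed = 1)
  b <- tiny_matrix(n_genes = 120, seed = 2)
  rownames(b$values) <- paste0("G", 21:140)  # share genes G21..G120
  colnames(b$values) <- paste0("T", 1:10)
  merged <- merge_datasets(list(a, b))
  expect_equal(nrow(merged$values), 100)
  expect_equal(ncol(merged$values), 20)

  # merging a matrix with itself under renamed samples doubles the samples
  a2 <- a
  colnames(a2$values) <- paste0("R", 1:10)
  self <- merge_datasets(list(a, a2))
  expect_equal(dim(self$values), c(120, 20))
  expect_setequal(rownames(self$values), rownames(a$values))

  # three sources -> three batch levels with sizes preserved
  c3 <- tiny_matrix(n_genes = 120, n_case = 3, n_control = 3, seed = 3)
  colnames(c3$values) <- paste0("U", 1:6)
  m3 <- merge_datasets(list(d1 = a, d2 = a2, d3 = c3))
  expect_equal(as.vector(table(m3$batch_labels)[c("d1", "d2", "d3")]),
               c(10, 10, 6))

  disjoint <- tiny_matrix(n_genes = 5, seed = 4)
  rownames(disjoint$values) <- paste0("X", 1:5)
  colnames(disjoint$values) <- paste0("V", 1:10)
  expect_error(merge_datasets(list(a, disjoint)), "intersection")

  # order-insensitive up to column permutation
  m12 <- merge_datasets(list(a, a2))
  m21 <- merge_datasets(list(a2, a))
  expect_equal(m12$values[, sort(colnames(m12$values))],
               m21$values[, sort(colnames(m21$values))])
})

test_that("combat_adjust removes batch structure, keeps the class signal", {
  cfg <- sim_config(n_genes = 600, n_de = 25, effect_logfc = 2,
                    n_batches = 2, batch_shift_sd = 2, seed = 21)
  sim <- simulate_expression(cfg)
  m <- sim$matrix
  batch_f <- function(vals, batch) {
    apply(vals, 1, function(x) {
      fit <- anova(lm(x ~ factor(batch)))
      fit$`F value`[1]
    })
  }
  f_before <- batch_f(m$values, m$batch_labels)
  adj <- combat_adjust(m, parametric = TRUE)
  f_after <- batch_f(adj$values, adj$batch_labels)
  expect_lt(median(f_after), 2)
  expect_lt(median(f_after), median(f_before))
  # dimensions and gene order preserved
  expect_identical(dimnames(adj$values), dimnames(m$values))
  # planted class contrast survives the adjustment: the adjustment itself
  # moves no gene's logFC by more than 0.2, and the planted effect size
  # is recovered on average
  case <- adj$class_labels == "case"
  pre <- rowMeans(m$values[, case]) - rowMeans(m$values[, !case])
  post <- rowMeans(adj$values[, case]) - rowMeans(adj$values[, !case])
  expect_lt(max(abs(post - pre)), 0.2)
  planted <- sim$de_truth$gene_id
  expect_lt(abs(mean(post[planted] * sim$de_truth$sign) - 2), 0.2)
})

test_that("combat_adjust is a near-identity without batch effects", {
  cfg <- sim_config(n_genes = 300, n_batches = 2, batch_shift_sd = 0,
                    n_case = 20, n_control = 20, n_de = 0, seed = 31)
  m <- simulate_expression(cfg)$matrix
  adj <- combat_adjust(m)
  dev <- abs(adj$values - m$values)
  # bulk identity; isolated tails move more because the empirical-Bayes
  # scale step rescales extreme residuals
  expect_lt(median(dev), 0.05)
  expect_lt(mean(dev), 0.05)
  expect_gt(cor(as.vector(adj$values), as.vector(m$values)), 0.999)
})

test_that("combat_adjust input contracts", {
  m <- tiny_matrix(batch = c(rep("b1", 9), "b2"))
  expect_error(combat_adjust(m), ">= 2 samples")
  expect_error(combat_adjust(tiny_matrix()), ">= 2 batches")
  # zero-variance gene is passed through untouched
  m2 <- tiny_matrix(n_genes = 60, batch = rep(c("b1", "b2"), 5))
  m2$values[1, ] <- 5
  adj <- combat_adjust(m2)
  expect_identical(adj$values[1, ], m2$values[1, ])
})

test_that("min-max normalization contracts hold on train and validation", {
  m <- tiny_matrix(n_genes = 30, seed = 7)
  tr <- minmax_normalize(m)
  expect_true(all(tr$matrix$values >= 0 & tr$matrix$values <= 1))
  expect_true(all(apply(tr$matrix$values, 1, min) == 0))
  expect_true(all(apply(tr$matrix$values, 1, max) == 1))
  # midpoint maps to 0.5
  g <- expression_matrix(matrix(c(5, 9, 7), 1),
                         class_labels = c("case", "case", "control"),
                         sample_ids = c("a", "b", "c"))
  expect_equal(minmax_normalize(g)$matrix$values[1, "c"], 0.5,
               ignore_attr = TRUE)
  # applying the stored ranges to the source matrix reproduces the
  # training-mode output; re-normalizing an already-normalized matrix
  # (whose per-gene range is [0,1]) is the identity
  expect_equal(minmax_normalize(m, ranges = tr$ranges)$matrix$values,
               tr$matrix$values, tolerance = 1e-12)
  expect_equal(minmax_normalize(tr$matrix)$matrix$values,
               tr$matrix$values, tolerance = 1e-12)
})

test_that("validation values outside the training range are clipped", {
  m <- tiny_matrix(n_genes = 5, seed = 8)
  tr <- minmax_normalize(m)
  v <- m
  v$values[1, 1] <- tr$ranges$min[1] - 10   # below training min
  v$values[2, 2] <- tr$ranges$max[2] + 10   # above training max
  out <- minmax_normalize(v, ranges = tr$ranges)$matrix$values
  expect_equal(out[1, 1], 0, ignore_attr = TRUE)
  expect_equal(out[2, 2], 1, ignore_attr = TRUE)
  expect_true(all(out >= 0 & out <= 1))
})

test_that("constant genes normalize to the centre of the range", {
  m <- tiny_matrix(n_genes = 3)
  m$values[2, ] <- 4.2
  out <- minmax_normalize(m)
  expect_true(all(out$matrix$values[2, ] == 0.5))
  expect_equal(out$ranges$min[2], out$ranges$max[2])
})
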