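test_that("metagene score is the mean over present genes", {
  m <- rbind(A = c(1, 2), B = c(3, 4), X = c(100, 100))
  colnames(m) <- c("S1", "S2")
  expect_equal(unname(metagene_score(m, c("A", "B"))), c(2, 3))
  expect_warning(sc <- metagene_score(m, c("A", "B", "C")), "absent")
  expect_equal(unname(sc), c(2, 3))
  expect_error(metagene_score(m, c("Q", "R")), "none")
})

test_that("ranked-split tertiles cut sorted scores into equal thirds", {
  m <- matrix(rep(1:6, each = 1), nrow = 1,
              dimnames = list("A", paste0("S", 1:6)))
  t6 <- assign_tertiles(m, "A")
  expect_identical(as.character(t6$label),
                   c("low", "low", "inter", "inter", "high", "high"))
  # equal scores: stable tie-break on sample id order
  tie <- matrix(1, nrow = 1, ncol = 6,
                dimnames = list("A", paste0("S", 1:6)))
  tt <- assign_tertiles(tie, "A")
  expect_identical(as.character(tt$label),
                   c("high", "high", "inter", "inter", "low", "low"))
  expect_identical(as.integer(table(tt$label)), rep(2L, 3))
  expect_error(assign_tertiles(m[, 1:2, drop = FALSE], "A"), "3 samples")
})

test_that("ranked-split is invariant to sample column order", {
  ds <- generate_dataset(
    synthetic_config(n_genes = 60L, n_samples = 45L, n_planted = 0L,
                     metagene_size = 8L), seed = 3)
  t1 <- assign_tertiles(ds$expression, ds$metagene_genes)
  perm <- sample(ncol(ds$expression))
  t2 <- assign_tertiles(ds$expression[, perm], ds$metagene_genes)
  expect_identical(t1$label[match(t2$sample_id, t1$sample_id)], t2$label)
})

test_that("tertile assignments recover the ground truth at separation 2", {
  ds <- generate_dataset(
    synthetic_config(n_genes = 150L, n_samples = 240L, n_planted = 0L,
                     metagene_size = 20L, tertile_separation = 2),
    seed = 41)
  tr <- assign_tertiles(ds$expression, ds$metagene_genes, "ranked-split")
  agree <- mean(as.character(tr$label) == as.character(ds$tertile_truth))
  expect_gte(agree, 0.95)
  # hierarchical mode finds the same dominant structure
  th <- assign_tertiles(ds$expression, ds$metagene_genes, "hierarchical")
  agree_h <- mean(as.character(th$label) == as.character(ds$tertile_truth))
  expect_gte(agree_h, 0.8)
})

test_that("NSC at delta 0 equals raw centroids; large delta collapses", {
  ds <- generate_dataset(
    synthetic_config(n_genes = 100L, n_samples = 90L, n_planted = 0L,
                     metagene_size = 12L, tertile_separation = 2),
    seed = 51)
  labels <- assign_tertiles(ds$expression, ds$metagene_genes)
  m0 <- nsc_train(ds$expression, ds$metagene_genes, labels, delta = 0)
  raw <- vapply(levels(labels$label), function(cl) {
    rowMeans(ds$expression[m0$genes,
                           labels$label == cl, drop = FALSE])
  }, numeric(length(m0$genes)))
  expect_equal(m0$centroids, raw, tolerance = 1e-12)

  mBig <- nsc_train(ds$expression, ds$metagene_genes, labels, delta = 1e6)
  for (cl in mBig$classes) {
    expect_equal(unname(mBig$centroids[, cl]), unname(mBig$overall),
                 tolerance = 1e-9)
  }
  # with all centroids collapsed, assignment is by prior alone
  pr <- nsc_assign(mBig, ds$expression)
  expect_identical(length(unique(pr$label)), 1L)

  # shrinkage is monotone: centroid offsets shrink as delta grows
  m1 <- nsc_train(ds$expression, ds$metagene_genes, labels, delta = 0.5)
  off0 <- abs(m0$centroids - m0$overall)
  off1 <- abs(m1$centroids - m1$overall)
  expect_true(all(off1 <= off0 + 1e-12))
})

test_that("NSC assignment matches a direct pooled nearest-centroid oracle", {
  ds <- generate_dataset(
    synthetic_config(n_genes = 80L, n_samples = 75L, n_planted = 0L,
                     metagene_size = 10L, tertile_separation = 1.5),
    seed = 61)
  labels <- assign_tertiles(ds$expression, ds$metagene_genes)
  model <- nsc_train(ds$expression, ds$metagene_genes, labels, delta = 0)
  got <- nsc_assign(model, ds$expression)
  # independent oracle: standardized distance to raw class means minus
  # 2 log prior
  x <- ds$expression[model$genes, ]
  w <- 1 / (model$s + model$s0)^2
  want <- apply(x, 2, function(col) {
    d <- vapply(model$classes, function(cl) {
      sum(w * (col - model$centroids[, cl])^2) - 2 * log(model$priors[[cl]])
    }, numeric(1))
    model$classes[which.min(d)]
  })
  expect_identical(as.character(got$label), unname(want))
})

test_that("NSC reclassifies training data and held-out cohorts accurately", {
  ds <- generate_dataset(
    synthetic_config(n_genes = 150L, n_samples = 210L, n_planted = 0L,
                     metagene_size = 20L, tertile_separation = 2),
    seed = 71)
  labels <- assign_tertiles(ds$expression, ds$metagene_genes)
  model <- nsc_train(ds$expression, ds$metagene_genes, labels, delta = 0)
  self <- nsc_assign(model, ds$expression)
  expect_gte(mean(self$label == labels$label), 0.9)

  held <- resample_cohort(ds, seed = 72)
  pred <- nsc_assign(model, held$expression)
  agree <- mean(as.character(pred$label) == as.character(held$tertile_truth))
  expect_gte(agree, 0.85)
})

test_that("NSC training rejects undersized classes", {
  m <- toy_expr(paste0("G", 1:5), paste0("S", 1:5), seed = 9)
  labels <- data.frame(sample_id = paste0("S", 1:5),
                       label = factor(c("high", "high", "inter", "inter",
                                        "low"),
                                      levels = c("high", "inter", "low")))
  expect_error(nsc_train(m, paste0("G", 1:5), labels), ">= 2 samples")
})
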