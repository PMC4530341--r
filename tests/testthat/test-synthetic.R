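small_cfg <- function(...) {
  synthetic_config(n_genes = 120L, n_samples = 150L, n_planted = 2L,
                   planted_size_range = c(4L, 6L), metagene_size = 10L, ...)
}

test_that("generation is deterministic given the seed", {
  a <- generate_dataset(small_cfg(), seed = 5)
  b <- generate_dataset(small_cfg(), seed = 5)
  expect_identical(a, b)
  c <- generate_dataset(small_cfg(), seed = 6)
  expect_false(identical(a$expression, c$expression))
})

test_that("planted sets are connected, disjoint, separated and hub-free", {
  ds <- generate_dataset(small_cfg(), seed = 11)
  expect_length(ds$planted, 2L)
  for (set in ds$planted) {
    expect_true(is_connected_subset(ds$network, set))
  }
  expect_length(intersect(ds$planted[[1]], ds$planted[[2]]), 0L)
  deg <- lengths(ds$network$adj)
  expect_true(all(deg[unlist(ds$planted)] <= ds$config$max_plant_degree))
  d <- igraph::distances(as_igraph(ds$network), v = ds$planted[[1]],
                         to = ds$planted[[2]])
  expect_gte(min(d), ds$config$min_plant_separation)
  # metagene block does not overlap planted sets
  expect_length(intersect(ds$metagene_genes, unlist(ds$planted)), 0L)
})

test_that("random breadth-first plants are connected across draws", {
  set.seed(42)
  net <- spnsurv:::generate_network(synthetic_config(n_genes = 200L))
  for (i in 1:50) {
    set <- plant_connected_set(net, 5L)
    expect_length(set, 5L)
    expect_true(is_connected_subset(net, set))
  }
  # forced outcome: the whole component on a path graph
  path4 <- net_from_string("A-B B-C C-D")
  expect_setequal(plant_connected_set(path4, 4L), c("A", "B", "C", "D"))
  expect_error(plant_connected_set(path4, 5L), "plant")
})

test_that("impossible plants raise a generation error", {
  cfg <- synthetic_config(n_genes = 30L, n_samples = 20L, n_planted = 8L,
                          planted_size_range = c(5L, 5L), metagene_size = 2L)
  expect_error(generate_dataset(cfg, seed = 1), "plant")
})

test_that("survival times are positive and censoring matches the target", {
  cfg <- synthetic_config(n_genes = 150L, n_samples = 400L, n_planted = 2L,
                          censoring_rate = 0.3, metagene_size = 10L)
  ds <- generate_dataset(cfg, seed = 3)
  expect_true(all(ds$survival$time > 0))
  expect_lt(abs(mean(ds$survival$event == 0) - 0.3), 0.1)
  # no censoring when the rate is zero
  ds0 <- generate_dataset(small_cfg(censoring_rate = 0), seed = 3)
  expect_true(all(ds0$survival$event == 1L))
})

test_that("metagene score separates ground-truth tertiles monotonically", {
  ds <- generate_dataset(small_cfg(tertile_separation = 1), seed = 9)
  sc <- metagene_score(ds$expression, ds$metagene_genes)
  means <- tapply(sc, ds$tertile_truth, mean)
  expect_true(means[["high"]] > means[["inter"]])
  expect_true(means[["inter"]] > means[["low"]])
  expect_setequal(levels(ds$tertile_truth), c("high", "inter", "low"))
  expect_true(all(table(ds$tertile_truth) >= 1L))
})

test_that("null generator produces survival unrelated to gene activity", {
  # with no planted effect, Cox scores of random connected 5-gene sets
  # stay at null levels
  cfg <- synthetic_config(n_genes = 200L, n_samples = 200L, n_planted = 0L,
                          censoring_rate = 0, metagene_size = 10L)
  ds <- generate_dataset(cfg, seed = 21)
  z <- zscore_expression(ds$expression)
  set.seed(99)
  s_vals <- replicate(100, {
    members <- plant_connected_set(ds$network, 5L)
    cox_score(subnetwork_activity(z, members),
              ds$survival$time, ds$survival$event)$score_s
  })
  expect_lte(quantile(s_vals, 0.95), -log(0.01))
})

test_that("co-expressed planted sets without effect score like the null", {
  # effect_beta = 0: planted co-expression must not create survival
  # association
  cfg_null <- synthetic_config(n_genes = 150L, n_samples = 200L,
                               n_planted = 0L, metagene_size = 10L)
  cfg_coex <- synthetic_config(n_genes = 150L, n_samples = 200L,
                               n_planted = 2L, effect_beta = 0,
                               planted_size_range = c(5L, 5L),
                               metagene_size = 10L)
  s_null <- s_coex <- numeric(60)
  for (i in 1:60) {
    d0 <- generate_dataset(cfg_null, seed = 1000 + i)
    z0 <- zscore_expression(d0$expression)
    set.seed(2000 + i)
    m0 <- plant_connected_set(d0$network, 5L)
    s_null[i] <- cox_score(subnetwork_activity(z0, m0),
                           d0$survival$time, d0$survival$event)$score_s
    d1 <- generate_dataset(cfg_coex, seed = 3000 + i)
    z1 <- zscore_expression(d1$expression)
    s_coex[i] <- cox_score(subnetwork_activity(z1, d1$planted[[1]]),
                           d1$survival$time, d1$survival$event)$score_s
  }
  expect_gt(ks.test(s_null, s_coex)$p.value, 0.01)
})

test_that("resampled cohorts share structure but not patients", {
  ds <- generate_dataset(small_cfg(), seed = 31)
  held <- resample_cohort(ds, seed = 32, n_samples = 80L)
  expect_identical(held$network, ds$network)
  expect_identical(held$planted, ds$planted)
  expect_identical(held$metagene_genes, ds$metagene_genes)
  expect_identical(ncol(held$expression), 80L)
  expect_length(intersect(colnames(held$expression),
                          colnames(ds$expression)), 0L)
})

test_that("dataset fixture files round-trip through the readers", {
  dir <- withr::local_tempdir()
  ds <- generate_dataset(small_cfg(), seed = 8)
  write_dataset(ds, dir)
  expr <- read_expression(file.path(dir, "expression.tsv"))
  expect_equal(expr, ds$expression, tolerance = 1e-12)
  net <- read_network(file.path(dir, "network_edges.tsv"))
  expect_identical(net$edges, ds$network$edges)
  surv <- read_survival(file.path(dir, "survival.tsv"))
  expect_equal(surv$time, ds$survival$time, tolerance = 1e-12)
  truth <- jsonlite::read_json(file.path(dir, "truth.json"))
  expect_length(truth$planted, length(ds$planted))
})
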