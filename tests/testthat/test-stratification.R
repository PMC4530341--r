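test_that("patient clustering separates well-separated activity blocks", {
  set.seed(5)
  act <- cbind(matrix(2 + rnorm(40, sd = 0.1), nrow = 2),
               matrix(-2 + rnorm(40, sd = 0.1), nrow = 2))
  rownames(act) <- c("SPN1", "SPN2")
  colnames(act) <- paste0("P", 1:40)
  strat <- cluster_patients(act)
  expect_identical(length(unique(strat$cluster[1:20])), 1L)
  expect_identical(length(unique(strat$cluster[21:40])), 1L)
  expect_false(strat$cluster[1] == strat$cluster[21])

  # invariant to patient order up to label swap
  perm <- sample(40)
  strat2 <- cluster_patients(act[, perm])
  same <- strat2$cluster[match(strat$sample_ids, strat2$sample_ids)]
  agree <- mean(same == strat$cluster)
  expect_true(agree == 1 || agree == 0)

  # two patients: forced singleton clusters
  two <- cluster_patients(act[, 1:2])
  expect_setequal(two$cluster, c(1L, 2L))
  # identical activities cannot be clustered
  flat <- matrix(1, 2, 5, dimnames = list(c("SPN1", "SPN2"), paste0("P", 1:5)))
  expect_error(cluster_patients(flat), "identical")
})

test_that("outcome labeling follows 5-year KM survival", {
  # cluster 1 all event-free at 120 months; cluster 2 all events by 24
  surv <- data.frame(sample_id = paste0("P", 1:20),
                     time = c(rep(120, 10), rep(24, 10)),
                     event = c(rep(0L, 10), rep(1L, 10)))
  strat <- structure(list(sample_ids = paste0("P", 1:20),
                          cluster = rep(1:2, each = 10),
                          centroids = matrix(c(0, 1), nrow = 1,
                                             dimnames = list("SPN1",
                                                             c("1", "2")))),
                     class = "patient_stratification")
  lab <- label_outcome(strat, surv)
  expect_identical(as.character(lab$outcome_label),
                   rep(c("good", "poor"), each = 10))
  expect_identical(colnames(lab$centroids), c("good", "poor"))
  expect_lt(lab$logrank_p, 0.01)

  # swapped cluster ids keep labels attached to the same patients
  strat_sw <- strat
  strat_sw$cluster <- 3L - strat$cluster
  lab_sw <- label_outcome(strat_sw, surv)
  expect_identical(lab_sw$outcome_label, lab$outcome_label)

  # tie on KM estimate: broken by larger mean observed time
  surv_tie <- data.frame(sample_id = paste0("P", 1:20),
                         time = c(rep(80, 10), rep(70, 10)),
                         event = rep(0L, 20))
  lab_tie <- label_outcome(strat, surv_tie)
  expect_identical(as.character(lab_tie$outcome_label),
                   rep(c("good", "poor"), each = 10))
})

test_that("KM curve equals the hand-computed product-limit estimator", {
  # all events at 1, 2, 3: survival steps 2/3, 1/3, 0
  km <- km_curve(c(1, 2, 3), c(1, 1, 1))
  expect_equal(km$surv, c(2 / 3, 1 / 3, 0))
  expect_equal(km$n_risk, c(3, 2, 1))
  # all censored: survival constant 1
  km0 <- km_curve(c(1, 2, 3), c(0, 0, 0))
  expect_true(all(km0$surv == 1))
  # single subject with an event: step from 1 to 0
  km1 <- km_curve(5, 1)
  expect_equal(km1$surv, 0)
  # probability conservation: S(t) = prod(1 - d/n) over event times
  set.seed(8)
  tm <- rexp(40, 0.1)
  ev <- rbinom(40, 1, 0.6)
  km2 <- km_curve(tm, ev)
  manual <- cumprod(1 - km2$n_event / km2$n_risk)
  expect_equal(km2$surv, manual, tolerance = 1e-12)
})

test_that("log-rank test matches the risk-set table oracle", {
  # identical groups: no signal at all
  tm <- c(1, 2, 3, 1, 2, 3)
  ev <- c(1L, 0L, 1L, 1L, 0L, 1L)
  grp <- rep(c("a", "b"), each = 3)
  same <- logrank_test(tm, ev, grp)
  expect_equal(same$chisq, 0, tolerance = 1e-12)
  expect_equal(same$p, 1, tolerance = 1e-12)

  # fixed micro-examples against the observed-minus-expected oracle
  cases <- list(
    list(time = c(1, 2, 3, 4), event = c(1L, 1L, 1L, 1L),
         group = c("g1", "g1", "g2", "g2")),
    list(time = c(2, 4, 4, 6, 8, 10), event = c(1L, 0L, 1L, 1L, 0L, 1L),
         group = c("a", "a", "a", "b", "b", "b")),
    list(time = c(1, 1, 2, 3, 5, 8, 13), event = c(1L, 1L, 0L, 1L, 1L, 0L, 1L),
         group = c("x", "y", "x", "y", "x", "y", "x")))
  for (cs in cases) {
    got <- logrank_test(cs$time, cs$event, cs$group)
    want <- oracle_logrank(cs$time, cs$event, cs$group)
    expect_equal(got$chisq, want$chisq, tolerance = 1e-10)
    expect_equal(got$p, want$p, tolerance = 1e-10)
  }

  # p is the exact chi-square(1) upper tail of the statistic
  got <- logrank_test(cases[[2]]$time, cases[[2]]$event, cases[[2]]$group)
  expect_equal(got$p, pchisq(got$chisq, 1, lower.tail = FALSE),
               tolerance = 1e-12)

  # symmetric under group relabeling; invariant to increasing time
  # transforms
  flip <- logrank_test(cases[[2]]$time, cases[[2]]$event,
                       ifelse(cases[[2]]$group == "a", "b", "a"))
  warp <- logrank_test(exp(cases[[2]]$time), cases[[2]]$event,
                       cases[[2]]$group)
  expect_equal(got$chisq, flip$chisq, tolerance = 1e-12)
  expect_equal(got$chisq, warp$chisq, tolerance = 1e-12)
})

test_that("classification metrics follow the confusion-table definitions", {
  lab <- factor(c(rep("poor", 6), rep("good", 4)), levels = c("good", "poor"))
  ev <- c(rep(1L, 6), rep(0L, 4))
  m <- classification_metrics(lab, ev)
  expect_identical(c(m$tp, m$fp, m$tn, m$fn), c(6L, 0L, 4L, 0L))
  expect_equal(c(m$accuracy, m$precision, m$recall), c(1, 1, 1))

  # all predicted good with 4/10 events
  lab2 <- factor(rep("good", 10), levels = c("good", "poor"))
  ev2 <- c(rep(1L, 4), rep(0L, 6))
  m2 <- classification_metrics(lab2, ev2)
  expect_identical(c(m2$tp, m2$fp, m2$tn, m2$fn), c(0L, 0L, 6L, 4L))
  expect_equal(m2$accuracy, 0.6)
  expect_identical(m2$recall, 0)
  expect_false(m2$precision_defined)

  # labels independent of events: accuracy near 1/2
  set.seed(10)
  n <- 1000L
  lab3 <- factor(sample(c("good", "poor"), n, TRUE),
                 levels = c("good", "poor"))
  ev3 <- rbinom(n, 1, 0.5)
  m3 <- classification_metrics(lab3, ev3)
  expect_lt(abs(m3$accuracy - 0.5), 0.05)
})

test_that("weighted activity reduces to the mean under uniform weights", {
  z <- rbind(A = c(1, 2, 3), B = c(3, 2, 1), C = c(0, 1, 0),
             D = c(2, 2, 2))
  colnames(z) <- paste0("S", 1:3)
  mk <- function(members) list(members = members, seed = members[1],
                               raw_p = 0.5, score_s = log(2), beta = 0,
                               adjusted_p = 0.5)
  # disjoint SPNs: every gene appears once, weights cancel
  disjoint <- structure(list(mk(c("A", "B")), mk(c("C", "D"))),
                        class = "subnetwork_list")
  expect_equal(weighted_activity(z, disjoint),
               build_activity_matrix(z, disjoint), tolerance = 1e-12)
  # gene A in 3 SPNs, partner varies: weight ratio 3:1
  trip <- structure(list(mk(c("A", "B")), mk(c("A", "C")), mk(c("A", "D"))),
                    class = "subnetwork_list")
  wact <- weighted_activity(z, trip)
  expect_equal(unname(wact[1, ]), unname((3 * z["A", ] + z["B", ]) / 4),
               tolerance = 1e-12)
})

test_that("self-classification reproduces training labels exactly", {
  ds <- generate_dataset(
    synthetic_config(n_genes = 120L, n_samples = 120L, n_planted = 2L,
                     planted_size_range = c(4L, 5L), effect_beta = 1.5,
                     metagene_size = 10L), seed = 81)
  res <- discover_spns(ds$expression, ds$network, ds$survival,
                       search_config(), null_trials = 0L)
  spns <- structure(utils::head(res$pns, 4L), class = "subnetwork_list")
  act <- build_activity_matrix(res$z, spns)
  strat <- label_outcome(cluster_patients(act), ds$survival)
  pred <- classify_cohort(spns, strat$centroids, ds$expression,
                          ds$survival, mode = "nearest-centroid")
  # centroid assignment is Voronoi while average-linkage clusters need
  # not be, so boundary patients can flip; agreement must still be high
  expect_gte(mean(pred$outcome_label == strat$outcome_label), 0.9)
  # an SPN losing every gene in the test cohort is dropped
  sub_expr <- ds$expression[setdiff(rownames(ds$expression),
                                    spns[[1]]$members), ]
  w <- capture_warnings(
    pred2 <- classify_cohort(spns, strat$centroids, sub_expr, ds$survival))
  expect_true(any(grepl("dropped", w)))
  expect_length(pred2$sample_ids, ncol(sub_expr))
})

test_that("cross-validation labels every sample and is reproducible", {
  ds <- generate_dataset(
    synthetic_config(n_genes = 80L, n_samples = 100L, n_planted = 1L,
                     planted_size_range = c(5L, 5L), effect_beta = 1.5,
                     metagene_size = 8L), seed = 91)
  cv <- cross_validate(ds$expression, ds$network, ds$survival, k = 5L,
                       repeats = 2L, config = search_config(max_size = 8L),
                       null_trials = 0L, seed = 17)
  expect_false(anyNA(cv$per_repeat))
  expect_identical(dim(cv$per_repeat), c(100L, 2L))
  expect_length(cv$repeat_p, 2L)
  cv2 <- cross_validate(ds$expression, ds$network, ds$survival, k = 5L,
                        repeats = 2L, config = search_config(max_size = 8L),
                        null_trials = 0L, seed = 17)
  expect_identical(cv, cv2)
})
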