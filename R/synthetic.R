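#' Configuration for the synthetic cohort generator
#'
#' Defaults describe the study conditions the pipeline is evaluated
#' under: a sparse scale-free interaction network, standard-normal
#' log-expression background, a small number of vertex-disjoint planted
#' connected subnetworks whose shared latent factor drives a
#' proportional-hazards survival signal, ~30% independent censoring,
#' and a proliferation metagene block that separates samples into three
#' equal ground-truth tertiles.
#'
#' @param n_genes number of genes (network nodes with expression).
#' @param n_samples number of patients.
#' @param network_model `"scale-free"` (Barabasi-Albert preferential
#'   attachment) or `"erdos-renyi"`.
#' @param mean_degree target mean degree of the network.
#' @param n_planted number of planted survival-associated subnetworks.
#' @param planted_size_range integer range of planted set sizes.
#' @param effect_beta log hazard ratio per unit planted-set activity.
#' @param censoring_rate target fraction of censored samples in `[0, 1)`.
#' @param baseline_hazard constant baseline hazard of the exponential
#'   survival model (per month).
#' @param metagene_size number of proliferation metagene genes.
#' @param tertile_separation between-tertile shift of the metagene block
#'   in expression (z) units.
#' @param loading loading of the planted latent risk factor on each
#'   member gene's expression.
#' @param risk_bimodality optional mode offset, in `[0, 1)`, of a
#'   balanced two-component Gaussian mixture for the planted risk
#'   factor ("activated in half the patients"); unit marginal variance
#'   is preserved (within-component sd = sqrt(1 - offset^2)). The
#'   default 0 keeps the factor a plain standard normal.
#' @param min_plant_separation minimum pairwise graph distance between
#'   planted sets. Separation keeps each planted module a distinct
#'   prognostic unit: modules adjacent in the network can be bridged by
#'   a survival-association search into a single higher-scoring
#'   subnetwork, leaving no well-defined per-module ground truth.
#' @param max_plant_degree planted members must have network degree at
#'   most this; global hubs belong to many neighbourhoods at once, so
#'   module boundaries through hubs are ambiguous (module-recovery
#'   benchmarks conventionally exclude them).
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_genes = 500L,
                             n_samples = 250L,
                             network_model = c("scale-free", "erdos-renyi"),
                             mean_degree = 4,
                             n_planted = 3L,
                             planted_size_range = c(5L, 8L),
                             effect_beta = 1.2,
                             censoring_rate = 0.3,
                             baseline_hazard = 0.01,
                             metagene_size = 20L,
                             tertile_separation = 2,
                             loading = 0.8,
                             risk_bimodality = 0,
                             min_plant_separation = 3L,
                             max_plant_degree = 10L) {
  stopifnot(risk_bimodality >= 0, risk_bimodality < 1)
  network_model <- match.arg(network_model)
  stopifnot(n_genes >= 3, n_samples >= 3, mean_degree > 0,
            n_planted >= 0, censoring_rate >= 0, censoring_rate < 1,
            baseline_hazard > 0, metagene_size >= 1,
            tertile_separation >= 0,
            length(planted_size_range) == 2L,
            planted_size_range[1L] >= 1L,
            planted_size_range[2L] <= n_genes)
  structure(list(n_genes = as.integer(n_genes),
                 n_samples = as.integer(n_samples),
                 network_model = network_model,
                 mean_degree = mean_degree,
                 n_planted = as.integer(n_planted),
                 planted_size_range = as.integer(planted_size_range),
                 effect_beta = effect_beta,
                 censoring_rate = censoring_rate,
                 baseline_hazard = baseline_hazard,
                 metagene_size = as.integer(metagene_size),
                 tertile_separation = tertile_separation,
                 loading = loading,
                 risk_bimodality = risk_bimodality,
                 min_plant_separation = as.integer(min_plant_separation),
                 max_plant_degree = as.integer(max_plant_degree)),
            class = "synthetic_config")
}

gene_names <- function(n) sprintf("G%04d", seq_len(n))
sample_names <- function(n) sprintf("S%04d", seq_len(n))

generate_network <- function(config) {
  n <- config$n_genes
  g <- if (config$network_model == "scale-free") {
    m <- max(1L, as.integer(round(config$mean_degree / 2)))
    igraph::sample_pa(n, m = m, directed = FALSE)
  } else {
    igraph::sample_gnp(n, p = min(1, config$mean_degree / (n - 1)))
  }
  el <- igraph::as_edgelist(g, names = FALSE)
  nm <- gene_names(n)
  interaction_network(cbind(nm[el[, 1L]], nm[el[, 2L]]), nodes = nm)
}

#' Plant a connected node set by random breadth-first growth
#'
#' Grows a connected set of exactly `size` nodes from a random seed by
#' repeatedly absorbing a uniformly chosen frontier node, avoiding
#' `exclude`. Uses the current RNG state.
#'
#' @param network an `interaction_network`.
#' @param size target number of nodes.
#' @param exclude nodes unavailable for planting (e.g. earlier plants,
#'   hubs).
#' @param attempts number of random restarts before giving up.
#' @return Character vector of `size` node ids inducing a connected
#'   subgraph.
#' @export
plant_connected_set <- function(network, size, exclude = character(),
                                attempts = 200L) {
  avail <- setdiff(network$nodes, exclude)
  if (length(avail) < size)
    stop("not enough unexcluded nodes to plant a set of size ", size)
  for (a in seq_len(attempts)) {
    seed <- sample(avail, 1L)
    members <- seed
    frontier <- setdiff(intersect(network$adj[[seed]], avail), members)
    while (length(members) < size && length(frontier) > 0L) {
      nxt <- if (length(frontier) == 1L) frontier else sample(frontier, 1L)
      members <- c(members, nxt)
      frontier <- setdiff(
        unique(c(frontier, intersect(network$adj[[nxt]], avail))), members)
    }
    if (length(members) == size) return(sort(members))
  }
  stop("could not plant a connected set of size ", size,
       " after ", attempts, " attempts")
}

# Plant vertex-disjoint connected sets with pairwise graph distance >=
# min_sep, avoiding nodes of degree > max_deg. Each planted module must
# remain a distinct recoverable unit: adjacent same-direction modules
# merge under any survival-association search into one higher-scoring
# subnetwork, and hubs blur module boundaries.
plant_separated_sets <- function(network, sizes, min_sep = 3L,
                                 max_deg = Inf, attempts = 500L) {
  deg <- lengths(network$adj)
  hubs <- network$nodes[deg > max_deg]
  ig <- as_igraph(network)
  planted <- list()
  used <- character()
  for (s in sizes) {
    placed <- FALSE
    for (a in seq_len(attempts)) {
      set <- tryCatch(
        plant_connected_set(network, s, exclude = c(used, hubs),
                            attempts = 10L),
        error = function(e) NULL)
      if (is.null(set)) next
      if (length(planted) > 0L && min_sep > 1L) {
        d <- min(igraph::distances(ig, v = set, to = used))
        if (d < min_sep) next
      }
      planted[[length(planted) + 1L]] <- set
      used <- c(used, set)
      placed <- TRUE
      break
    }
    if (!placed)
      stop("could not place ", length(sizes), " planted sets with pairwise ",
           "distance >= ", min_sep, "; network too dense or small")
  }
  planted
}

#' Generate a synthetic cohort
#'
#' Draws an interaction network, background expression, planted
#' survival-associated subnetworks, proportional-hazards survival times
#' with independent censoring, and a proliferation-metagene tertile
#' structure, all from `config`. Deterministic given `seed`.
#'
#' Expression is i.i.d. standard normal per gene; each planted connected
#' set shares a per-sample latent risk factor r_j ~ N(0,1) (optionally
#' a balanced two-component mixture, see [synthetic_config()]) added
#' with
#' the configured loading to every member gene. Planted sets are
#' vertex-disjoint, avoid hubs, and keep a minimum pairwise graph
#' distance (see [synthetic_config()]). The log hazard for
#' sample j is `log(baseline_hazard) + effect_beta * sum_s a_sj`, where
#' a_sj is planted set s's mean z-score activity; survival times are
#' exponential and censoring times independent exponentials calibrated
#' to the target censoring fraction. Metagene genes (disjoint from
#' planted sets) receive a per-tertile shift of -sep, 0, +sep.
#'
#' @param config a [synthetic_config()].
#' @param seed integer seed; the generator is a pure function of
#'   `(config, seed)`.
#' @return List of class `spn_dataset`: `expression`, `network`,
#'   `survival`, `planted` (list of gene sets), `metagene_genes`,
#'   `tertile_truth` (factor high/inter/low per sample), `config`.
#' @export
generate_dataset <- function(config = synthetic_config(), seed = 1L) {
  set.seed(seed)
  network <- generate_network(config)

  planted <- list()
  if (config$n_planted > 0L) {
    sizes <- sample(seq(config$planted_size_range[1L],
                        config$planted_size_range[2L]),
                    config$n_planted, replace = TRUE)
    planted <- plant_separated_sets(network, sizes,
                                    config$min_plant_separation,
                                    config$max_plant_degree)
  }
  used <- unlist(planted)

  # proliferation metagene block, disjoint from planted sets
  pool <- setdiff(network$nodes, used)
  if (length(pool) < config$metagene_size)
    stop("not enough genes left for the metagene block")
  metagene <- sort(sample(pool, config$metagene_size))

  ds <- sample_cohort(config, network, planted, metagene,
                      prefix = "S")
  ds$seed <- seed
  ds
}

#' Draw an independent cohort from an existing study structure
#'
#' Generates new patients (expression, survival, tertile truth) from
#' the same network, planted subnetworks and metagene as `dataset` —
#' e.g. a held-out validation cohort for SPNs trained on the original
#' cohort. Sample ids are prefixed `T` to keep the cohorts distinct.
#'
#' @param dataset an `spn_dataset`.
#' @param seed integer seed for the new cohort.
#' @param n_samples number of new patients (defaults to the original
#'   cohort size).
#' @return A new `spn_dataset` sharing `network`, `planted` and
#'   `metagene_genes` with the input.
#' @export
resample_cohort <- function(dataset, seed, n_samples = NULL) {
  config <- dataset$config
  if (!is.null(n_samples)) config$n_samples <- as.integer(n_samples)
  set.seed(seed)
  ds <- sample_cohort(config, dataset$network, dataset$planted,
                      dataset$metagene_genes, prefix = "T")
  ds$seed <- seed
  ds
}

# draw expression, tertile structure and survival for one cohort given
# the fixed study structure (network, planted sets, metagene)
sample_cohort <- function(config, network, planted, metagene, prefix) {
  n_g <- config$n_genes
  n_s <- config$n_samples
  genes <- network$nodes
  samples <- sprintf("%s%04d", prefix, seq_len(n_s))

  expr <- matrix(rnorm(n_g * n_s), nrow = n_g,
                 dimnames = list(genes, samples))
  mu <- config$risk_bimodality
  for (set in planted) {
    # optional balanced two-component mixture with unit marginal
    # variance: the module is "activated" in ~half the patients
    r <- if (mu > 0) {
      sample(c(-mu, mu), n_s, replace = TRUE) +
        rnorm(n_s, sd = sqrt(1 - mu^2))
    } else {
      rnorm(n_s)
    }
    expr[set, ] <- expr[set, , drop = FALSE] +
      config$loading * matrix(r, nrow = length(set), ncol = n_s, byrow = TRUE)
  }

  tert <- assign_truth_tertiles(n_s)
  shift <- c(high = config$tertile_separation, inter = 0,
             low = -config$tertile_separation)
  expr[metagene, ] <- expr[metagene, , drop = FALSE] +
    matrix(shift[as.character(tert)], nrow = length(metagene), ncol = n_s,
           byrow = TRUE)

  # linear predictor from planted-set mean z activities
  lp <- numeric(n_s)
  if (length(planted) > 0L && config$effect_beta != 0) {
    z <- row_standardize(expr)
    for (set in planted) {
      lp <- lp + config$effect_beta * colMeans(z[set, , drop = FALSE])
    }
  }
  hazard <- config$baseline_hazard * exp(lp)
  t_event <- rexp(n_s, rate = hazard)
  if (config$censoring_rate > 0) {
    c_rate <- calibrate_censoring(hazard, config$censoring_rate)
    t_cens <- rexp(n_s, rate = c_rate)
    time <- pmin(t_event, t_cens)
    event <- as.integer(t_event <= t_cens)
  } else {
    time <- t_event
    event <- rep(1L, n_s)
  }
  time <- pmax(time, 1e-6)
  surv <- data.frame(sample_id = samples, time = time, event = event,
                     stringsAsFactors = FALSE)

  structure(list(expression = expr, network = network, survival = surv,
                 planted = planted, metagene_genes = metagene,
                 tertile_truth = tert, config = config),
            class = "spn_dataset")
}

# equal-as-possible ground-truth tertiles, assigned by a random
# permutation of the sample positions
assign_truth_tertiles <- function(n_samples) {
  base <- n_samples %/% 3L
  sizes <- rep(base, 3L)
  extra <- n_samples %% 3L
  if (extra >= 1L) sizes[1L] <- sizes[1L] + 1L
  if (extra >= 2L) sizes[2L] <- sizes[2L] + 1L
  labels <- rep(c("high", "inter", "low"), times = sizes)
  factor(labels[sample.int(n_samples)], levels = c("high", "inter", "low"))
}

# censoring rate for exponential censoring C ~ Exp(c) against
# heterogeneous event rates: P(censored) = mean(c / (c + lambda_j))
calibrate_censoring <- function(hazard, target) {
  f <- function(cr) mean(cr / (cr + hazard)) - target
  uniroot(f, lower = 1e-10, upper = 1e6, tol = 1e-10)$root
}

row_standardize <- function(mat) {
  mu <- rowMeans(mat)
  sdv <- apply(mat, 1L, sd)
  sdv[sdv == 0] <- 1
  (mat - mu) / sdv
}

#' Write a synthetic dataset's fixture files
#'
#' Expression TSV, network edge list, survival TSV and a truth JSON
#' (planted sets, metagene genes, tertile labels).
#'
#' @param dataset an `spn_dataset`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_expression(dataset$expression, file.path(dir, "expression.tsv"))
  e <- dataset$network$edges
  writeLines(paste(e[, 1L], e[, 2L], sep = "\t"),
             file.path(dir, "network_edges.tsv"))
  write_survival(dataset$survival, file.path(dir, "survival.tsv"))
  truth <- list(planted = lapply(dataset$planted, as.list),
                metagene_genes = as.list(dataset$metagene_genes),
                tertile_truth = as.list(as.character(dataset$tertile_truth)),
                seed = dataset$seed)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}
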