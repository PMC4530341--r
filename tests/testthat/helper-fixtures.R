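# Shared fixtures and independent oracles used across test files.

# small undirected network from an edge string like "A-B B-C"
net_from_string <- function(s, nodes = character()) {
  pairs <- strsplit(strsplit(trimws(s), "\\s+")[[1]], "-", fixed = TRUE)
  interaction_network(do.call(rbind, pairs), nodes = nodes)
}

# deterministic toy expression matrix
toy_expr <- function(genes, samples, seed = 1) {
  set.seed(seed)
  matrix(rnorm(length(genes) * length(samples)),
         nrow = length(genes), dimnames = list(genes, samples))
}

toy_survival <- function(n, seed = 1, rate = 0.05, censor = 0.3,
                         prefix = "S") {
  set.seed(seed)
  tm <- rexp(n, rate)
  cs <- rexp(n, rate * censor / (1 - censor))
  data.frame(sample_id = sprintf("%s%03d", prefix, seq_len(n)),
             time = pmin(tm, cs), event = as.integer(tm <= cs),
             stringsAsFactors = FALSE)
}

# --- independent Cox partial-likelihood oracle -----------------------
# Written-out Efron log partial likelihood, evaluated by explicit
# risk-set loops (O(n^2)); maximized by stats::optimize. Kept free of
# any package internals so it can arbitrate the fast implementation.
oracle_cox_loglik <- function(beta, x, time, event) {
  ll <- 0
  ev_times <- sort(unique(time[event == 1]))
  for (t in ev_times) {
    D <- which(time == t & event == 1)
    R <- which(time >= t)
    d <- length(D)
    wR <- sum(exp(beta * x[R]))
    wD <- sum(exp(beta * x[D]))
    ll <- ll + beta * sum(x[D])
    for (l in seq_len(d) - 1L) {
      ll <- ll - log(wR - (l / d) * wD)
    }
  }
  ll
}

oracle_cox_score <- function(x, time, event) {
  opt <- optimize(oracle_cox_loglik, interval = c(-25, 25), x = x,
                  time = time, event = event, maximum = TRUE,
                  tol = 1e-9)
  ll0 <- oracle_cox_loglik(0, x, time, event)
  chisq <- max(0, 2 * (opt$objective - ll0))
  list(beta = opt$maximum, chisq = chisq,
       score_s = -pchisq(chisq, 1, lower.tail = FALSE, log.p = TRUE))
}

# --- independent log-rank oracle -------------------------------------
# Observed-minus-expected over the pooled risk-set table with the
# hypergeometric variance, two groups, 1 df.
oracle_logrank <- function(time, event, group) {
  group <- as.integer(factor(group))
  ev_times <- sort(unique(time[event == 1]))
  OmE <- 0
  V <- 0
  for (t in ev_times) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & group == 1L)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & group == 1L)
    OmE <- OmE + d1 - d * n1 / n
    if (n > 1)
      V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  chisq <- OmE^2 / V
  list(chisq = chisq, p = pchisq(chisq, 1, lower.tail = FALSE))
}

# --- combinatorial hypergeometric tail oracle ------------------------
# P[X >= k] summed directly from binomial coefficients.
oracle_hyper_tail <- function(k, n, K, N) {
  if (k <= 0) return(1)
  j <- k:min(n, K)
  sum(exp(lchoose(K, j) + lchoose(N - K, n - j) - lchoose(N, n)))
}

# enumerate all connected subsets of size <= max_size of a network
# (exhaustive-oracle helper for the greedy search quality property)
enumerate_connected_subsets <- function(network, max_size) {
  nodes <- network$nodes
  out <- as.list(nodes)
  frontier <- lapply(nodes, function(n) n)
  seen <- new.env(parent = emptyenv())
  for (n in nodes) assign(n, TRUE, envir = seen)
  current <- frontier
  for (size in seq_len(max_size - 1L)) {
    nxt <- list()
    for (set in current) {
      nb <- setdiff(unique(unlist(network$adj[set])), set)
      for (g in nb) {
        cand <- sort(c(set, g))
        key <- paste(cand, collapse = "|")
        if (!exists(key, envir = seen)) {
          assign(key, TRUE, envir = seen)
          nxt[[length(nxt) + 1L]] <- cand
        }
      }
    }
    out <- c(out, nxt)
    current <- nxt
  }
  out
}
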