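# Small graphs, cohorts and brute-force oracles shared across tests.

# interaction_network from a compact edge string: "A-B,B-C"
net_from_string <- function(s) {
  pairs <- strsplit(strsplit(s, ",", fixed = TRUE)[[1]], "-", fixed = TRUE)
  edges <- do.call(rbind, pairs)
  column_normalize(interaction_network(edges))
}

# random connected-ish undirected simple graph as an interaction_network
random_network <- function(n, p_edge = 0.1, seed = 1) {
  set.seed(seed)
  repeat {
    g <- igraph::sample_gnp(n, p_edge)
    g <- igraph::largest_component(g)
    if (igraph::vcount(g) >= max(3, n * 0.5)) break
    p_edge <- p_edge * 1.5
  }
  el <- igraph::as_edgelist(g, names = FALSE)
  ids <- sprintf("N%03d", seq_len(igraph::vcount(g)))
  column_normalize(interaction_network(cbind(ids[el[, 1]], ids[el[, 2]])))
}

# valid random start vector on a network
random_p0 <- function(network, n_seeds = 5, seed = 1) {
  set.seed(seed)
  v <- stats::setNames(numeric(length(network$nodes)), network$nodes)
  idx <- sample(seq_along(v), n_seeds)
  v[idx] <- stats::runif(n_seeds)
  v / sum(v)
}

# brute-force Harrell C-index: explicit double loop
cindex_bruteforce <- function(scores, time, event) {
  num <- 0; den <- 0
  n <- length(time)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (time[i] < time[j] && event[i] == 1) {
      den <- den + 1
      if (scores[i] > scores[j]) num <- num + 1
      else if (scores[i] == scores[j]) num <- num + 0.5
    }
  }
  if (den == 0) stop("no comparable pairs")
  num / den
}

# random censored survival fixture
random_survival <- function(n, seed = 1, tie_prob = 0.2) {
  set.seed(seed)
  time <- stats::rexp(n, 0.1) + 0.5
  ties <- stats::runif(n) < tie_prob
  time[ties] <- ceiling(time[ties])
  list(time = time, event = stats::rbinom(n, 1, 0.7),
       scores = stats::rnorm(n))
}

# Breslow partial log-likelihood for a single covariate (oracle for cox_fit)
breslow_loglik <- function(beta, x, time, event) {
  ll <- 0
  for (t in sort(unique(time[event == 1]))) {
    d <- which(time == t & event == 1)
    risk <- which(time >= t)
    ll <- ll + beta * sum(x[d]) - length(d) * log(sum(exp(beta * x[risk])))
  }
  ll
}

# tiny benchmark for fast pipeline tests
small_config <- function(...) {
  synthetic_config(n_genes = 400L, module_size = 40L,
                   n_mutated_genes = 60L, n_samples = 60L, ...)
}
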