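# shared fixtures: tiny graphs and configurations built in code

toy_graph <- function(edges, confidence = NULL) {
  # edges: data.frame(from, to) or matrix; default confidence 0.9
  df <- as.data.frame(edges, stringsAsFactors = FALSE)
  names(df)[1:2] <- c("from", "to")
  df$confidence <- if (is.null(confidence)) rep(0.9, nrow(df)) else confidence
  igraph::graph_from_data_frame(df, directed = FALSE)
}

# star S - L1..L4
star_graph <- function() {
  toy_graph(data.frame(from = "S", to = paste0("L", 1:4)))
}

# two 8-cliques on a 30-node background, used by the pulldown recovery test
two_clique_graph <- function() {
  cl1 <- t(utils::combn(sprintf("A%02d", 1:8), 2))
  cl2 <- t(utils::combn(sprintf("B%02d", 1:8), 2))
  extra <- cbind(sprintf("C%02d", 1:13), c(sprintf("C%02d", 2:13), "A01"))
  bridge <- rbind(c("A02", "C05"), c("B03", "C09"))
  toy_graph(rbind(cl1, cl2, extra, bridge))
}

random_modules <- function(n_modules, universe_size = 60, seed = 1,
                           g = NULL) {
  set.seed(seed)
  ids <- sprintf("P%03d", seq_len(universe_size))
  lapply(seq_len(n_modules), function(i) {
    nodes <- sample(ids, sample(4:12, 1))
    network_module(sprintf("m%02d", i), nodes, seeds = nodes[1])
  })
}

small_cfg <- function(seed = 1, ...) {
  simulation_config(n_proteins = 120, n_planted_modules = 2,
                    module_size_range = c(8L, 10L), p_in = 0.6, p_out = 0.02,
                    hub_count = 1, n_metabolites = 8, n_discriminant = 5,
                    links_per_metabolite = c(2L, 4L),
                    group_sizes = c(4L, 4L, 4L, 4L), rng_seed = seed, ...)
}

small_metab <- function(values, ...) {
  metabolite_table(values, ...)
}

# independent step-up BH, coded from the definition
bh_reference <- function(p) {
  n <- length(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  q <- pmin(1, cummin(n / (n:1) * p[o]))[ro]
  q
}

# hypergeometric upper-tail by explicit enumeration
hyper_tail_reference <- function(k, K, M, n) {
  ks <- k:min(K, n)
  sum(choose(K, ks) * choose(M - K, n - ks)) / choose(M, n)
}
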