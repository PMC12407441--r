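test_that("confidence filter drops weak edges and isolated nodes", {
  g <- toy_graph(data.frame(from = c("A", "B"), to = c("B", "C")),
                 confidence = c(0.05, 0.5))
  gf <- filter_interactome(g, 0.1)
  expect_setequal(igraph::V(gf)$name, c("B", "C"))
  expect_equal(igraph::ecount(gf), 1)
  expect_equal(igraph::graph_attr(gf, "removed_edges"), 1)
  # threshold zero is the identity on edges
  expect_equal(igraph::ecount(filter_interactome(g, 0)), 2)
  expect_error(filter_interactome(g, 1.5), "min_confidence")
})

test_that("surviving edge count equals a brute-force confidence count", {
  sim <- generate_interactome(small_cfg(seed = 17))
  gf <- filter_interactome(sim$graph, 0.1)
  expect_equal(igraph::ecount(gf),
               sum(igraph::E(sim$graph)$confidence >= 0.1))
})

test_that("first-order networks are induced neighborhoods", {
  m <- first_order_network(star_graph(), "S")
  expect_equal(length(m$nodes), 5)
  expect_equal(nrow(m$edges), 4)
  expect_identical(m$seeds, "S")
  tri <- toy_graph(data.frame(from = c("A", "B", "C"), to = c("B", "C", "A")))
  mt <- first_order_network(tri, "A")
  expect_equal(length(mt$nodes), 3)
  expect_equal(nrow(mt$edges), 3)    # includes the neighbor-neighbor edge
  ms <- first_order_network(tri, "A", mode = "star")
  expect_equal(nrow(ms$edges), 2)
  expect_warning(mo <- first_order_network(tri, "Z"), "absent")
  expect_equal(length(mo$nodes), 0)
})

test_that("first-order extraction equals brute-force neighborhood induction", {
  sim <- generate_interactome(small_cfg(seed = 23))
  gf <- filter_interactome(sim$graph, 0.1)
  el <- igraph::as_edgelist(gf)
  seeds <- sample(igraph::V(gf)$name, 20)
  for (s in seeds) {
    m <- first_order_network(gf, s)
    nbrs <- unique(c(el[el[, 1] == s, 2], el[el[, 2] == s, 1]))
    expect_setequal(m$nodes, c(s, nbrs))
    in_mod <- el[, 1] %in% m$nodes & el[, 2] %in% m$nodes
    expect_equal(nrow(m$edges), sum(in_mod))
  }
})

test_that("pruning removes hubs weakly engaged in the module, never seeds", {
  # hub H: high global degree, 2 in-module edges; module built around seed S
  mod_nodes <- sprintf("M%02d", 1:19)
  mod_edges <- data.frame(from = "S", to = mod_nodes)
  extra <- data.frame(from = "H", to = c("S", "M01"))
  hub_edges <- data.frame(from = "H", to = sprintf("X%03d", 1:400))
  chain <- data.frame(from = sprintf("X%03d", 1:499),
                      to = sprintf("X%03d", 2:500))
  g <- toy_graph(rbind(mod_edges, extra, hub_edges, chain))
  m <- first_order_network(g, "S")
  expect_true("H" %in% m$nodes)
  p <- prune_overconnected(m, g, degree_percentile = 0.99,
                           inside_fraction_min = 0.10)
  expect_false("H" %in% p$nodes)
  expect_true("S" %in% p$seeds)
  # a module with no node above the percentile is unchanged
  quiet <- first_order_network(g, "X450")  # outside the hub's reach
  expect_identical(prune_overconnected(quiet, g)$nodes, quiet$nodes)
  # seeds are protected even when over-connected
  mh <- first_order_network(g, "H")
  ph <- prune_overconnected(mh, g)
  expect_true("H" %in% ph$nodes)
})

test_that("pruning is monotone in the inside-fraction threshold", {
  sim <- generate_interactome(small_cfg(seed = 29))
  gf <- filter_interactome(sim$graph, 0.1)
  s <- igraph::V(gf)$name[which.max(igraph::degree(gf))]
  m <- first_order_network(gf, s)
  sizes <- vapply(c(0, 0.05, 0.1, 0.3, 1), function(f)
    length(prune_overconnected(m, gf, 0.9, f)$nodes), numeric(1))
  expect_true(all(diff(sizes) <= 0))
})

test_that("capping keeps seeds plus top-confidence neighbors with id tie-break", {
  set.seed(41)
  leaves <- sprintf("L%03d", 1:300)
  conf <- round(runif(300), 2)          # coarse grid forces ties
  g <- toy_graph(data.frame(from = "S", to = leaves), confidence = conf)
  m <- first_order_network(g, "S")
  capped <- cap_network(m, g, max_nodes = 200)
  expect_equal(length(capped$nodes), 200)
  expect_true("S" %in% capped$nodes)
  # brute-force ranking: confidence desc, id asc
  ord <- leaves[order(-conf, leaves)]
  expect_setequal(capped$nodes, c("S", head(ord, 199)))
  # under-cap modules unchanged
  small <- first_order_network(star_graph(), "S")
  expect_identical(cap_network(small, star_graph())$nodes, small$nodes)
})

test_that("strong seed enrichment exempts a module from the cap", {
  leaves <- sprintf("L%03d", 1:300)
  g <- toy_graph(data.frame(from = "S", to = leaves))
  m <- first_order_network(g, "S")
  ex <- cap_network(m, g, max_nodes = 200, exemption_q = 1e-4, seed_q = 1e-6)
  expect_equal(length(ex$nodes), 301)
  expect_true(ex$cap_exempt)
})

test_that("containment merging handles the textbook cases", {
  g <- toy_graph(data.frame(from = c("A", "B", "C", "A", "E"),
                            to = c("B", "C", "D", "E", "F")))
  n1 <- network_module("n1", c("A", "B", "C", "D"), seeds = "A")
  n2 <- network_module("n2", c("A", "B", "C"), seeds = "B")
  merged <- merge_overlapping(list(n1, n2), g)
  expect_equal(length(merged), 1)
  expect_setequal(merged[[1]]$nodes, c("A", "B", "C", "D"))
  expect_setequal(merged[[1]]$seeds, c("A", "B"))
  expect_setequal(merged[[1]]$merged_from, c("n1", "n2"))
  n3 <- network_module("n3", c("A", "B", "E", "F"))
  kept <- merge_overlapping(list(n1, n3), g)   # overlap 0.5
  expect_equal(length(kept), 2)
})

test_that("whitelisted pairs survive above-threshold overlap", {
  g <- toy_graph(data.frame(from = c("A", "B", "C"), to = c("B", "C", "D")))
  n1 <- network_module("n1", c("A", "B", "C", "D"))
  n2 <- network_module("n2", c("A", "B", "C"))
  kept <- merge_overlapping(list(n1, n2), g,
                            whitelist = list(c("n1", "n2")))
  expect_equal(length(kept), 2)
})

test_that("merge reaches the fixpoint found by an exhaustive oracle", {
  g <- toy_graph(t(utils::combn(sprintf("P%03d", 1:60), 2)))  # complete graph
  mods <- random_modules(30, universe_size = 60, seed = 55)
  merged <- merge_overlapping(mods, g, overlap_min = 0.75)

  # oracle: recompute every pairwise overlap each round from scratch
  oracle_sets <- lapply(mods, function(m)
    list(id = m$network_id, nodes = m$nodes, size0 = length(m$nodes)))
  repeat {
    best <- NULL; best_ov <- 0.75; best_key <- NULL
    for (i in seq_along(oracle_sets)) for (j in seq_along(oracle_sets)) {
      if (i >= j) next
      a <- oracle_sets[[i]]; b <- oracle_sets[[j]]
      ov <- length(intersect(a$nodes, b$nodes)) /
        min(length(a$nodes), length(b$nodes))
      key <- paste(sort(c(a$id, b$id)), collapse = "\r")
      if (ov > best_ov || (ov == best_ov && !is.null(best) &&
                           key < best_key)) {
        best <- c(i, j); best_ov <- ov; best_key <- key
      }
    }
    if (is.null(best)) break
    a <- oracle_sets[[best[1]]]; b <- oracle_sets[[best[2]]]
    lead <- if (length(a$nodes) > length(b$nodes)) a
    else if (length(b$nodes) > length(a$nodes)) b
    else if (a$id <= b$id) a else b
    oracle_sets[[best[1]]] <- list(id = lead$id,
                                   nodes = union(a$nodes, b$nodes))
    oracle_sets[[best[2]]] <- NULL
  }
  expect_equal(length(merged), length(oracle_sets))
  got <- lapply(merged, function(m) sort(m$nodes))
  want <- lapply(oracle_sets, function(s) sort(s$nodes))
  expect_setequal(vapply(got, paste, character(1), collapse = ","),
                  vapply(want, paste, character(1), collapse = ","))
  # fixpoint: no residual pair above the threshold
  ov <- overlap_matrix(merged, "containment")
  expect_true(all(ov <= 0.75))
})

test_that("metabolite annotation counts intersections exactly", {
  sm <- structure(list(map = list(histidine = "P1", laurate = c("P2", "P9")),
                       seed_proteins = c("P1", "P2", "P9"),
                       unmapped = character(0)), class = "seed_map")
  m <- network_module("n1", c("P1", "P3"))
  expect_identical(annotate_metabolites(m, sm)$linked_metabolites, "histidine")
  m2 <- network_module("n2", c("P7", "P8"))
  expect_identical(annotate_metabolites(m2, sm)$linked_metabolites,
                   character(0))
})

test_that("no pipeline stage removes a seed from its own module", {
  cfg <- small_cfg(seed = 37)
  sim <- generate_interactome(cfg)
  tab <- generate_associations(sim$truth, cfg)
  sm <- resolve_metabolites(c(sim$truth$discriminant_metabolites,
                              sim$truth$decoy_metabolites), tab)
  mods <- suppressWarnings(run_pulldown(sim$graph, sm))
  for (m in mods) expect_true(all(m$seeds %in% m$nodes))
})

test_that("the pulldown recovers planted cliques on a toy graph", {
  g <- two_clique_graph()
  sm <- structure(list(map = list(metA = "A01", metB = "B05"),
                       seed_proteins = c("A01", "B05"),
                       unmapped = character(0)), class = "seed_map")
  mods <- run_pulldown(g, sm)
  # the two clique modules must be present (background chain nodes may
  # attach through the bridge edges)
  nodesets <- lapply(mods, `[[`, "nodes")
  hasA <- any(vapply(nodesets, function(s)
    all(sprintf("A%02d", 1:8) %in% s), logical(1)))
  hasB <- any(vapply(nodesets, function(s)
    all(sprintf("B%02d", 1:8) %in% s), logical(1)))
  expect_true(hasA && hasB)
})

test_that("zero mapped seeds yield an empty collection with a warning", {
  g <- star_graph()
  sm <- structure(list(map = list(), seed_proteins = character(0),
                       unmapped = "x"), class = "seed_map")
  expect_warning(mods <- run_pulldown(g, sm), "empty collection")
  expect_equal(length(mods), 0)
})

test_that("the pulldown is deterministic given identical inputs", {
  cfg <- small_cfg(seed = 43)
  sim <- generate_interactome(cfg)
  tab <- generate_associations(sim$truth, cfg)
  sm <- resolve_metabolites(sim$truth$discriminant_metabolites, tab)
  m1 <- suppressWarnings(run_pulldown(sim$graph, sm))
  m2 <- suppressWarnings(run_pulldown(sim$graph, sm))
  expect_identical(lapply(m1, `[[`, "nodes"), lapply(m2, `[[`, "nodes"))
})

test_that("xgmml writer and reader round-trip a collection", {
  cfg <- small_cfg(seed = 47)
  sim <- generate_interactome(cfg)
  tab <- generate_associations(sim$truth, cfg)
  sm <- resolve_metabolites(sim$truth$discriminant_metabolites, tab)
  mods <- suppressWarnings(run_pulldown(sim$graph, sm))[1:5]
  path <- withr::local_tempfile(fileext = ".xgmml")
  write_xgmml(mods, path)
  back <- read_xgmml(path)
  expect_equal(length(back), 5)
  for (i in seq_along(back)) {
    expect_identical(sort(back[[i]]$nodes), sort(mods[[i]]$nodes))
    expect_identical(sort(back[[i]]$seeds), sort(mods[[i]]$seeds))
    expect_identical(back[[i]]$linked_metabolites,
                     mods[[i]]$linked_metabolites)
    expect_equal(nrow(back[[i]]$edges), nrow(mods[[i]]$edges))
  }
})
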