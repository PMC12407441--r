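test_that("invalid configurations are rejected naming the offending field", {
  expect_error(simulation_config(n_proteins = 0), "n_proteins")
  expect_error(simulation_config(p_in = 1.2), "p_in")
  expect_error(simulation_config(n_proteins = 20, module_size_range = c(5, 30)),
               "module_size_range")
  expect_error(simulation_config(n_metabolites = 5, n_discriminant = 6),
               "n_discriminant")
  expect_error(simulation_config(group_sizes = c(3, 3, 3)), "group_sizes")
})

test_that("degenerate probabilities give cliques and no cross-module edges", {
  cfg <- simulation_config(n_proteins = 50, n_planted_modules = 2,
                           module_size_range = c(10L, 10L), p_in = 1,
                           p_out = 0, hub_count = 0, n_metabolites = 4,
                           n_discriminant = 2, rng_seed = 11)
  sim <- generate_interactome(cfg)
  g <- sim$graph
  for (mod in sim$truth$modules) {
    sg <- igraph::induced_subgraph(g, mod)
    expect_equal(igraph::ecount(sg), choose(10, 2))  # 10-clique
  }
  # every edge lies within one module
  el <- igraph::as_edgelist(g)
  mod_of <- rep(names(sim$truth$modules),
                lengths(sim$truth$modules))
  names(mod_of) <- unlist(sim$truth$modules)
  expect_true(all(!is.na(mod_of[el[, 1]])))
  expect_true(all(mod_of[el[, 1]] == mod_of[el[, 2]]))
})

test_that("generators are bit-reproducible given the seed", {
  cfg <- small_cfg(seed = 42)
  s1 <- generate_interactome(cfg)
  s2 <- generate_interactome(cfg)
  expect_identical(igraph::as_edgelist(s1$graph), igraph::as_edgelist(s2$graph))
  expect_identical(igraph::E(s1$graph)$confidence,
                   igraph::E(s2$graph)$confidence)
  expect_identical(generate_associations(s1$truth, cfg),
                   generate_associations(s2$truth, cfg))
  a1 <- generate_abundance(cfg, s1$truth)
  a2 <- generate_abundance(cfg, s2$truth)
  expect_identical(a1$plasma$values, a2$plasma$values)
})

test_that("realized within-module density tracks p_in over replicates", {
  dens <- replicate(20, {
    cfg <- simulation_config(n_proteins = 500, p_in = 0.4, p_out = 0.01,
                             rng_seed = sample.int(1e6, 1))
    sim <- generate_interactome(cfg)
    mean(vapply(sim$truth$modules, function(mod) {
      sg <- igraph::induced_subgraph(sim$graph, mod)
      igraph::ecount(sg) / choose(length(mod), 2)
    }, numeric(1)))
  })
  expect_lt(abs(mean(dens) - 0.4), 0.05)
})

test_that("planted modules are denser than background when p_in >> p_out", {
  cfg <- simulation_config(n_proteins = 250, n_planted_modules = 3,
                           module_size_range = c(12L, 16L),
                           p_in = 0.3, p_out = 0.05, rng_seed = 5)
  sim <- generate_interactome(cfg)
  in_mod <- unlist(sim$truth$modules)
  bg <- setdiff(igraph::V(sim$graph)$name, in_mod)
  bg_dens <- igraph::ecount(igraph::induced_subgraph(sim$graph, bg)) /
    choose(length(bg), 2)
  mod_dens <- vapply(sim$truth$modules, function(mod)
    igraph::ecount(igraph::induced_subgraph(sim$graph, mod)) /
      choose(length(mod), 2), numeric(1))
  expect_true(all(mod_dens >= bg_dens))
})

test_that("hub proteins reach at least ten times the median degree", {
  sim <- generate_interactome(small_cfg(seed = 9))
  deg <- igraph::degree(sim$graph)
  expect_true(all(deg[sim$truth$hubs] >= 10 * stats::median(deg)))
})

test_that("association tables honor configured link counts", {
  cfg <- small_cfg(seed = 3)
  cfg$links_per_metabolite <- c(3L, 3L)
  sim <- generate_interactome(cfg)
  tab <- generate_associations(sim$truth, cfg, text_mining_fraction = 0)
  expect_equal(nrow(tab), cfg$n_metabolites * 3)
  expect_true(all(tab$association_class %in% c("physical", "functional")))
  # expected row count under variable links: mean of the range per metabolite
  cfg2 <- small_cfg(seed = 4)
  cfg2$n_metabolites <- 20L; cfg2$n_discriminant <- 20L
  cfg2$links_per_metabolite <- c(2L, 8L)   # mean 5
  sim2 <- generate_interactome(cfg2)
  tab2 <- generate_associations(sim2$truth, cfg2, text_mining_fraction = 0)
  expect_lt(abs(nrow(tab2) - 100), 30)  # 20 x 5 +/- sampling noise
})

test_that("discriminant metabolites link preferentially into their module", {
  cfg <- small_cfg(seed = 8)
  sim <- generate_interactome(cfg)
  tab <- generate_associations(sim$truth, cfg, in_module_fraction = 1,
                               text_mining_fraction = 0)
  for (m in sim$truth$discriminant_metabolites) {
    mod <- sim$truth$modules[[sim$truth$metabolite_module[[m]]]]
    prots <- tab$protein_id[tab$metabolite_id == m]
    expect_true(all(prots %in% mod))
  }
})

test_that("abundance generator reproduces the configured group effect", {
  # group-mean log difference should recover effect_log2 * ln 2
  errs <- replicate(50, {
    cfg <- simulation_config(n_proteins = 30, n_planted_modules = 1,
                             module_size_range = c(5L, 5L),
                             n_metabolites = 6, n_discriminant = 4,
                             group_sizes = c(6L, 6L, 6L, 6L),
                             effect_log2 = 2, missing_rate = 0,
                             rng_seed = sample.int(1e6, 1))
    sim <- generate_interactome(cfg)
    ab <- generate_abundance(cfg, sim$truth)
    v <- log(ab$plasma$values)
    meta <- ab$plasma$metadata
    m <- sim$truth$discriminant_metabolites[
      sim$truth$metabolite_category == "Diet"][1]
    mean(v[meta$diet == "HFD", m]) - mean(v[meta$diet == "CD", m])
  })
  expect_lt(abs(mean(errs) - 2 * log(2)), 0.15 * 2 * log(2))
})

test_that("missingness is absent at rate zero and left-censored otherwise", {
  cfg <- small_cfg(seed = 2)
  cfg$missing_rate <- 0
  sim <- generate_interactome(cfg)
  ab <- generate_abundance(cfg, sim$truth)
  expect_false(anyNA(ab$plasma$values))
  cfg$missing_rate <- 0.3
  ab2 <- generate_abundance(cfg, sim$truth)
  expect_gt(mean(is.na(ab2$plasma$values)), 0.15)
  # left-censoring: every observed value exceeds the column's censor bound
  v <- ab2$feces$values
  for (j in seq_len(ncol(v))) {
    if (!anyNA(v[, j])) next
    expect_true(min(v[, j], na.rm = TRUE) > 0)
  }
})

test_that("asv counts conserve sequencing depth per sample", {
  cfg <- small_cfg(seed = 6)
  a <- generate_asv_counts(cfg, depth = 10000)
  expect_true(all(rowSums(a$counts) == 10000))
  one <- generate_asv_counts(simulation_config(group_sizes = c(1L, 1L, 1L, 1L),
                                               rng_seed = 1), depth = 500)
  expect_true(all(rowSums(one$counts) == 500))
})

test_that("gene-set corruption matches the configured noise fraction", {
  cfg <- small_cfg(seed = 10)
  cfg$module_size_range <- c(20L, 20L)
  sim <- generate_interactome(cfg)
  gs0 <- generate_gene_sets(sim$truth, cfg, noise_fraction = 0)
  expect_identical(gs0$sets[["AD_mod01"]], sim$truth$modules$mod01)
  overlaps <- replicate(20, {
    cfg2 <- small_cfg(seed = sample.int(1e6, 1))
    cfg2$module_size_range <- c(20L, 20L)
    sim2 <- generate_interactome(cfg2)
    gs <- generate_gene_sets(sim2$truth, cfg2, noise_fraction = 0.5)
    length(intersect(gs$sets[["AD_mod01"]], sim2$truth$modules$mod01))
  })
  expect_lt(abs(mean(overlaps) - 10), 2)  # |module| = 20, half swapped
})

test_that("interactome and ground-truth writers round-trip", {
  sim <- generate_interactome(small_cfg(seed = 12))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_interactome(sim$graph, path)
  g2 <- read_interactome(path)
  expect_equal(igraph::ecount(g2), igraph::ecount(sim$graph))
  expect_equal(sort(igraph::V(g2)$name),
               sort(igraph::V(sim$graph)$name[igraph::degree(sim$graph) > 0]))
  jp <- withr::local_tempfile(fileext = ".json")
  write_ground_truth(sim$truth, jp)
  back <- jsonlite::read_json(jp, simplifyVector = TRUE)
  expect_equal(sort(unlist(back$modules$mod01)), sim$truth$modules$mod01)
})
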