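#' Simulation configuration for the synthetic benchmark
#'
#' Bundles every knob of the synthetic-data generators: a confidence-weighted
#' interactome with planted dense modules and promiscuous hubs, a
#' metabolite-to-protein association table, four-group (wild-type/transgenic x
#' control/high-fat diet) metabolite intensity matrices with left-censored
#' missingness, and Dirichlet-multinomial amplicon count tables.
#'
#' Defaults describe the benchmark used throughout the test-suite: a
#' 500-protein interactome with five planted modules of 15-25 proteins
#' (within-module edge probability 0.4 against a 0.01 background), five hub
#' proteins, edge confidences drawn from Beta(1, 3) so that a meaningful
#' fraction of edges falls below the 0.1 confidence filter, 30 metabolites of
#' which 20 discriminate the experimental groups, and group sizes 6/3/6/6
#' matching a four-group rodent design after sample attrition.
#'
#' @param n_proteins number of proteins in the interactome.
#' @param n_planted_modules number of planted dense modules.
#' @param module_size_range integer vector of length 2, inclusive bounds for
#'   module sizes.
#' @param p_in within-module edge probability.
#' @param p_out background edge probability (per node pair).
#' @param hub_count number of designated promiscuous hub proteins, wired to at
#'   least ten times the median degree.
#' @param confidence_beta_params shape parameters of the Beta distribution
#'   edge confidences are drawn from.
#' @param n_metabolites total number of metabolites.
#' @param n_discriminant number of metabolites carrying a true group effect
#'   and module-directed protein links.
#' @param links_per_metabolite integer vector of length 2, inclusive bounds
#'   for the number of protein links per metabolite.
#' @param group_sizes integer vector of length 4: samples in the WT-CD,
#'   WT-HFD, Tg-CD and Tg-HFD groups.
#' @param effect_log2 log2 fold-change applied to discriminant metabolites
#'   between their contrasted groups.
#' @param missing_rate overall fraction of left-censored missing cells in the
#'   abundance matrices.
#' @param n_taxa number of taxa in the amplicon count table.
#' @param rng_seed integer seed; all generators are reproducible given it.
#' @return a validated list of class `simulation_config`.
#' @export
simulation_config <- function(n_proteins = 500L,
                              n_planted_modules = 5L,
                              module_size_range = c(15L, 25L),
                              p_in = 0.4,
                              p_out = 0.01,
                              hub_count = 5L,
                              confidence_beta_params = c(1, 3),
                              n_metabolites = 30L,
                              n_discriminant = 20L,
                              links_per_metabolite = c(3L, 8L),
                              group_sizes = c(6L, 3L, 6L, 6L),
                              effect_log2 = 1,
                              missing_rate = 0.3,
                              n_taxa = 120L,
                              rng_seed = 1L) {
  cfg <- list(n_proteins = as.integer(n_proteins),
              n_planted_modules = as.integer(n_planted_modules),
              module_size_range = as.integer(module_size_range),
              p_in = p_in, p_out = p_out,
              hub_count = as.integer(hub_count),
              confidence_beta_params = as.numeric(confidence_beta_params),
              n_metabolites = as.integer(n_metabolites),
              n_discriminant = as.integer(n_discriminant),
              links_per_metabolite = as.integer(links_per_metabolite),
              group_sizes = as.integer(group_sizes),
              effect_log2 = effect_log2,
              missing_rate = missing_rate,
              n_taxa = as.integer(n_taxa),
              rng_seed = as.integer(rng_seed))
  validate_simulation_config(cfg)
  class(cfg) <- "simulation_config"
  cfg
}

validate_simulation_config <- function(cfg) {
  bad <- function(field, why) {
    stop("invalid simulation configuration: field '", field, "' ", why,
         call. = FALSE)
  }
  if (!isTRUE(cfg$n_proteins >= 1)) bad("n_proteins", "must be >= 1")
  if (!isTRUE(cfg$n_planted_modules >= 0)) bad("n_planted_modules", "must be >= 0")
  if (length(cfg$module_size_range) != 2 ||
      any(cfg$module_size_range < 1) ||
      cfg$module_size_range[1] > cfg$module_size_range[2])
    bad("module_size_range", "must be an increasing pair of positive integers")
  if (cfg$module_size_range[2] > cfg$n_proteins)
    bad("module_size_range", "max exceeds n_proteins")
  if (cfg$n_planted_modules * cfg$module_size_range[2] > cfg$n_proteins)
    bad("n_planted_modules", "modules cannot be disjoint within n_proteins")
  for (f in c("p_in", "p_out", "missing_rate")) {
    if (!is.numeric(cfg[[f]]) || cfg[[f]] < 0 || cfg[[f]] > 1)
      bad(f, "must lie in [0, 1]")
  }
  if (length(cfg$confidence_beta_params) != 2 ||
      any(cfg$confidence_beta_params <= 0))
    bad("confidence_beta_params", "must be two positive shape parameters")
  if (!isTRUE(cfg$n_metabolites >= 1)) bad("n_metabolites", "must be >= 1")
  if (cfg$n_discriminant > cfg$n_metabolites)
    bad("n_discriminant", "cannot exceed n_metabolites")
  if (length(cfg$links_per_metabolite) != 2 ||
      any(cfg$links_per_metabolite < 1) ||
      cfg$links_per_metabolite[1] > cfg$links_per_metabolite[2])
    bad("links_per_metabolite", "must be an increasing pair of positive integers")
  if (length(cfg$group_sizes) != 4 || any(cfg$group_sizes < 1))
    bad("group_sizes", "must be four positive integers")
  if (!isTRUE(cfg$effect_log2 >= 0)) bad("effect_log2", "must be >= 0")
  if (!isTRUE(cfg$n_taxa >= 1)) bad("n_taxa", "must be >= 1")
  if (cfg$hub_count < 0) bad("hub_count", "must be >= 0")
  invisible(cfg)
}

protein_ids <- function(n) sprintf("P%04d", seq_len(n))

#' Generate a synthetic interactome with planted modules
#'
#' Planted modules are stochastic-block-model cliques-in-expectation (each
#' within-module pair is an edge with probability `p_in`) embedded in a
#' degree-skewed background in which each of the
#' `round(p_out * n * (n - 1) / 2)` background edges picks its endpoints with
#' probability proportional to current degree + 1 (preferential attachment
#' flavour, so the background carries realistic degree heterogeneity).
#' `hub_count` designated proteins are additionally wired until their degree
#' reaches at least ten times the median degree, emulating promiscuous
#' proteins that a pulldown must prune. Every edge carries a confidence score
#' drawn from `Beta(confidence_beta_params)`.
#'
#' Discriminant metabolites are assigned round-robin to planted modules here
#' so that the ground truth is complete before association-table generation.
#'
#' @param cfg a [simulation_config()].
#' @return a list with elements `graph` (an undirected simple [igraph] graph
#'   whose edges carry a `confidence` attribute) and `truth`, a list with
#'   `modules` (module id -> protein id vector), `hubs`,
#'   `discriminant_metabolites`, `decoy_metabolites`, `metabolite_module`
#'   (discriminant metabolite -> module id) and `metabolite_category`
#'   (Diet or Genotype contrast per discriminant metabolite).
#' @export
generate_interactome <- function(cfg) {
  validate_simulation_config(cfg)
  set.seed(cfg$rng_seed)
  n <- cfg$n_proteins
  ids <- protein_ids(n)

  rng <- cfg$module_size_range
  sizes <- if (cfg$n_planted_modules > 0) {
    if (rng[1] == rng[2]) rep(rng[1], cfg$n_planted_modules)
    else sample(seq(rng[1], rng[2]), cfg$n_planted_modules, replace = TRUE)
  } else integer(0)
  pool <- sample(ids)
  modules <- list()
  off <- 0
  for (k in seq_along(sizes)) {
    modules[[sprintf("mod%02d", k)]] <- sort(pool[(off + 1):(off + sizes[k])])
    off <- off + sizes[k]
  }

  # background: degree-biased edge sampling at expected density p_out
  n_bg <- round(cfg$p_out * n * (n - 1) / 2)
  deg <- rep(0L, n)
  seen <- new.env(hash = TRUE, size = max(16L, 2L * n_bg))
  from <- integer(0); to <- integer(0)
  while (length(from) < n_bg) {
    m <- max(64L, 2L * (n_bg - length(from)))
    a <- sample.int(n, m, replace = TRUE, prob = deg + 1)
    b <- sample.int(n, m, replace = TRUE, prob = deg + 1)
    keep <- a != b
    a <- a[keep]; b <- b[keep]
    lo <- pmin(a, b); hi <- pmax(a, b)
    for (i in seq_along(lo)) {
      key <- paste0(lo[i], "_", hi[i])
      if (is.null(seen[[key]])) {
        assign(key, TRUE, envir = seen)
        from <- c(from, lo[i]); to <- c(to, hi[i])
        deg[lo[i]] <- deg[lo[i]] + 1L; deg[hi[i]] <- deg[hi[i]] + 1L
        if (length(from) >= n_bg) break
      }
    }
  }

  # planted modules: Bernoulli(p_in) per within-module pair
  for (mod in modules) {
    idx <- match(mod, ids)
    if (length(idx) < 2) next
    pairs <- utils::combn(sort(idx), 2)
    draw <- stats::runif(ncol(pairs)) < cfg$p_in
    for (j in which(draw)) {
      key <- paste0(pairs[1, j], "_", pairs[2, j])
      if (is.null(seen[[key]])) {
        assign(key, TRUE, envir = seen)
        from <- c(from, pairs[1, j]); to <- c(to, pairs[2, j])
        deg[pairs[1, j]] <- deg[pairs[1, j]] + 1L
        deg[pairs[2, j]] <- deg[pairs[2, j]] + 1L
      }
    }
  }

  # hubs: non-module proteins wired to >= 10x the median degree
  non_module <- setdiff(seq_len(n), match(unlist(modules), ids))
  hubs <- integer(0)
  if (cfg$hub_count > 0) {
    cand <- if (length(non_module) >= cfg$hub_count) non_module else seq_len(n)
    hubs <- sample(cand, cfg$hub_count)
    # hub wiring raises the median itself, so top up until the guarantee
    # holds against the final degree distribution
    for (round in 1:10) {
      med <- max(1, stats::median(deg))
      target <- min(n - 1L, ceiling(10 * med) + 2L)
      if (all(deg[hubs] >= 10 * med)) break
      for (h in hubs) {
        need <- target - deg[h]
        if (need <= 0) next
        others <- setdiff(seq_len(n), h)
        pick <- sample(others, length(others))
        added <- 0L
        for (b in pick) {
          lo <- min(h, b); hi <- max(h, b)
          key <- paste0(lo, "_", hi)
          if (is.null(seen[[key]])) {
            assign(key, TRUE, envir = seen)
            from <- c(from, lo); to <- c(to, hi)
            deg[lo] <- deg[lo] + 1L; deg[hi] <- deg[hi] + 1L
            added <- added + 1L
            if (added >= need) break
          }
        }
      }
    }
  }

  conf <- stats::rbeta(length(from), cfg$confidence_beta_params[1],
                       cfg$confidence_beta_params[2])
  edges <- data.frame(from = ids[from], to = ids[to],
                      confidence = conf, stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(
    edges, directed = FALSE,
    vertices = data.frame(name = ids, stringsAsFactors = FALSE))

  mets_disc <- sprintf("met_d%02d", seq_len(cfg$n_discriminant))
  mets_decoy <- if (cfg$n_metabolites > cfg$n_discriminant)
    sprintf("met_x%02d", seq_len(cfg$n_metabolites - cfg$n_discriminant))
  else character(0)
  met_mod <- if (length(modules) > 0 && length(mets_disc) > 0)
    stats::setNames(names(modules)[(seq_along(mets_disc) - 1) %%
                                     length(modules) + 1], mets_disc)
  else stats::setNames(character(0), character(0))
  met_cat <- stats::setNames(
    rep(c("Diet", "Genotype"), length.out = length(mets_disc)), mets_disc)

  truth <- list(modules = modules,
                hubs = ids[hubs],
                discriminant_metabolites = mets_disc,
                decoy_metabolites = mets_decoy,
                metabolite_module = met_mod,
                metabolite_category = met_cat)
  list(graph = g, truth = truth)
}

#' Generate a synthetic metabolite-protein association table
#'
#' Discriminant metabolites draw `in_module_fraction` of their protein links
#' from their assigned planted module and the rest from the remaining
#' proteins; decoy metabolites link to proteins uniformly at random. Each
#' metabolite carries a synonym and a mock structural key, and every link is
#' classified as a physical or functional association; an extra
#' `text_mining_fraction` of links is appended with the `text-mining` class so
#' that downstream evidence filtering is exercised.
#'
#' @param truth ground truth from [generate_interactome()].
#' @param cfg the same [simulation_config()].
#' @param in_module_fraction fraction of a discriminant metabolite's links
#'   drawn from its planted module.
#' @param text_mining_fraction extra text-mining rows appended, as a fraction
#'   of the supported rows.
#' @return an [association_table()] data frame.
#' @export
generate_associations <- function(truth, cfg, in_module_fraction = 0.8,
                                  text_mining_fraction = 0.1) {
  validate_simulation_config(cfg)
  set.seed(cfg$rng_seed + 1L)
  ids <- protein_ids(cfg$n_proteins)
  mets <- c(truth$discriminant_metabolites, truth$decoy_metabolites)
  rows <- list()
  for (i in seq_along(mets)) {
    m <- mets[i]
    n_links <- if (cfg$links_per_metabolite[1] == cfg$links_per_metabolite[2])
      cfg$links_per_metabolite[1]
    else sample(seq(cfg$links_per_metabolite[1], cfg$links_per_metabolite[2]), 1)
    mod <- unname(truth$metabolite_module[m])
    if (length(mod) == 1 && !is.na(mod)) {
      members <- truth$modules[[mod]]
      n_in <- min(length(members), round(in_module_fraction * n_links))
      inside <- sample(members, n_in)
      outside <- sample(setdiff(ids, members), n_links - n_in)
      prots <- c(inside, outside)
    } else {
      prots <- sample(ids, n_links)
    }
    rows[[i]] <- data.frame(
      metabolite_id = m,
      synonyms = paste(paste0(m, "_syn1"), toupper(m), sep = ";"),
      structural_key = sprintf("IKEY%04d", i),
      protein_id = prots,
      association_class = sample(c("physical", "functional"),
                                 length(prots), replace = TRUE),
      source = sample(c("uniprot", "pubchem", "hmdb", "chembl", "stitch"),
                      length(prots), replace = TRUE),
      stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, rows)
  n_tm <- round(text_mining_fraction * nrow(tab))
  if (n_tm > 0) {
    pick <- sample(seq_along(mets), n_tm, replace = TRUE)
    tm <- data.frame(
      metabolite_id = mets[pick],
      synonyms = paste(paste0(mets[pick], "_syn1"), toupper(mets[pick]), sep = ";"),
      structural_key = sprintf("IKEY%04d", pick),
      protein_id = sample(ids, n_tm, replace = TRUE),
      association_class = "text-mining",
      source = "text-mining",
      stringsAsFactors = FALSE)
    tab <- rbind(tab, tm)
  }
  rownames(tab) <- NULL
  association_table(tab)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generate four-group metabolite abundance tables
#'
#' Intensities are lognormal around metabolite-specific baselines.
#' Discriminant metabolites are shifted by `effect_log2 * log(2)` on the
#' natural-log scale between their contrasted groups (Diet metabolites:
#' high-fat vs control diet; Genotype metabolites: transgenic vs wild type).
#' Missingness is left-censored: within each metabolite the cells below that
#' metabolite's missingness quantile are set to `NA`, emulating
#' limit-of-detection dropout, with a configurable fraction of metabolites
#' given elevated missingness so the 30% missingness filter is exercised.
#'
#' @param cfg a [simulation_config()].
#' @param truth ground truth from [generate_interactome()].
#' @param high_missing_fraction fraction of metabolites whose missingness is
#'   raised to `high_missing_rate`.
#' @param high_missing_rate per-metabolite missingness for that fraction.
#' @return list with two [metabolite_table()] blocks, `plasma` and `feces`.
#' @export
generate_abundance <- function(cfg, truth = NULL,
                               high_missing_fraction = 0.15,
                               high_missing_rate = 0.5) {
  validate_simulation_config(cfg)
  set.seed(cfg$rng_seed + 2L)
  groups <- c("WT-CD", "WT-HFD", "Tg-CD", "Tg-HFD")
  group <- rep(groups, times = cfg$group_sizes)
  n_s <- length(group)
  samples <- sprintf("S%02d", seq_len(n_s))
  genotype <- ifelse(grepl("^WT", group), "WT", "Tg")
  diet <- ifelse(grepl("CD$", group), "CD", "HFD")
  meta <- data.frame(sample_id = samples, genotype = genotype, diet = diet,
                     group = group,
                     volume = stats::runif(n_s, 0.8, 1.2),
                     stringsAsFactors = FALSE)
  mets <- if (!is.null(truth))
    c(truth$discriminant_metabolites, truth$decoy_metabolites)
  else sprintf("met_%02d", seq_len(cfg$n_metabolites))
  disc <- if (!is.null(truth)) truth$discriminant_metabolites else character(0)
  cat_of <- if (!is.null(truth)) truth$metabolite_category else
    stats::setNames(character(0), character(0))

  make_block <- function(block) {
    mu <- stats::rnorm(length(mets), mean = 10, sd = 1)
    logx <- matrix(stats::rnorm(n_s * length(mets), sd = 0.5),
                   nrow = n_s, dimnames = list(samples, mets))
    logx <- sweep(logx, 2, mu, "+")
    for (m in disc) {
      shift <- cfg$effect_log2 * log(2)
      up <- if (identical(unname(cat_of[m]), "Genotype")) genotype == "Tg"
      else diet == "HFD"
      logx[up, m] <- logx[up, m] + shift
    }
    x <- exp(logx)
    if (cfg$missing_rate > 0) {
      n_high <- round(high_missing_fraction * length(mets))
      high_cols <- if (n_high > 0) sample(seq_along(mets), n_high) else integer(0)
      base_rate <- max(0, (cfg$missing_rate -
                             high_missing_fraction * high_missing_rate) /
                         max(1e-12, 1 - high_missing_fraction))
      for (j in seq_along(mets)) {
        r <- if (j %in% high_cols) high_missing_rate else base_rate
        if (r <= 0) next
        thr <- stats::quantile(x[, j], r, names = FALSE)
        x[x[, j] < thr, j] <- NA_real_
      }
    }
    metabolite_table(x, metadata = meta, block = block)
  }
  list(plasma = make_block("plasma"), feces = make_block("feces"))
}

#' Generate Dirichlet-multinomial amplicon counts
#'
#' Each sample's composition is drawn from a Dirichlet distribution around a
#' common lognormal base composition (`overdispersion` is the Dirichlet
#' concentration: smaller means more sample-to-sample variation), and counts
#' are multinomial at fixed `depth`, so every row sums exactly to `depth`.
#'
#' @param cfg a [simulation_config()].
#' @param depth sequencing depth per sample.
#' @param overdispersion Dirichlet concentration parameter.
#' @return an [asv_table()].
#' @export
generate_asv_counts <- function(cfg, depth = 10000L, overdispersion = 50) {
  validate_simulation_config(cfg)
  set.seed(cfg$rng_seed + 3L)
  n_s <- sum(cfg$group_sizes)
  samples <- sprintf("S%02d", seq_len(n_s))
  taxa <- sprintf("ASV%03d", seq_len(cfg$n_taxa))
  base <- exp(stats::rnorm(cfg$n_taxa, sd = 1.5))
  base <- base / sum(base)
  counts <- matrix(0L, nrow = n_s, ncol = cfg$n_taxa,
                   dimnames = list(samples, taxa))
  for (i in seq_len(n_s)) {
    gam <- stats::rgamma(cfg$n_taxa, shape = base * overdispersion, rate = 1)
    if (sum(gam) == 0) gam <- base
    p <- gam / sum(gam)
    counts[i, ] <- as.integer(stats::rmultinom(1, depth, p))
  }
  asv_table(counts)
}

#' Generate gene sets from planted modules
#'
#' One gene set per planted module, corrupted by swapping
#' `round(noise_fraction * size)` members for random proteins outside the
#' module (class label `AD-related`), plus `n_decoy_sets` random sets of
#' comparable size (class label `annotation`).
#'
#' @param truth ground truth from [generate_interactome()].
#' @param cfg a [simulation_config()].
#' @param noise_fraction fraction of members swapped out of each planted set.
#' @param n_decoy_sets number of random decoy sets.
#' @return a [gene_set_collection()].
#' @export
generate_gene_sets <- function(truth, cfg, noise_fraction = 0.1,
                               n_decoy_sets = 5L) {
  validate_simulation_config(cfg)
  set.seed(cfg$rng_seed + 4L)
  ids <- protein_ids(cfg$n_proteins)
  sets <- list(); cls <- character(0)
  for (k in seq_along(truth$modules)) {
    members <- truth$modules[[k]]
    n_swap <- round(noise_fraction * length(members))
    if (n_swap > 0) {
      out <- sample(members, n_swap)
      repl <- sample(setdiff(ids, members), n_swap)
      members <- sort(c(setdiff(members, out), repl))
    }
    nm <- paste0("AD_", names(truth$modules)[k])
    sets[[nm]] <- members
    cls <- c(cls, "AD-related")
  }
  size_ref <- if (length(truth$modules) > 0)
    round(mean(lengths(truth$modules))) else 20L
  for (d in seq_len(n_decoy_sets)) {
    nm <- sprintf("ann_random%02d", d)
    sets[[nm]] <- sort(sample(ids, size_ref))
    cls <- c(cls, "annotation")
  }
  gene_set_collection(sets, class = cls)
}

#' Write an interactome as a three-column edge-list TSV
#'
#' Columns `protein_a`, `protein_b`, `confidence`.
#'
#' @param g an igraph interactome with a `confidence` edge attribute.
#' @param path output file.
#' @export
write_interactome <- function(g, path) {
  el <- igraph::as_edgelist(g)
  df <- data.frame(protein_a = el[, 1], protein_b = el[, 2],
                   confidence = igraph::E(g)$confidence,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an interactome from a three-column edge-list TSV
#'
#' @param path TSV with columns `protein_a`, `protein_b`, `confidence`.
#' @return an undirected igraph graph with a `confidence` edge attribute.
#' @export
read_interactome <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("protein_a", "protein_b", "confidence") %in% names(df)))
  igraph::graph_from_data_frame(
    data.frame(from = df$protein_a, to = df$protein_b,
               confidence = as.numeric(df$confidence)),
    directed = FALSE)
}

#' Write ground truth as a JSON sidecar
#' @param truth ground-truth list from [generate_interactome()].
#' @param path output file.
#' @export
write_ground_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = FALSE, pretty = TRUE)
  invisible(path)
}
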