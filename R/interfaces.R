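#' Pipeline configuration
#'
#' Every tunable of the end-to-end pipeline, with the published settings as
#' defaults: confidence filter 0.1, 200-node cap, 75% overlap merge,
#' q-value threshold 0.05, at least 3 linked metabolites for exploratory
#' modules, top 20 annotations, significance ceiling 0.01 and enrichment
#' floor 1.5.
#'
#' @param min_confidence interactome confidence filter.
#' @param degree_percentile,inside_fraction_min over-connected pruning rule.
#' @param max_nodes,exemption_q module size cap and exemption q-value.
#' @param overlap_min,overlap_metric merge threshold and metric
#'   (`"containment"` or `"jaccard"`).
#' @param whitelist list of module-id pairs exempt from merging.
#' @param bh_family BH family scope (`"per-class"` or `"global"`).
#' @param background background universe choice (`"interactome"`,
#'   `"union-of-networks"`, or a character vector of protein ids).
#' @param q_max enrichment significance threshold.
#' @param min_metabolites minimum linked metabolites for the exploratory set.
#' @param top_k annotation shortlist size.
#' @param p_max,es_min annotation prioritization thresholds.
#' @param max_missing metabolite missingness filter.
#' @param prevalence_min taxa prevalence filter.
#' @param outlier_components,outlier_quantile multivariate outlier rule.
#' @param sim a [simulation_config()] used when running synthetically.
#' @param rng_seed seed forwarded to the synthetic generators.
#' @return a named list of class `pipeline_config`.
#' @export
pipeline_config <- function(min_confidence = 0.1,
                            degree_percentile = 0.99,
                            inside_fraction_min = 0.10,
                            max_nodes = 200,
                            exemption_q = 1e-4,
                            overlap_min = 0.75,
                            overlap_metric = "containment",
                            whitelist = NULL,
                            bh_family = "per-class",
                            background = "interactome",
                            q_max = 0.05,
                            min_metabolites = 3,
                            top_k = 20,
                            p_max = 0.01,
                            es_min = 1.5,
                            max_missing = 0.30,
                            prevalence_min = 0.10,
                            outlier_components = 2,
                            outlier_quantile = 0.99,
                            sim = NULL,
                            rng_seed = 1L) {
  cfg <- as.list(environment())
  if (is.null(cfg$sim)) cfg$sim <- simulation_config(rng_seed = rng_seed)
  class(cfg) <- "pipeline_config"
  cfg
}

config_for_json <- function(config) {
  cfg <- unclass(config)
  cfg$sim <- unclass(cfg$sim)
  cfg$whitelist <- if (is.null(cfg$whitelist)) list() else cfg$whitelist
  cfg
}

#' Run the full pipeline end to end
#'
#' With `synthetic = TRUE`, generates all inputs from `config$sim`
#' (interactome with planted modules, association table, gene sets,
#' abundance and amplicon tables), runs the QC stage, resolves metabolites
#' to seed proteins, performs the virtual pulldown, enrichment,
#' classification and summarization, and writes every artifact plus a
#' machine-readable run manifest to `out_dir`. With real inputs, pass file
#' paths through `inputs` (elements `interactome`, `associations`,
#' `queries`, `gene_sets`; optional `abundance`, `asv`).
#'
#' @param config a [pipeline_config()].
#' @param inputs named list of file paths (ignored when `synthetic = TRUE`).
#' @param synthetic generate inputs from `config$sim`.
#' @param out_dir output directory, created if needed.
#' @return invisibly, a list with the pipeline objects (`modules`,
#'   `enrichment`, `classification`, `tables`, `manifest`, ...).
#' @export
run_all <- function(config = pipeline_config(), inputs = list(),
                    synthetic = FALSE, out_dir = tempfile("metapull_run_")) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  qc_report <- character(0)

  if (synthetic) {
    sim <- generate_interactome(config$sim)
    g <- sim$graph
    truth <- sim$truth
    assoc <- generate_associations(truth, config$sim)
    queries <- c(truth$discriminant_metabolites, truth$decoy_metabolites)
    gsets <- generate_gene_sets(truth, config$sim)
    abundance <- generate_abundance(config$sim, truth)
    asv <- generate_asv_counts(config$sim)
  } else {
    for (need in c("interactome", "associations", "queries", "gene_sets")) {
      if (is.null(inputs[[need]]))
        stop("missing input '", need,
             "'; supply a path or use synthetic = TRUE", call. = FALSE)
    }
    g <- read_interactome(inputs$interactome)
    assoc <- read_association_table(inputs$associations)
    queries <- readLines(inputs$queries, warn = FALSE)
    queries <- queries[nzchar(queries)]
    gsets <- read_gmt(inputs$gene_sets)
    truth <- NULL
    abundance <- if (!is.null(inputs$abundance))
      list(plasma = read_feature_table(inputs$abundance, block = "plasma"))
    asv <- if (!is.null(inputs$asv)) {
      raw <- utils::read.delim(inputs$asv, row.names = 1, check.names = FALSE)
      asv_table(as.matrix(raw))
    }
  }

  # QC stage
  if (!is.null(abundance)) {
    abundance <- lapply(abundance, function(b) {
      before <- ncol(b$values)
      b <- qc_metabolites(b, max_missing = config$max_missing)
      qc_report <<- c(qc_report,
                      sprintf("[%s] metabolites: %d -> %d", b$block, before,
                              ncol(b$values)),
                      paste0("  ", b$qc_log))
      b
    })
    outliers <- unique(unlist(lapply(abundance, function(b)
      as.character(detect_outliers(b$values,
                                   n_components = config$outlier_components,
                                   quantile = config$outlier_quantile)))))
    qc_report <- c(qc_report,
                   sprintf("outlier samples flagged (union over blocks): %s",
                           if (length(outliers))
                             paste(outliers, collapse = ", ") else "none"))
    abundance <- lapply(abundance, function(b) {
      b$values <- b$values[setdiff(rownames(b$values), outliers), ,
                           drop = FALSE]
      b
    })
  }
  if (!is.null(asv)) {
    before <- ncol(asv$counts)
    asv <- filter_asvs(asv, prevalence_min = config$prevalence_min)
    clr <- clr_transform(asv)
    qc_report <- c(qc_report,
                   sprintf("[asv] taxa: %d -> %d (prevalence/median filter), CLR applied",
                           before, ncol(asv$counts)))
  } else clr <- NULL

  # seed mapping
  seed_map <- resolve_metabolites(queries, assoc)
  stats <- association_stats(seed_map)

  # pulldown
  params <- pulldown_params(min_confidence = config$min_confidence,
                            degree_percentile = config$degree_percentile,
                            inside_fraction_min = config$inside_fraction_min,
                            max_nodes = config$max_nodes,
                            exemption_q = config$exemption_q,
                            overlap_min = config$overlap_min,
                            overlap_metric = config$overlap_metric,
                            whitelist = config$whitelist)
  modules <- run_pulldown(g, seed_map, params)
  run_log <- attr(modules, "run_log")
  gf <- attr(modules, "graph")

  # enrichment: user/synthetic gene sets plus the seed-protein set
  seed_set <- gene_set_collection(
    list(seed_proteins = seed_map$seed_proteins), "seed-proteins")
  all_sets <- combine_gene_sets(gsets, seed_set)
  background <- if (identical(config$background, "interactome"))
    igraph::V(gf)$name
  else if (identical(config$background, "union-of-networks"))
    sort(unique(unlist(lapply(modules, `[[`, "nodes"))))
  else config$background
  enrichment <- enrich_collection(modules, all_sets, background,
                                  family = config$bh_family)
  classification <- classify_networks(
    modules, enrichment, ad_classes = "AD-related",
    seed_set_name = "seed_proteins", q_max = config$q_max,
    min_metabolites = config$min_metabolites)

  tbl_all <- module_table(modules, enrichment)
  tbl_set2 <- module_table(modules, enrichment, ids = classification$set2)
  top_ids <- utils::head(tbl_set2$network_id, config$top_k)
  summaries <- if (length(top_ids) > 0 &&
                   any(enrichment$network_id %in% top_ids))
    aggregate_annotations(enrichment, top_ids, q_max = config$q_max)
  else NULL
  top_annotations <- if (!is.null(summaries))
    select_top_annotations(summaries, top_k = config$top_k,
                           p_max = config$p_max, es_min = config$es_min)
  else NULL
  representation <- if (nrow(tbl_set2) > 0)
    metabolite_representation(tbl_set2) else integer(0)

  # write artifacts
  write_seed_map(seed_map, file.path(out_dir, "seed_map.tsv"))
  write_xgmml(modules, file.path(out_dir, "collection.xgmml"))
  utils::write.table(enrichment, file.path(out_dir, "enrichment.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_module_summary(tbl_all, file.path(out_dir, "modules_all.tsv"))
  write_module_summary(tbl_set2, file.path(out_dir, "modules_exploratory.tsv"))
  if (!is.null(summaries))
    utils::write.table(summaries, file.path(out_dir, "annotation_summary.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(qc_report, file.path(out_dir, "qc_report.txt"))

  cfg_json <- config_for_json(config)
  manifest <- list(
    package = "metapull",
    version = as.character(utils::packageVersion("metapull")),
    config = cfg_json,
    config_hash = sum(utf8ToInt(jsonlite::toJSON(cfg_json,
                                                 auto_unbox = TRUE))),
    stage_counts = list(
      interactome_nodes = igraph::vcount(g),
      interactome_edges = igraph::ecount(g),
      filtered_nodes = igraph::vcount(gf),
      filtered_edges = igraph::ecount(gf),
      mapped_metabolites = unname(stats["n_mapped_metabolites"]),
      seed_proteins = unname(stats["n_unique_proteins"]),
      metabolite_protein_pairs = unname(stats["n_pairs"]),
      seeds_in_graph = run_log$seeds_in_graph,
      networks_extracted = run_log$extracted,
      networks_final = run_log$after_merge,
      set1 = length(classification$set1),
      set2 = length(classification$set2)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  invisible(list(out_dir = out_dir, modules = modules, graph = gf,
                 seed_map = seed_map, enrichment = enrichment,
                 classification = classification,
                 tables = list(all = tbl_all, exploratory = tbl_set2),
                 summaries = summaries, top_annotations = top_annotations,
                 representation = representation,
                 abundance = abundance, clr = clr,
                 truth = if (synthetic) truth else NULL,
                 manifest = manifest))
}
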