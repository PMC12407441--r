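#' Network module container
#'
#' A module is an induced subgraph of the confidence-filtered interactome:
#' a node set, the induced edges, the seed proteins it grew from, the
#' metabolites linked to its proteins, and merge provenance.
#'
#' @param network_id module identifier.
#' @param nodes character vector of protein ids.
#' @param edges data frame `from`, `to`, `confidence` (induced edges).
#' @param seeds seed proteins, a subset of `nodes`.
#' @param linked_metabolites metabolite ids whose seed sets intersect the
#'   module.
#' @param merged_from ancestor module ids.
#' @param cap_exempt whether the module was exempted from the size cap.
#' @return an object of class `network_module`.
#' @export
network_module <- function(network_id, nodes, edges = NULL,
                           seeds = character(0),
                           linked_metabolites = character(0),
                           merged_from = character(0),
                           cap_exempt = FALSE) {
  nodes <- unique(as.character(nodes))
  seeds <- intersect(unique(as.character(seeds)), nodes)
  if (is.null(edges))
    edges <- data.frame(from = character(0), to = character(0),
                        confidence = numeric(0), stringsAsFactors = FALSE)
  structure(list(network_id = network_id, nodes = nodes, edges = edges,
                 seeds = seeds,
                 linked_metabolites = unique(as.character(linked_metabolites)),
                 merged_from = merged_from, cap_exempt = isTRUE(cap_exempt)),
            class = "network_module")
}

#' @export
print.network_module <- function(x, ...) {
  cat(sprintf("network_module %s: %d nodes, %d edges, %d seed(s), %d metabolite(s)%s\n",
              x$network_id, length(x$nodes), nrow(x$edges), length(x$seeds),
              length(x$linked_metabolites),
              if (x$cap_exempt) " [cap exempt]" else ""))
  invisible(x)
}

induced_edges <- function(g, nodes) {
  nodes <- intersect(nodes, igraph::V(g)$name)
  sg <- igraph::induced_subgraph(g, nodes)
  el <- igraph::as_edgelist(sg)
  data.frame(from = el[, 1], to = el[, 2],
             confidence = if (igraph::ecount(sg)) igraph::E(sg)$confidence
             else numeric(0),
             stringsAsFactors = FALSE)
}

reinduce <- function(m, g) {
  m$edges <- induced_edges(g, m$nodes)
  m
}

#' Filter an interactome by edge confidence
#'
#' Retains edges with confidence at or above `min_confidence` and drops
#' nodes left without any edge. Removal counts are attached as graph
#' attributes `removed_edges` and `removed_nodes`.
#'
#' @param g an igraph interactome with a `confidence` edge attribute.
#' @param min_confidence threshold in \[0, 1\] (default 0.1).
#' @return the filtered graph.
#' @export
filter_interactome <- function(g, min_confidence = 0.1) {
  if (!is.numeric(min_confidence) || min_confidence < 0 || min_confidence > 1)
    stop("min_confidence must lie in [0, 1]", call. = FALSE)
  conf <- igraph::E(g)$confidence
  if (is.null(conf)) stop("interactome edges lack a 'confidence' attribute",
                          call. = FALSE)
  keep <- which(conf >= min_confidence)
  gf <- igraph::subgraph_from_edges(g, keep, delete.vertices = FALSE)
  iso <- which(igraph::degree(gf) == 0)
  gf <- igraph::delete_vertices(gf, iso)
  gf <- igraph::set_graph_attr(gf, "removed_edges",
                               igraph::ecount(g) - length(keep))
  igraph::set_graph_attr(gf, "removed_nodes", length(iso))
}

#' First-order pulldown around a seed protein
#'
#' The virtual pulldown of a seed: the seed plus its direct interaction
#' partners in the filtered interactome. With `mode = "induced"` (default)
#' all edges among those nodes are kept, including neighbor-neighbor edges;
#' with `mode = "star"` only seed-incident edges are kept.
#'
#' @param g the confidence-filtered interactome.
#' @param seed a protein id. A seed absent from the interactome yields an
#'   empty module with a warning.
#' @param mode `"induced"` or `"star"`.
#' @return a [network_module()] with `seeds = seed`.
#' @export
first_order_network <- function(g, seed, mode = c("induced", "star")) {
  mode <- match.arg(mode)
  if (!seed %in% igraph::V(g)$name) {
    warning("seed protein '", seed, "' absent from the interactome",
            call. = FALSE)
    return(network_module(paste0("net_", seed), character(0)))
  }
  nb <- igraph::neighbors(g, seed)$name
  nodes <- unique(c(seed, nb))
  edges <- induced_edges(g, nodes)
  if (mode == "star")
    edges <- edges[edges$from == seed | edges$to == seed, , drop = FALSE]
  network_module(paste0("net_", seed), nodes, edges, seeds = seed)
}

#' Prune over-connected nodes from a module
#'
#' Removes non-seed nodes that are both globally promiscuous (global degree
#' above the `degree_percentile` quantile of the interactome degree
#' distribution) and weakly engaged in the module (within-module degree
#' divided by global degree below `inside_fraction_min`). Edges are
#' re-induced after removal; seed proteins are never removed.
#'
#' @param m a [network_module()].
#' @param g the filtered interactome the module was built from.
#' @param degree_percentile quantile defining "over-connected" (default 0.99).
#' @param inside_fraction_min minimum within-module engagement (default 0.10).
#' @return the pruned module.
#' @export
prune_overconnected <- function(m, g, degree_percentile = 0.99,
                                inside_fraction_min = 0.10) {
  stopifnot(inherits(m, "network_module"))
  if (length(m$nodes) == 0) return(m)
  deg_all <- igraph::degree(g)
  thr <- stats::quantile(deg_all, degree_percentile, names = FALSE)
  sg <- igraph::induced_subgraph(g, intersect(m$nodes, names(deg_all)))
  deg_in <- igraph::degree(sg)
  drop <- vapply(m$nodes, function(v) {
    if (v %in% m$seeds) return(FALSE)
    gd <- deg_all[[v]]
    if (is.null(gd) || is.na(gd)) return(FALSE)
    inside <- if (v %in% names(deg_in)) deg_in[[v]] else 0
    gd > thr && (inside / gd) < inside_fraction_min
  }, logical(1))
  m$nodes <- m$nodes[!drop]
  reinduce(m, g)
}

#' Cap a module at a maximum size
#'
#' Modules larger than `max_nodes` are reduced to the seed proteins plus the
#' neighbors ranked by descending maximum edge confidence to any seed, ties
#' broken by ascending protein id. A module whose pre-cap seed-protein
#' enrichment q-value is at or below `exemption_q` is exempted and kept
#' whole (`cap_exempt` flag set).
#'
#' @param m a [network_module()].
#' @param g the filtered interactome.
#' @param max_nodes size cap (default 200).
#' @param exemption_q q-value at or below which a module escapes the cap.
#' @param seed_q optional pre-cap seed-enrichment q-value for the module.
#' @return the capped (or exempted) module.
#' @export
cap_network <- function(m, g, max_nodes = 200, exemption_q = 1e-4,
                        seed_q = NULL) {
  stopifnot(inherits(m, "network_module"))
  if (length(m$nodes) <= max_nodes) return(m)
  if (!is.null(seed_q) && is.finite(seed_q) && seed_q <= exemption_q) {
    m$cap_exempt <- TRUE
    return(m)
  }
  others <- setdiff(m$nodes, m$seeds)
  seed_edges <- m$edges[m$edges$from %in% m$seeds | m$edges$to %in% m$seeds, ,
                        drop = FALSE]
  best <- stats::setNames(rep(-Inf, length(others)), others)
  if (nrow(seed_edges)) {
    partner <- ifelse(seed_edges$from %in% m$seeds, seed_edges$to,
                      seed_edges$from)
    for (i in seq_along(partner)) {
      p <- partner[i]
      if (p %in% others && seed_edges$confidence[i] > best[[p]])
        best[[p]] <- seed_edges$confidence[i]
    }
  }
  ord <- others[order(-best[others], others)]
  keep_n <- max(0, max_nodes - length(m$seeds))
  m$nodes <- c(m$seeds, utils::head(ord, keep_n))
  reinduce(m, g)
}

module_overlap <- function(a, b, metric = "containment") {
  inter <- length(intersect(a, b))
  if (inter == 0) return(0)
  if (metric == "containment") inter / min(length(a), length(b))
  else inter / length(union(a, b))
}

#' Pairwise overlap matrix of a module collection
#'
#' @param modules list of [network_module()]s.
#' @param metric `"containment"` (intersection over the smaller node set,
#'   default) or `"jaccard"`.
#' @return symmetric matrix of overlaps with module ids as dimnames.
#' @export
overlap_matrix <- function(modules, metric = c("containment", "jaccard")) {
  metric <- match.arg(metric)
  ids <- vapply(modules, `[[`, character(1), "network_id")
  all_nodes <- sort(unique(unlist(lapply(modules, `[[`, "nodes"))))
  k <- length(modules)
  if (k == 0 || length(all_nodes) == 0)
    return(matrix(0, k, k, dimnames = list(ids, ids)))
  M <- Matrix::sparseMatrix(
    i = unlist(lapply(modules, function(m) match(m$nodes, all_nodes))),
    j = rep(seq_len(k), vapply(modules, function(m) length(m$nodes), 1L)),
    x = 1, dims = c(length(all_nodes), k))
  inter <- as.matrix(Matrix::crossprod(M))
  sizes <- vapply(modules, function(m) length(m$nodes), 1L)
  denom <- if (metric == "containment") outer(sizes, sizes, pmin)
  else outer(sizes, sizes, `+`) - inter
  ov <- ifelse(denom > 0, inter / denom, 0)
  diag(ov) <- 0
  dimnames(ov) <- list(ids, ids)
  ov
}

pair_key <- function(a, b) paste(sort(c(a, b)), collapse = "\r")

#' Merge modules with substantial overlap
#'
#' Overlap between two modules is the intersection size divided by the
#' smaller node set (containment, default) or the Jaccard index. The pair
#' with the highest overlap strictly above `overlap_min` is merged first
#' (ties broken by lexicographic id), the merged module re-induced from the
#' interactome, and the process repeated to a fixpoint. Whitelisted pairs are
#' never merged, allowing overlapping modules of distinct origin to coexist.
#'
#' @param modules list of [network_module()]s built from the same filtered
#'   interactome.
#' @param g the filtered interactome (for edge re-induction).
#' @param overlap_min merge threshold; merging requires overlap strictly
#'   greater than this value (default 0.75).
#' @param metric `"containment"` or `"jaccard"`.
#' @param whitelist list of length-2 character vectors of module ids that
#'   must not be merged with each other.
#' @return the merged module list; each merged module keeps the id of its
#'   largest constituent (ties: lexicographically smaller id) and records all
#'   ancestor ids in `merged_from`.
#' @export
merge_overlapping <- function(modules, g, overlap_min = 0.75,
                              metric = c("containment", "jaccard"),
                              whitelist = NULL) {
  metric <- match.arg(metric)
  if (length(modules) < 2) return(modules)
  wl <- character(0)
  if (!is.null(whitelist))
    wl <- vapply(whitelist, function(p) pair_key(p[1], p[2]), character(1))
  mods <- modules
  repeat {
    ov <- overlap_matrix(mods, metric)
    ids <- rownames(ov)
    if (length(wl)) {
      for (i in seq_along(ids)) for (j in seq_along(ids)) {
        if (i < j && pair_key(ids[i], ids[j]) %in% wl) {
          ov[i, j] <- 0; ov[j, i] <- 0
        }
      }
    }
    ov[lower.tri(ov, diag = TRUE)] <- 0
    cand <- which(ov > overlap_min, arr.ind = TRUE)
    if (nrow(cand) == 0) break
    vals <- ov[cand]
    best <- cand[vals == max(vals), , drop = FALSE]
    if (nrow(best) > 1) {
      keys <- apply(best, 1, function(rc) pair_key(ids[rc[1]], ids[rc[2]]))
      best <- best[order(keys)[1], , drop = FALSE]
    }
    i <- best[1, 1]; j <- best[1, 2]
    a <- mods[[i]]; b <- mods[[j]]
    lead <- if (length(a$nodes) > length(b$nodes)) a
    else if (length(b$nodes) > length(a$nodes)) b
    else if (a$network_id <= b$network_id) a else b
    merged <- network_module(
      network_id = lead$network_id,
      nodes = union(a$nodes, b$nodes),
      seeds = union(a$seeds, b$seeds),
      linked_metabolites = union(a$linked_metabolites, b$linked_metabolites),
      merged_from = sort(unique(c(a$merged_from %||% character(0),
                                  b$merged_from %||% character(0),
                                  a$network_id, b$network_id))),
      cap_exempt = a$cap_exempt || b$cap_exempt)
    merged <- reinduce(merged, g)
    mods[[i]] <- merged
    mods[[j]] <- NULL
  }
  mods
}

#' Attach linked metabolites to a module
#'
#' A metabolite is linked to a module when its seed-protein set intersects
#' the module's node set; the count of linked metabolites is the
#' "metabolites linked" statistic of the module tables.
#'
#' @param m a [network_module()].
#' @param seed_map a [resolve_metabolites()] result.
#' @return the module with `linked_metabolites` filled in.
#' @export
annotate_metabolites <- function(m, seed_map) {
  stopifnot(inherits(m, "network_module"), inherits(seed_map, "seed_map"))
  linked <- names(seed_map$map)[vapply(seed_map$map, function(p)
    length(intersect(p, m$nodes)) > 0, logical(1))]
  m$linked_metabolites <- sort(linked)
  m
}

#' Default pulldown parameters
#'
#' Defaults follow the published pipeline settings: confidence filter 0.1,
#' over-connected pruning at the 99th degree percentile with 10% minimum
#' inside fraction, 200-node cap with enrichment-based exemption, and
#' merging above 75% containment overlap.
#'
#' @param min_confidence edge-confidence filter threshold.
#' @param degree_percentile,inside_fraction_min pruning rule knobs.
#' @param max_nodes,exemption_q cap size and exemption q-value.
#' @param overlap_min,overlap_metric merge threshold and metric.
#' @param whitelist list of id pairs never merged.
#' @param mode neighborhood mode, `"induced"` or `"star"`.
#' @return a named list of parameters.
#' @export
pulldown_params <- function(min_confidence = 0.1, degree_percentile = 0.99,
                            inside_fraction_min = 0.10, max_nodes = 200,
                            exemption_q = 1e-4, overlap_min = 0.75,
                            overlap_metric = "containment",
                            whitelist = NULL, mode = "induced") {
  list(min_confidence = min_confidence,
       degree_percentile = degree_percentile,
       inside_fraction_min = inside_fraction_min,
       max_nodes = max_nodes, exemption_q = exemption_q,
       overlap_min = overlap_min, overlap_metric = overlap_metric,
       whitelist = whitelist, mode = mode)
}

#' Run the whole virtual-pulldown pipeline
#'
#' Orchestrates: confidence filtering, per-seed first-order extraction,
#' over-connected pruning, pre-cap seed-enrichment computation, size capping
#' with exemptions, overlap merging and metabolite annotation. The pipeline
#' is fully deterministic given its inputs.
#'
#' @param g an igraph interactome with a `confidence` edge attribute.
#' @param seed_map a [resolve_metabolites()] result.
#' @param params a [pulldown_params()] list.
#' @return list of [network_module()]s with a `run_log` attribute recording
#'   stage counts (`seeds`, `seeds_in_graph`, `extracted`, `after_merge`,
#'   `filtered_edges_removed`, ...).
#' @export
run_pulldown <- function(g, seed_map, params = pulldown_params()) {
  stopifnot(inherits(seed_map, "seed_map"))
  gf <- filter_interactome(g, params$min_confidence)
  seeds <- seed_map$seed_proteins
  present <- intersect(seeds, igraph::V(gf)$name)
  if (length(present) < length(seeds))
    warning(length(seeds) - length(present),
            " seed protein(s) absent from the filtered interactome",
            call. = FALSE)
  log <- list(seeds = length(seeds), seeds_in_graph = length(present),
              filtered_edges_removed =
                igraph::graph_attr(gf, "removed_edges"),
              filtered_nodes_removed =
                igraph::graph_attr(gf, "removed_nodes"))
  if (length(present) == 0) {
    warning("no mapped seed protein occurs in the interactome; ",
            "returning an empty collection", call. = FALSE)
    out <- list()
    attr(out, "run_log") <- c(log, list(extracted = 0, after_merge = 0))
    attr(out, "graph") <- gf
    return(out)
  }
  mods <- lapply(present, function(s)
    first_order_network(gf, s, mode = params$mode))
  mods <- lapply(mods, prune_overconnected, g = gf,
                 degree_percentile = params$degree_percentile,
                 inside_fraction_min = params$inside_fraction_min)
  # pre-cap seed enrichment for cap exemption
  background <- igraph::V(gf)$name
  pvals <- vapply(mods, function(m)
    fisher_ora(m$nodes, seeds, background)$p_value, numeric(1))
  qvals <- bh_adjust(pvals)
  mods <- mapply(function(m, q)
    cap_network(m, gf, max_nodes = params$max_nodes,
                exemption_q = params$exemption_q, seed_q = q),
    mods, qvals, SIMPLIFY = FALSE)
  n_extracted <- length(mods)
  mods <- merge_overlapping(mods, gf, overlap_min = params$overlap_min,
                            metric = params$overlap_metric,
                            whitelist = params$whitelist)
  mods <- lapply(mods, annotate_metabolites, seed_map = seed_map)
  ord <- order(vapply(mods, `[[`, character(1), "network_id"))
  mods <- mods[ord]
  attr(mods, "run_log") <- c(log, list(extracted = n_extracted,
                                       after_merge = length(mods)))
  attr(mods, "graph") <- gf
  mods
}
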