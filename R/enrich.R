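#' Gene set collection
#'
#' Named protein sets with a class label per set (e.g. `AD-related`,
#' `seed-proteins`, `annotation`).
#'
#' @param sets named list of character vectors; names unique, sets non-empty.
#' @param class character vector of class labels, one per set (recycled if
#'   length 1).
#' @return an object of class `gene_set_collection`.
#' @export
gene_set_collection <- function(sets, class = "annotation") {
  stopifnot(is.list(sets))
  if (is.null(names(sets)) || anyDuplicated(names(sets)) ||
      any(!nzchar(names(sets))))
    stop("gene sets require unique non-empty names", call. = FALSE)
  if (any(lengths(sets) == 0))
    stop("gene sets must be non-empty", call. = FALSE)
  sets <- lapply(sets, function(s) sort(unique(as.character(s))))
  class <- rep_len(as.character(class), length(sets))
  structure(list(sets = sets,
                 class = stats::setNames(class, names(sets))),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("gene_set_collection: %d sets (%s)\n", length(x$sets),
              paste(sprintf("%s: %d", names(table(x$class)), table(x$class)),
                    collapse = ", ")))
  invisible(x)
}

#' Combine two gene-set collections
#' @param a,b `gene_set_collection`s with disjoint set names.
#' @export
combine_gene_sets <- function(a, b) {
  gene_set_collection(c(a$sets, b$sets), c(unname(a$class), unname(b$class)))
}

#' Read / write gene sets in GMT format
#'
#' One set per line: name, description (used as the class label), then
#' member ids, tab-separated.
#'
#' @param path GMT file.
#' @return a [gene_set_collection()].
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  sets <- lapply(fields, function(f) f[-(1:2)])
  names(sets) <- vapply(fields, `[[`, character(1), 1)
  cls <- vapply(fields, function(f)
    if (nzchar(f[2])) f[2] else "annotation", character(1))
  gene_set_collection(sets, cls)
}

#' @rdname read_gmt
#' @param gs a [gene_set_collection()].
#' @export
write_gmt <- function(gs, path) {
  lines <- vapply(names(gs$sets), function(nm)
    paste(c(nm, gs$class[[nm]], gs$sets[[nm]]), collapse = "\t"),
    character(1))
  writeLines(lines, path)
  invisible(path)
}

#' One-sided Fisher over-representation test
#'
#' Tests whether a module's node set overlaps a gene set more than expected
#' under hypergeometric sampling from the background universe. The gene set
#' is intersected with the background before testing. The p-value is the
#' upper tail P(X >= k) of the hypergeometric distribution for the 2x2 table
#' (k, n - k; K - k, M - K - n + k), equivalent to a one-sided (greater)
#' Fisher exact test; the enrichment score is (k/n) / (K/M). p-values are
#' floored at 1e-300 so that reported significance never collapses to an
#' exact zero.
#'
#' @param network_nodes character vector of module proteins (must lie in the
#'   background).
#' @param gene_set character vector of gene-set proteins.
#' @param background character vector: the test universe, by default the node
#'   set of the filtered interactome.
#' @return list with `k`, `n`, `K`, `M`, `p_value`, `enrichment_score`.
#' @export
fisher_ora <- function(network_nodes, gene_set, background) {
  network_nodes <- unique(as.character(network_nodes))
  background <- unique(as.character(background))
  if (length(network_nodes) == 0) stop("empty network", call. = FALSE)
  if (length(background) == 0) stop("empty background", call. = FALSE)
  if (!all(network_nodes %in% background))
    stop("network nodes must be contained in the background", call. = FALSE)
  gs <- intersect(unique(as.character(gene_set)), background)
  k <- length(intersect(network_nodes, gs))
  n <- length(network_nodes)
  K <- length(gs)
  M <- length(background)
  p <- if (K == 0) 1 else stats::phyper(k - 1, K, M - K, n, lower.tail = FALSE)
  p <- min(1, max(p, 1e-300))
  es <- if (K > 0 && n > 0) (k / n) / (K / M) else NA_real_
  list(k = k, n = n, K = K, M = M, p_value = p, enrichment_score = es)
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up false-discovery-rate control with monotonicity
#' enforcement (delegates to [stats::p.adjust()]).
#'
#' @param p_values numeric vector of p-values in \[0, 1\].
#' @return q-values in the input order.
#' @export
bh_adjust <- function(p_values) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  stats::p.adjust(p_values, method = "BH")
}

#' Enrichment of every module against every gene set
#'
#' Runs [fisher_ora()] for each module x gene-set pair and applies
#' Benjamini-Hochberg correction within the configured family scope:
#' `"per-class"` (default; all tests sharing one gene-set class across the
#' collection form one family) or `"global"` (a single family).
#'
#' @param modules list of [network_module()]s.
#' @param gene_sets a [gene_set_collection()].
#' @param background test universe (default: union of the filtered
#'   interactome nodes recorded on the collection, else union of module
#'   nodes).
#' @param family BH family scope, `"per-class"` or `"global"`.
#' @return data frame of class `enrichment_result` with columns
#'   `network_id`, `gene_set`, `set_class`, `k`, `n`, `K`, `M`, `p_value`,
#'   `q_value`, `enrichment_score`.
#' @export
enrich_collection <- function(modules, gene_sets, background = NULL,
                              family = c("per-class", "global")) {
  family <- match.arg(family)
  stopifnot(inherits(gene_sets, "gene_set_collection"))
  if (is.null(background)) {
    g <- attr(modules, "graph")
    background <- if (!is.null(g)) igraph::V(g)$name
    else sort(unique(unlist(lapply(modules, `[[`, "nodes"))))
  }
  rows <- list()
  for (m in modules) {
    if (length(m$nodes) == 0) next
    for (nm in names(gene_sets$sets)) {
      r <- fisher_ora(m$nodes, gene_sets$sets[[nm]], background)
      rows[[length(rows) + 1]] <- data.frame(
        network_id = m$network_id, gene_set = nm,
        set_class = unname(gene_sets$class[[nm]]),
        k = r$k, n = r$n, K = r$K, M = r$M,
        p_value = r$p_value, enrichment_score = r$enrichment_score,
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, rows)
  if (is.null(res)) {
    res <- data.frame(network_id = character(0), gene_set = character(0),
                      set_class = character(0), k = integer(0), n = integer(0),
                      K = integer(0), M = integer(0), p_value = numeric(0),
                      enrichment_score = numeric(0), q_value = numeric(0))
  } else {
    res$q_value <- NA_real_
    groups <- if (family == "per-class") res$set_class else rep("all", nrow(res))
    for (grp in unique(groups)) {
      idx <- which(groups == grp)
      res$q_value[idx] <- bh_adjust(res$p_value[idx])
    }
  }
  class(res) <- c("enrichment_result", "data.frame")
  res
}

#' Classify modules into disease-core and exploratory sets
#'
#' Set #1 (disease core): modules significantly enriched (BH q <=
#' `q_max`) in at least one gene set of a disease-associated class.
#' Set #2 (exploratory): modules significantly enriched in the seed-protein
#' set and linked to at least `min_metabolites` discriminant metabolites.
#' The two sets may overlap.
#'
#' @param modules list of [network_module()]s (with linked metabolites
#'   annotated).
#' @param enrichment an [enrich_collection()] result that includes both the
#'   disease-class sets and the seed-protein set.
#' @param ad_classes class label(s) identifying disease gene sets.
#' @param seed_set_name name of the seed-protein gene set.
#' @param q_max significance threshold (default 0.05).
#' @param min_metabolites minimum linked metabolites for Set #2 (default 3).
#' @return list with `set1` and `set2` character vectors of module ids.
#' @export
classify_networks <- function(modules, enrichment,
                              ad_classes = "AD-related",
                              seed_set_name = "seed_proteins",
                              q_max = 0.05, min_metabolites = 3) {
  stopifnot(inherits(enrichment, "enrichment_result"))
  if (!any(enrichment$set_class %in% ad_classes))
    stop("enrichment lacks gene sets of class: ",
         paste(ad_classes, collapse = ", "), call. = FALSE)
  if (!any(enrichment$gene_set == seed_set_name))
    stop("enrichment lacks the seed-protein set '", seed_set_name, "'",
         call. = FALSE)
  ad <- enrichment[enrichment$set_class %in% ad_classes &
                     enrichment$q_value <= q_max, , drop = FALSE]
  set1 <- sort(unique(ad$network_id))
  seed_rows <- enrichment[enrichment$gene_set == seed_set_name, , drop = FALSE]
  met_count <- vapply(modules, function(m) length(m$linked_metabolites), 1L)
  names(met_count) <- vapply(modules, `[[`, character(1), "network_id")
  ok_seed <- seed_rows$network_id[seed_rows$q_value <= q_max]
  ok_met <- names(met_count)[met_count >= min_metabolites]
  set2 <- sort(intersect(ok_seed, ok_met))
  list(set1 = set1, set2 = set2)
}

#' Rank exploratory modules
#'
#' Stable ordering by the composite key: number of linked metabolites
#' (descending), then seed-enrichment q-value (ascending), then module id.
#'
#' @param tbl data frame with columns `network_id`, `n_metabolites`,
#'   `seed_q` (as produced by [module_table()]).
#' @return the `network_id`s in rank order.
#' @export
rank_networks <- function(tbl) {
  stopifnot(all(c("network_id", "n_metabolites", "seed_q") %in% names(tbl)))
  tbl$network_id[order(-tbl$n_metabolites, tbl$seed_q, tbl$network_id)]
}
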