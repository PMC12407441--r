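#' Aggregate annotations across a fixed module subset
#'
#' For each annotation tested against the selected modules, computes the
#' geometric mean of its (by default BH-corrected) significance values
#' across exactly those modules and the arithmetic mean of its enrichment
#' scores. An annotation not tested in a given module contributes 1.0 to the
#' geometric mean by default (`missing = "one"`) or is skipped
#' (`missing = "skip"`); values are floored at 1e-300 before the log.
#'
#' @param enrichment an [enrich_collection()] result.
#' @param network_ids the fixed module subset to aggregate over (e.g. the
#'   top 20 exploratory modules).
#' @param value `"q"` to aggregate corrected values (default) or `"p"` for
#'   raw p-values.
#' @param missing `"one"` (impute 1.0 for missing tests, default) or
#'   `"skip"`.
#' @param q_max threshold for the `n_networks_significant` count.
#' @return data frame of class `annotation_summary` with columns
#'   `annotation`, `set_class`, `geometric_mean_p`, `mean_enrichment`,
#'   `n_networks_significant`, sorted by ascending geometric mean.
#' @export
aggregate_annotations <- function(enrichment, network_ids,
                                  value = c("q", "p"),
                                  missing = c("one", "skip"),
                                  q_max = 0.05) {
  value <- match.arg(value)
  missing <- match.arg(missing)
  stopifnot(inherits(enrichment, "enrichment_result"))
  sub <- enrichment[enrichment$network_id %in% network_ids, , drop = FALSE]
  if (nrow(sub) == 0) stop("no enrichment results for the given modules",
                           call. = FALSE)
  col <- if (value == "q") "q_value" else "p_value"
  k <- length(unique(network_ids))
  out <- lapply(split(sub, sub$gene_set), function(d) {
    v <- pmax(d[[col]], 1e-300)
    if (missing == "one" && nrow(d) < k) v <- c(v, rep(1, k - nrow(d)))
    es <- d$enrichment_score[is.finite(d$enrichment_score)]
    data.frame(annotation = d$gene_set[1], set_class = d$set_class[1],
               geometric_mean_p = exp(mean(log(v))),
               mean_enrichment = if (length(es)) mean(es) else 0,
               n_networks_significant = sum(d$q_value <= q_max),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  res <- res[order(res$geometric_mean_p, res$annotation), , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("annotation_summary", "data.frame")
  res
}

#' Select the top prioritized annotations
#'
#' Sorts by ascending geometric-mean significance (ties broken by annotation
#' name), truncates to the `top_k` best, then keeps those with significance
#' at or below `p_max` and mean enrichment at or above `es_min`.
#'
#' @param summaries an [aggregate_annotations()] result.
#' @param top_k size of the shortlist before filtering (default 20).
#' @param p_max significance ceiling (default 0.01).
#' @param es_min enrichment-score floor (default 1.5).
#' @return the filtered `annotation_summary`.
#' @export
select_top_annotations <- function(summaries, top_k = 20, p_max = 0.01,
                                   es_min = 1.5) {
  stopifnot(inherits(summaries, "data.frame"))
  s <- summaries[order(summaries$geometric_mean_p, summaries$annotation), ,
                 drop = FALSE]
  s <- utils::head(s, top_k)
  s <- s[s$geometric_mean_p <= p_max & s$mean_enrichment >= es_min, ,
         drop = FALSE]
  rownames(s) <- NULL
  s
}

split_metabolite_names <- function(x) {
  parts <- strsplit(ifelse(is.na(x), "", x), ";", fixed = TRUE)
  lapply(parts, function(p) unique(trimws(p[nzchar(trimws(p))])))
}

#' Count in how many modules each metabolite is represented
#'
#' Exact full-name membership counting over a module-summary table: for each
#' distinct metabolite name, the number of modules whose linked-metabolite
#' list contains that exact name. Name variants (e.g. a lipid and its
#' ether-linked derivative) are deliberately distinct.
#'
#' @param records either a list of [network_module()]s or a data frame with a
#'   `metabolites_names` column of semicolon-joined names (one row per
#'   module), as in the packaged exploratory-network table.
#' @return named integer vector, metabolite -> module count, sorted by
#'   decreasing count then name.
#' @export
metabolite_representation <- function(records) {
  lists <- if (is.data.frame(records)) {
    stopifnot("metabolites_names" %in% names(records))
    split_metabolite_names(records$metabolites_names)
  } else {
    lapply(records, function(m) unique(m$linked_metabolites))
  }
  counts <- table(unlist(lists, use.names = FALSE))
  out <- stats::setNames(as.integer(counts), names(counts))
  out[order(-out, names(out))]
}

#' Tabular report of a classified module collection
#'
#' One row per module, mirroring the published module tables: module id,
#' size (node count), number of linked metabolites, semicolon-joined
#' metabolite names, and the seed-protein enrichment q-value; rows ordered
#' by [rank_networks()].
#'
#' @param modules list of [network_module()]s.
#' @param enrichment an [enrich_collection()] result containing the
#'   seed-protein set.
#' @param seed_set_name name of the seed-protein gene set.
#' @param ids optional subset of module ids to report (default: all).
#' @return data frame with columns `network_id`, `size`, `n_metabolites`,
#'   `metabolites_names`, `seed_q`.
#' @export
module_table <- function(modules, enrichment = NULL,
                         seed_set_name = "seed_proteins", ids = NULL) {
  all_ids <- vapply(modules, `[[`, character(1), "network_id")
  if (!is.null(ids)) modules <- modules[all_ids %in% ids]
  if (length(modules) == 0)
    return(data.frame(network_id = character(0), size = integer(0),
                      n_metabolites = integer(0),
                      metabolites_names = character(0),
                      seed_q = numeric(0), stringsAsFactors = FALSE))
  seed_q <- rep(NA_real_, length(modules))
  if (!is.null(enrichment)) {
    sq <- enrichment[enrichment$gene_set == seed_set_name, , drop = FALSE]
    seed_q <- sq$q_value[match(vapply(modules, `[[`, character(1),
                                      "network_id"), sq$network_id)]
  }
  tbl <- data.frame(
    network_id = vapply(modules, `[[`, character(1), "network_id"),
    size = vapply(modules, function(m) length(m$nodes), 1L),
    n_metabolites = vapply(modules, function(m)
      length(m$linked_metabolites), 1L),
    metabolites_names = vapply(modules, function(m)
      paste(sort(m$linked_metabolites), collapse = ";"), character(1)),
    seed_q = seed_q, stringsAsFactors = FALSE)
  tbl <- tbl[match(rank_networks(tbl), tbl$network_id), , drop = FALSE]
  rownames(tbl) <- NULL
  tbl
}

#' Read a module-summary table
#'
#' TSV with columns `network_id`, `size`, `n_metabolites`,
#' `metabolites_names`, `seed_q`; the packaged
#' `extdata/exploratory_networks.tsv` transcribes the 20 published
#' exploratory networks in this format.
#'
#' @param path TSV path; default loads the packaged exploratory-network
#'   table.
#' @return a data frame.
#' @export
read_module_summary <- function(path = system.file(
  "extdata", "exploratory_networks.tsv", package = "metapull")) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                          quote = "")
  stopifnot(all(c("network_id", "size", "n_metabolites",
                  "metabolites_names", "seed_q") %in% names(df)))
  df
}

#' @rdname read_module_summary
#' @param tbl a module-summary data frame.
#' @export
write_module_summary <- function(tbl, path) {
  utils::write.table(tbl, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Long-format annotation dot-plot data
#'
#' One row per (annotation, module) pair with the corrected significance and
#' enrichment score, suitable for external dot-plot rendering.
#'
#' @param enrichment an [enrich_collection()] result.
#' @param network_ids module subset.
#' @param annotations optional annotation subset.
#' @return data frame `annotation`, `network_id`, `q_value`,
#'   `enrichment_score`.
#' @export
annotation_long <- function(enrichment, network_ids, annotations = NULL) {
  sub <- enrichment[enrichment$network_id %in% network_ids, , drop = FALSE]
  if (!is.null(annotations))
    sub <- sub[sub$gene_set %in% annotations, , drop = FALSE]
  out <- sub[, c("gene_set", "network_id", "q_value", "enrichment_score")]
  names(out)[1] <- "annotation"
  rownames(out) <- NULL
  out
}
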