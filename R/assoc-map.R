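#' Metabolite-protein association table
#'
#' Validates the documented TSV schema: one row per (metabolite, protein)
#' link with identifier aliases and an evidence class from the closed
#' vocabulary `physical`, `functional`, `text-mining`.
#'
#' @param df data frame with columns `metabolite_id`, `synonyms`
#'   (semicolon-separated, may be empty), `structural_key`, `protein_id`,
#'   `association_class`, `source`.
#' @return the validated data frame with class `association_table`.
#' @export
association_table <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  req <- c("metabolite_id", "synonyms", "structural_key", "protein_id",
           "association_class", "source")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("association table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (any(!nzchar(df$protein_id)) || anyNA(df$protein_id))
    stop("protein_id must be non-empty", call. = FALSE)
  vocab <- c("physical", "functional", "text-mining")
  bad <- setdiff(unique(df$association_class), vocab)
  if (length(bad))
    stop("unknown association_class value(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  # same primary id mapping to conflicting structural keys: warn, keep both
  keys <- unique(df[, c("metabolite_id", "structural_key")])
  dup <- unique(keys$metabolite_id[duplicated(keys$metabolite_id)])
  if (length(dup))
    warning("metabolite id(s) with conflicting structural keys (retained): ",
            paste(dup, collapse = ", "), call. = FALSE)
  class(df) <- c("association_table", "data.frame")
  df
}

#' @rdname association_table
#' @param path TSV file in the documented schema.
#' @export
read_association_table <- function(path) {
  association_table(utils::read.delim(path, stringsAsFactors = FALSE))
}

#' @rdname association_table
#' @param tab an `association_table`.
#' @export
write_association_table <- function(tab, path) {
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

split_synonyms <- function(s) {
  out <- strsplit(ifelse(is.na(s), "", s), ";", fixed = TRUE)
  lapply(out, function(x) trimws(x[nzchar(trimws(x))]))
}

#' Resolve metabolite queries to seed proteins
#'
#' Each query is matched against the association table in three precedence
#' tiers: exact primary-id match, then exact structural-key match, then
#' case-insensitive match against primary names and synonyms. The first tier
#' with any hit wins. Rows whose evidence class is in `exclude_classes`
#' (by default unsupported text-mining co-mentions) are discarded before
#' matching, so a metabolite supported only by excluded evidence ends up
#' unmapped. Resolution is deterministic and independent of table row order.
#'
#' @param query_ids character vector of metabolite queries (ids, structural
#'   keys or names).
#' @param table an [association_table()].
#' @param exclude_classes evidence classes excluded before matching.
#' @return an object of class `seed_map`: list with `map` (query ->
#'   sorted protein-id vector, mapped queries only), `seed_proteins` (sorted
#'   unique union) and `unmapped` (queries without a match).
#' @export
resolve_metabolites <- function(query_ids, table,
                                exclude_classes = "text-mining") {
  stopifnot(length(query_ids) > 0, inherits(table, "association_table"))
  tab <- table[!(table$association_class %in% exclude_classes), ,
               drop = FALSE]
  syns <- split_synonyms(tab$synonyms)
  name_keys <- tolower(tab$metabolite_id)
  map <- list()
  unmapped <- character(0)
  for (q in unique(query_ids)) {
    hit <- which(tab$metabolite_id == q)
    if (!length(hit)) hit <- which(tab$structural_key == q)
    if (!length(hit)) {
      ql <- tolower(q)
      hit <- which(name_keys == ql |
                     vapply(syns, function(s) ql %in% tolower(s), logical(1)))
    }
    if (length(hit)) map[[q]] <- sort(unique(tab$protein_id[hit]))
    else unmapped <- c(unmapped, q)
  }
  structure(list(map = map,
                 seed_proteins = sort(unique(unlist(map, use.names = FALSE))),
                 unmapped = unmapped),
            class = "seed_map")
}

#' @export
print.seed_map <- function(x, ...) {
  cat(sprintf("seed_map: %d mapped metabolites -> %d seed proteins (%d unmapped)\n",
              length(x$map), length(x$seed_proteins), length(x$unmapped)))
  invisible(x)
}

#' Summary counts of a resolved seed map
#'
#' @param map a [resolve_metabolites()] result.
#' @return named numeric vector with `n_mapped_metabolites` (distinct mapped
#'   metabolites), `n_unique_proteins` (distinct proteins over all pairs) and
#'   `n_pairs` (distinct metabolite-protein pairs after exclusions).
#' @export
association_stats <- function(map) {
  stopifnot(inherits(map, "seed_map"))
  c(n_mapped_metabolites = length(map$map),
    n_unique_proteins = length(unique(unlist(map$map, use.names = FALSE))),
    n_pairs = sum(lengths(map$map)))
}

#' Export a seed map as two-column TSV (metabolite, protein)
#' @param map a `seed_map`.
#' @param path output file.
#' @export
write_seed_map <- function(map, path) {
  df <- data.frame(
    metabolite = rep(names(map$map), lengths(map$map)),
    protein = unlist(map$map, use.names = FALSE),
    stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a seed map from two-column TSV
#' @param path TSV with columns `metabolite`, `protein`.
#' @return a `seed_map`.
#' @export
read_seed_map <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("metabolite", "protein") %in% names(df)))
  map <- lapply(split(df$protein, df$metabolite), function(p) sort(unique(p)))
  structure(list(map = map,
                 seed_proteins = sort(unique(df$protein)),
                 unmapped = character(0)),
            class = "seed_map")
}
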