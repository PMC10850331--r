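#' Read / write gene-set collections in GMT format
#'
#' Standard GMT dialect: one set per line, tab-separated — set name,
#' description, then member genes. Empty sets and duplicate set names are
#' rejected; malformed lines (< 3 fields) raise an error naming the line.
#'
#' @param path GMT file path.
#' @return `read_gmt` returns a `gene_set_collection`: named list of gene
#'   vectors with attributes `descriptions` and `source`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- list(); desc <- character()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L)
      stop("malformed GMT line ", i, ": expected at least 3 tab-separated ",
           "fields")
    name <- f[1L]
    if (name %in% names(sets)) stop("duplicate set name: ", name)
    genes <- unique(f[-c(1L, 2L)])
    genes <- genes[nzchar(genes)]
    if (length(genes) == 0L) stop("empty gene set at line ", i, ": ", name)
    sets[[name]] <- genes
    desc[name] <- f[2L]
  }
  structure(sets, descriptions = desc, source = basename(path),
            class = "gene_set_collection")
}

#' @rdname read_gmt
#' @param collection A `gene_set_collection` (or plain named list of gene
#'   vectors).
#' @export
write_gmt <- function(collection, path) {
  desc <- attr(collection, "descriptions")
  lines <- vapply(names(collection), function(nm) {
    d <- if (!is.null(desc) && nm %in% names(desc)) desc[[nm]] else "na"
    paste(c(nm, d, collection[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Over-representation analysis of a gene list
#'
#' One-sided Fisher exact test (hypergeometric upper tail) of the overlap
#' between a query gene list and each set of a collection, against an
#' explicit gene universe. Sets are intersected with the universe first.
#' P-values are Benjamini-Hochberg adjusted across the collection
#' (`method = "bonferroni"` is available); fold enrichment is
#' `(overlap/|query|) / (|set in universe|/|universe|)`.
#'
#' @param query Character vector of genes of interest (must be a subset of
#'   `universe`).
#' @param collection A `gene_set_collection` or named list of gene vectors.
#' @param universe Character vector: the background gene list (e.g. all
#'   genes passing the expression filter).
#' @param method Multiple-testing correction (default `"BH"`).
#' @return An `enrichment_table` data.frame with columns `set`, `set_size`,
#'   `overlap`, `p_value`, `q_value`, `fold_enrichment`, sorted by p.
#' @export
overrepresentation <- function(query, collection, universe,
                               method = c("BH", "bonferroni")) {
  method <- match.arg(method)
  query <- unique(query); universe <- unique(universe)
  if (length(query) == 0L || length(universe) == 0L)
    stop("empty query or universe")
  if (!all(query %in% universe))
    stop("query genes outside the universe: ",
         paste(utils::head(setdiff(query, universe), 5), collapse = ", "))
  rows <- lapply(names(collection), function(nm) {
    set <- intersect(collection[[nm]], universe)
    m <- length(set)
    if (m == 0L) return(NULL)
    ov <- length(intersect(set, query))
    # P(X >= ov) drawing |query| genes from the universe
    p <- stats::phyper(ov - 1L, m, length(universe) - m, length(query),
                       lower.tail = FALSE)
    fold <- (ov / length(query)) / (m / length(universe))
    data.frame(set = nm, set_size = m, overlap = ov, p_value = p,
               fold_enrichment = fold, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  if (is.null(tab)) stop("no set overlaps the universe")
  tab$q_value <- stats::p.adjust(tab$p_value, method = method)
  tab <- tab[order(tab$p_value, tab$set),
             c("set", "set_size", "overlap", "p_value", "q_value",
               "fold_enrichment")]
  rownames(tab) <- NULL
  class(tab) <- c("enrichment_table", "data.frame")
  tab
}
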