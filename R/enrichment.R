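#' Gene-set collection
#'
#' Named gene sets, each tagged with a functional category: protein type
#' (`P`), location of final gene product (`L`), biological process (`B`)
#' or cellular component (`C`).
#'
#' @param sets named list of character vectors (gene symbols)
#' @param category character vector of tags in `P`, `L`, `B`, `C` (recycled)
#' @return object of class `gene_set_collection`
#' @export
gene_set_collection <- function(sets, category = "B") {
  if (is.null(names(sets)) || any(!nzchar(names(sets))))
    stop("all gene sets must be named")
  if (anyDuplicated(names(sets))) stop("gene set names must be unique")
  sets <- lapply(sets, function(x) sort(unique(canonical_gene(x))))
  if (any(lengths(sets) == 0L)) stop("gene sets must be non-empty")
  category <- rep_len(as.character(category), length(sets))
  if (!all(category %in% c("P", "L", "B", "C")))
    stop("categories must be one of P, L, B, C")
  structure(list(sets = sets, category = stats::setNames(category, names(sets))),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("gene_set_collection: %d sets (sizes %d-%d)\n",
              length(x$sets), min(lengths(x$sets)), max(lengths(x$sets))))
  invisible(x)
}

#' Read gene sets from a GMT file
#'
#' GMT: one set per line, tab-separated `name`, `description`, genes...
#' The description field carries the category tag (`P`/`L`/`B`/`C`; any
#' other value maps to `B`).
#'
#' @param path file path
#' @return gene_set_collection
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 3L)
  if (length(bad))
    stop(sprintf("%s: GMT line %d has fewer than 3 fields", path, bad[1]))
  sets <- lapply(parts, function(p) p[-(1:2)])
  names(sets) <- vapply(parts, `[`, "", 1L)
  cat_tag <- vapply(parts, `[`, "", 2L)
  cat_tag[!cat_tag %in% c("P", "L", "B", "C")] <- "B"
  gene_set_collection(sets, cat_tag)
}

#' Write gene sets to a GMT file
#'
#' @param gsc gene_set_collection
#' @param path output path
#' @param header_lines optional `#`-prefixed comment lines
#' @export
write_gmt <- function(gsc, path, header_lines = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(header_lines)) writeLines(header_lines, con)
  writeLines(vapply(names(gsc$sets), function(nm) {
    paste(c(nm, gsc$category[[nm]], gsc$sets[[nm]]), collapse = "\t")
  }, ""), con)
  invisible(path)
}

#' Hypergeometric over-representation p-value
#'
#' Upper-tail probability of observing at least the actual overlap between
#' a community and an annotation set when the community is drawn uniformly
#' from the universe. A transparent stand-in for web-based functional
#' annotation tools (no EASE correction, no fuzzy clustering).
#'
#' @param universe background gene set
#' @param community gene set drawn from the universe
#' @param annotation annotation gene set (intersected with the universe)
#' @return raw p-value
#' @export
hypergeom_enrich <- function(universe, community, annotation) {
  universe <- unique(canonical_gene(universe))
  if (!length(universe)) stop("empty universe")
  community <- intersect(unique(canonical_gene(community)), universe)
  annotation <- intersect(unique(canonical_gene(annotation)), universe)
  k <- length(intersect(community, annotation))
  stats::phyper(k - 1, length(annotation), length(universe) - length(annotation),
                length(community), lower.tail = FALSE)
}

#' Enrichment of annotation sets in communities
#'
#' Hypergeometric test of every annotation set in every community, with
#' Benjamini-Hochberg correction applied within each community's battery
#' of tests; reports rows with adjusted p below `threshold`, at most
#' `top_k` per community, ranked by adjusted then raw p.
#'
#' @param communities named list of gene sets, or a `community_partition`
#'   (all its communities are used, named by index)
#' @param sets gene_set_collection
#' @param universe background gene set (default: union of community and
#'   annotation genes)
#' @param threshold adjusted-p cutoff
#' @param top_k maximum reported sets per community
#' @return data.frame with columns `community`, `set_name`, `category`,
#'   `set_size`, `overlap`, `p`, `p_adj`
#' @export
enrich_communities <- function(communities, sets, universe = NULL,
                               threshold = 1e-4, top_k = 3L) {
  if (inherits(communities, "community_partition")) {
    communities <- stats::setNames(communities$communities,
                                   as.character(seq_along(communities$communities) - 1L))
  }
  stopifnot(inherits(sets, "gene_set_collection"))
  if (is.null(universe))
    universe <- unique(c(unlist(communities), unlist(sets$sets)))
  universe <- unique(canonical_gene(universe))
  rows <- lapply(names(communities), function(cn) {
    comm <- communities[[cn]]
    p <- vapply(sets$sets, function(s) hypergeom_enrich(universe, comm, s),
                numeric(1))
    padj <- stats::p.adjust(p, method = "BH")
    ov <- vapply(sets$sets, function(s)
      length(intersect(intersect(canonical_gene(comm), universe),
                       intersect(s, universe))), integer(1))
    df <- data.frame(community = cn, set_name = names(sets$sets),
                     category = unname(sets$category),
                     set_size = unname(lengths(sets$sets)),
                     overlap = unname(ov), p = unname(p), p_adj = unname(padj),
                     stringsAsFactors = FALSE)
    df <- df[df$p_adj < threshold, , drop = FALSE]
    df <- df[order(df$p_adj, df$p, df$set_name), , drop = FALSE]
    utils::head(df, top_k)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
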