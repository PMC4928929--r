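GAP_CHARS <- c("-", ".", "*", "X", "B", "Z")

#' Per-gene evolutionary annotation
#'
#' Holds, per gene symbol, an evolutionary rate (ER; nonsynonymous
#' substitutions per amino-acid site per billion years, "cold" = low,
#' "hot" = high) and a phylostratigraphic age index in 0..12 (0 = oldest
#' clade, 12 = youngest, i.e. the human clade). Genes missing one attribute
#' are retained with the other recorded as `NA`.
#'
#' @param er named non-negative numeric vector (gene -> ER)
#' @param age named integer vector (gene -> age in 0..12)
#' @return object of class `evo_annotation` with fields `er` and `age`,
#'   both covering the union of the gene sets
#' @export
evo_annotation <- function(er = numeric(), age = integer()) {
  names(er) <- canonical_gene(names(er))
  names(age) <- canonical_gene(names(age))
  if (any(er < 0, na.rm = TRUE)) stop("evolutionary rates must be >= 0")
  age <- round(age)
  storage.mode(age) <- "integer"        # keep names (as.integer would drop them)
  if (any(age < 0 | age > 12, na.rm = TRUE)) stop("ages must be integers in [0, 12]")
  genes <- sort(unique(c(names(er), names(age))))
  er_full <- stats::setNames(rep(NA_real_, length(genes)), genes)
  age_full <- stats::setNames(rep(NA_integer_, length(genes)), genes)
  er_full[names(er)] <- unname(er)
  age_full[names(age)] <- unname(age)
  structure(list(er = er_full, age = age_full, genes = genes),
            class = "evo_annotation")
}

#' @export
print.evo_annotation <- function(x, ...) {
  cat(sprintf("evo_annotation: %d genes (%d with ER, %d with age)\n",
              length(x$genes), sum(!is.na(x$er)), sum(!is.na(x$age))))
  invisible(x)
}

#' Fetch one annotation attribute as a named vector
#'
#' @param ann evo_annotation
#' @param attribute `"er"` or `"age"`
#' @param drop_na drop genes lacking the attribute
#' @return named numeric vector
#' @export
annotation_values <- function(ann, attribute = c("er", "age"), drop_na = TRUE) {
  attribute <- match.arg(attribute)
  v <- as.numeric(ann[[attribute]])
  names(v) <- ann$genes
  if (drop_na) v <- v[!is.na(v)]
  v
}

#' Evolutionary rate of one alignment column
#'
#' The rate of an amino-acid position is the number of different residues
#' observed at that position divided by the total evolutionary time span of
#' the phylogeny, in substitutions per site per billion years. Under the
#' `distinct_minus_one` convention the count is reduced by one (a fully
#' conserved column then has rate 0). Gap and ambiguity characters
#' (`- . * X B Z`) are excluded from the count.
#'
#' @param column character vector of residues (one per taxon)
#' @param total_span total evolutionary time span in billions of years
#'   (sum of all branch lengths of the dated tree)
#' @param convention `"distinct"` (default) or `"distinct_minus_one"`
#' @return non-negative rate, or `NA_real_` for an uninformative column
#'   (fewer than 2 non-gap residues)
#' @export
column_rate <- function(column, total_span,
                        convention = c("distinct", "distinct_minus_one")) {
  convention <- match.arg(convention)
  stopifnot(is.numeric(total_span), total_span > 0)
  res <- toupper(as.character(column))
  res <- res[!res %in% GAP_CHARS & !is.na(res) & nzchar(res)]
  if (length(res) < 2L) return(NA_real_)
  k <- length(unique(res))
  if (convention == "distinct_minus_one") k <- k - 1L
  k / total_span
}

#' Evolutionary rate of a gene from its alignment and a dated tree
#'
#' Averages [column_rate()] over all informative columns of the amino-acid
#' multiple alignment; the time span is the sum of all branch lengths of the
#' tree (expected in billions of years).
#'
#' @param alignment a character matrix (taxa x columns), an `ape` `AAbin`
#'   matrix, or a path to an aligned amino-acid FASTA file
#' @param tree an `ape` `phylo` object or a path to a Newick file; branch
#'   lengths must be present and positive
#' @inheritParams column_rate
#' @return mean per-column rate
#' @export
gene_er <- function(alignment, tree,
                    convention = c("distinct", "distinct_minus_one")) {
  convention <- match.arg(convention)
  aln <- as_alignment_matrix(alignment)
  if (is.character(tree) && length(tree) == 1L) tree <- ape::read.tree(tree)
  if (!inherits(tree, "phylo")) stop("tree must be a phylo object or a Newick file path")
  if (is.null(tree$edge.length) || any(tree$edge.length <= 0))
    stop("tree must carry positive branch lengths (in billions of years)")
  span <- sum(tree$edge.length)
  taxa <- rownames(aln)
  if (!is.null(taxa) && !setequal(taxa, tree$tip.label))
    warning("alignment taxa and tree tips differ; time span taken from the tree as given")
  rates <- apply(aln, 2L, column_rate, total_span = span, convention = convention)
  rates <- rates[!is.na(rates)]
  if (!length(rates)) stop("alignment has no informative columns")
  mean(rates)
}

as_alignment_matrix <- function(alignment) {
  if (is.character(alignment) && length(alignment) == 1L && file.exists(alignment)) {
    aa <- ape::read.FASTA(alignment, type = "AA")
    alignment <- toupper(as.character(as.matrix(aa)))
  } else if (inherits(alignment, "AAbin")) {
    alignment <- toupper(as.character(as.matrix(alignment)))
  }
  if (!is.matrix(alignment))
    stop("alignment sequences must have equal length (a matrix of residues)")
  alignment
}

#' Clade presence/absence profile
#'
#' Ordered ortholog presence over 13 clades along the human lineage, index
#' 0 = earliest-branching (oldest), 12 = the human clade.
#'
#' @param presence logical matrix or data.frame, genes in rows (rownames =
#'   gene symbols), 13 clade columns ordered oldest to youngest
#' @return object of class `clade_profile`
#' @export
clade_profile <- function(presence) {
  m <- as.matrix(presence)
  mode(m) <- "logical"
  if (ncol(m) != 13L) stop("clade profile must have 13 clade columns (oldest to youngest)")
  if (is.null(rownames(m))) stop("clade profile rows must be named by gene")
  rownames(m) <- canonical_gene(rownames(m))
  if (any(rowSums(m) == 0L))
    stop("every gene must be present in at least one clade")
  structure(list(presence = m, clades = colnames(m)), class = "clade_profile")
}

#' Read a clade presence table
#'
#' TSV with a `gene` column followed by 13 binary clade columns, header
#' naming clades oldest to youngest.
#'
#' @param path file path
#' @return clade_profile
#' @export
read_clade_profile <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                           stringsAsFactors = FALSE)
  if (!"gene" %in% names(tab)) stop(sprintf("%s: first column must be 'gene'", path))
  m <- as.matrix(tab[, setdiff(names(tab), "gene"), drop = FALSE])
  rownames(m) <- tab$gene
  clade_profile(m)
}

#' Phylostratigraphic age of a gene
#'
#' The age is the index of the earliest-branching clade (smallest index)
#' in which an ortholog of the gene is present: 0 for genes traceable to the
#' oldest clade, 12 for genes found only in the human clade.
#'
#' @param profile clade_profile
#' @param gene gene symbol
#' @return integer age in 0..12
#' @export
gene_age <- function(profile, gene) {
  stopifnot(inherits(profile, "clade_profile"))
  gene <- canonical_gene(gene)
  if (!gene %in% rownames(profile$presence))
    stop(sprintf("gene '%s' absent from clade profile", gene))
  as.integer(min(which(profile$presence[gene, ])) - 1L)
}

#' Load per-gene ER and age tables
#'
#' Each table is a two-column TSV (`gene`, value) with a header; lines
#' starting with `#` are skipped. Genes present in only one table are
#' retained with the other attribute `NA`.
#'
#' @param er_path path to the ER table (or `NULL`)
#' @param age_path path to the age table (or `NULL`)
#' @return evo_annotation
#' @export
load_annotation <- function(er_path = NULL, age_path = NULL) {
  read_two_col <- function(path, what) {
    tab <- utils::read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                             stringsAsFactors = FALSE)
    if (nrow(tab) == 0L) {
      warning(sprintf("%s: empty %s table", path, what))
      return(stats::setNames(numeric(0), character(0)))
    }
    if (ncol(tab) < 2L) stop(sprintf("%s: expected two columns (gene, value)", path))
    val <- suppressWarnings(as.numeric(tab[[2L]]))
    if (anyNA(val)) {
      bad <- which(is.na(val))[1]
      stop(sprintf("%s: non-numeric %s value '%s' at data row %d",
                   path, what, tab[[2L]][bad], bad))
    }
    stats::setNames(val, tab[[1L]])
  }
  er <- if (!is.null(er_path)) read_two_col(er_path, "ER") else numeric()
  age <- if (!is.null(age_path)) read_two_col(age_path, "age") else numeric()
  evo_annotation(er = er, age = age)
}

#' Write annotation tables
#'
#' @param ann evo_annotation
#' @param er_path,age_path output paths (either may be `NULL`)
#' @param header_lines optional `#`-prefixed comment lines
#' @export
write_annotation <- function(ann, er_path = NULL, age_path = NULL,
                             header_lines = NULL) {
  write_one <- function(v, path, col) {
    v <- v[!is.na(v)]
    con <- file(path, "w")
    on.exit(close(con))
    if (length(header_lines)) writeLines(header_lines, con)
    writeLines(paste0("gene\t", col), con)
    writeLines(sprintf("%s\t%.10g", names(v), as.numeric(v)), con)
  }
  if (!is.null(er_path)) write_one(ann$er, er_path, "er")
  if (!is.null(age_path)) write_one(ann$age, age_path, "age")
  invisible(ann)
}
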