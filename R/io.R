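## File interfaces. All tabular formats are plain TSV so that every pipeline
## stage can be driven from files alone (no in-memory shortcuts needed).

#' Write an expression matrix and its sample annotations as TSV
#'
#' The matrix file has the gene ID in the first column (`gene_id`) and one
#' column per sample; the annotation file has one row per sample.
#'
#' @param x an `expr_matrix`.
#' @param expr_path path for the expression TSV.
#' @param annot_path path for the annotation TSV.
#' @return Invisibly, `x`.
#' @export
write_expression_tsv <- function(x, expr_path, annot_path) {
  stopifnot(inherits(x, "expr_matrix"))
  df <- data.frame(gene_id = rownames(x$values), x$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, expr_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(x$samples, annot_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(x)
}

#' Read an expression matrix and annotations from TSV
#'
#' @param expr_path expression TSV written by [write_expression_tsv()].
#' @param annot_path matching sample-annotation TSV.
#' @return An `expr_matrix`.
#' @export
read_expression_tsv <- function(expr_path, annot_path) {
  df <- utils::read.table(expr_path, sep = "\t", header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  ann <- utils::read.table(annot_path, sep = "\t", header = TRUE,
                           check.names = FALSE, stringsAsFactors = FALSE)
  expression_matrix(m, ann)
}

#' Read a gene-set collection in GMT format
#'
#' Standard GMT: one set per line, tab-separated fields
#' `name<TAB>description<TAB>member1<TAB>member2...`.
#'
#' @param path GMT file.
#' @param universe gene universe for enrichment; defaults to the union of all
#'   set members.
#' @return A `gene_set_collection`: list with `sets` (named list of character
#'   vectors) and `universe`.
#' @export
read_gmt <- function(path, universe = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- list()
  for (ln in lines) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3) stop("malformed GMT line: ", substr(ln, 1, 40))
    sets[[f[1]]] <- unique(f[-(1:2)])
  }
  gene_set_collection(sets, universe %||% unique(unlist(sets)))
}

#' Write a gene-set collection as GMT
#'
#' @param sets a `gene_set_collection` or named list of character vectors.
#' @param path output file.
#' @return Invisibly, `path`.
#' @export
write_gmt <- function(sets, path) {
  if (inherits(sets, "gene_set_collection")) sets <- sets$sets
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, "na", sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Gene-set collection
#'
#' @param sets named list of character vectors (set name -> member gene IDs).
#' @param universe character vector of all genes eligible for enrichment;
#'   set members must be a subset.
#' @return A `gene_set_collection` object.
#' @export
gene_set_collection <- function(sets, universe) {
  if (is.null(names(sets)) || any(!nzchar(names(sets))))
    stop("all sets must be named")
  universe <- unique(universe)
  stray <- setdiff(unlist(sets), universe)
  if (length(stray))
    stop(length(stray), " set members outside the universe (e.g. ",
         stray[1], ")")
  structure(list(sets = lapply(sets, unique), universe = universe),
            class = "gene_set_collection")
}

#' Read a two-column orthologue map
#'
#' @param path TSV with header columns `gene_a`, `gene_b`.
#' @return data.frame with columns `gene_a`, `gene_b`.
#' @export
read_ortholog_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  if (!all(c("gene_a", "gene_b") %in% names(df)))
    stop("ortholog map needs columns gene_a, gene_b")
  df[, c("gene_a", "gene_b")]
}

#' Write an orthologue map as TSV
#'
#' @param map data.frame with columns `gene_a`, `gene_b`.
#' @param path output file.
#' @return Invisibly, `path`.
#' @export
write_ortholog_tsv <- function(map, path) {
  utils::write.table(map[, c("gene_a", "gene_b")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a DEG table as TSV
#'
#' @param deg a `deg_table` (see [compute_deg()]).
#' @param path output file.
#' @return Invisibly, `path`.
#' @export
write_deg_tsv <- function(deg, path) {
  stopifnot(inherits(deg, "deg_table"))
  utils::write.table(deg$table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a DEG table from TSV
#'
#' @param path TSV written by [write_deg_tsv()].
#' @return A `deg_table`.
#' @export
read_deg_tsv <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  need <- c("gene", "contrast", "log2fc", "p_raw", "p_adj", "call")
  if (!all(need %in% names(tab))) stop("not a DEG table TSV")
  structure(list(table = tab,
                 contrast = contrast_spec(
                   sub(" vs .*$", "", tab$contrast[1]),
                   day = suppressWarnings(
                     as.numeric(sub("^.* day ", "", tab$contrast[1]))),
                   reference = sub("^.* vs ", "",
                                   sub(" day .*$", "", tab$contrast[1])))),
            class = "deg_table")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
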