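#' Expression matrix with sample annotations
#'
#' Container for a log2-scale expression matrix (genes x samples) together
#' with one annotation row per sample. This is the common currency of the
#' whole pipeline: the simulator produces it, QC, differential expression,
#' clustering and metagene scoring consume it.
#'
#' @param values numeric matrix, genes in rows, samples in columns. Must have
#'   unique, non-empty rownames (gene IDs) and colnames (sample IDs) and only
#'   finite values.
#' @param annotations data.frame with one row per sample and columns
#'   `sample_id`, `condition`, `day`, `replicate`, `species`, `model_type`.
#'   `model_type` must be one of `"culture"`, `"in_vivo"`, `"reference"`.
#'   Rows are matched to matrix columns by `sample_id`.
#'
#' @return An object of class `expr_matrix`: a list with elements `values`
#'   (the matrix) and `samples` (the annotation data.frame, reordered to the
#'   column order of `values`).
#' @export
expression_matrix <- function(values, annotations) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must have gene rownames and sample colnames")
  if (anyDuplicated(rownames(values)))
    stop("duplicate gene IDs")
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample IDs")
  if (!all(is.finite(values)))
    stop("all expression values must be finite")
  required <- c("sample_id", "condition", "day", "replicate", "species",
                "model_type")
  missing_cols <- setdiff(required, names(annotations))
  if (length(missing_cols))
    stop("annotation columns missing: ", paste(missing_cols, collapse = ", "))
  if (!all(colnames(values) %in% annotations$sample_id))
    stop("every sample needs an annotation row")
  if (!all(annotations$model_type %in% c("culture", "in_vivo", "reference")))
    stop("model_type must be culture, in_vivo or reference")
  ann <- annotations[match(colnames(values), annotations$sample_id), ,
                     drop = FALSE]
  rownames(ann) <- NULL
  structure(list(values = values, samples = ann), class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix: %d genes x %d samples\n",
              nrow(x$values), ncol(x$values)))
  cat("conditions:", paste(unique(x$samples$condition), collapse = ", "), "\n")
  cat("days:", paste(sort(unique(x$samples$day)), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

#' Subset an expression matrix
#'
#' @param x an `expr_matrix`.
#' @param genes gene IDs (or logical/integer index) to keep; NULL keeps all.
#' @param samples sample IDs (or logical/integer index) to keep; NULL keeps
#'   all.
#' @return An `expr_matrix` restricted to the requested genes and samples.
#' @export
subset_expr <- function(x, genes = NULL, samples = NULL) {
  stopifnot(inherits(x, "expr_matrix"))
  v <- x$values
  if (!is.null(genes)) {
    if (is.character(genes)) {
      bad <- setdiff(genes, rownames(v))
      if (length(bad)) stop("unknown genes: ", paste(bad[1:min(3, length(bad))],
                                                     collapse = ", "))
    }
    v <- v[genes, , drop = FALSE]
  }
  if (!is.null(samples)) {
    if (is.character(samples)) {
      bad <- setdiff(samples, colnames(v))
      if (length(bad)) stop("unknown samples: ",
                            paste(bad[1:min(3, length(bad))], collapse = ", "))
    }
    v <- v[, samples, drop = FALSE]
  }
  expression_matrix(v, x$samples[x$samples$sample_id %in% colnames(v), ,
                                 drop = FALSE])
}

#' Select sample IDs by annotation
#'
#' @param x an `expr_matrix`.
#' @param condition,day,species,model_type optional filters; NULL means no
#'   constraint on that field.
#' @return Character vector of matching sample IDs (possibly empty).
#' @export
samples_where <- function(x, condition = NULL, day = NULL, species = NULL,
                          model_type = NULL) {
  stopifnot(inherits(x, "expr_matrix"))
  ann <- x$samples
  keep <- rep(TRUE, nrow(ann))
  if (!is.null(condition)) keep <- keep & ann$condition %in% condition
  if (!is.null(day))       keep <- keep & !is.na(ann$day) & ann$day %in% day
  if (!is.null(species))   keep <- keep & ann$species %in% species
  if (!is.null(model_type)) keep <- keep & ann$model_type %in% model_type
  ann$sample_id[keep]
}
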