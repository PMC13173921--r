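#' Expression matrix container
#'
#' A genes x samples numeric matrix tagged with its value scale. The value
#' scale records what the numbers mean: `"counts"` (non-negative integers from
#' RNA-seq quantification), `"log2_intensity"` (log2-scale microarray
#' intensities), or `"transformed"` (normalized log2-scale values produced by
#' [transform_counts()] or supplied externally).
#'
#' @param values numeric matrix, rows = genes, columns = samples, with
#'   rownames and colnames set (or supplied via `gene_ids` / `sample_ids`).
#' @param value_scale one of `"counts"`, `"log2_intensity"`, `"transformed"`.
#' @param platform_tag free-form string describing the assay platform.
#' @param gene_ids,sample_ids optional explicit IDs overriding dimnames.
#' @return An object of class `expr_matrix`: a list with elements `values`
#'   (the matrix, dimnames set), `value_scale` and `platform_tag`.
#' @export
expression_matrix <- function(values, value_scale, platform_tag = "",
                              gene_ids = NULL, sample_ids = NULL) {
  value_scale <- match.arg(value_scale,
                           c("counts", "log2_intensity", "transformed"))
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (!is.null(gene_ids)) rownames(values) <- gene_ids
  if (!is.null(sample_ids)) colnames(values) <- sample_ids
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("expression matrix needs gene and sample IDs")
  em <- structure(list(values = values, value_scale = value_scale,
                       platform_tag = as.character(platform_tag)),
                  class = "expr_matrix")
  validate_expr_matrix(em)
}

validate_expr_matrix <- function(em) {
  v <- em$values
  g <- rownames(v); s <- colnames(v)
  if (anyDuplicated(g))
    stop("duplicate gene IDs: ", paste(head(unique(g[duplicated(g)]), 5),
                                       collapse = ", "))
  if (anyDuplicated(s))
    stop("duplicate sample IDs: ", paste(unique(s[duplicated(s)]),
                                         collapse = ", "))
  if (anyNA(v)) {
    bad <- which(is.na(v), arr.ind = TRUE)[1, ]
    stop(sprintf("missing value at gene '%s', sample '%s'",
                 g[bad[1]], s[bad[2]]))
  }
  if (em$value_scale == "counts") {
    if (any(v < 0)) stop("counts must be non-negative")
    if (any(v != round(v))) stop("counts must be integral")
  }
  em
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix: %d genes x %d samples [%s%s]\n",
              nrow(x$values), ncol(x$values), x$value_scale,
              if (nzchar(x$platform_tag)) paste0(", ", x$platform_tag) else ""))
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

#' Gene and sample identifiers of an expression matrix
#' @param em an `expr_matrix`.
#' @return Character vector of IDs.
#' @export
gene_ids <- function(em) rownames(em$values)

#' @rdname gene_ids
#' @export
sample_ids <- function(em) colnames(em$values)

# Row/column subsetting that preserves class and tags.
subset_genes <- function(em, keep) {
  em$values <- em$values[keep, , drop = FALSE]
  em
}
subset_samples <- function(em, keep) {
  em$values <- em$values[, keep, drop = FALSE]
  em
}

#' Read a delimited expression matrix
#'
#' Expects tab-separated UTF-8 text with gene (or probe) IDs in the first
#' column and a header row of sample IDs — the dominant orientation of GEO
#' series matrices. `transpose = TRUE` accepts samples-as-rows input.
#'
#' Any cell that does not parse as a finite number (including literal `NA`)
#' aborts with the offending gene/sample coordinates; imputation is never
#' attempted.
#'
#' @param path file path.
#' @param value_scale value scale tag, see [expression_matrix()].
#' @param platform_tag free-form platform string.
#' @param transpose set `TRUE` when rows are samples.
#' @param sep field separator, tab by default.
#' @return An `expr_matrix`.
#' @export
read_expression <- function(path, value_scale, platform_tag = "",
                            transpose = FALSE, sep = "\t") {
  dt <- data.table::fread(path, sep = sep, header = TRUE,
                          colClasses = "character", data.table = FALSE)
  if (ncol(dt) < 2) stop("expected an ID column plus at least one sample")
  ids <- dt[[1]]
  cm <- as.matrix(dt[, -1, drop = FALSE])
  num <- suppressWarnings(array(as.numeric(cm), dim = dim(cm),
                                dimnames = list(ids, colnames(cm))))
  bad <- which(!is.finite(num), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf("non-numeric value '%s' at row '%s', column '%s'",
                 cm[bad[1, 1], bad[1, 2]], ids[bad[1, 1]],
                 colnames(cm)[bad[1, 2]]))
  if (transpose) num <- t(num)
  expression_matrix(num, value_scale = value_scale,
                    platform_tag = platform_tag)
}

#' Write an expression matrix as TSV
#'
#' Inverse of [read_expression()]; values survive a round trip to within
#' 1e-12 (15 significant digits are written).
#'
#' @param em an `expr_matrix`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(em, path) {
  df <- data.frame(gene_id = gene_ids(em), em$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  data.table::fwrite(df, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Read a phenotype table
#'
#' Two-column delimited text: sample ID then label. Labels are folded
#' case-insensitively to `"disease"` / `"control"`; anything else is an error.
#'
#' @param path file path.
#' @param sep field separator.
#' @param header whether the file has a header row.
#' @return A `data.frame` with columns `sample_id`, `label`.
#' @export
read_phenotype <- function(path, sep = "\t", header = TRUE) {
  dt <- data.table::fread(path, sep = sep, header = header,
                          colClasses = "character", data.table = FALSE)
  if (ncol(dt) < 2) stop("phenotype table needs two columns")
  phenotype_table(dt[[1]], dt[[2]])
}

#' Construct a phenotype table
#'
#' @param sample_id character vector of unique sample IDs.
#' @param label disease/control labels (case-insensitive).
#' @return A `data.frame` with columns `sample_id`, `label`.
#' @export
phenotype_table <- function(sample_id, label) {
  sample_id <- as.character(sample_id)
  lab <- tolower(trimws(as.character(label)))
  unknown <- setdiff(unique(lab), c("disease", "control"))
  if (length(unknown) > 0)
    stop("unknown phenotype label(s): ", paste(unknown, collapse = ", "),
         " (expected disease/control)")
  if (anyDuplicated(sample_id))
    stop("duplicate sample IDs in phenotype table")
  data.frame(sample_id = sample_id, label = lab, stringsAsFactors = FALSE)
}

#' Align an expression matrix with a phenotype table
#'
#' Restricts both to their sample intersection, in the matrix's column order,
#' and reports how many samples each side lost. Idempotent.
#'
#' @param em an `expr_matrix`.
#' @param pheno a phenotype table.
#' @return List with elements `matrix`, `pheno`, `dropped_from_matrix`,
#'   `dropped_from_pheno`.
#' @export
align_samples <- function(em, pheno) {
  keep <- sample_ids(em)[sample_ids(em) %in% pheno$sample_id]
  if (length(keep) == 0)
    stop("no samples shared between expression matrix and phenotype table")
  out_m <- subset_samples(em, keep)
  out_p <- pheno[match(keep, pheno$sample_id), , drop = FALSE]
  rownames(out_p) <- NULL
  list(matrix = out_m, pheno = out_p,
       dropped_from_matrix = ncol(em$values) - length(keep),
       dropped_from_pheno = nrow(pheno) - length(keep))
}
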