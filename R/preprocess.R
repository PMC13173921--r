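#' Remove red-blood-cell globin genes
#'
#' Whole-blood RNA is dominated by the erythrocyte globins HBB, HBA2 and
#' HBA1, whose expression exceeds every other transcript by two orders of
#' magnitude; dropping them removes a platform- and protocol-sensitive noise
#' source. Absent genes are a no-op.
#'
#' @param em an `expr_matrix`.
#' @param rbc_genes gene IDs to drop.
#' @return The matrix without the globin rows; the number removed is attached
#'   as attribute `n_removed`.
#' @export
remove_rbc_genes <- function(em, rbc_genes = c("HBB", "HBA2", "HBA1")) {
  keep <- !(gene_ids(em) %in% rbc_genes)
  out <- subset_genes(em, keep)
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' Restrict to protein-coding genes
#'
#' Keeps only genes on `coding_list`; for count matrices, genes with a total
#' count of zero are additionally dropped.
#'
#' @param em an `expr_matrix`.
#' @param coding_list character vector of coding gene IDs (nonempty).
#' @return Filtered `expr_matrix`.
#' @export
restrict_to_coding <- function(em, coding_list) {
  if (length(coding_list) == 0) stop("coding_list is empty")
  keep <- gene_ids(em) %in% coding_list
  if (em$value_scale == "counts")
    keep <- keep & rowSums(em$values) > 0
  if (!any(keep)) stop("no genes left after coding-gene restriction")
  subset_genes(em, keep)
}

#' Collapse probes to genes
#'
#' For genes represented by multiple probes, the probe with the highest
#' across-sample mean expression is retained; exact ties go to the
#' lexicographically smallest probe ID (determinism). Probes absent from the
#' map are dropped with a warning.
#'
#' @param em an `expr_matrix` whose rows are probe IDs.
#' @param probe_map data.frame with columns `probe_id`, `gene_id`
#'   (`probe_id` unique).
#' @return An `expr_matrix` with one row per gene.
#' @export
collapse_probes <- function(em, probe_map) {
  stopifnot(all(c("probe_id", "gene_id") %in% names(probe_map)))
  if (anyDuplicated(probe_map$probe_id))
    stop("probe_id must be unique in the probe map")
  probes <- gene_ids(em)
  hit <- match(probes, probe_map$probe_id)
  if (anyNA(hit)) {
    warning(sum(is.na(hit)), " probe(s) absent from the probe map; dropped")
    em <- subset_genes(em, !is.na(hit))
    probes <- gene_ids(em)
    hit <- hit[!is.na(hit)]
  }
  gene <- probe_map$gene_id[hit]
  means <- rowMeans(em$values)
  # per gene: max mean, ties by smallest probe ID (radix = C locale)
  o <- order(gene, -means, probes, method = "radix")
  keep <- o[!duplicated(gene[o])]
  keep <- sort(keep) # preserve input row order
  out <- subset_genes(em, keep)
  rownames(out$values) <- gene[keep]
  validate_expr_matrix(out)
}

#' Filter low-variability genes by interquartile range
#'
#' Genes whose across-sample IQR falls at or below the `drop_fraction`
#' empirical quantile (linear interpolation, type 7) of all gene IQRs are
#' removed — the standard noise filter for microarray matrices. Inclusive at
#' the cutoff, so ties with the threshold are all removed;
#' `drop_fraction = 0` is the identity.
#'
#' @param em an `expr_matrix` with at least 4 samples.
#' @param drop_fraction fraction of low-IQR genes to drop, in `[0, 1)`.
#' @return Filtered `expr_matrix`.
#' @export
iqr_filter <- function(em, drop_fraction = 0.25) {
  stopifnot(drop_fraction >= 0, drop_fraction < 1)
  if (ncol(em$values) < 4) stop("iqr_filter needs at least 4 samples")
  if (drop_fraction == 0) return(em)
  iqrs <- matrixStats::rowIQRs(em$values)
  cutoff <- unname(quantile(iqrs, drop_fraction, type = 7))
  keep <- iqrs > cutoff
  if (!any(keep))
    stop("IQR filter removed every gene (degenerate, e.g. constant matrix)")
  subset_genes(em, keep)
}

#' Normalize and log-transform a count matrix
#'
#' A variance-stabilizing stand-in for count data: size factors by
#' DESeq2-style median-of-ratios (reference = per-gene geometric mean over
#' genes positive in every sample), renormalized to geometric mean 1, then
#' `log2(count / size_factor + pseudocount)`. When fewer than 50 all-positive
#' genes are available, library-size factors (normalized to geometric mean 1)
#' are used instead.
#'
#' @param em an `expr_matrix` with `value_scale == "counts"`.
#' @param pseudocount added before the log, default 1.
#' @param size_factors optional explicit per-sample factors overriding the
#'   median-of-ratios estimate.
#' @return List with `matrix` (an `expr_matrix`, `value_scale`
#'   `"transformed"`) and `params` (size factors, pseudocount, number of
#'   all-positive reference genes).
#' @export
transform_counts <- function(em, pseudocount = 1, size_factors = NULL) {
  if (em$value_scale != "counts")
    stop("transform_counts expects a counts matrix")
  v <- em$values
  if (any(colSums(v) == 0))
    stop("sample(s) with zero total count: ",
         paste(sample_ids(em)[colSums(v) == 0], collapse = ", "))
  allpos <- rowSums(v > 0) == ncol(v)
  n_ref <- sum(allpos)
  if (is.null(size_factors)) {
    if (n_ref >= 50) {
      logref <- rowMeans(log(v[allpos, , drop = FALSE]))
      sf <- apply(log(v[allpos, , drop = FALSE]) - logref, 2,
                  function(lr) exp(median(lr)))
    } else {
      sf <- colSums(v)
    }
    sf <- sf / exp(mean(log(sf))) # geometric mean 1
  } else {
    stopifnot(length(size_factors) == ncol(v), all(size_factors > 0))
    sf <- size_factors
  }
  out <- em
  out$values <- log2(sweep(v, 2, sf, "/") + pseudocount)
  out$value_scale <- "transformed"
  list(matrix = validate_expr_matrix(out),
       params = list(size_factors = setNames(sf, sample_ids(em)),
                     pseudocount = pseudocount,
                     reference_gene_count = n_ref))
}
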