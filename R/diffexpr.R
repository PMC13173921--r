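#' Benjamini-Hochberg step-up adjustment
#'
#' Standard BH false-discovery-rate correction: with p-values sorted
#' ascending, `q_(i) = min over j >= i of min(1, p_(j) * m / j)`, returned in
#' the original order.
#'
#' @param pvalues numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, same order as input.
#' @export
bh_adjust <- function(pvalues) {
  if (any(pvalues < 0 | pvalues > 1) || anyNA(pvalues))
    stop("p-values must lie in [0, 1]")
  m <- length(pvalues)
  if (m == 0) return(numeric(0))
  o <- order(pvalues)
  q <- pmin(1, pvalues[o] * m / seq_len(m))
  q <- rev(cummin(rev(q)))
  out <- numeric(m)
  out[o] <- q
  out
}

#' Per-gene differential expression
#'
#' Simplified differential-expression engine for log2-scale matrices
#' (transformed counts or microarray intensities): per gene, the log2 fold
#' change is the disease-minus-control mean difference, the p-value a
#' two-sided Welch t-test, adjusted by [bh_adjust()]. Direction is `"up"` /
#' `"down"` when `padj < padj_cutoff` with positive/negative log2FC, else
#' `"ns"`. Zero within-group variances are floored at 1e-12 (equal-mean genes
#' still get p = 1). An externally computed table with the same columns can
#' be injected anywhere a `de_table` is accepted.
#'
#' @param em an `expr_matrix` on a log2-like scale (`"transformed"` or
#'   `"log2_intensity"`).
#' @param pheno aligned phenotype table (both labels, >= 2 samples each).
#' @param padj_cutoff adjusted-p significance gate, default 0.05.
#' @return A `data.frame` (class `de_table`) with columns `gene_id`,
#'   `log2fc`, `pvalue`, `padj`, `direction`.
#' @export
differential_expression <- function(em, pheno, padj_cutoff = 0.05) {
  if (em$value_scale == "counts")
    stop("run transform_counts() first: DE operates on a log2-like scale")
  stopifnot(identical(sample_ids(em), pheno$sample_id))
  d <- em$values[, pheno$label == "disease", drop = FALSE]
  c_ <- em$values[, pheno$label == "control", drop = FALSE]
  n1 <- ncol(d); n2 <- ncol(c_)
  if (n1 < 2 || n2 < 2)
    stop("need at least 2 samples per group")
  m1 <- rowMeans(d); m2 <- rowMeans(c_)
  v1 <- pmax(matrixStats::rowVars(d), 1e-12)
  v2 <- pmax(matrixStats::rowVars(c_), 1e-12)
  se2 <- v1 / n1 + v2 / n2
  tstat <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * pt(abs(tstat), df, lower.tail = FALSE)
  padj <- bh_adjust(p)
  lfc <- m1 - m2
  dir <- ifelse(padj < padj_cutoff & lfc > 0, "up",
                ifelse(padj < padj_cutoff & lfc < 0, "down", "ns"))
  structure(data.frame(gene_id = gene_ids(em), log2fc = lfc, pvalue = p,
                       padj = padj, direction = dir,
                       stringsAsFactors = FALSE, row.names = NULL),
            class = c("de_table", "data.frame"))
}

#' Ranked DEG pools for gene-set construction
#'
#' Orders genes by absolute log2 fold change (descending, ties broken by
#' gene ID) within each direction and truncates to `pool_size` per direction.
#' Significant genes (direction `"up"`/`"down"`) rank first; if a direction
#' holds fewer than `pool_size` of them, the pool is padded with same-sign
#' non-significant genes and a warning is raised, so downstream stages stay
#' runnable on weak-signal data. `require_significant = TRUE` restores a hard
#' error when a direction has no significant gene at all.
#'
#' @param de a `de_table`.
#' @param pool_size genes retained per direction, default 200.
#' @param require_significant error (rather than pad) when a direction has
#'   zero significant genes.
#' @return List (class `deg_pools`) with character vectors `up` and `down`.
#' @export
rank_degs <- function(de, pool_size = 200, require_significant = FALSE) {
  one <- function(dir_label, sign_ok) {
    sig <- de[de$direction == dir_label, , drop = FALSE]
    if (nrow(sig) == 0 && require_significant)
      stop("no significant ", dir_label,
           "-regulated genes; consider relaxing padj_cutoff")
    rest <- de[de$direction == "ns" & sign_ok(de$log2fc), , drop = FALSE]
    ord <- function(x) x[order(-abs(x$log2fc), x$gene_id,
                               method = "radix"), "gene_id"]
    pool <- c(ord(sig), ord(rest))
    if (length(pool) < pool_size)
      warning(sprintf("only %d %s-direction genes available (pool_size %d)",
                      length(pool), dir_label, pool_size))
    n_pad <- min(pool_size, length(pool)) - nrow(sig)
    if (n_pad > 0)
      warning(sprintf(
        "%s pool padded with %d non-significant same-sign genes",
        dir_label, n_pad))
    head(pool, pool_size)
  }
  up <- one("up", function(l) l > 0)
  down <- one("down", function(l) l < 0)
  if (length(up) == 0 || length(down) == 0)
    stop("empty DEG pool in at least one direction")
  structure(list(up = up, down = down), class = "deg_pools")
}
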