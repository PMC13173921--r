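#' Parameters of the enrichment scorer
#'
#' @param tau walk weight exponent applied to the rank statistic, `>= 0`;
#'   default 1.
#' @param es_mode `"signed_diff"` (sum of the positive maximum and negative
#'   minimum of the walk, the reference implementation's default) or
#'   `"max_dev"` (walk value of largest absolute deviation).
#' @return List of class `gsva_params`.
#' @export
gsva_params <- function(tau = 1, es_mode = c("signed_diff", "max_dev")) {
  stopifnot(tau >= 0)
  structure(list(tau = tau, es_mode = match.arg(es_mode)),
            class = "gsva_params")
}

#' Gaussian kernel CDF per gene
#'
#' For gene i and sample j, `z_ij = (1/n) sum_k Phi((x_ij - x_ik) / h_i)`
#' with bandwidth `h_i = sd_i / 4` (sample SD, n-1 denominator). This places
#' each expression value on a smoothed within-gene empirical CDF scale,
#' invariant to per-gene positive affine transforms of the input. Constant
#' genes get the midpoint value 0.5.
#'
#' @param em an `expr_matrix` (or bare numeric matrix) with >= 2 samples.
#' @return Numeric matrix of CDF values in (0, 1), same dimnames.
#' @export
kcdf_gaussian <- function(em) {
  x <- if (inherits(em, "expr_matrix")) em$values else as.matrix(em)
  n <- ncol(x)
  if (n < 2) stop("kernel CDF needs at least 2 samples")
  h <- matrixStats::rowSds(x) / 4
  z <- matrix(0.5, nrow(x), n, dimnames = dimnames(x))
  live <- which(h > 0)
  for (i in live) {
    z[i, ] <- colMeans(pnorm(outer(-x[i, ], x[i, ], "+"), sd = h[i]))
  }
  z
}

#' Symmetric rank statistic
#'
#' Within each sample, genes are sorted by kernel-CDF value descending (ties
#' broken by gene ID ascending, C locale) and assigned ranks 1..p; the
#' statistic is `r_ij = |p/2 - rank_ij|`, largest at both extremes of the
#' ranking so that up- and down-shifted genes both carry weight.
#'
#' @param z kernel-CDF matrix from [kcdf_gaussian()] (rownames = gene IDs).
#' @return List with `order` (p x n integer matrix; column j holds the gene
#'   row indices of sample j in descending-z order), `pos` (p x n; position
#'   of each gene row in that ordering), `r` (p x n matrix of the statistic,
#'   gene-indexed), and `p` (gene count).
#' @export
rank_stat <- function(z) {
  p <- nrow(z); n <- ncol(z)
  g <- rownames(z)
  ord <- matrix(0L, p, n)
  pos <- matrix(0L, p, n)
  r <- matrix(0, p, n, dimnames = dimnames(z))
  for (j in seq_len(n)) {
    o <- order(-z[, j], g, method = "radix")
    ord[, j] <- o
    pos[o, j] <- seq_len(p)
    r[, j] <- abs(p / 2 - pos[, j])
  }
  list(order = ord, pos = pos, r = r, p = p)
}

#' Enrichment-score random walk for one gene set
#'
#' Walks each sample's descending ranking: in-set genes add their normalized
#' weight `r^tau / sum_in(r^tau)`, out-of-set genes subtract `1/(p - k)`.
#' The walk closes at 0 by construction; the enrichment score summarizes its
#' extremes per `es_mode` and always lies in `[-1, 1]`. If the in-set weights
#' sum to 0 (all members sit exactly at mid-rank), in-set steps are taken as
#' 0 and the score is minus the maximal out-of-set deficit — a documented
#' degenerate case.
#'
#' @param rs rank structure from [rank_stat()].
#' @param members character vector of member gene IDs (strict nonempty
#'   subset of the matrix genes).
#' @param params a [gsva_params()] object.
#' @return Numeric vector, one enrichment score per sample.
#' @export
walk_es <- function(rs, members, params = gsva_params()) {
  idx <- match(members, rownames(rs$r))
  if (anyNA(idx)) stop("gene set member(s) absent from the matrix")
  drop(gsva_walk_cpp(rs$pos, rs$r^params$tau, list(as.integer(idx - 1L)),
                     if (params$es_mode == "signed_diff") 0L else 1L))
}

#' Single-sample gene-set enrichment scores
#'
#' The full scorer: Gaussian kernel CDF per gene, symmetric rank statistic
#' per sample, and the KS-like walk for every gene set. The kernel CDF and
#' ranking are computed once and reused across sets. Sets are filtered to
#' genes present in the matrix (with a warning when members are lost); a set
#' left empty, or covering every matrix gene, is an error.
#'
#' Note the kernel CDF couples samples: adding or removing a sample changes
#' every z value of that gene, so each cohort must be scored on its own
#' matrix (train and test are never pooled).
#'
#' @param em an `expr_matrix` on a log2-like scale.
#' @param sets a `gene_set_collection` (see [sample_gene_sets()]) or a named
#'   list of character vectors.
#' @param params a [gsva_params()] object.
#' @return Matrix of class `enrichment_matrix`, gene sets x samples, scores
#'   in `[-1, 1]`; the parameters and set provenance ride along as
#'   attributes.
#' @export
gsva_scores <- function(em, sets, params = gsva_params()) {
  memb <- if (inherits(sets, "gene_set_collection"))
    lapply(sets$sets, `[[`, "members") else sets
  if (is.null(names(memb)) && inherits(sets, "gene_set_collection"))
    names(memb) <- vapply(sets$sets, `[[`, "", "set_id")
  stopifnot(!is.null(names(memb)), !anyDuplicated(names(memb)))
  g <- gene_ids(em)
  filt <- lapply(memb, intersect, g)
  lost <- sum(lengths(memb) - lengths(filt))
  if (lost > 0)
    warning(lost, " set member(s) absent from the matrix were dropped")
  empty <- names(filt)[lengths(filt) == 0]
  if (length(empty) > 0)
    stop("gene set(s) empty after filtering to matrix genes: ",
         paste(head(empty, 10), collapse = ", "))
  if (any(lengths(filt) >= length(g)))
    stop("a gene set covers every matrix gene; the walk is undefined")
  z <- kcdf_gaussian(em)
  rs <- rank_stat(z)
  idx0 <- lapply(filt, function(m) as.integer(match(m, g) - 1L))
  es <- gsva_walk_cpp(rs$pos, rs$r^params$tau, idx0,
                      if (params$es_mode == "signed_diff") 0L else 1L)
  dimnames(es) <- list(names(filt), sample_ids(em))
  structure(es, class = c("enrichment_matrix", class(es)),
            params = params,
            set_sizes = lengths(filt))
}
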