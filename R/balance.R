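#' Smoothed-bootstrap oversampling of the minority class
#'
#' ROSE-style class balancing for the training feature matrix: every
#' original row is kept, and `n_majority - n_minority` synthetic minority
#' rows are generated by resampling minority rows with replacement and
#' adding independent per-feature Gaussian noise with bandwidth
#' `h_q = sigma_q * (4 / ((d + 2) * n_min))^(1 / (d + 4))`, where `sigma_q`
#' is the minority-class SD of feature q and d the feature count (the
#' multivariate-normal rule-of-thumb kernel with a diagonal bandwidth).
#' `shrink` scales the bandwidth; `shrink = 0` is a plain bootstrap. Never
#' apply this to test data.
#'
#' @param features samples x features numeric matrix (rownames = sample
#'   IDs).
#' @param labels vector of `"disease"` / `"control"`, one per row; each
#'   class needs >= 2 rows.
#' @param seed integer seed.
#' @param shrink bandwidth multiplier, default 1.
#' @return A `balanced_set`: list with `features`, `labels`, `synthetic`
#'   (logical flags, `TRUE` for generated rows), `seed`.
#' @export
rose_oversample <- function(features, labels, seed = 1, shrink = 1) {
  features <- as.matrix(features)
  stopifnot(nrow(features) == length(labels), all(is.finite(features)),
            shrink >= 0)
  labels <- as.character(labels)
  cnt <- table(labels)
  if (length(cnt) != 2) stop("need exactly two classes")
  if (min(cnt) < 2) stop("each class needs >= 2 rows (bandwidth undefined)")
  minority <- names(cnt)[which.min(cnt)]
  n_syn <- as.integer(max(cnt) - min(cnt))
  if (n_syn == 0)
    return(structure(list(features = features, labels = labels,
                          synthetic = rep(FALSE, nrow(features)),
                          seed = seed),
                     class = "balanced_set"))
  mrows <- which(labels == minority)
  n_min <- length(mrows)
  d <- ncol(features)
  sigma <- matrixStats::colSds(features[mrows, , drop = FALSE])
  h <- sigma * (4 / ((d + 2) * n_min))^(1 / (d + 4))
  withr::with_seed(seed, {
    pick <- sample(mrows, n_syn, replace = TRUE)
    noise <- matrix(rnorm(n_syn * d), n_syn, d) *
      rep(shrink * h, each = n_syn)
  })
  syn <- features[pick, , drop = FALSE] + noise
  rownames(syn) <- sprintf("synth_%s_%d", minority, seq_len(n_syn))
  structure(list(features = rbind(features, syn),
                 labels = c(labels, rep(minority, n_syn)),
                 synthetic = c(rep(FALSE, nrow(features)),
                               rep(TRUE, n_syn)),
                 seed = seed),
            class = "balanced_set")
}
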