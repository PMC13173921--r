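# Independent brute-force oracles and tiny fixture builders. Every oracle
# follows the textbook definition directly (loops, enumeration), with no code
# shared with the implementation it checks.

em_fix <- function(values, value_scale = "transformed", genes = NULL,
                   samples = NULL) {
  values <- as.matrix(values)
  if (is.null(genes)) genes <- sprintf("g%02d", seq_len(nrow(values)))
  if (is.null(samples)) samples <- sprintf("s%02d", seq_len(ncol(values)))
  expression_matrix(values, value_scale, gene_ids = genes,
                    sample_ids = samples)
}

# literal BH step-up: q_(i) = min over j >= i of min(1, p_(j) * m / j)
bf_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- numeric(m)
  for (i in seq_len(m))
    q[i] <- min(1, min(ps[i:m] * m / (i:m)))
  out <- numeric(m)
  out[o] <- q
  out
}

# all-pairs concordance with half credit for ties
bf_auc <- function(scores, pos) {
  s1 <- scores[pos]; s0 <- scores[!pos]
  tot <- 0
  for (a in s1) for (b in s0)
    tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(s1) * length(s0))
}

# exact two-sided Mann-Whitney p by enumeration of all group assignments
# (tie-free inputs only): doubles the smaller tail, capped at 1
bf_wilcoxon_exact <- function(x, y) {
  nx <- length(x)
  pool <- c(x, y)
  u_obs <- sum(rank(pool)[seq_len(nx)]) - nx * (nx + 1) / 2
  combos <- utils::combn(length(pool), nx)
  u_all <- apply(combos, 2, function(ix)
    sum(rank(pool)[ix]) - nx * (nx + 1) / 2)
  min(1, 2 * min(mean(u_all <= u_obs), mean(u_all >= u_obs)))
}

# full GSVA pipeline from the definitions: per-gene Gaussian kernel CDF,
# per-sample ranking (ties by gene id), symmetric rank statistic, and the
# complete O(p) random walk per set and sample
bf_gsva <- function(x, sets, tau = 1, es_mode = "signed_diff") {
  p <- nrow(x); n <- ncol(x)
  z <- matrix(NA_real_, p, n, dimnames = dimnames(x))
  for (i in seq_len(p)) {
    h <- sd(x[i, ]) / 4
    for (j in seq_len(n))
      z[i, j] <- if (h == 0) 0.5 else mean(pnorm((x[i, j] - x[i, ]) / h))
  }
  es <- matrix(NA_real_, length(sets), n,
               dimnames = list(names(sets), colnames(x)))
  for (j in seq_len(n)) {
    ord <- order(-z[, j], rownames(x), method = "radix")
    r <- abs(p / 2 - order(ord)) # order(ord) = rank of each gene
    for (si in seq_along(sets)) {
      inset <- rownames(x) %in% sets[[si]]
      k <- sum(inset)
      w <- r^tau
      denom <- sum(w[inset])
      nu <- numeric(p)
      run <- 0
      for (l in seq_len(p)) {
        g <- ord[l]
        run <- run + if (inset[g]) {
          if (denom > 0) w[g] / denom else 0
        } else {
          -1 / (p - k)
        }
        nu[l] <- run
      }
      es[si, j] <- if (es_mode == "signed_diff") {
        max(0, max(nu)) + min(0, min(nu))
      } else if (max(nu) >= -min(nu)) { # |nu| ties resolve positive
        max(nu)
      } else {
        min(nu)
      }
    }
  }
  es
}

# small two-cohort fixture for classifier tests: 2 informative features
separable_fixture <- function(n_per_class = 30, seed = 42) {
  withr::with_seed(seed, {
    x <- rbind(matrix(rnorm(n_per_class * 2, 3), ncol = 2),
               matrix(rnorm(n_per_class * 2, -3), ncol = 2))
  })
  colnames(x) <- c("f1", "f2")
  rownames(x) <- sprintf("s%03d", seq_len(nrow(x)))
  list(x = x, y = rep(c("disease", "control"), each = n_per_class))
}

# reduced-budget pipeline config used by the slower integration checks
accept_cfg <- function(seed, ...) {
  wbtdc_config(seed = seed, size_grid = c(10, 25, 50, 100, 200, 400),
               reps_per_direction = 20, folds = 5, repeats = 1,
               n_trees = 300,
               rf = rf_grid(200, 120, mtry = c(7, 14), min_n = c(2, 10),
                            n_trees = 300),
               ...)
}
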