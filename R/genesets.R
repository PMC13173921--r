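#' Default gene-set size grid
#'
#' 24 candidate set sizes spanning 10 to 1000 genes, dense in the 30-200
#' region where whole-blood optima tend to fall.
#'
#' @return Integer vector of length 24.
#' @export
default_size_grid <- function() {
  as.integer(c(10, 20, 30, 40, 50, 60, 70, 80, 90, 100, 125, 150, 175, 200,
               250, 300, 350, 400, 500, 600, 700, 800, 900, 1000))
}

#' Shapiro-Wilk normality gate
#'
#' Tests whether a vector of enrichment scores is plausibly normal; the size
#' scan records the answer but always proceeds with the rank-sum test (the
#' distribution-free choice). Vectors longer than 5000 (the test's hard
#' limit) are reduced deterministically to 5000 evenly spaced order
#' statistics.
#'
#' @param scores numeric vector, length >= 3.
#' @param alpha normality threshold, default 0.05.
#' @return List with `pvalue` and `is_normal` (`pvalue >= alpha`).
#' @export
normality_gate <- function(scores, alpha = 0.05) {
  n <- length(scores)
  if (n < 3) stop("normality_gate needs at least 3 values")
  if (n > 5000) {
    s <- sort(scores)
    scores <- s[round(seq(1, n, length.out = 5000))]
  }
  if (sd(scores) == 0) return(list(pvalue = 0, is_normal = FALSE))
  p <- shapiro.test(scores)$p.value
  list(pvalue = p, is_normal = p >= alpha)
}

#' Two-sided Wilcoxon rank-sum (Mann-Whitney) test
#'
#' Exact p-value when `min(n_x, n_y) <= 8` and there are no ties; otherwise
#' the normal approximation with tie correction and continuity correction.
#'
#' @param x,y nonempty numeric vectors.
#' @return Two-sided p-value.
#' @export
wilcoxon_rank_sum <- function(x, y) {
  nx <- length(x); ny <- length(y)
  stopifnot(nx > 0, ny > 0)
  all_v <- c(x, y)
  rk <- rank(all_v)
  w <- sum(rk[seq_len(nx)]) - nx * (nx + 1) / 2 # Mann-Whitney U of x
  ties <- any(duplicated(all_v))
  if (!ties && min(nx, ny) <= 8) {
    p <- 2 * min(pwilcox(w, nx, ny),
                 pwilcox(w - 1, nx, ny, lower.tail = FALSE))
    return(min(1, p))
  }
  n <- nx + ny
  mu <- nx * ny / 2
  tab <- table(all_v)
  sigma2 <- nx * ny / 12 * ((n + 1) - sum(tab^3 - tab) / (n * (n - 1)))
  if (sigma2 <= 0) return(1)
  z <- (w - mu - sign(w - mu) * 0.5) / sqrt(sigma2)
  min(1, 2 * pnorm(abs(z), lower.tail = FALSE))
}

#' Scan candidate gene-set sizes
#'
#' For each size s in the grid and each direction, draws
#' `reps_per_direction` random subsets of size s from that direction's DEG
#' pool, scores them with the enrichment scorer (the kernel CDF and ranking
#' of the training matrix are computed once and shared by every draw), and
#' summarizes the disease-versus-control contrast of each draw by a
#' two-sided Wilcoxon rank-sum p-value and the median enrichment-score
#' difference.
#'
#' The working size is chosen by a plateau rule on
#' `M(s) = median(-log10 p)`: the longest contiguous grid run with
#' `M(s) >= plateau_frac * max M` is the chosen range and its smallest
#' member the chosen size — a deterministic reading of "stabilization" of
#' the score differences. Pooled scores also pass through the
#' Shapiro-Wilk gate; the rank-sum test is used regardless of its outcome.
#'
#' @param em training `expr_matrix` (log2-like scale).
#' @param pheno aligned phenotype table.
#' @param pools a `deg_pools` object from [rank_degs()].
#' @param grid integer vector of candidate sizes (clamped to pool sizes with
#'   a warning); default [default_size_grid()].
#' @param reps_per_direction random subsets per direction per size,
#'   default 500.
#' @param seed integer seed; the scan is bit-reproducible given it.
#' @param params a [gsva_params()] object.
#' @param plateau_frac plateau threshold as a fraction of the peak `M(s)`,
#'   default 0.95.
#' @param min_es_diff fallback gate when no `pool_builder` is supplied:
#'   minimal directional median ES difference (disease minus control,
#'   sign-corrected per direction) for a size to count as carrying signal;
#'   default 0.1, a tenth of the ES scale.
#' @param pool_builder optional function mapping a phenotype table to a
#'   `deg_pools` object (i.e. the DE + ranking stage as a closure over the
#'   training matrix). When supplied, the significance gate is calibrated
#'   by label permutation: the whole selection-plus-scan procedure is
#'   repeated on `n_perm` label permutations (`perm_reps` subsets per
#'   direction each, reusing the matrix's kernel CDF and ranking), and a
#'   size counts as significant only when its directional ES difference
#'   exceeds the permutation mean by 3 permutation SDs. This matters
#'   because the pools are the most-differential genes of the very matrix
#'   being scanned, so selection alone yields substantial, extremely
#'   "significant" ES contrasts even on exchangeable (null) labels.
#' @param n_perm,perm_reps permutation-calibration budget.
#' @return A `size_scan_result`: list with `table` (one row per size:
#'   summaries of p and ES difference per direction and pooled, plus the
#'   permutation baseline when calibrated), `chosen_range`, `chosen_size`,
#'   `normality_pvalue`, `stable_significance` (>= 3 contiguous sizes with
#'   pooled median p < 0.05 and directional ES difference clearing the
#'   gate), `reps`, `seed`.
#' @export
scan_set_sizes <- function(em, pheno, pools, grid = default_size_grid(),
                           reps_per_direction = 500, seed = 1,
                           params = gsva_params(), plateau_frac = 0.95,
                           min_es_diff = 0.1, pool_builder = NULL,
                           n_perm = 5, perm_reps = 5) {
  stopifnot(identical(sample_ids(em), pheno$sample_id))
  if (min(lengths(pools[c("up", "down")])) < 10)
    stop("fewer than 10 usable genes in a DEG pool")
  grid <- sort(unique(as.integer(grid)))
  maxs <- min(length(pools$up), length(pools$down))
  if (any(grid > maxs)) {
    warning("grid sizes beyond the pool size were clamped to ", maxs)
    grid <- sort(unique(pmin(grid, maxs)))
  }
  pool_idx <- list(up = match(pools$up, gene_ids(em)),
                   down = match(pools$down, gene_ids(em)))
  for (dn in c("up", "down")) {
    if (anyNA(pool_idx[[dn]])) {
      warning(sum(is.na(pool_idx[[dn]])), " ", dn,
              "-pool gene(s) absent from the matrix were dropped")
      pool_idx[[dn]] <- pool_idx[[dn]][!is.na(pool_idx[[dn]])]
    }
  }
  grid <- grid[grid <= min(lengths(pool_idx))]
  is_dis <- pheno$label == "disease"

  z <- kcdf_gaussian(em)
  rs <- rank_stat(z)
  rw <- rs$r^params$tau
  mode <- if (params$es_mode == "signed_diff") 0L else 1L

  # directional median ES difference for one pool pair at one size
  dir_effect <- function(idx_list, s, reps, is_dis_vec) {
    eff <- c(up = NA_real_, down = NA_real_)
    for (dn in c("up", "down")) {
      pool <- idx_list[[dn]]
      s_eff <- min(s, length(pool))
      sets <- lapply(seq_len(reps), function(i)
        as.integer(sample(pool, s_eff) - 1L))
      es <- gsva_walk_cpp(rs$pos, rw, sets, mode)
      dd <- apply(es, 1, function(e)
        median(e[is_dis_vec]) - median(e[!is_dis_vec]))
      eff[dn] <- median(dd)
    }
    min(eff["up"], -eff["down"])
  }

  withr::with_seed(seed, {
    rows <- list()
    pooled_es <- list()
    for (s in grid) {
      rec <- list(size = s)
      pvals_all <- numeric(0); esdiff_all <- numeric(0)
      for (dn in c("up", "down")) {
        pool <- pool_idx[[dn]]
        sets <- lapply(seq_len(reps_per_direction), function(i)
          as.integer(sample(pool, s) - 1L))
        es <- gsva_walk_cpp(rs$pos, rw, sets, mode)
        pv <- apply(es, 1, function(e)
          wilcoxon_rank_sum(e[is_dis], e[!is_dis]))
        dd <- apply(es, 1, function(e) median(e[is_dis]) - median(e[!is_dis]))
        rec[[paste0("p_median_", dn)]] <- median(pv)
        rec[[paste0("p_iqr_", dn)]] <- unname(diff(quantile(pv, c(.25, .75))))
        rec[[paste0("es_diff_median_", dn)]] <- median(dd)
        pvals_all <- c(pvals_all, pv); esdiff_all <- c(esdiff_all, dd)
        pooled_es[[length(pooled_es) + 1L]] <- as.numeric(es)
      }
      rec$p_median <- median(pvals_all)
      rec$p_iqr <- unname(diff(quantile(pvals_all, c(.25, .75))))
      rec$es_diff_median <- median(esdiff_all)
      rec$m_stat <- median(-log10(pmax(pvals_all, 1e-300)))
      rows[[length(rows) + 1L]] <- rec
    }

    # permutation calibration of the selection-inflated contrast
    null_effect <- NULL
    if (!is.null(pool_builder)) {
      e_perm <- matrix(NA_real_, n_perm, length(grid))
      for (k in seq_len(n_perm)) {
        ph_k <- pheno
        ph_k$label <- sample(ph_k$label)
        pk <- suppressWarnings(pool_builder(ph_k))
        idx_k <- lapply(pk[c("up", "down")], function(g) {
          i <- match(g, gene_ids(em))
          i[!is.na(i)]
        })
        dis_k <- ph_k$label == "disease"
        for (gi in seq_along(grid))
          e_perm[k, gi] <- dir_effect(idx_k, grid[gi], perm_reps, dis_k)
      }
      null_effect <- colMeans(e_perm) + 3 * apply(e_perm, 2, sd)
    }
  })
  tab <- do.call(rbind, lapply(rows, function(r)
    as.data.frame(r, stringsAsFactors = FALSE)))
  if (!is.null(null_effect)) tab$es_null_baseline <- null_effect

  m <- tab$m_stat
  ok <- m >= plateau_frac * max(m)
  run <- longest_run(ok)
  chosen_range <- c(tab$size[run[1]], tab$size[run[2]])
  chosen_size <- tab$size[run[1]]
  effect <- pmin(tab$es_diff_median_up, -tab$es_diff_median_down)
  gate <- if (is.null(null_effect)) min_es_diff else null_effect
  sig_run <- longest_run(tab$p_median < 0.05 & effect > gate)
  stable_sig <- !is.na(sig_run[1]) && (sig_run[2] - sig_run[1] + 1) >= 3
  norm_p <- normality_gate(unlist(pooled_es))$pvalue

  structure(list(table = tab, chosen_range = chosen_range,
                 chosen_size = chosen_size, normality_pvalue = norm_p,
                 stable_significance = stable_sig,
                 reps = reps_per_direction, seed = seed),
            class = "size_scan_result")
}

# first/last index of the longest TRUE run (first such run on ties);
# c(NA, NA) when all FALSE
longest_run <- function(ok) {
  if (!any(ok)) return(c(NA_integer_, NA_integer_))
  r <- rle(ok)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cand <- which(r$values)
  best <- cand[which.max(r$lengths[cand])]
  c(starts[best], ends[best])
}

#' @export
print.size_scan_result <- function(x, ...) {
  cat(sprintf(
    "size scan: %d sizes x %d reps/direction; chosen size %d (range %d-%d)\n",
    nrow(x$table), x$reps, x$chosen_size, x$chosen_range[1],
    x$chosen_range[2]))
  cat(sprintf("pooled-ES Shapiro-Wilk p = %.3g; stable significance: %s\n",
              x$normality_pvalue, x$stable_significance))
  invisible(x)
}

#' Sample random gene sets from the DEG pools
#'
#' Draws `n_up` + `n_down` independent uniform without-replacement subsets
#' of `set_size` genes from the up- and down-regulated pools; the default
#' composition is 100 upregulated plus 100 downregulated sets. Sets may
#' overlap one another; the draw is deterministic given the seed.
#'
#' @param pools a `deg_pools` object.
#' @param set_size members per set (<= each pool's length).
#' @param n_up,n_down number of sets per direction, default 100 each.
#' @param seed integer seed.
#' @return A `gene_set_collection`: list with `sets` (each a list with
#'   `set_id`, `direction`, `members`) and `provenance`.
#' @export
sample_gene_sets <- function(pools, set_size, n_up = 100, n_down = 100,
                             seed = 1) {
  stopifnot(set_size >= 1)
  if (set_size > length(pools$up) || set_size > length(pools$down))
    stop("set_size exceeds a DEG pool size")
  withr::with_seed(seed, {
    mk <- function(dir, n) {
      pool <- pools[[dir]]
      lapply(seq_len(n), function(i)
        list(set_id = sprintf("%s_%03d", dir, i), direction = dir,
             members = sample(pool, set_size)))
    }
    sets <- c(mk("up", n_up), mk("down", n_down))
  })
  structure(list(sets = sets,
                 provenance = list(seed = seed, set_size = set_size,
                                   pool_size = c(up = length(pools$up),
                                                 down = length(pools$down)))),
            class = "gene_set_collection")
}

#' Write gene sets in GMT format
#'
#' Standard tab-separated GMT lines: set ID, description (the direction
#' here), then the member genes.
#'
#' @param collection a `gene_set_collection`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(collection, path) {
  lines <- vapply(collection$sets, function(s)
    paste(c(s$set_id, s$direction, s$members), collapse = "\t"), "")
  writeLines(lines, path)
  invisible(path)
}

#' Read gene sets from a GMT file
#'
#' @param path GMT file path.
#' @return A `gene_set_collection` (direction taken from the description
#'   field when it is `up`/`down`, otherwise `NA`).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3) stop("malformed GMT line: ", substr(l, 1, 40))
    list(set_id = f[1],
         direction = if (f[2] %in% c("up", "down")) f[2] else NA_character_,
         members = f[-(1:2)])
  })
  ids <- vapply(sets, `[[`, "", "set_id")
  if (anyDuplicated(ids)) stop("duplicate set IDs in GMT file")
  structure(list(sets = sets, provenance = list(source = path)),
            class = "gene_set_collection")
}
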