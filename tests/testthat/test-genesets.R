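test_that("normality gate flags skew and accepts normal quantiles", {
  # right-skewed squared normals are rejected nearly always
  rejected <- vapply(1:20, function(s) {
    withr::with_seed(300 + s, x <- rnorm(500)^2)
    !normality_gate(x)$is_normal
  }, TRUE)
  expect_gte(sum(rejected), 19)

  # exact standard-normal quantiles pass
  q <- qnorm(seq_len(100) / 101)
  expect_true(normality_gate(q)$is_normal)

  expect_error(normality_gate(c(1, 2)), "at least 3")
  # > 5000 values are reduced deterministically, not an error
  withr::with_seed(1, big <- rnorm(6000))
  expect_true(normality_gate(big)$is_normal)
})

test_that("Wilcoxon rank-sum: exact micro-cases and symmetry", {
  expect_equal(wilcoxon_rank_sum(c(1, 2), c(3, 4)), 1 / 3)
  expect_equal(wilcoxon_rank_sum(c(5, 9, 2), c(5, 9, 2)), 1)
  withr::with_seed(31, {
    x <- rnorm(7); y <- rnorm(12)
  })
  expect_equal(wilcoxon_rank_sum(x, y), wilcoxon_rank_sum(y, x))
})

test_that("Wilcoxon agrees with wilcox.test in both regimes", {
  withr::with_seed(32, {
    for (i in 1:25) {
      # exact regime: small tie-free samples
      x <- runif(sample(2:6, 1)); y <- runif(sample(2:6, 1))
      expect_equal(wilcoxon_rank_sum(x, y),
                   wilcox.test(x, y, exact = TRUE)$p.value,
                   tolerance = 1e-12)
      # approximate regime: larger samples with forced ties
      xa <- sample(1:6, 15, replace = TRUE)
      ya <- sample(1:6, 18, replace = TRUE)
      expect_equal(wilcoxon_rank_sum(xa, ya),
                   suppressWarnings(
                     wilcox.test(xa, ya, exact = FALSE,
                                 correct = TRUE)$p.value),
                   tolerance = 1e-10)
    }
  })
})

test_that("gene-set sampling is uniform without replacement and seeded", {
  pools <- structure(list(up = sprintf("u%03d", 1:50),
                          down = sprintf("d%03d", 1:50)),
                     class = "deg_pools")
  gs <- sample_gene_sets(pools, set_size = 10, seed = 77)
  expect_length(gs$sets, 200)
  dirs <- vapply(gs$sets, `[[`, "", "direction")
  expect_equal(unname(table(dirs)[c("up", "down")]), c(100L, 100L),
               ignore_attr = TRUE)
  for (s in gs$sets) {
    expect_length(s$members, 10)
    expect_false(anyDuplicated(s$members) > 0)
    expect_true(all(s$members %in% pools[[s$direction]]))
  }
  expect_identical(sample_gene_sets(pools, 10, seed = 77), gs)
  gs2 <- sample_gene_sets(pools, 10, seed = 78)
  expect_false(identical(lapply(gs$sets, `[[`, "members"),
                         lapply(gs2$sets, `[[`, "members")))

  # set_size equal to the pool makes every set the full pool
  gs3 <- sample_gene_sets(pools, 50, n_up = 3, n_down = 3, seed = 1)
  for (s in gs3$sets)
    expect_setequal(s$members, pools[[s$direction]])
  expect_error(sample_gene_sets(pools, 51, seed = 1), "exceeds")
})

test_that("GMT files round-trip", {
  pools <- structure(list(up = sprintf("u%03d", 1:30),
                          down = sprintf("d%03d", 1:30)),
                     class = "deg_pools")
  gs <- sample_gene_sets(pools, 5, n_up = 4, n_down = 4, seed = 3)
  p <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(gs, p)
  back <- read_gmt(p)
  expect_identical(lapply(back$sets, `[[`, "members"),
                   lapply(gs$sets, `[[`, "members"))
  expect_identical(vapply(back$sets, `[[`, "", "direction"),
                   vapply(gs$sets, `[[`, "", "direction"))
})

scan_fixture <- function(seed, effect_mean = 1, n_genes = 600,
                         n_train = c(25, 25)) {
  sim <- simulate_cohort_pair(n_genes = n_genes, n_train = n_train,
                              n_test = c(5, 5), effect_mean = effect_mean,
                              seed = seed)
  tr <- transform_counts(remove_rbc_genes(sim$train))$matrix
  de <- differential_expression(tr, sim$train_pheno)
  pools <- suppressWarnings(rank_degs(de, 200))
  list(m = tr, pheno = sim$train_pheno, pools = pools)
}

test_that("size scan emits one record per grid value, reproducibly", {
  fx <- scan_fixture(41)
  grid <- c(10, 30, 60, 120)
  sc <- scan_set_sizes(fx$m, fx$pheno, fx$pools, grid = grid,
                       reps_per_direction = 5, seed = 9)
  expect_equal(nrow(sc$table), length(grid))
  expect_equal(sc$table$size, grid)
  expect_true(sc$chosen_size %in% grid)
  expect_true(sc$chosen_size >= sc$chosen_range[1] &&
                sc$chosen_size <= sc$chosen_range[2])
  sc2 <- scan_set_sizes(fx$m, fx$pheno, fx$pools, grid = grid,
                        reps_per_direction = 5, seed = 9)
  expect_identical(sc, sc2)

  expect_warning(scan_set_sizes(fx$m, fx$pheno, fx$pools,
                                grid = c(10, 5000),
                                reps_per_direction = 2, seed = 1),
                 "clamped")
})

test_that("null-label scans show flat mid-range p-values", {
  # permuted labels: median rank-sum p per size should hover mid-range
  meds <- NULL
  for (s in 1:3) {
    fx <- scan_fixture(50 + s, effect_mean = 0)
    ph <- fx$pheno
    ph$label <- withr::with_seed(60 + s, sample(ph$label))
    sc <- suppressWarnings(
      scan_set_sizes(fx$m, ph, fx$pools,
                     grid = c(10, 25, 50, 100, 150, 200),
                     reps_per_direction = 20, seed = 70 + s))
    meds <- rbind(meds, sc$table$p_median)
    expect_false(sc$stable_significance)
  }
  frac_mid <- mean(meds >= 0.2 & meds <= 0.8)
  expect_gte(frac_mid, 0.8)
})
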