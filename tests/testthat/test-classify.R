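test_that("tuning grid candidates respect their bounds", {
  g <- rf_grid(200, 120)
  expect_true(all(g$mtry >= 1 & g$mtry <= 200))
  expect_true(all(g$min_n >= 2 & g$min_n <= 120))
  expect_equal(g$n_trees, 1000L)
  expect_equal(rf_grid(4, 50)$mtry, sort(unique(c(1L, 2L, 4L, 1L))))
})

test_that("forest tuning selects, refits and predicts deterministically", {
  fx <- separable_fixture()
  grid <- rf_grid(2, 60, mtry = 1, min_n = 5, n_trees = 100)
  m <- tune_and_fit(fx$x, fx$y, grid = grid, folds = 5, repeats = 1,
                    seed = 13)
  expect_equal(nrow(m$cv_table), 1)
  expect_identical(m$best_params, list(mtry = 1L, min_n = 5L))
  expect_gte(m$cv_table$mean_accuracy, 0.95)

  # trivially separable data: every grid point is near-perfect
  grid2 <- rf_grid(2, 60, mtry = c(1, 2), min_n = c(2, 10), n_trees = 100)
  m2 <- tune_and_fit(fx$x, fx$y, grid = grid2, folds = 5, repeats = 2,
                     seed = 14)
  expect_true(all(m2$cv_table$mean_accuracy >= 0.95))
  pr <- predict_scores(m2, fx$x)
  expect_gte(mean((pr >= 0.5) == (fx$y == "disease")), 0.95)

  # determinism contract
  m3 <- tune_and_fit(fx$x, fx$y, grid = grid2, folds = 5, repeats = 2,
                     seed = 14)
  expect_identical(m3$cv_table, m2$cv_table)
  expect_identical(m3$best_params, m2$best_params)
  expect_identical(predict_scores(m3, fx$x), pr)

  expect_error(tune_and_fit(fx$x, rep("disease", nrow(fx$x)),
                            grid = grid, seed = 1),
               "single class")
})

test_that("prediction aligns features by name", {
  fx <- separable_fixture()
  m <- tune_and_fit(fx$x, fx$y,
                    grid = rf_grid(2, 60, mtry = 1, min_n = 5,
                                   n_trees = 50),
                    folds = 5, repeats = 1, seed = 3)
  swapped <- fx$x[, c("f2", "f1")]
  expect_identical(predict_scores(m, swapped), predict_scores(m, fx$x))

  extra <- cbind(fx$x, f3 = 1)
  expect_warning(pr <- predict_scores(m, extra), "extra")
  expect_identical(pr, predict_scores(m, fx$x))

  expect_error(predict_scores(m, fx$x[, "f1", drop = FALSE]), "f2")
})

test_that("fold assignment is stratified", {
  y <- rep(c("disease", "control"), c(21, 34))
  withr::with_seed(8, fold <- wbtdc:::stratified_folds(y, 5))
  for (f in 1:5) {
    tab <- table(y[fold == f])
    expect_true(abs(tab["disease"] - 21 / 5) <= 1)
    expect_true(abs(tab["control"] - 34 / 5) <= 1)
  }
})

test_that("metrics match their closed forms and the all-pairs oracle", {
  m <- compute_metrics(c(0.9, 0.8, 0.7, 0.85),
                       c("disease", "disease", "control", "control"))
  expect_equal(m$roc_auc, 0.75) # 3 of 4 pairs concordant
  expect_equal(m$n_test, 4)
  expect_equal(sum(m$confusion), 4)

  perfect <- compute_metrics(c(0.99, 0.95, 0.05, 0.01),
                             c("disease", "disease", "control", "control"))
  expect_equal(perfect$roc_auc, 1)
  expect_equal(perfect$balanced_accuracy, 1)

  ties <- compute_metrics(rep(0.4, 6), rep(c("disease", "control"), 3))
  expect_equal(ties$roc_auc, 0.5)

  # balanced classes with symmetric errors: balanced accuracy == accuracy
  sym <- compute_metrics(c(0.9, 0.2, 0.8, 0.3),
                         c("disease", "disease", "control", "control"))
  expect_equal(sym$balanced_accuracy, sym$accuracy)

  # ROC curve is a monotone staircase from (0,0) to (1,1)
  withr::with_seed(15, {
    sc <- round(runif(40), 2)
    tr <- sample(c("disease", "control"), 40, replace = TRUE)
  })
  mm <- compute_metrics(sc, tr)
  expect_true(all(diff(mm$roc_points$fpr) >= 0))
  expect_true(all(diff(mm$roc_points$tpr) >= 0))
  expect_equal(unlist(mm$roc_points[1, 1:2]), c(fpr = 0, tpr = 0))
  expect_equal(unlist(mm$roc_points[nrow(mm$roc_points), 1:2]),
               c(fpr = 1, tpr = 1))
  expect_equal(mm$roc_auc, bf_auc(sc, tr == "disease"), tolerance = 1e-12)

  expect_warning(one <- compute_metrics(c(0.6, 0.7),
                                        c("disease", "disease")),
                 "undefined")
  expect_true(is.na(one$roc_auc))
  expect_equal(one$accuracy, 1)
})

test_that("conventional features carry the top DEGs shared by both arms", {
  withr::with_seed(33, {
    x_tr <- matrix(rnorm(30 * 8, 5), 30, 8)
    x_te <- matrix(rnorm(30 * 6, 5), 30, 6)
  })
  genes <- sprintf("g%02d", 1:30)
  m_tr <- em_fix(x_tr, genes = genes)
  present <- setdiff(genes, c("g09", "g10", "g21")) # 3 genes missing in test
  m_te <- em_fix(x_te[1:27, ], genes = present)
  de <- structure(data.frame(
    gene_id = genes,
    log2fc = seq(2, -2, length.out = 30),
    pvalue = rep(0.001, 30), padj = rep(0.01, 30),
    direction = rep(c("up", "ns", "down"), each = 10),
    stringsAsFactors = FALSE), class = c("de_table", "data.frame"))

  cf <- conventional_features(m_tr, m_te, de, n_per_direction = 8)
  expect_equal(ncol(cf$train), 16)
  expect_identical(colnames(cf$train), colnames(cf$test))
  # top |log2fc| genes of each direction
  expect_identical(cf$genes[1:8], genes[1:8])
  expect_identical(cf$genes[9], "g30")

  # genes absent from the test matrix leave both arms, with a warning
  expect_warning(cf10 <- conventional_features(m_tr, m_te, de, 10),
                 "dropped")
  expect_equal(ncol(cf10$train), 17)
  expect_identical(colnames(cf10$train), colnames(cf10$test))
  expect_true(all(cf10$genes %in% gene_ids(m_te)))

  cf1 <- conventional_features(m_tr, m_te, de, n_per_direction = 1)
  expect_equal(ncol(cf1$train), 2)

  m_te_tiny <- em_fix(x_te[1:4, ], genes = genes[c(1, 2, 29, 30)])
  expect_error(suppressWarnings(
    conventional_features(m_tr, m_te_tiny, de, 10)), "fewer than 10")
})
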