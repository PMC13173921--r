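#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end pipeline with the stated-world
#' defaults: BH gate 0.05, DEG pools of 200 per direction, 24-point size
#' grid with 500 resamples per direction, 100 + 100 sampled gene sets,
#' Gaussian-kernel scorer with tau = 1 and signed-difference scores, ROSE
#' balancing on, 10-fold x 3 CV over the default forest grid with 1000
#' trees. Every stochastic stage derives its own seed from the single
#' `seed` here.
#'
#' @param seed master integer seed.
#' @param padj_cutoff,pool_size,n_sets,size_grid,reps_per_direction,
#'   plateau_frac DE and size-scan controls (see [differential_expression()],
#'   [rank_degs()], [scan_set_sizes()], [sample_gene_sets()]).
#' @param gsva a [gsva_params()] object.
#' @param iqr_drop IQR-filter drop fraction for microarray-scale matrices;
#'   `iqr_rnaseq` extends the filter to RNA-seq-derived matrices.
#' @param balance apply [rose_oversample()] to training features.
#' @param rf optional [rf_grid()]; `folds`, `repeats` control CV;
#'   `n_trees` the forest size.
#' @param benchmark also run the conventional expression-feature arm.
#' @param n_benchmark_genes DEGs per direction for the conventional arm.
#' @param coding_list optional protein-coding gene IDs; `probe_map`
#'   optional probe-to-gene data.frame for the test matrix.
#' @param set_size override the scan's chosen set size (skips the scan).
#' @return List of class `wbtdc_config`.
#' @export
wbtdc_config <- function(seed = 1, padj_cutoff = 0.05, pool_size = 200,
                         n_sets = 100, size_grid = default_size_grid(),
                         reps_per_direction = 500, plateau_frac = 0.95,
                         gsva = gsva_params(), iqr_drop = 0.25,
                         iqr_rnaseq = FALSE, balance = TRUE, rf = NULL,
                         folds = 10, repeats = 3, n_trees = 1000,
                         benchmark = TRUE, n_benchmark_genes = 100,
                         coding_list = NULL, probe_map = NULL,
                         set_size = NULL) {
  stopifnot(seed == round(seed), padj_cutoff > 0, padj_cutoff < 1,
            pool_size >= 1, n_sets >= 1, reps_per_direction >= 1)
  structure(list(seed = as.integer(seed), padj_cutoff = padj_cutoff,
                 pool_size = pool_size, n_sets = n_sets,
                 size_grid = size_grid,
                 reps_per_direction = reps_per_direction,
                 plateau_frac = plateau_frac, gsva = gsva,
                 iqr_drop = iqr_drop, iqr_rnaseq = iqr_rnaseq,
                 balance = balance, rf = rf, folds = folds,
                 repeats = repeats, n_trees = n_trees,
                 benchmark = benchmark,
                 n_benchmark_genes = n_benchmark_genes,
                 coding_list = coding_list, probe_map = probe_map,
                 set_size = set_size),
            class = "wbtdc_config")
}

checksum <- function(x) fnv1a_hash_cpp(serialize(x, NULL, version = 2))

# preprocessing shared by both cohorts; stage log rides along
preprocess_matrix <- function(em, config) {
  log <- list()
  note <- function(stage, m) {
    log[[stage]] <<- c(genes = nrow(m$values), samples = ncol(m$values))
    m
  }
  em <- note("input", em)
  em <- note("rbc_removed", remove_rbc_genes(em))
  if (!is.null(config$probe_map) && em$value_scale == "log2_intensity")
    em <- note("probes_collapsed", collapse_probes(em, config$probe_map))
  if (!is.null(config$coding_list))
    em <- note("coding_restricted",
               restrict_to_coding(em, config$coding_list))
  params <- NULL
  if (em$value_scale == "counts") {
    tc <- transform_counts(em)
    em <- note("counts_transformed", tc$matrix)
    params <- tc$params
    if (config$iqr_rnaseq && config$iqr_drop > 0)
      em <- note("iqr_filtered", iqr_filter(em, config$iqr_drop))
  } else if (config$iqr_drop > 0) {
    em <- note("iqr_filtered", iqr_filter(em, config$iqr_drop))
  }
  list(matrix = em, log = log, transform_params = params)
}

#' Run the whole pipeline on a training/testing cohort pair
#'
#' End-to-end orchestration: preprocess both cohorts (globin removal,
#' optional probe collapsing and coding restriction, count transformation,
#' IQR filter), differential expression and DEG pools on the training
#' cohort only, gene-set size scan, random gene-set sampling, enrichment
#' scoring of each cohort on its own matrix, ROSE balancing of the training
#' features, random-forest tuning and fitting, and evaluation on the test
#' cohort — plus, by default, the conventional expression-feature benchmark
#' arm under the identical protocol. The test cohort never feeds any
#' training-side stage; sample-ID disjointness is asserted.
#'
#' @param train,test `expr_matrix` objects (training counts or log2 scale;
#'   test any log2-like scale).
#' @param train_pheno,test_pheno phenotype tables.
#' @param config a [wbtdc_config()].
#' @return A `wbtdc_run`: list with `metrics` (WBT-DC arm
#'   `metrics_report`), `metrics_conventional` (or `NULL`), `model`,
#'   `model_conventional`, `de`, `scan`, `sets`, `manifest`.
#' @export
run_wbt_dc <- function(train, train_pheno, test, test_pheno, config) {
  stopifnot(inherits(config, "wbtdc_config"))
  if (length(intersect(train_pheno$sample_id, test_pheno$sample_id)) > 0)
    stop("train and test cohorts share sample IDs; refusing to continue")
  seed <- config$seed
  stage_log <- list()

  a_tr <- align_samples(train, train_pheno)
  a_te <- align_samples(test, test_pheno)
  pp_tr <- preprocess_matrix(a_tr$matrix, config)
  pp_te <- preprocess_matrix(a_te$matrix, config)
  stage_log$train <- pp_tr$log
  stage_log$test <- pp_te$log
  m_tr <- pp_tr$matrix
  m_te <- pp_te$matrix

  de <- differential_expression(m_tr, a_tr$pheno, config$padj_cutoff)
  pools <- suppressWarnings(rank_degs(de, config$pool_size))

  if (is.null(config$set_size)) {
    pool_builder <- function(ph)
      rank_degs(differential_expression(m_tr, ph, config$padj_cutoff),
                config$pool_size)
    scan <- suppressWarnings(scan_set_sizes(
      m_tr, a_tr$pheno, pools, grid = config$size_grid,
      reps_per_direction = config$reps_per_direction, seed = seed + 1L,
      params = config$gsva, plateau_frac = config$plateau_frac,
      pool_builder = pool_builder))
    set_size <- scan$chosen_size
  } else {
    scan <- NULL
    set_size <- config$set_size
  }
  set_size <- min(set_size, length(pools$up), length(pools$down))
  sets <- sample_gene_sets(pools, set_size, config$n_sets, config$n_sets,
                           seed = seed + 2L)

  feats_tr <- t(suppressWarnings(gsva_scores(m_tr, sets, config$gsva)))
  feats_te <- t(suppressWarnings(gsva_scores(m_te, sets, config$gsva)))

  fit_arm <- function(ftr, labels, fte, seed_off) {
    if (config$balance) {
      bal <- rose_oversample(ftr, labels, seed = seed + seed_off)
      stopifnot(!any(rownames(bal$features) %in% test_pheno$sample_id))
      ftr <- bal$features
      labels <- bal$labels
    }
    grid <- config$rf
    if (is.null(grid))
      grid <- rf_grid(ncol(ftr), nrow(ftr), n_trees = config$n_trees)
    model <- tune_and_fit(ftr, labels, grid = grid, folds = config$folds,
                          repeats = config$repeats, seed = seed + seed_off + 1L)
    scores <- predict_scores(model, fte)
    list(model = model, scores = scores)
  }

  arm <- fit_arm(feats_tr, a_tr$pheno$label, feats_te, 3L)
  metrics <- compute_metrics(arm$scores,
                             a_te$pheno$label[match(names(arm$scores),
                                                    a_te$pheno$sample_id)])

  arm_c <- NULL
  metrics_c <- NULL
  if (config$benchmark) {
    cf <- suppressWarnings(conventional_features(
      m_tr, m_te, de, config$n_benchmark_genes))
    arm_c <- fit_arm(cf$train, a_tr$pheno$label, cf$test, 5L)
    metrics_c <- compute_metrics(
      arm_c$scores,
      a_te$pheno$label[match(names(arm_c$scores), a_te$pheno$sample_id)])
  }

  cfg_plain <- config[setdiff(names(config), c("probe_map", "coding_list"))]
  cfg_plain$gsva <- unclass(cfg_plain$gsva)
  if (!is.null(cfg_plain$rf)) cfg_plain$rf <- unclass(cfg_plain$rf)
  manifest <- list(
    package_version = as.character(utils::packageVersion("wbtdc")),
    seed = seed,
    config = cfg_plain,
    set_size = set_size,
    stage_log = stage_log,
    checksums = list(
      train_input = checksum(train$values),
      test_input = checksum(test$values),
      train_preprocessed = checksum(m_tr$values),
      test_preprocessed = checksum(m_te$values),
      de_table = checksum(de),
      gene_sets = checksum(lapply(sets$sets, `[[`, "members")),
      train_features = checksum(feats_tr),
      test_features = checksum(feats_te),
      scores = checksum(arm$scores),
      scores_conventional = if (is.null(arm_c)) NULL
                            else checksum(arm_c$scores)))

  structure(list(metrics = metrics, metrics_conventional = metrics_c,
                 model = arm$model,
                 model_conventional = if (is.null(arm_c)) NULL
                                      else arm_c$model,
                 scores = arm$scores,
                 scores_conventional = if (is.null(arm_c)) NULL
                                       else arm_c$scores,
                 de = de, scan = scan, sets = sets,
                 manifest = manifest),
            class = "wbtdc_run")
}

#' @export
print.wbtdc_run <- function(x, ...) {
  cat("WBT-DC arm:          "); print(x$metrics)
  if (!is.null(x$metrics_conventional)) {
    cat("conventional arm:    "); print(x$metrics_conventional)
  }
  cat(sprintf("gene sets: %d x %d genes (chosen size %d)\n",
              length(x$sets$sets), x$sets$provenance$set_size,
              x$manifest$set_size))
  invisible(x)
}

#' Write a run manifest as JSON
#'
#' @param run a `wbtdc_run`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(run, path) {
  jsonlite::write_json(run$manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}
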