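#' Simulate a paired training/testing cohort with platform shift
#'
#' Generates the world the pipeline is designed for: a shared disease signal
#' observed through two different assay platforms. The training cohort is
#' RNA-seq-like — negative-binomial counts with log-normal per-gene
#' baselines and per-sample library-size jitter; disease samples shift the
#' differentially expressed (DE) genes by per-gene log2 effects. The testing
#' cohort is microarray-like — Gaussian log2 intensities built from the
#' *same* per-gene baselines and effects, then distorted by a
#' disease-independent platform shift: per-gene affine jitter (scale and
#' offset on the log2 scale) plus an optional global monotone warp
#' (`x -> x^0.8` on the linear scale). Samples therefore cluster by cohort
#' before they cluster by disease status, which is exactly the cross-platform
#' transfer problem.
#'
#' Three globin genes (HBB, HBA2, HBA1) with extreme baselines are appended
#' so the red-blood-cell filter always has work to do. DE genes are placed
#' uniformly across the baseline-expression range so the IQR filter does not
#' silently remove them.
#'
#' @param n_genes simulated genes (before the 3 appended globins).
#' @param n_train,n_test `(disease, control)` sample counts.
#' @param n_de `(up, down)` DE gene counts.
#' @param effect_mean mean per-gene log2 effect size; each DE gene's effect
#'   is `effect_mean * Uniform(0.5, 1.5)`, so 0 gives an exact null.
#' @param noise_sd test-cohort biological noise SD on the log2 scale.
#' @param nb_dispersion negative-binomial dispersion of the count model.
#' @param platform_scale_sd,platform_offset_sd SDs of the per-gene log-scale
#'   jitter and log2 offset of the platform shift; set both to 0 (and
#'   `warp = FALSE`) for a shift-free pair.
#' @param warp apply the global monotone warp.
#' @param seed integer seed; matrices are bit-reproducible given it.
#' @return List with `train` / `train_pheno` (counts + phenotype),
#'   `test` / `test_pheno` (log2 intensities + phenotype) and `truth` (DE
#'   gene lists, effect sizes, platform-shift parameters, seed).
#' @export
simulate_cohort_pair <- function(n_genes = 2000, n_train = c(60, 60),
                                 n_test = c(40, 40), n_de = c(100, 100),
                                 effect_mean = 1.0, noise_sd = 0.5,
                                 nb_dispersion = 0.1,
                                 platform_scale_sd = 0.2,
                                 platform_offset_sd = 1.0, warp = TRUE,
                                 seed = 1) {
  stopifnot(n_genes >= sum(n_de) + 10, all(n_train >= 2), all(n_test >= 2),
            effect_mean >= 0, noise_sd >= 0, nb_dispersion > 0,
            platform_scale_sd >= 0, platform_offset_sd >= 0)
  withr::with_seed(seed, {
    ids <- sprintf("g%05d", seq_len(n_genes))
    base_log2 <- log2(rlnorm_vec(n_genes, log(100), 1))
    # DE genes spread evenly over the baseline range, up/down interleaved
    o <- order(base_log2)
    slots <- o[round(seq(1, n_genes, length.out = sum(n_de)))]
    de_up <- ids[slots[seq_len(n_de[1])]]
    de_down <- ids[slots[n_de[1] + seq_len(n_de[2])]]
    eff_up <- effect_mean * runif(n_de[1], 0.5, 1.5)
    eff_down <- effect_mean * runif(n_de[2], 0.5, 1.5)
    shift <- setNames(numeric(n_genes), ids)
    shift[de_up] <- eff_up
    shift[de_down] <- -eff_down

    # globins: enormous baseline, no disease signal
    glob <- c("HBB", "HBA2", "HBA1")
    ids_all <- c(ids, glob)
    base_all <- c(base_log2, log2(c(5e4, 3e4, 3e4)))
    shift_all <- c(shift, setNames(c(0, 0, 0), glob))
    p <- length(ids_all)

    mk_pheno <- function(prefix, n_dc) {
      phenotype_table(
        sprintf("%s_%03d", prefix, seq_len(sum(n_dc))),
        rep(c("disease", "control"), n_dc))
    }
    train_pheno <- mk_pheno("tr", n_train)
    test_pheno <- mk_pheno("te", n_test)

    # training cohort: NB counts, per-sample library factor
    nt <- nrow(train_pheno)
    lib <- rlnorm_vec(nt, 0, 0.15)
    mu <- 2^(base_all + outer(shift_all,
                              as.numeric(train_pheno$label == "disease")))
    mu <- sweep(mu, 2, lib, "*")
    counts <- matrix(rnbinom(p * nt, size = 1 / nb_dispersion, mu = mu),
                     p, nt, dimnames = list(ids_all, train_pheno$sample_id))
    train <- expression_matrix(counts, "counts", "rnaseq-sim")

    # testing cohort: same log2 signal model, then platform distortion
    ns <- nrow(test_pheno)
    sig <- base_all + outer(shift_all,
                            as.numeric(test_pheno$label == "disease")) +
      matrix(rnorm(p * ns, 0, noise_sd), p, ns)
    a <- exp(rnorm(p, 0, platform_scale_sd))
    b <- rnorm(p, 0, platform_offset_sd)
    y <- sig
    if (warp) y <- y * 0.8 # x -> x^0.8 on the linear scale
    y <- y * a + b
    dimnames(y) <- list(ids_all, test_pheno$sample_id)
    test <- expression_matrix(y, "log2_intensity", "array-sim")
  })
  list(train = train, train_pheno = train_pheno,
       test = test, test_pheno = test_pheno,
       truth = list(de_genes_up = de_up, de_genes_down = de_down,
                    effect_sizes = c(setNames(eff_up, de_up),
                                     setNames(-eff_down, de_down)),
                    baseline_log2 = setNames(base_all, ids_all),
                    platform_shift = list(scale_sd = platform_scale_sd,
                                          offset_sd = platform_offset_sd,
                                          scale = setNames(a, ids_all),
                                          offset = setNames(b, ids_all),
                                          warp = warp),
                    noise_sd = noise_sd, nb_dispersion = nb_dispersion,
                    seed = seed))
}

rlnorm_vec <- function(n, meanlog, sdlog) exp(rnorm(n, meanlog, sdlog))

#' Inject class imbalance into a phenotype table
#'
#' Subsamples one class so that minority/majority = `ratio`, to exercise
#' the oversampling stage.
#'
#' @param pheno phenotype table.
#' @param ratio target minority/majority ratio in `(0, 1)`.
#' @param seed integer seed.
#' @param shrink_class which class to subsample, default `"control"`.
#' @return The reduced phenotype table.
#' @export
inject_imbalance <- function(pheno, ratio, seed = 1,
                             shrink_class = c("control", "disease")) {
  stopifnot(ratio > 0, ratio < 1)
  shrink_class <- match.arg(shrink_class)
  idx <- which(pheno$label == shrink_class)
  other <- sum(pheno$label != shrink_class)
  n_keep <- round(ratio * other)
  if (n_keep < 4) stop("imbalance would leave fewer than 4 samples")
  if (n_keep >= length(idx)) stop("class already at or below target ratio")
  withr::with_seed(seed, keep <- sort(sample(idx, n_keep)))
  out <- pheno[sort(c(which(pheno$label != shrink_class), keep)), ,
               drop = FALSE]
  rownames(out) <- NULL
  out
}
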