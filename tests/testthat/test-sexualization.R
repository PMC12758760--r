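test_that("log2 ratio vectors follow the pseudocount definition", {
  norm <- rbind(a = c(8, 8, 2, 2), b = c(5, 5, 5, 5), c = c(0, 0, 0, 0))
  colnames(norm) <- sprintf("s%d", 1:4)
  num <- c("s1", "s2"); den <- c("s3", "s4")
  r0 <- log2_ratio_vector(norm, num, den, pseudocount = 0)
  expect_equal(unname(r0["a"]), 2)
  expect_equal(unname(r0["b"]), 0)
  r <- log2_ratio_vector(norm, num, den, pseudocount = 0.5)
  expect_equal(unname(r["c"]), 0)  # both means zero: pseudocount guards
  expect_error(log2_ratio_vector(norm, character(0), den), "empty")
  expect_warning(log2_ratio_vector(norm, num, den, genes = c("a", "nope")),
                 "absent")
})

test_that("IQR outlier fences match hand computation under type-7 quartiles", {
  # [1,2,3,4,100]: Q1 = 2, Q3 = 4, upper fence 7 -> only 100 flagged
  expect_equal(iqr_outlier_mask(c(1, 2, 3, 4, 100)),
               c(FALSE, FALSE, FALSE, FALSE, TRUE))
  # constant vector: IQR 0, values on the fences, strict inequality keeps all
  expect_equal(iqr_outlier_mask(rep(3, 6)), rep(FALSE, 6))
  # symmetric without extremes
  expect_equal(iqr_outlier_mask(c(-2, -1, 0, 1, 2)), rep(FALSE, 5))
  expect_warning(flags <- iqr_outlier_mask(c(1, 2, 3)), "fewer than 4")
  expect_equal(flags, rep(FALSE, 3))
})

test_that("Spearman rho is Pearson on mean ranks", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(spearman_rho(x, x^3), 1)
  expect_equal(spearman_rho(x, -exp(x)), -1)
  # ties resolved by mean ranks, checked against brute force
  xt <- c(1, 1, 2, 3); yt <- c(2, 3, 1, 4)
  expect_equal(spearman_rho(xt, yt), spearman_brute(xt, yt), tolerance = 1e-12)
  set.seed(6)
  for (i in 1:10) {
    a <- sample(1:5, 20, replace = TRUE)
    b <- sample(1:5, 20, replace = TRUE)
    if (sd(a) == 0 || sd(b) == 0) next
    expect_equal(spearman_rho(a, b), spearman_brute(a, b), tolerance = 1e-12)
  }
  expect_true(is.na(spearman_rho(rep(1, 5), 1:5)))
  expect_error(spearman_rho(1:2, 1:2), "at least 3")
})

test_that("the permutation test is reproducible and p lies on the +1 grid", {
  fix <- sexualization_fixture(300, seed = 31)
  panel <- rownames(fix$counts)[1:40]
  r1 <- sexualization_permutation_test(fix$counts, fix$samples, panel,
                                       knockout_sex = "F", n_perm = 99,
                                       seed = 12)
  r2 <- sexualization_permutation_test(fix$counts, fix$samples, panel,
                                       knockout_sex = "F", n_perm = 99,
                                       seed = 12)
  expect_identical(r1$rho_null, r2$rho_null)
  expect_identical(r1$p_one_sided, r2$p_one_sided)
  expect_gt(r1$p_one_sided, 0)
  expect_lte(r1$p_one_sided, 1)
  # p sits on the k/(n_perm+1) grid
  expect_true(abs(r1$p_one_sided * 100 - round(r1$p_one_sided * 100)) < 1e-9)
  expect_equal(r1$direction, "masculinization")
  # opposite-tail accounting on the same null distribution
  ge <- sum(r1$rho_null >= r1$rho_observed)
  le <- sum(r1$rho_null <= r1$rho_observed)
  ties <- sum(r1$rho_null == r1$rho_observed)
  expect_equal(ge + le, length(r1$rho_null) + ties)
  expect_equal(r1$p_one_sided, (1 + ge) / (length(r1$rho_null) + 1))
})

test_that("male knockouts test the feminization (lower) tail", {
  fix <- sexualization_fixture(200, knockout_sex = "M", seed = 8)
  panel <- rownames(fix$counts)[1:30]
  r <- sexualization_permutation_test(fix$counts, fix$samples, panel,
                                      knockout_sex = "M", n_perm = 49,
                                      seed = 4)
  expect_equal(r$direction, "feminization")
  le <- sum(r$rho_null <= r$rho_observed)
  expect_equal(r$p_one_sided, (1 + le) / (length(r$rho_null) + 1))
})

test_that("exhaustive enumeration matches an independent oracle", {
  fix <- sexualization_fixture(15, n_per_group = 3, knockout_sex = "F",
                               dispersion = 0.1, seed = 77)
  cm <- fix$counts
  panel <- rownames(cm)[1:3]
  pool <- rownames(cm)[4:15]
  got <- sexualization_permutation_test(cm, fix$samples, panel,
                                        knockout_sex = "F",
                                        exhaustive = TRUE)
  expect_equal(got$n_perm, choose(12, 3))

  # oracle: everything recomputed from the raw counts with naive code
  sf_o <- size_factors_brute(cm)
  norm_o <- sweep(cm, 2, sf_o, "/")
  wt_m <- fix$samples$sample_id[fix$samples$genotype == "wildtype" &
                                  fix$samples$sex == "M"]
  wt_f <- fix$samples$sample_id[fix$samples$genotype == "wildtype" &
                                  fix$samples$sex == "F"]
  ko <- fix$samples$sample_id[fix$samples$genotype == "knockout"]
  x <- log2((rowMeans(norm_o[, wt_m]) + 0.5) / (rowMeans(norm_o[, wt_f]) + 0.5))
  y <- log2((rowMeans(norm_o[, ko]) + 0.5) / (rowMeans(norm_o[, wt_f]) + 0.5))
  mask_o <- function(v) {
    if (length(v) < 4) return(rep(FALSE, length(v)))
    q <- quantile(v, c(0.25, 0.75), type = 7, names = FALSE)
    v > q[2] + 1.5 * (q[2] - q[1]) | v < q[1] - 1.5 * (q[2] - q[1])
  }
  rho_o <- function(idx) {
    xx <- x[idx]; yy <- y[idx]
    drop <- mask_o(xx) | mask_o(yy)
    if (sum(!drop) < 3) return(NA_real_)
    spearman_brute(xx[!drop], yy[!drop])
  }
  obs_o <- rho_o(panel)
  nulls_o <- vapply(combn(pool, 3, simplify = FALSE), rho_o, numeric(1))
  p_o <- (1 + sum(nulls_o >= obs_o, na.rm = TRUE)) / (length(nulls_o) + 1)
  expect_equal(got$rho_observed, obs_o, tolerance = 1e-12)
  expect_equal(sort(got$rho_null), sort(nulls_o), tolerance = 1e-12)
  expect_equal(got$p_one_sided, p_o, tolerance = 1e-12)
})

test_that("a knockout copying the male-female axis on the panel is detected", {
  cfg <- simulation_config(n_genes = 1000, panel_size = 60,
                           panel_ko_copy_sex = TRUE, n_sex_biased = 0,
                           n_ko_dysregulated = 0, lane_effect_log2 = 0,
                           seed = 3)
  sim <- simulate_counts(cfg)
  keep <- sim$samples$line == "dmrt1.L"
  cm <- sim$counts[, sim$samples$sample_id[keep]]
  smp <- sim$samples[keep, ]
  panel <- sim$annotation$gene_id[sim$annotation$is_panel_member]
  r <- sexualization_permutation_test(cm, smp, panel, knockout_sex = "F",
                                      n_perm = 199, seed = 15)
  expect_gt(r$rho_observed, 0.7)
  expect_lte(r$p_one_sided, 0.05)
})

test_that("pool smaller than the panel and bad n_perm raise errors", {
  fix <- sexualization_fixture(10, seed = 2)
  panel <- rownames(fix$counts)[1:8]
  expect_error(sexualization_permutation_test(fix$counts, fix$samples, panel,
                                              knockout_sex = "F", n_perm = 10),
               "pool")
  expect_error(sexualization_permutation_test(fix$counts, fix$samples,
                                              rownames(fix$counts)[1:4],
                                              knockout_sex = "F", n_perm = 0),
               "n_perm")
})
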