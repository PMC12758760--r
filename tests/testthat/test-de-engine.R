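test_that("size factors follow the median-of-ratios closed form", {
  a <- c(10L, 20L, 40L, 8L)
  cm <- cbind(s1 = a, s2 = 2L * a)
  rownames(cm) <- sprintf("g%d.L", 1:4)
  sf <- size_factors(cm)
  # proportional columns give factors (1/sqrt(2), sqrt(2))
  expect_equal(unname(sf), c(1 / sqrt(2), sqrt(2)), tolerance = 1e-12)
  # identical columns -> all ones; single sample -> 1
  cm2 <- cbind(s1 = a, s2 = a, s3 = a)
  rownames(cm2) <- rownames(cm)
  expect_equal(unname(size_factors(cm2)), rep(1, 3))
  expect_equal(unname(size_factors(cm[, 1, drop = FALSE])), 1)
  # agrees with an independent implementation on random matrices
  set.seed(3)
  cm3 <- matrix(rpois(200 * 6, 50) + 1L, nrow = 200,
                dimnames = list(sprintf("g%03d", 1:200), sprintf("s%d", 1:6)))
  expect_equal(unname(size_factors(cm3)), unname(size_factors_brute(cm3)),
               tolerance = 1e-10)
  expect_error(size_factors(matrix(0L, 2, 2,
                                   dimnames = list(c("a", "b"), c("x", "y")))),
               "all-zero")
})

test_that("dispersion estimation recovers the simulated regimes", {
  set.seed(42)
  sf50 <- setNames(rep(1, 50), sprintf("s%d", 1:50))
  # Poisson data (true dispersion 0): unshrunk estimates sit at the floor
  cm_pois <- matrix(rpois(2000 * 50, 100), nrow = 2000,
                    dimnames = list(sprintf("g%04d", 1:2000), names(sf50)))
  d0 <- estimate_dispersions(cm_pois, sf50, shrink = 0)
  expect_lte(median(d0), 2e-8)
  # NB data with dispersion 0.1 at high means
  cm_nb <- matrix(rnbinom(2000 * 50, mu = 200, size = 10), nrow = 2000,
                  dimnames = dimnames(cm_pois))
  d1 <- estimate_dispersions(cm_nb, sf50)
  expect_gte(median(d1), 0.05)
  expect_lte(median(d1), 0.2)
  # zero-variance gene pinned at the floor without shrinkage
  cm_const <- rbind(flat = rep(50L, 10), varying = rpois(10, 50))
  colnames(cm_const) <- sprintf("s%d", 1:10)
  d2 <- estimate_dispersions(cm_const, setNames(rep(1, 10), colnames(cm_const)),
                             shrink = 0)
  expect_equal(unname(d2["flat"]), 1e-8)
  expect_true(all(d1 > 0) && all(d0 > 0))
})

test_that("the Wald test recovers simulated effects with correct signs", {
  lfc <- rep(0, 1000)
  set.seed(11)
  idx <- sample(1000, 100)
  lfc[idx] <- sample(c(-2, 2), 100, replace = TRUE)
  fix <- two_group_fixture(1000, 6, dispersion = 0.05, lfc = lfc, seed = 11)
  res <- de_test(fix$counts, fix$samples,
                 contrast = list(factor = "genotype",
                                 levels = c("wildtype", "knockout")))
  tp <- res$significant & fix$true_lfc != 0
  expect_gt(sum(tp), 50)  # the strong effects are detectable
  expect_gte(mean(sign(res$logFC[tp]) == sign(fix$true_lfc[tp])), 0.95)
  expect_true(all(res$pvalue >= 0 & res$pvalue <= 1))
  expect_true(all(res$qvalue >= res$pvalue - 1e-12))
})

test_that("a relabeled split of identical columns yields no significant gene", {
  set.seed(7)
  col <- rpois(300, 60)
  cm <- matrix(rep(col, 8), nrow = 300,
               dimnames = list(sprintf("g%03d.L", 1:300), sprintf("s%d", 1:8)))
  storage.mode(cm) <- "integer"
  smp <- data.frame(sample_id = colnames(cm), line = "x",
                    genotype = rep(c("wildtype", "knockout"), each = 4),
                    sex = "M", lane = "run1")
  res <- de_test(cm, smp, contrast = list(factor = "genotype",
                                          levels = c("wildtype", "knockout")))
  expect_equal(sum(res$significant), 0)
})

test_that("a missing contrast level raises an error", {
  fix <- two_group_fixture(50, 3, seed = 2)
  smp <- fix$samples
  smp$genotype <- "wildtype"
  expect_error(de_test(fix$counts, smp,
                       contrast = list(factor = "genotype",
                                       levels = c("wildtype", "knockout"))),
               "zero samples")
  expect_error(de_test(fix$counts, fix$samples,
                       contrast = list(factor = "genotype",
                                       levels = c("wildtype", "knockout")),
                       covariates = "nope"),
               "covariates")
})

test_that("complete separation is capped and flagged", {
  set.seed(5)
  cm <- matrix(rpois(20 * 8, 40), nrow = 20,
               dimnames = list(sprintf("g%02d.L", 1:20), sprintf("s%d", 1:8)))
  cm[1, 1:4] <- 0L  # zero in all wildtype samples, positive in knockouts
  smp <- data.frame(sample_id = colnames(cm), line = "x",
                    genotype = rep(c("wildtype", "knockout"), each = 4),
                    sex = "M", lane = "run1")
  res <- de_test(cm, smp, contrast = list(factor = "genotype",
                                          levels = c("wildtype", "knockout")))
  expect_true(res$capped[1])
  expect_lte(abs(res$logFC[1]), 30)
})

test_that("BH adjustment matches hand computations and handles edge cases", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.37), 0.37)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(9)
  for (i in 1:20) {
    p <- runif(sample(3:50, 1))
    expect_equal(bh_adjust(p), bh_brute(p), tolerance = 1e-12)
  }
})

test_that("consensus reports overlap set arithmetic", {
  mk <- function(ids, sig) data.frame(gene_id = ids, significant = sig)
  universe <- letters[1:6]
  A <- mk(universe, universe %in% c("a", "b", "c"))
  B <- mk(universe, universe %in% c("b", "c", "d"))
  out <- consensus_de(A, B)
  expect_equal(out$n_overlap, 2)
  expect_setequal(out$overlap, c("b", "c"))
  expect_equal(consensus_de(A, A)$n_overlap, 3)
  B0 <- mk(universe, universe %in% c("d", "e"))
  expect_equal(consensus_de(A, B0)$n_overlap, 0)
  expect_error(consensus_de(A, mk(LETTERS[1:6], rep(FALSE, 6))), "universes")
})

test_that("null p-values are approximately uniform", {
  fix <- two_group_fixture(1500, 6, dispersion = 0.05, seed = 21)
  res <- de_test(fix$counts, fix$samples,
                 contrast = list(factor = "genotype",
                                 levels = c("wildtype", "knockout")))
  ks <- suppressWarnings(ks.test(res$pvalue, "punif"))$statistic
  expect_lt(unname(ks), 0.08)
})

test_that("scaling one sample rescales its factor and leaves logFC stable", {
  fix <- two_group_fixture(800, 6, dispersion = 0.02, seed = 13)
  cm <- fix$counts
  cm2 <- cm
  cm2[, 1] <- cm2[, 1] * 3L
  sf1 <- size_factors(cm)
  sf2 <- size_factors(cm2)
  expect_equal(unname(sf2[1] / sf1[1]) / unname(sf2[2] / sf1[2]), 3,
               tolerance = 0.02)
  r1 <- de_test(cm, fix$samples,
                contrast = list(factor = "genotype",
                                levels = c("wildtype", "knockout")))
  r2 <- de_test(cm2, fix$samples,
                contrast = list(factor = "genotype",
                                levels = c("wildtype", "knockout")))
  expect_lt(median(abs(r1$logFC - r2$logFC), na.rm = TRUE), 0.05)
})
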