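# Independent oracles and fixture builders shared across tests. These stay
# deliberately naive (loops, closed forms, enumeration) so they cannot share
# a defect with the implementation they check.

# brute-force Benjamini-Hochberg step-up
bh_brute <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    j <- which(o == i)  # rank of p[i]
    q[i] <- min(1, min(p[o][j:m] * m / (j:m)))
  }
  q
}

# brute-force Spearman: Pearson on explicitly computed mean ranks
mean_ranks <- function(v) {
  r <- numeric(length(v))
  for (i in seq_along(v)) {
    r[i] <- sum(v < v[i]) + (sum(v == v[i]) + 1) / 2
  }
  r
}
spearman_brute <- function(x, y) {
  rx <- mean_ranks(x); ry <- mean_ranks(y)
  num <- sum((rx - mean(rx)) * (ry - mean(ry)))
  den <- sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  num / den
}

# brute-force two-sided exact binomial p (minimum-likelihood method)
binom_two_sided_brute <- function(k, n, p0) {
  pmf <- dbinom(0:n, n, p0)
  sum(pmf[pmf <= pmf[k + 1] * (1 + 1e-7)])
}

# independent median-of-ratios normalization (genes positive in all samples)
size_factors_brute <- function(cm) {
  use <- apply(cm > 0, 1, all)
  geo <- exp(rowMeans(log(cm[use, , drop = FALSE])))
  sf <- apply(cm[use, , drop = FALSE], 2, function(col) median(col / geo))
  sf / exp(mean(log(sf)))
}

# small two-group count fixture with the package's sample-table layout
two_group_fixture <- function(n_genes, n_per_group, mu = 100, dispersion = 0.05,
                              lfc = NULL, seed = 1) {
  set.seed(seed)
  grp <- rep(c("wildtype", "knockout"), each = n_per_group)
  eff <- if (is.null(lfc)) rep(0, n_genes) else lfc
  mu0 <- exp(runif(n_genes, log(20), log(500)))
  m <- outer(mu0, rep(1, 2 * n_per_group))
  m[, grp == "knockout"] <- m[, grp == "knockout"] * 2^eff
  cm <- matrix(rnbinom(length(m), mu = m, size = 1 / dispersion),
               nrow = n_genes,
               dimnames = list(sprintf("g%04d.L", seq_len(n_genes)),
                               sprintf("s%02d", seq_len(2 * n_per_group))))
  samples <- data.frame(sample_id = colnames(cm), line = "fix",
                        genotype = grp, sex = "M", lane = "run1",
                        stringsAsFactors = FALSE)
  list(counts = cm, samples = samples, true_lfc = eff)
}

# sexualization fixture: wildtype M/F plus knockouts of one sex
sexualization_fixture <- function(n_genes, n_per_group = 3, knockout_sex = "F",
                                  mu = 100, dispersion = 0.05, seed = 1,
                                  sex_lfc = rep(0, n_genes),
                                  ko_lfc = rep(0, n_genes)) {
  set.seed(seed)
  groups <- data.frame(
    genotype = rep(c("wildtype", "wildtype", "knockout"), each = n_per_group),
    sex = rep(c("M", "F", knockout_sex), each = n_per_group),
    stringsAsFactors = FALSE)
  mu0 <- exp(runif(n_genes, log(30), log(300)))
  m <- outer(mu0, rep(1, nrow(groups)))
  male <- groups$sex == "M"
  ko <- groups$genotype == "knockout"
  m[, male] <- m[, male] * 2^sex_lfc
  m[, ko] <- m[, ko] * 2^ko_lfc
  cm <- matrix(rnbinom(length(m), mu = m, size = 1 / dispersion),
               nrow = n_genes,
               dimnames = list(sprintf("g%04d.S", seq_len(n_genes)),
                               sprintf("s%02d", seq_len(nrow(groups)))))
  samples <- data.frame(sample_id = colnames(cm), line = "fix",
                        genotype = groups$genotype, sex = groups$sex,
                        lane = "run1", stringsAsFactors = FALSE)
  list(counts = cm, samples = samples)
}
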