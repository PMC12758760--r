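# Permutation test for masculinization/feminization of a knockout
# transcriptome: Spearman correlation between the wildtype male:female and
# knockout:same-sex-wildtype log2 expression-ratio vectors over a
# sex-related gene panel, referenced to correlations of random gene sets.

#' Per-gene log2 expression ratio between two sample groups
#'
#' `log2((mean normalized count in numerator + pseudocount) /
#' (mean in denominator + pseudocount))`, computed over the supplied genes.
#'
#' @param cm_normalized Matrix of normalized counts (counts divided by
#'   size factors).
#' @param numerator_ids,denominator_ids Sample ids of the two groups.
#' @param genes Gene ids to evaluate (default: all rows).
#' @param pseudocount Stabilizing constant added to both means.
#' @return Named numeric vector of log2 ratios.
#' @export
log2_ratio_vector <- function(cm_normalized, numerator_ids, denominator_ids,
                              genes = rownames(cm_normalized),
                              pseudocount = 0.5) {
  if (length(numerator_ids) == 0 || length(denominator_ids) == 0)
    stop("empty sample group")
  missing <- setdiff(genes, rownames(cm_normalized))
  if (length(missing)) {
    warning(length(missing), " gene(s) absent from matrix; skipped")
    genes <- setdiff(genes, missing)
  }
  num <- rowMeans(cm_normalized[genes, numerator_ids, drop = FALSE])
  den <- rowMeans(cm_normalized[genes, denominator_ids, drop = FALSE])
  log2((num + pseudocount) / (den + pseudocount))
}

#' Flag outliers beyond 1.5 interquartile ranges
#'
#' A value is flagged when it exceeds `Q3 + 1.5 * IQR` or falls below
#' `Q1 - 1.5 * IQR`, with quartiles computed by linear interpolation
#' (quantile type 7). Strict inequalities: values exactly at a fence are
#' kept, so a constant vector flags nothing.
#'
#' @param values Numeric vector (at least 4 finite values; fewer give no
#'   flags with a warning).
#' @return Logical vector, `TRUE` where flagged.
#' @export
iqr_outlier_mask <- function(values) {
  finite <- is.finite(values)
  if (sum(finite) < 4) {
    warning("fewer than 4 finite values; no outliers flagged")
    return(rep(FALSE, length(values)))
  }
  q <- stats::quantile(values[finite], c(0.25, 0.75), type = 7, names = FALSE)
  iqr <- q[2] - q[1]
  flag <- values > q[2] + 1.5 * iqr | values < q[1] - 1.5 * iqr
  flag & finite
}

#' Spearman rank correlation
#'
#' Pearson correlation of average ranks (ties receive their mean rank).
#' Returns `NA` when either rank vector has zero variance.
#'
#' @param x,y Numeric vectors of equal length (>= 3).
#' @return Correlation in `[-1, 1]`, or `NA`.
#' @export
spearman_rho <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 3) stop("need at least 3 paired values")
  rx <- rank(x); ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) return(NA_real_)
  stats::cor(rx, ry, method = "pearson")
}

#' Permutation test for transcriptome masculinization or feminization
#'
#' For the chosen knockout sex, builds two per-gene log2 ratio vectors over
#' the sex-related panel: `x` = wildtype male : wildtype female, and
#' `y` = knockout : same-sex wildtype. After joint outlier exclusion (a
#' gene is dropped if flagged by the 1.5 IQR rule in either vector), the
#' observed Spearman correlation is referenced to a null distribution in
#' which the same number of genes is repeatedly drawn at random (without
#' replacement) from all non-panel genes of the matrix, with ratio vectors,
#' outlier masking and correlation recomputed per draw.
#'
#' For female knockouts the tested direction is masculinization
#' (`p = (1 + #\{rho_null >= rho_obs\}) / (n_perm + 1)`); for male knockouts
#' it is feminization (lower tail). With `exhaustive = TRUE` all subsets of
#' the pool are enumerated instead of sampled (only feasible for tiny
#' pools).
#'
#' @param cm Count matrix (unfiltered for abundance: the panel is exempt
#'   from the low-count filter).
#' @param samples Sample table aligned to `cm`, containing wildtype samples
#'   of both sexes and knockout samples of `knockout_sex`.
#' @param panel Character vector of panel gene ids (panel genes absent from
#'   the matrix are dropped with a warning).
#' @param knockout_sex `"F"` or `"M"`.
#' @param n_perm Number of permutation replicates (default 1000).
#' @param seed Integer seed for the permutation draws.
#' @param pseudocount Pseudocount for the ratio computation.
#' @param sf Size factors; computed by [size_factors()] when `NULL`.
#' @param exhaustive Enumerate every pool subset instead of sampling.
#' @return An object of class `"sexualization_result"`: a list with
#'   `rho_observed`, `rho_null`, `p_one_sided`, `direction`,
#'   `n_genes_used`, `n_perm`, `seed`, and the per-gene `ratios` table
#'   (panel gene, x, y, outlier flag).
#' @export
sexualization_permutation_test <- function(cm, samples, panel,
                                           knockout_sex = c("F", "M"),
                                           n_perm = 1000, seed = 1L,
                                           pseudocount = 0.5, sf = NULL,
                                           exhaustive = FALSE) {
  knockout_sex <- match.arg(knockout_sex)
  assert_count_matrix(cm)
  if (!exhaustive && n_perm < 1) stop("n_perm must be >= 1")
  samples <- align_tables(cm, samples)$samples

  wt_m <- samples$sample_id[samples$genotype == "wildtype" & samples$sex == "M"]
  wt_f <- samples$sample_id[samples$genotype == "wildtype" & samples$sex == "F"]
  ko <- samples$sample_id[samples$genotype == "knockout" &
                            samples$sex == knockout_sex]
  wt_same <- if (knockout_sex == "F") wt_f else wt_m
  if (!length(wt_m) || !length(wt_f) || !length(ko))
    stop("required sample groups missing (wildtype M, wildtype F, knockout ",
         knockout_sex, ")")

  if (is.null(sf)) sf <- size_factors(cm)
  norm <- sweep(cm, 2, sf[colnames(cm)], "/")

  panel_present <- intersect(panel, rownames(cm))
  if (length(panel_present) < length(panel))
    warning(length(panel) - length(panel_present),
            " panel gene(s) absent from matrix; dropped")
  k <- length(panel_present)
  if (k < 3) stop("fewer than 3 panel genes present in the matrix")

  # ratio vectors for every gene, computed once; permutations index into them
  x_all <- log2_ratio_vector(norm, wt_m, wt_f, pseudocount = pseudocount)
  y_all <- log2_ratio_vector(norm, ko, wt_same, pseudocount = pseudocount)

  rho_masked <- function(idx) {
    x <- x_all[idx]; y <- y_all[idx]
    drop <- suppressWarnings(iqr_outlier_mask(x) | iqr_outlier_mask(y))
    if (sum(!drop) < 3) return(c(rho = NA_real_, n = sum(!drop)))
    c(rho = spearman_rho(x[!drop], y[!drop]), n = sum(!drop))
  }

  obs <- rho_masked(panel_present)
  rho_obs <- obs[["rho"]]

  pool <- setdiff(rownames(cm), panel)
  if (length(pool) < k)
    stop("permutation pool (", length(pool),
         " genes) smaller than the panel (", k, ")")

  if (exhaustive) {
    subsets <- utils::combn(pool, k, simplify = FALSE)
    rho_null <- vapply(subsets, function(s) rho_masked(s)[["rho"]], numeric(1))
  } else {
    rho_null <- withr::with_seed(as.integer(seed), {
      vapply(seq_len(n_perm),
             function(i) rho_masked(sample(pool, k))[["rho"]],
             numeric(1))
    })
  }
  n_eff <- length(rho_null)

  direction <- if (knockout_sex == "F") "masculinization" else "feminization"
  if (is.na(rho_obs)) {
    p <- NA_real_
  } else if (direction == "masculinization") {
    p <- (1 + sum(rho_null >= rho_obs, na.rm = TRUE)) / (n_eff + 1)
  } else {
    p <- (1 + sum(rho_null <= rho_obs, na.rm = TRUE)) / (n_eff + 1)
  }

  ratios <- data.frame(gene_id = panel_present,
                       x_wtM_vs_wtF = unname(x_all[panel_present]),
                       y_ko_vs_wt = unname(y_all[panel_present]),
                       outlier = suppressWarnings(
                         iqr_outlier_mask(x_all[panel_present]) |
                           iqr_outlier_mask(y_all[panel_present])),
                       stringsAsFactors = FALSE)

  structure(list(rho_observed = rho_obs, rho_null = rho_null,
                 p_one_sided = p, direction = direction,
                 n_genes_used = unname(obs[["n"]]), n_perm = n_eff,
                 seed = as.integer(seed), ratios = ratios),
            class = "sexualization_result")
}

#' @export
print.sexualization_result <- function(x, ...) {
  cat("Sexualization permutation test (", x$direction, ")\n", sep = "")
  cat(sprintf("  observed Spearman rho: %.4f over %d panel genes\n",
              x$rho_observed, x$n_genes_used))
  cat(sprintf("  one-sided permutation p: %.4g (%d replicates)\n",
              x$p_one_sided, x$n_perm))
  invisible(x)
}
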