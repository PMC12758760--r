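# Self-contained negative-binomial differential-expression stage: median-of-
# ratios normalization, method-of-moments dispersions shrunk toward an
# a/mean + b trend, per-gene NB GLM with a log-size-factor offset, Wald test
# on the contrast coefficient, Benjamini-Hochberg FDR calling.

DISPERSION_FLOOR <- 1e-8
LOGFC_CAP <- 30

#' Median-of-ratios size factors
#'
#' Per-sample normalization factors computed as the median across genes of
#' the ratio of each sample's counts to the per-gene geometric mean,
#' rescaled so the factors have geometric mean 1. Genes with a zero count in
#' any sample are excluded from the reference; when no gene is positive in
#' every sample, the reference falls back to genes positive in at least 90%
#' of samples.
#'
#' @param cm Count matrix.
#' @return Named positive numeric vector, one factor per sample.
#' @export
size_factors <- function(cm) {
  assert_count_matrix(cm)
  if (all(cm == 0)) stop("all-zero count matrix")
  if (ncol(cm) == 1) return(stats::setNames(1, colnames(cm)))
  pos_frac <- rowMeans(cm > 0)
  use <- pos_frac == 1
  if (!any(use)) use <- pos_frac >= 0.9
  if (!any(use)) stop("no gene positive in >= 90% of samples")
  sub <- cm[use, , drop = FALSE]
  geo <- exp(rowMeans(log(sub)))
  finite <- is.finite(geo) & geo > 0
  sf <- apply(sub[finite, , drop = FALSE], 2, function(col)
    stats::median(col / geo[finite]))
  sf <- sf / exp(mean(log(sf)))
  stats::setNames(sf, colnames(cm))
}

#' Per-gene dispersion estimates with trend shrinkage
#'
#' Method-of-moments estimates `max((var - mean) / mean^2, floor)` on
#' size-factor-normalized counts, shrunk toward a trend `a/mean + b` fitted
#' by least squares on the genes with positive raw estimates. The shrunk
#' value is `(1 - shrink) * raw + shrink * trend`, floored at a small
#' positive constant.
#'
#' @param cm Count matrix.
#' @param sf Size factors from [size_factors()].
#' @param shrink Shrinkage weight toward the trend, in `[0, 1]`.
#' @return Named numeric vector of per-gene dispersions (all > 0).
#' @export
estimate_dispersions <- function(cm, sf = size_factors(cm), shrink = 0.5) {
  assert_count_matrix(cm)
  if (ncol(cm) < 2) stop("dispersion estimation needs >= 2 samples")
  norm <- sweep(cm, 2, sf, "/")
  m <- rowMeans(norm)
  v <- apply(norm, 1, stats::var)
  raw <- ifelse(m > 0, (v - m) / m^2, 0)
  raw <- pmax(raw, DISPERSION_FLOOR)
  pos <- raw > DISPERSION_FLOOR & m > 0
  if (sum(pos) >= 2 && length(unique(m[pos])) >= 2) {
    fit <- stats::lm.fit(cbind(1 / m[pos], 1), raw[pos])
    a <- max(fit$coefficients[1], 0)
    b <- max(fit$coefficients[2], 0)
  } else {
    a <- 0; b <- stats::median(raw)
  }
  trend <- ifelse(m > 0, a / m + b, b)
  disp <- pmax((1 - shrink) * raw + shrink * trend, DISPERSION_FLOOR)
  stats::setNames(disp, rownames(cm))
}

#' Negative-binomial Wald differential-expression test
#'
#' Fits, per gene, a negative-binomial log-linear model with
#' `log(size factor)` offset and design `~ covariates + contrast factor`,
#' using the per-gene dispersion as fixed. The Wald statistic of the
#' contrast coefficient is referenced to the standard normal; p-values are
#' Benjamini-Hochberg adjusted across all tested genes and genes are called
#' significant at `q < alpha_fdr`. Genes where one contrast level has only
#' zero counts (complete separation) are reported with the log2 fold change
#' capped in magnitude and flagged.
#'
#' @param cm Count matrix.
#' @param samples Sample table aligned to `cm` columns.
#' @param contrast List `list(factor = <column>, levels = c(ref, alt))`;
#'   the reported log2 fold change is `alt` relative to `ref`.
#' @param covariates Character vector of additional sample-table columns to
#'   adjust for (e.g. a sequencing-lane batch factor).
#' @param alpha_fdr FDR threshold for the `significant` call.
#' @param sf Size factors (computed from `cm` by default).
#' @param dispersions Per-gene dispersions (estimated by default).
#' @param dispersion_shrink Shrinkage weight used when `dispersions` is
#'   `NULL`; exposed so two engine configurations can be compared.
#' @return A `data.frame` with columns `gene_id`, `logFC` (log2), `SE`
#'   (log2 scale), `pvalue`, `qvalue`, `significant`, `capped`.
#' @export
de_test <- function(cm, samples, contrast, covariates = character(0),
                    alpha_fdr = 0.10, sf = NULL, dispersions = NULL,
                    dispersion_shrink = 0.5) {
  assert_count_matrix(cm)
  stopifnot(is.list(contrast), !is.null(contrast$factor),
            length(contrast$levels) == 2)
  if (!contrast$factor %in% names(samples))
    stop("contrast factor not a SampleTable column: ", contrast$factor)
  bad_cov <- setdiff(covariates, names(samples))
  if (length(bad_cov))
    stop("covariates not SampleTable columns: ", paste(bad_cov, collapse = ", "))
  samples <- align_tables(cm, samples)$samples

  grp <- samples[[contrast$factor]]
  keep <- grp %in% contrast$levels
  if (!all(keep)) {
    cm <- cm[, keep, drop = FALSE]
    samples <- samples[keep, , drop = FALSE]
    grp <- grp[keep]
  }
  n_per <- table(factor(grp, levels = contrast$levels))
  if (any(n_per == 0))
    stop("contrast level with zero samples: ",
         paste(contrast$levels[n_per == 0], collapse = ", "))

  if (is.null(sf)) sf <- size_factors(cm)
  sf <- sf[colnames(cm)]
  if (is.null(dispersions))
    dispersions <- estimate_dispersions(cm, sf, shrink = dispersion_shrink)

  fac <- factor(grp, levels = contrast$levels)
  covdf <- samples[, covariates, drop = FALSE]
  # drop covariates that are constant after subsetting
  covdf <- covdf[, vapply(covdf, function(x) length(unique(x)) > 1,
                          logical(1)), drop = FALSE]
  design_df <- cbind(covdf, .contrast = fac)
  X <- stats::model.matrix(~ ., data = design_df)
  coef_idx <- ncol(X)  # contrast term is last
  offset <- log(sf)

  alt <- fac == contrast$levels[2]
  n_genes <- nrow(cm)
  logfc <- se <- pval <- rep(NA_real_, n_genes)
  capped <- logical(n_genes)
  ln2 <- log(2)

  for (g in seq_len(n_genes)) {
    y <- cm[g, ]
    sep <- (sum(y[alt]) == 0) != (sum(y[!alt]) == 0)
    fit <- tryCatch(
      suppressWarnings(stats::glm.fit(
        X, y, offset = offset,
        family = MASS::negative.binomial(theta = 1 / dispersions[g]))),
      error = function(e) NULL)
    if (is.null(fit) || !is.finite(fit$coefficients[coef_idx])) {
      if (all(y == 0)) { logfc[g] <- 0; se[g] <- NA; pval[g] <- 1 }
      next
    }
    beta <- fit$coefficients[coef_idx]
    xtwx <- crossprod(X * sqrt(fit$weights))
    vcov_g <- tryCatch(solve(xtwx), error = function(e) NULL)
    if (is.null(vcov_g)) next
    se_nat <- sqrt(vcov_g[coef_idx, coef_idx])
    lf <- beta / ln2
    if (sep || abs(lf) > LOGFC_CAP) {
      lf <- sign(lf) * min(abs(lf), LOGFC_CAP)
      capped[g] <- TRUE
    }
    logfc[g] <- lf
    se[g] <- se_nat / ln2
    z <- beta / se_nat
    pval[g] <- 2 * stats::pnorm(-abs(z))
  }
  pval[is.na(pval)] <- 1
  qval <- bh_adjust(pval)
  data.frame(gene_id = rownames(cm), logFC = logfc, SE = se,
             pvalue = pval, qvalue = qval,
             significant = qval < alpha_fdr & !is.na(logfc),
             capped = capped,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Standard step-up adjustment, capped at 1.
#'
#' @param pvals Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted q-values in the input order.
#' @export
bh_adjust <- function(pvals) {
  if (anyNA(pvals) || any(pvals < 0 | pvals > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvals, method = "BH")
}

#' Consensus between two differential-expression analyses
#'
#' @param resA,resB `DEResultTable`s over the same gene universe (as
#'   returned by [de_test()]).
#' @return A list with counts `n_A`, `n_B`, `n_overlap` and id vectors
#'   `sig_A`, `sig_B`, `overlap`.
#' @export
consensus_de <- function(resA, resB) {
  stopifnot(all(c("gene_id", "significant") %in% names(resA)),
            all(c("gene_id", "significant") %in% names(resB)))
  if (!setequal(resA$gene_id, resB$gene_id))
    stop("gene universes differ between the two analyses")
  sig_A <- resA$gene_id[resA$significant]
  sig_B <- resB$gene_id[resB$significant]
  overlap <- intersect(sig_A, sig_B)
  list(n_A = length(sig_A), n_B = length(sig_B),
       n_overlap = length(overlap),
       sig_A = sig_A, sig_B = sig_B, overlap = overlap)
}

#' Write a DE result table as TSV
#'
#' @param res Result of [de_test()].
#' @param path Output path.
#' @param annotation Optional annotation supplying a `subgenome` column.
#' @return `path`, invisibly.
#' @export
write_de_table <- function(res, path, annotation = NULL) {
  out <- res
  if (!is.null(annotation)) {
    out$subgenome <- annotation$subgenome[match(out$gene_id,
                                                annotation$gene_id)]
  } else {
    out$subgenome <- subgenome_from_id(out$gene_id)
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
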