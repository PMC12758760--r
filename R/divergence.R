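# Summaries over DE output: intersection with sex-biased gene sets and
# subgenome (L/S) bias with an exact binomial test.

#' Intersect differentially expressed genes with sex-biased gene sets
#'
#' Computes how many of the significant genes fall in the union of one or
#' more previously identified sex-biased gene sets, as a count and as a
#' percentage of the significant set, with a per-set breakdown.
#'
#' @param de_sig Character vector of significant gene ids.
#' @param sexbiased A named list of character vectors (one per comparison).
#' @return A list with `count`, `percent` (`NA` when `de_sig` is empty),
#'   `union_size`, and `per_set` (named counts of `de_sig` hits per set).
#' @export
sexbias_intersection <- function(de_sig, sexbiased) {
  de_sig <- unique(de_sig)
  if (!is.list(sexbiased)) sexbiased <- list(sexbiased)
  union_set <- unique(unlist(sexbiased, use.names = FALSE))
  count <- length(intersect(de_sig, union_set))
  percent <- if (length(de_sig) == 0) NA_real_ else 100 * count / length(de_sig)
  per_set <- vapply(sexbiased,
                    function(s) length(intersect(de_sig, unique(s))),
                    integer(1))
  list(count = count, percent = percent,
       union_size = length(union_set), per_set = per_set)
}

#' Subgenome composition of a gene set, with exact binomial test
#'
#' Counts how many genes of a significant set lie on the L and S subgenomes
#' and tests the L proportion against the genome-wide reference (~57% of
#' protein-coding genes on L) with a two-sided exact binomial test
#' (minimum-likelihood method). Genes without a subgenome assignment are
#' excluded and reported.
#'
#' @param de_sig Character vector of gene ids.
#' @param annotation Gene annotation with `gene_id` and `subgenome`
#'   columns; when `NULL`, subgenome is parsed from the `.L`/`.S` id suffix.
#' @param reference_prop Reference L fraction.
#' @return A list with `n_L`, `n_S`, `n_NA`, `prop_L` and `p_value`.
#' @export
subgenome_proportion <- function(de_sig, annotation = NULL,
                                 reference_prop = 0.57) {
  de_sig <- unique(de_sig)
  if (is.null(annotation)) {
    sg <- subgenome_from_id(de_sig)
  } else {
    sg <- annotation$subgenome[match(de_sig, annotation$gene_id)]
  }
  n_L <- sum(sg == "L", na.rm = TRUE)
  n_S <- sum(sg == "S", na.rm = TRUE)
  n_NA <- length(de_sig) - n_L - n_S
  if (n_L + n_S == 0) stop("no gene with a subgenome assignment")
  p <- stats::binom.test(n_L, n_L + n_S, p = reference_prop)$p.value
  list(n_L = n_L, n_S = n_S, n_NA = n_NA,
       prop_L = n_L / (n_L + n_S), p_value = p)
}
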