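#' Study design table for the 42-tadpole knockout experiment
#'
#' Returns the per-sample metadata of the two-line F2 sibling design used
#' throughout the package: a `dmrt1.L` line (5 wildtype males, 3 wildtype
#' females, 6 knockout males, 6 knockout females, one sequencing lane) and a
#' `dmrt1.S` line (6 wildtype males, 6 wildtype females, 3 knockout males,
#' 7 knockout females, sequenced over two lanes).
#'
#' The `dmrt1.S` lane assignment splits the line as: lane `run1` carries
#' 4 knockout females, 1 knockout male, 3 wildtype females and 3 wildtype
#' males; lane `run2` carries the remaining 3 knockout females, 2 knockout
#' males, 3 wildtype females and 3 wildtype males.
#'
#' @param library_size_factors Optional numeric vector of per-sample relative
#'   library sizes (length 42, all positive). Defaults to a fixed,
#'   deterministic log-spaced spread between 0.7 and 1.4 so that
#'   normalization is exactly recoverable.
#' @return A `data.frame` with columns `sample_id`, `line`, `genotype`,
#'   `sex`, `lane`, `library_size_factor`.
#' @export
tadpole_design <- function(library_size_factors = NULL) {
  mk <- function(line, genotype, sex, n, lane) {
    data.frame(line = rep(line, n), genotype = rep(genotype, n),
               sex = rep(sex, n), lane = rep(lane, n),
               stringsAsFactors = FALSE)
  }
  l_line <- rbind(
    mk("dmrt1.L", "wildtype", "M", 5, "run1"),
    mk("dmrt1.L", "wildtype", "F", 3, "run1"),
    mk("dmrt1.L", "knockout", "M", 6, "run1"),
    mk("dmrt1.L", "knockout", "F", 6, "run1")
  )
  s_line <- rbind(
    mk("dmrt1.S", "knockout", "F", 4, "run1"),
    mk("dmrt1.S", "knockout", "M", 1, "run1"),
    mk("dmrt1.S", "wildtype", "F", 3, "run1"),
    mk("dmrt1.S", "wildtype", "M", 3, "run1"),
    mk("dmrt1.S", "knockout", "F", 3, "run2"),
    mk("dmrt1.S", "knockout", "M", 2, "run2"),
    mk("dmrt1.S", "wildtype", "F", 3, "run2"),
    mk("dmrt1.S", "wildtype", "M", 3, "run2")
  )
  design <- rbind(l_line, s_line)
  n <- nrow(design)
  if (is.null(library_size_factors)) {
    library_size_factors <- exp(seq(log(0.7), log(1.4), length.out = n))
  }
  stopifnot(length(library_size_factors) == n, all(library_size_factors > 0))
  design$sample_id <- sprintf("s%02d_%s_%s%s", seq_len(n),
                              sub("dmrt1\\.", "", design$line),
                              substr(design$genotype, 1, 2), design$sex)
  design$library_size_factor <- library_size_factors
  design[, c("sample_id", "line", "genotype", "sex", "lane",
             "library_size_factor")]
}

#' Configuration for the synthetic allotetraploid count simulator
#'
#' Builds a validated configuration for [simulate_counts()]. Defaults mirror
#' the study conditions: a two-subgenome transcriptome with ~57% of genes on
#' the L subgenome, a 90-gene sex-related panel, a female-specific marker
#' gene expressed at a low mean in females and structurally zero in males,
#' sex-biased and knockout-dysregulated gene sets, a lane (batch) effect on
#' a random half of genes, explicit library-size factors, and
#' negative-binomial noise with a `a/mean + b` dispersion trend.
#'
#' @param n_genes Number of genes to simulate.
#' @param prop_subgenome_L Fraction of genes assigned to subgenome L.
#' @param samples Sample table with columns `sample_id`, `line`, `genotype`,
#'   `sex`, `lane`, `library_size_factor`; defaults to [tadpole_design()].
#' @param baseline_mean_log_range Two numbers: natural-log range of the
#'   uniform distribution of per-gene baseline mean counts.
#' @param dispersion_params Two numbers `(a, b)`: dispersion trend
#'   `a/mean + b` evaluated at the baseline mean.
#' @param n_sex_biased Number of truly sex-biased genes.
#' @param log2FC_sex Magnitude of the sex effect in log2 units; sign (male-
#'   or female-biased) is randomized per gene.
#' @param n_ko_dysregulated Number of genes truly dysregulated in knockouts.
#' @param log2FC_ko Magnitude of the knockout effect in log2 units; sign
#'   randomized per gene.
#' @param female_marker_mean Expected count of the female-specific marker in
#'   females (always exactly 0 in males).
#' @param lane_effect_log2 Multiplicative log2 shift applied to a random half
#'   of genes in samples belonging to the second lane level.
#' @param panel_size Size of the sex-related gene panel.
#' @param panel_ko_copy_sex Positive-control switch: when `TRUE`, every panel
#'   gene receives a sex effect of magnitude `log2FC_sex` (random sign) and
#'   an identical knockout effect, so the knockout transcriptome mimics the
#'   male-female axis on the panel.
#' @param seed Integer seed; identical configurations give identical output.
#' @return A list of class `"sim_config"`.
#' @export
simulation_config <- function(n_genes = 10000,
                              prop_subgenome_L = 0.57,
                              samples = tadpole_design(),
                              baseline_mean_log_range = c(log(5), log(500)),
                              dispersion_params = c(a = 1, b = 0.05),
                              n_sex_biased = 200,
                              log2FC_sex = 1.5,
                              n_ko_dysregulated = 300,
                              log2FC_ko = 1.5,
                              female_marker_mean = 20,
                              lane_effect_log2 = 0.5,
                              panel_size = 90,
                              panel_ko_copy_sex = FALSE,
                              seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes),
              prop_subgenome_L = prop_subgenome_L,
              samples = samples,
              baseline_mean_log_range = baseline_mean_log_range,
              dispersion_params = unname(dispersion_params),
              n_sex_biased = as.integer(n_sex_biased),
              log2FC_sex = log2FC_sex,
              n_ko_dysregulated = as.integer(n_ko_dysregulated),
              log2FC_ko = log2FC_ko,
              female_marker_mean = female_marker_mean,
              lane_effect_log2 = lane_effect_log2,
              panel_size = as.integer(panel_size),
              panel_ko_copy_sex = isTRUE(panel_ko_copy_sex),
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  with(cfg, {
    if (n_genes < 1) stop("n_genes must be positive")
    if (prop_subgenome_L < 0 || prop_subgenome_L > 1)
      stop("prop_subgenome_L must lie in [0, 1]")
    if (is.null(samples) || nrow(samples) == 0)
      stop("configuration error: sample list is empty")
    req <- c("sample_id", "line", "genotype", "sex", "lane",
             "library_size_factor")
    missing_cols <- setdiff(req, names(samples))
    if (length(missing_cols))
      stop("samples table lacks columns: ", paste(missing_cols, collapse = ", "))
    if (anyDuplicated(samples$sample_id)) stop("duplicate sample ids")
    if (any(samples$library_size_factor <= 0))
      stop("all library_size_factors must be > 0")
    if (length(baseline_mean_log_range) != 2 ||
        diff(baseline_mean_log_range) < 0)
      stop("baseline_mean_log_range must be an increasing pair")
    if (length(dispersion_params) != 2 || any(dispersion_params < 0) ||
        sum(dispersion_params) <= 0)
      stop("dispersion trend must be positive for positive means")
    if (n_sex_biased > n_genes || n_ko_dysregulated > n_genes)
      stop("configuration error: effect gene counts exceed n_genes")
    if (panel_size > n_genes) stop("panel_size exceeds n_genes")
    if (n_sex_biased < 0 || n_ko_dysregulated < 0 || panel_size < 0)
      stop("counts must be nonnegative")
  })
  invisible(cfg)
}

#' Simulate an allotetraploid gonad count matrix with known ground truth
#'
#' Draws a gene-by-sample matrix of negative-binomial counts under the model
#' `mean = baseline * 2^sex_effect * 2^ko_effect * 2^lane_effect *
#' library_size_factor`, where the sex effect applies to truly sex-biased
#' genes in males (sign randomized per gene), the knockout effect applies to
#' dysregulated genes in knockout samples, and the lane effect applies to a
#' random half of genes in second-lane samples. Variance follows
#' `mean + dispersion * mean^2` with the dispersion trend evaluated at the
#' baseline mean. One gene is the female-specific marker (a dm-w analog):
#' negative-binomial with mean `female_marker_mean` in females and exactly
#' zero in males. A fraction `prop_subgenome_L` of genes is annotated to
#' subgenome L (gene ids carry `.L`/`.S` suffixes); `panel_size` genes form
#' the sex-related panel.
#'
#' @param config A [simulation_config()] object.
#' @return A list with elements `counts` (integer matrix, genes x samples),
#'   `samples` (the sample table), `annotation` (`gene_id`, `chromosome`,
#'   `subgenome`, `is_panel_member`), and `truth` (per-gene flags and true
#'   log2 effects).
#' @export
simulate_counts <- function(config) {
  validate_sim_config(config)
  withr::with_seed(config$seed, simulate_counts_impl(config))
}

simulate_counts_impl <- function(cfg) {
  n <- cfg$n_genes
  smp <- cfg$samples
  n_smp <- nrow(smp)

  n_L <- round(n * cfg$prop_subgenome_L)
  subgenome <- rep(c("L", "S"), c(n_L, n - n_L))
  gene_id <- sprintf("gene%05d.%s", seq_len(n), subgenome)
  chromosome <- sprintf("chr%d%s", ((seq_len(n) - 1L) %% 9L) + 1L, subgenome)

  baseline <- exp(stats::runif(n, cfg$baseline_mean_log_range[1],
                               cfg$baseline_mean_log_range[2]))
  a <- cfg$dispersion_params[1]; b <- cfg$dispersion_params[2]
  dispersion <- a / baseline + b

  is_sex_biased <- is_ko <- is_marker <- logical(n)
  sex_lfc <- ko_lfc <- numeric(n)

  # female marker: a gene kept out of the panel and effect sets
  marker_idx <- sample.int(n, 1L)
  is_marker[marker_idx] <- TRUE
  gene_id[marker_idx] <- "dm-w"
  subgenome[marker_idx] <- NA_character_
  chromosome[marker_idx] <- "chr2S"

  pool <- setdiff(seq_len(n), marker_idx)
  panel_idx <- sort(sample(pool, cfg$panel_size))
  is_panel <- logical(n); is_panel[panel_idx] <- TRUE

  if (cfg$n_sex_biased > 0) {
    sb <- sample(pool, cfg$n_sex_biased)
    is_sex_biased[sb] <- TRUE
    sex_lfc[sb] <- sample(c(-1, 1), cfg$n_sex_biased, replace = TRUE) *
      cfg$log2FC_sex
  }
  if (cfg$n_ko_dysregulated > 0) {
    ko <- sample(pool, cfg$n_ko_dysregulated)
    is_ko[ko] <- TRUE
    ko_lfc[ko] <- sample(c(-1, 1), cfg$n_ko_dysregulated, replace = TRUE) *
      cfg$log2FC_ko
  }
  if (cfg$panel_ko_copy_sex) {
    # positive control: panel genes sex-biased, knockout effect mirrors the
    # male-female axis exactly
    is_sex_biased[panel_idx] <- TRUE
    sex_lfc[panel_idx] <- sample(c(-1, 1), length(panel_idx), replace = TRUE) *
      cfg$log2FC_sex
    is_ko[panel_idx] <- TRUE
    ko_lfc[panel_idx] <- sex_lfc[panel_idx]
  }

  lane_levels <- unique(smp$lane)
  lane_hit <- sample(c(TRUE, FALSE), n, replace = TRUE)

  counts <- matrix(0L, nrow = n, ncol = n_smp,
                   dimnames = list(gene_id, smp$sample_id))
  male <- smp$sex == "M"
  knockout <- smp$genotype == "knockout"
  in_lane2 <- if (length(lane_levels) >= 2) smp$lane == lane_levels[2] else
    rep(FALSE, n_smp)

  for (j in seq_len(n_smp)) {
    lfc <- numeric(n)
    if (male[j]) lfc <- lfc + sex_lfc
    if (knockout[j]) lfc <- lfc + ko_lfc
    if (in_lane2[j]) lfc[lane_hit] <- lfc[lane_hit] + cfg$lane_effect_log2
    mu <- baseline * 2^lfc * smp$library_size_factor[j]
    mu[marker_idx] <- if (male[j]) 0 else
      cfg$female_marker_mean * smp$library_size_factor[j]
    y <- integer(n)
    pos <- mu > 0
    y[pos] <- stats::rnbinom(sum(pos), mu = mu[pos], size = 1 / dispersion[pos])
    counts[, j] <- y
  }

  annotation <- data.frame(gene_id = gene_id, chromosome = chromosome,
                           subgenome = subgenome, is_panel_member = is_panel,
                           stringsAsFactors = FALSE)
  truth <- data.frame(gene_id = gene_id,
                      is_sex_biased = is_sex_biased,
                      is_ko_dysregulated = is_ko,
                      is_female_marker = is_marker,
                      is_panel_member = is_panel,
                      log2FC_sex = sex_lfc,
                      log2FC_ko = ko_lfc,
                      baseline_mean = baseline,
                      dispersion = dispersion,
                      lane_affected = lane_hit,
                      stringsAsFactors = FALSE)
  list(counts = counts, samples = smp, annotation = annotation, truth = truth)
}

#' Configuration for synthetic histology and sperm-morphometry measurements
#'
#' @param groups Data frame with columns `label`, `n_units`,
#'   `mean_proportion` (in (0,1)) and `concentration` (> 0); per-unit sperm
#'   pixel proportions are drawn from Beta distributions with these means.
#' @param head_length_groups Data frame with columns `label`, `n`, `mean`
#'   and `sd` (micrometres); head lengths are drawn from normal
#'   distributions.
#' @param seed Integer seed.
#' @return A list of class `"histo_sim_config"`.
#' @export
histo_sim_config <- function(groups, head_length_groups = NULL, seed = 1L) {
  if (!is.null(groups)) {
    stopifnot(all(c("label", "n_units", "mean_proportion", "concentration")
                  %in% names(groups)))
    if (any(groups$mean_proportion <= 0 | groups$mean_proportion >= 1))
      stop("mean_proportion must lie strictly in (0, 1)")
    if (any(groups$concentration <= 0)) stop("concentration must be > 0")
    if (any(groups$n_units < 1)) stop("n_units must be >= 1")
  }
  if (!is.null(head_length_groups)) {
    stopifnot(all(c("label", "n", "mean", "sd") %in% names(head_length_groups)))
    if (any(head_length_groups$sd < 0)) stop("sd must be >= 0")
    if (any(head_length_groups$n < 1)) stop("n must be >= 1")
  }
  structure(list(groups = groups, head_length_groups = head_length_groups,
                 seed = as.integer(seed)),
            class = "histo_sim_config")
}

#' Simulate per-testis sperm proportions and sperm-head lengths
#'
#' Proportions are Beta-distributed with the configured group means
#' (shape1 = mean * concentration, shape2 = (1 - mean) * concentration);
#' head lengths are normal. Output is reproducible under the configured seed.
#'
#' @param config A [histo_sim_config()] object.
#' @return A list with data frames `proportions` (`label`, `unit`,
#'   `proportion`) and `head_lengths` (`label`, `unit`, `length_um`); either
#'   may be `NULL` when not configured.
#' @export
simulate_histology <- function(config) {
  stopifnot(inherits(config, "histo_sim_config"))
  withr::with_seed(config$seed, {
    props <- NULL
    if (!is.null(config$groups)) {
      props <- do.call(rbind, lapply(seq_len(nrow(config$groups)), function(i) {
        g <- config$groups[i, ]
        data.frame(label = g$label, unit = seq_len(g$n_units),
                   proportion = stats::rbeta(g$n_units,
                                             g$mean_proportion * g$concentration,
                                             (1 - g$mean_proportion) * g$concentration),
                   stringsAsFactors = FALSE)
      }))
    }
    heads <- NULL
    if (!is.null(config$head_length_groups)) {
      heads <- do.call(rbind, lapply(seq_len(nrow(config$head_length_groups)),
                                     function(i) {
        g <- config$head_length_groups[i, ]
        data.frame(label = g$label, unit = seq_len(g$n),
                   length_um = stats::rnorm(g$n, g$mean, g$sd),
                   stringsAsFactors = FALSE)
      }))
    }
    list(proportions = props, head_lengths = heads)
  })
}
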