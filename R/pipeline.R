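# Orchestration: simulate (or load) -> per-line abundance filter -> per-sex
# knockout-vs-wildtype DE under two engine configurations -> consensus ->
# sex-bias intersection and subgenome summaries -> sexualization permutation
# tests; machine-readable reports plus a manifest.

#' Pipeline configuration
#'
#' @param sim A [simulation_config()] describing the synthetic inputs, or
#'   `NULL` when `counts`/`samples`/`annotation` are given directly.
#' @param counts,samples,annotation Pre-built inputs (used when `sim` is
#'   `NULL`).
#' @param alpha_fdr FDR threshold for significance calls.
#' @param filter_threshold Mean-count abundance filter threshold.
#' @param n_perm Permutation replicates for the sexualization tests.
#' @param seed Master seed; per-stage seeds are derived from it.
#' @param out_dir Output directory, or `NULL` to skip writing files.
#' @return A list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(sim = simulation_config(), counts = NULL,
                            samples = NULL, annotation = NULL,
                            alpha_fdr = 0.10, filter_threshold = 2.0,
                            n_perm = 1000, seed = 1L, out_dir = NULL) {
  if (alpha_fdr <= 0 || alpha_fdr >= 1) stop("alpha_fdr must lie in (0, 1)")
  if (filter_threshold < 0) stop("filter_threshold must be >= 0")
  if (n_perm < 1) stop("n_perm must be >= 1")
  if (is.null(sim) && (is.null(counts) || is.null(samples)))
    stop("either a simulation config or counts + samples must be supplied")
  structure(list(sim = sim, counts = counts, samples = samples,
                 annotation = annotation, alpha_fdr = alpha_fdr,
                 filter_threshold = filter_threshold,
                 n_perm = as.integer(n_perm), seed = as.integer(seed),
                 out_dir = out_dir),
            class = "pipeline_config")
}

config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(deparse(config[setdiff(names(config), "out_dir")]), tmp)
  unname(tools::md5sum(tmp))
}

#' Run the full knockout-transcriptome analysis pipeline
#'
#' For each line in the design: applies the per-line abundance filter, runs
#' knockout-vs-wildtype differential expression within each sex under two
#' engine configurations (gene-wise dispersions half-shrunk toward the trend
#' versus trend-only dispersions, standing in for the study's two analysis
#' routes), takes their consensus,
#' intersects significant genes with the line's wildtype male-vs-female
#' sex-biased set, summarizes subgenome composition, and runs the
#' sexualization permutation test for each knockout sex (masculinization in
#' females, feminization in males). The wildtype male-vs-female contrast is
#' also reported per line. Lane is included as a covariate whenever a line
#' spans more than one lane.
#'
#' @param config A [pipeline_config()].
#' @return A report list (class `"pipeline_report"`) with one entry per
#'   line, plus a `manifest`; when `config$out_dir` is set, DE tables (TSV),
#'   per-contrast reports (JSON) and the manifest are also written there.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!is.null(config$sim)) {
    sim <- simulate_counts(config$sim)
    cm <- sim$counts; samples <- sim$samples; annotation <- sim$annotation
  } else {
    cm <- config$counts; samples <- config$samples
    annotation <- config$annotation
  }
  bundle <- align_tables(cm, samples, annotation)
  cm <- bundle$counts; samples <- bundle$samples
  annotation <- bundle$annotation
  if (is.null(annotation))
    annotation <- data.frame(gene_id = rownames(cm),
                             subgenome = subgenome_from_id(rownames(cm)),
                             is_panel_member = FALSE,
                             stringsAsFactors = FALSE)
  panel <- annotation$gene_id[annotation$is_panel_member]

  out_dir <- config$out_dir
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)

  lines <- unique(samples$line)
  report <- list()
  seed_offset <- 0L
  for (ln in lines) {
    in_line <- samples$line == ln
    cm_line <- cm[, samples$sample_id[in_line], drop = FALSE]
    smp_line <- samples[in_line, , drop = FALSE]
    filt <- low_count_filter(cm_line, config$filter_threshold)
    cm_f <- filt$counts
    covars <- if (length(unique(smp_line$lane)) > 1) "lane" else character(0)
    line_rep <- list(n_samples = nrow(smp_line),
                     n_genes_tested = nrow(cm_f),
                     n_genes_removed = length(filt$removed_gene_ids),
                     covariates = covars)

    # wildtype male-vs-female contrast defines the line's sex-biased sets
    wt <- smp_line$genotype == "wildtype"
    cm_wt <- cm_f[, smp_line$sample_id[wt], drop = FALSE]
    smp_wt <- smp_line[wt, , drop = FALSE]
    mf <- lapply(c(A = 0.5, B = 1), function(shr)
      de_test(cm_wt, smp_wt, contrast = list(factor = "sex",
                                             levels = c("F", "M")),
              covariates = intersect(covars, names(which(
                vapply(smp_wt[covars], function(x) length(unique(x)) > 1,
                       logical(1))))),
              alpha_fdr = config$alpha_fdr, dispersion_shrink = shr))
    sexbiased_sets <- lapply(mf, function(r) r$gene_id[r$significant])
    line_rep$wildtype_MF <- list(
      n_A = sum(mf$A$significant), n_B = sum(mf$B$significant),
      consensus = consensus_de(mf$A, mf$B)$n_overlap)

    for (sx in c("F", "M")) {
      in_sex <- smp_line$sex == sx
      if (!any(smp_line$genotype == "knockout" & in_sex)) next
      cm_sx <- cm_f[, smp_line$sample_id[in_sex], drop = FALSE]
      smp_sx <- smp_line[in_sex, , drop = FALSE]
      cov_sx <- intersect(covars, names(which(
        vapply(smp_sx[covars], function(x) length(unique(x)) > 1,
               logical(1)))))
      res <- lapply(c(A = 0.5, B = 1), function(shr)
        de_test(cm_sx, smp_sx,
                contrast = list(factor = "genotype",
                                levels = c("wildtype", "knockout")),
                covariates = cov_sx, alpha_fdr = config$alpha_fdr,
                dispersion_shrink = shr))
      cons <- consensus_de(res$A, res$B)
      inter <- lapply(res, function(r)
        sexbias_intersection(r$gene_id[r$significant], sexbiased_sets))
      subg <- lapply(res, function(r) {
        sig <- r$gene_id[r$significant]
        if (sum(!is.na(annotation$subgenome[
          match(sig, annotation$gene_id)])) == 0) NULL else
            subgenome_proportion(sig, annotation)
      })
      seed_offset <- seed_offset + 1L
      sexu <- sexualization_permutation_test(
        cm_line, smp_line, panel, knockout_sex = sx,
        n_perm = config$n_perm, seed = config$seed + 1000L * seed_offset)

      key <- paste0(ln, "_", sx)
      contrast_rep <- list(
        line = ln, sex = sx,
        de = list(n_A = cons$n_A, n_B = cons$n_B,
                  n_overlap = cons$n_overlap),
        sexbias_intersection = inter,
        subgenome = subg,
        sexualization = list(rho = sexu$rho_observed,
                             p = sexu$p_one_sided,
                             direction = sexu$direction,
                             n_genes_used = sexu$n_genes_used,
                             n_perm = sexu$n_perm))
      line_rep$contrasts[[key]] <- contrast_rep

      if (!is.null(out_dir)) {
        write_de_table(res$A, file.path(out_dir, paste0("de_", key, "_A.tsv")),
                       annotation)
        write_de_table(res$B, file.path(out_dir, paste0("de_", key, "_B.tsv")),
                       annotation)
        jsonlite::write_json(
          contrast_rep, file.path(out_dir, paste0("report_", key, ".json")),
          auto_unbox = TRUE, digits = NA, pretty = TRUE, null = "null")
      }
    }
    report[[ln]] <- line_rep
  }

  manifest <- list(package = "gonadtx",
                   version = as.character(utils::packageVersion("gonadtx")),
                   seed = config$seed, n_perm = config$n_perm,
                   alpha_fdr = config$alpha_fdr,
                   filter_threshold = config$filter_threshold,
                   config_md5 = config_hash(config),
                   contrasts = unlist(lapply(report, function(l)
                     names(l$contrasts)), use.names = FALSE))
  report$manifest <- manifest
  class(report) <- "pipeline_report"
  if (!is.null(out_dir)) {
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    write_report(report, file.path(out_dir, "summary.txt"))
  }
  report
}

#' Write a human-readable pipeline summary
#'
#' One paragraph per contrast: significant-gene counts under both engine
#' configurations and their overlap, the sex-biased intersection, subgenome
#' composition, and the sexualization test result.
#'
#' @param report A `"pipeline_report"` from [run_pipeline()].
#' @param path Output text file.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  lines <- character(0)
  add <- function(...) lines <<- c(lines, sprintf(...))
  for (ln in setdiff(names(report), "manifest")) {
    l <- report[[ln]]
    add("Line %s: %d samples, %d genes tested (%d removed by filter)",
        ln, l$n_samples, l$n_genes_tested, l$n_genes_removed)
    add("  wildtype M vs F: %d (engine A) / %d (engine B) significant, %d consensus",
        l$wildtype_MF$n_A, l$wildtype_MF$n_B, l$wildtype_MF$consensus)
    for (key in names(l$contrasts)) {
      ct <- l$contrasts[[key]]
      add("  knockout %s vs wildtype %s:", ct$sex, ct$sex)
      add("    significant genes: A %d, B %d, overlap %d",
          ct$de$n_A, ct$de$n_B, ct$de$n_overlap)
      pc <- ct$sexbias_intersection$A$percent
      add("    sex-biased among engine-A calls: %d (%s)",
          ct$sexbias_intersection$A$count,
          if (is.na(pc)) "NA" else sprintf("%.0f%%", pc))
      if (!is.null(ct$subgenome$A))
        add("    subgenome L proportion (engine A): %.2f (nL=%d, nS=%d, p=%.3g)",
            ct$subgenome$A$prop_L, ct$subgenome$A$n_L, ct$subgenome$A$n_S,
            ct$subgenome$A$p_value)
      add("    sexualization (%s): rho=%.3f, p=%.4g (%d genes, %d perms)",
          ct$sexualization$direction, ct$sexualization$rho,
          ct$sexualization$p, ct$sexualization$n_genes_used,
          ct$sexualization$n_perm)
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' @export
print.pipeline_report <- function(x, ...) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  write_report(x, tmp)
  cat(readLines(tmp), sep = "\n")
  invisible(x)
}
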