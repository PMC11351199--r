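## Evidence integration: recurrent deletion loci -> transcriptional
## consistency -> proliferation gain in the knockout screen.

#' Pipeline configuration
#'
#' All thresholds default to the discovery procedure's standard values.
#'
#' @param alpha per-direction FDR level for cytoband enrichment.
#' @param lst_cut control-group LST cutoff (strict `<`).
#' @param min_deleted minimum deletion-bearing cases for TCS.
#' @param tcs_cut,norm_tcs_cut TCS pass thresholds (strict `>`).
#' @param rps_fraction fraction of negative-RPS genes kept.
#' @param depmap_cut DepMap gene-effect cutoff (strict `>`).
#' @param del_offset,amp_offset ploidy-relative status offsets.
#' @param overlap_frac minimum covered band fraction (strict `>`).
#' @param comut_q_cut co-mutation significance threshold on q.
#' @param n_perm permutation-null iterations (0 disables the test).
#' @param test_amplification also test amplification enrichment.
#' @param use_depmap apply the DepMap filter when gene effects exist.
#' @param seed RNG seed for the permutation chain.
#' @return named list of class `sv_config`.
#' @export
sv_config <- function(alpha = 0.05, lst_cut = 12, min_deleted = 5,
                      tcs_cut = 0.7, norm_tcs_cut = 1.5, rps_fraction = 0.5,
                      depmap_cut = -0.5, del_offset = 1, amp_offset = 3,
                      overlap_frac = 0.5, comut_q_cut = 0.10, n_perm = 0,
                      test_amplification = FALSE, use_depmap = FALSE,
                      seed = 1) {
  structure(as.list(environment()), class = "sv_config")
}

#' Integrate the three evidence streams
#'
#' A gene is a final synthetic-viability candidate when it lies in an
#' enriched deletion locus, shows transcriptional consistency with the
#' deletion, and increases proliferation in the knockout screen. Per-gene
#' evidence booleans are retained for every gene in the union.
#'
#' @param enriched_genes genes in enriched deletion loci.
#' @param tcs_genes genes passing the TCS filter.
#' @param proliferation_genes genes increasing knockout proliferation.
#' @param track `"BRCA1"` or `"BRCA2"`.
#' @param cohort cohort label recorded for provenance.
#' @return data.frame: `gene`, `track`, `in_enriched_deletion`,
#'   `tcs_pass`, `proliferation_pass`, `candidate`, `cohorts`.
#' @export
integrate_candidates <- function(enriched_genes, tcs_genes,
                                 proliferation_genes, track = "BRCA1",
                                 cohort = "cohort") {
  all_genes <- sort(unique(c(enriched_genes, tcs_genes, proliferation_genes)))
  df <- data.frame(
    gene = all_genes, track = track,
    in_enriched_deletion = all_genes %in% enriched_genes,
    tcs_pass = all_genes %in% tcs_genes,
    proliferation_pass = all_genes %in% proliferation_genes,
    stringsAsFactors = FALSE)
  df$candidate <- df$in_enriched_deletion & df$tcs_pass & df$proliferation_pass
  df$cohorts <- cohort
  df
}

#' Combine candidate lists across cohorts (union)
#'
#' Final candidates for a track are the union over cohorts; the
#' `cohorts` field records which cohorts contributed each gene.
#'
#' @param per_cohort named list of [integrate_candidates()] outputs.
#' @param track track label for the combined list.
#' @return data.frame of final candidates with merged `cohorts`.
#' @export
combine_tracks <- function(per_cohort, track = "BRCA2") {
  stopifnot(length(per_cohort) >= 1)
  rows <- lapply(names(per_cohort), function(nm) {
    df <- per_cohort[[nm]]
    df <- df[df$candidate, , drop = FALSE]
    if (nrow(df)) df$cohorts <- nm
    df
  })
  all <- do.call(rbind, rows)
  if (is.null(all) || !nrow(all)) {
    out <- per_cohort[[1]][0, , drop = FALSE]
    return(out)
  }
  genes <- sort(unique(all$gene))
  out <- all[match(genes, all$gene), , drop = FALSE]
  out$track <- track
  out$cohorts <- vapply(genes, function(g)
    paste(sort(unique(all$cohorts[all$gene == g])), collapse = ","),
    character(1))
  rownames(out) <- NULL
  out
}

#' Run the full discovery pipeline
#'
#' Executes classification, cytoband copy-number calling, deletion
#' enrichment (optionally amplification and the fixed-margin permutation
#' null), TCS scoring, RPS scoring (when BF tables are present) and
#' evidence integration on a dataset bundle.
#'
#' @param bundle an `sv_bundle` (from [read_dataset()] or
#'   [simulate_dataset()]).
#' @param config an [sv_config()].
#' @param track candidate track label, `"BRCA1"` or `"BRCA2"`.
#' @param cohort cohort label recorded in the candidate table.
#' @return object of class `synviab`: list with `groups`, `callmatrix`,
#'   `enrichment` (and `enrichment_amp`, `permutation` when requested),
#'   `enriched_genes`, `tcs`, `tcs_genes`, `rps`, `proliferation_genes`,
#'   `candidates`, `config`, `skipped`.
#' @export
run_pipeline <- function(bundle, config = sv_config(), track = "BRCA1",
                         cohort = unique(bundle$samples$cancer_type)[1]) {
  stopifnot(inherits(bundle, "sv_bundle"))
  validate_bundle(bundle)
  skipped <- character()

  grp <- classify_group(bundle$samples, lst_cut = config$lst_cut)
  groups <- stats::setNames(grp$group, grp$sample_id)

  cm <- build_call_matrix(bundle, overlap_frac = config$overlap_frac,
                          del_offset = config$del_offset,
                          amp_offset = config$amp_offset)

  enr <- fisher_cytoband_enrichment(cm, groups, "deletion",
                                    alpha = config$alpha)
  enr_amp <- if (config$test_amplification)
    fisher_cytoband_enrichment(cm, groups, "amplification",
                               alpha = config$alpha)
  perm <- if (config$n_perm > 0)
    permutation_empirical_p(cm, groups, "deletion", alpha = config$alpha,
                            n_perm = config$n_perm, seed = config$seed)

  enriched_genes <- genes_in_enriched_loci(enr, bundle$genes,
                                           bundle$cytobands)

  tcs <- compute_tcs_table(bundle$expression, cm, bundle$genes, groups,
                           min_deleted = config$min_deleted,
                           tcs_cut = config$tcs_cut,
                           norm_cut = config$norm_tcs_cut)
  tcs_genes <- select_consistent_genes(tcs, enriched_genes)

  rps <- NULL; prolif <- NULL; candidates <- NULL
  if (!is.null(bundle$bf_tables) &&
      all(c("wt", "ko") %in% names(bundle$bf_tables))) {
    rps <- compute_rps(bundle$bf_tables$wt, bundle$bf_tables$ko)
    prolif <- intersect(select_switch_candidates(rps),
                        select_top_negative_rps(rps, config$rps_fraction))
    if (config$use_depmap && !is.null(bundle$gene_effects))
      prolif <- intersect(prolif,
                          depmap_proliferation_filter(bundle$gene_effects,
                                                      cutoff = config$depmap_cut))
    candidates <- integrate_candidates(enriched_genes, tcs_genes, prolif,
                                       track = track, cohort = cohort)
  } else {
    skipped <- c(skipped,
                 "integration skipped: BF tables (wt, ko) not provided")
  }

  structure(list(groups = grp, callmatrix = cm, enrichment = enr,
                 enrichment_amp = enr_amp, permutation = perm,
                 enriched_genes = enriched_genes, tcs = tcs,
                 tcs_genes = tcs_genes, rps = rps,
                 proliferation_genes = prolif, candidates = candidates,
                 config = config, skipped = skipped),
            class = "synviab")
}

#' @export
print.synviab <- function(x, ...) {
  n_case <- sum(x$groups$group == "case")
  n_ctrl <- sum(x$groups$group == "control")
  cat("Synthetic-viability discovery pipeline\n")
  cat(sprintf("  cohort: %d cases, %d controls, %d excluded\n",
              n_case, n_ctrl, sum(x$groups$group == "excluded")))
  cat(sprintf("  cytobands tested: %d; enriched deletions: %d\n",
              nrow(x$enrichment), sum(x$enrichment$enriched)))
  if (!is.null(x$permutation))
    cat(sprintf("  permutation null: empirical p = %.4g (%d iterations)\n",
                x$permutation$p, length(x$permutation$perm_stats)))
  cat(sprintf("  genes in enriched loci: %d; TCS-consistent: %d\n",
              length(x$enriched_genes), length(x$tcs_genes)))
  if (!is.null(x$candidates))
    cat(sprintf("  proliferation-gain genes: %d; final candidates: %d\n",
                length(x$proliferation_genes), sum(x$candidates$candidate)))
  for (s in x$skipped) cat("  [skipped]", s, "\n")
  invisible(x)
}

#' @export
summary.synviab <- function(object, ...) {
  out <- list(
    groups = table(object$groups$group),
    n_enriched = sum(object$enrichment$enriched),
    top_bands = utils::head(
      object$enrichment[order(object$enrichment$q), ], 10),
    n_tcs_pass = length(object$tcs_genes),
    candidates = if (!is.null(object$candidates))
      object$candidates[object$candidates$candidate, , drop = FALSE],
    permutation_p = if (!is.null(object$permutation)) object$permutation$p)
  class(out) <- "summary.synviab"
  out
}

#' @export
print.summary.synviab <- function(x, ...) {
  cat("Group sizes:\n"); print(x$groups)
  cat("\nEnriched deletion cytobands:", x$n_enriched, "\n")
  cat("Top bands by q:\n"); print(x$top_bands, digits = 3)
  if (!is.null(x$permutation_p))
    cat("\nPermutation empirical p:", format(x$permutation_p, digits = 4), "\n")
  cat("\nTCS-consistent genes in enriched loci:", x$n_tcs_pass, "\n")
  if (!is.null(x$candidates)) {
    cat("\nFinal candidates (", nrow(x$candidates), "):\n", sep = "")
    print(x$candidates, row.names = FALSE)
  }
  invisible(x)
}

#' Case/control alteration-frequency plot
#'
#' Scatter of per-cytoband alteration frequency in controls versus
#' cases; enriched bands highlighted.
#'
#' @param x a `synviab` object.
#' @param ... passed to [graphics::plot()].
#' @export
plot.synviab <- function(x, ...) {
  e <- x$enrichment
  graphics::plot(e$control_freq, e$case_freq,
                 col = ifelse(e$enriched, "firebrick", "grey50"),
                 pch = 16, cex = 0.7,
                 xlab = "control deletion frequency",
                 ylab = "case deletion frequency", ...)
  graphics::abline(0, 1, lty = 2)
  invisible(x)
}

#' Write all pipeline result tables
#'
#' @param result a `synviab` object.
#' @param out_dir output directory.
#' @param ... passed to [write_results()].
#' @return written file paths, invisibly.
#' @export
write_pipeline_results <- function(result, out_dir, ...) {
  tables <- list(groups = result$groups,
                 enrichment_deletion = result$enrichment,
                 tcs = result$tcs)
  if (!is.null(result$enrichment_amp))
    tables$enrichment_amplification <- result$enrichment_amp
  if (!is.null(result$rps)) tables$rps <- result$rps
  if (!is.null(result$candidates)) tables$candidates <- result$candidates
  if (!is.null(result$permutation))
    tables$permutation <- data.frame(iteration = seq_along(result$permutation$perm_stats),
                                     statistic = result$permutation$perm_stats)
  write_results(tables, out_dir,
                config = unclass(result$config)[
                  vapply(result$config, function(v) length(v) == 1, logical(1))],
                seed = result$config$seed, ...)
}
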