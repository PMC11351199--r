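## Transcriptional consistency score (TCS).
##
## Expression is dichotomised at the per-gene median over ALL tumors
## (regardless of group or copy-number status); "low" means strictly
## below the median. For a gene, TCS is the proportion of
## deletion-bearing case tumors with low expression, evaluated only when
## at least `min_deleted` (default 5) case tumors carry the deletion.
## The control TCS is the analogous proportion among control tumors
## WITHOUT the deletion, and the normalized TCS is their ratio. A gene
## passes when TCS > 0.7 and normalized TCS > 1.5.

#' Dichotomise expression at the all-sample median
#'
#' @param expr gene x sample numeric matrix (FPKM scale).
#' @return logical matrix, `TRUE` where the value is strictly below the
#'   gene's median across all samples.
#' @export
dichotomize_expression <- function(expr) {
  stopifnot(is.matrix(expr), ncol(expr) >= 2)
  med <- apply(expr, 1, stats::median)
  expr < med
}

#' Map genes to their covering cytoband
#'
#' A gene inherits the cytoband containing its interval midpoint.
#'
#' @param genes gene annotation data.frame.
#' @param cytobands cytoband data.frame.
#' @return character vector of band names (NA where the midpoint falls
#'   in no band), named by gene.
#' @export
map_genes_to_bands <- function(genes, cytobands) {
  band <- rep(NA_character_, nrow(genes))
  mid <- floor((genes$start + genes$end) / 2)
  for (ch in unique(genes$chrom)) {
    gi <- which(genes$chrom == ch)
    bi <- which(cytobands$chrom == ch)
    if (!length(bi)) next
    hit <- IRanges::findOverlaps(
      IRanges::IRanges(mid[gi] + 1, width = 1),
      IRanges::IRanges(cytobands$start[bi] + 1, cytobands$end[bi]))
    band[gi[S4Vectors::queryHits(hit)]] <- cytobands$name[bi][S4Vectors::subjectHits(hit)]
  }
  if (any(is.na(band)))
    warning(sum(is.na(band)), " gene(s) with midpoint in no cytoband")
  stats::setNames(band, genes$gene)
}

#' Per-sample deletion status of one gene
#'
#' The gene inherits the deletion call of the cytoband containing its
#' midpoint; missing band cells propagate as missing.
#'
#' @param gene gene symbol.
#' @param callmatrix an `sv_callmatrix`.
#' @param genes gene annotation data.frame.
#' @return named logical vector over samples (NA = missing call).
#' @export
gene_deletion_status <- function(gene, callmatrix, genes) {
  bands <- suppressWarnings(map_genes_to_bands(genes, callmatrix$cytobands))
  b <- bands[[gene]]
  if (is.na(b)) {
    warning("gene midpoint in no cytoband: ", gene)
    return(stats::setNames(rep(NA, ncol(callmatrix$status)),
                           colnames(callmatrix$status)))
  }
  st <- callmatrix$status[b, ]
  stats::setNames(ifelse(is.na(st), NA, st == "deleted"),
                  colnames(callmatrix$status))
}

#' Transcriptional consistency scores for all genes
#'
#' Vectorised computation of TCS, control TCS, normalized TCS and the
#' pass flag for every gene of the expression table.
#'
#' @param expr gene x sample FPKM matrix.
#' @param callmatrix an `sv_callmatrix`.
#' @param genes gene annotation data.frame.
#' @param groups named vector mapping sample id to `"case"`/`"control"`.
#' @param min_deleted minimum number of deletion-bearing case tumors for
#'   TCS to be evaluated (default 5).
#' @param tcs_cut,norm_cut pass thresholds (strict `>`), defaults 0.7
#'   and 1.5.
#' @return data.frame with one row per gene: `gene`, `band`,
#'   `n_case_deleted`, `tcs`, `control_tcs`, `normalized_tcs`, `passes`.
#'   `normalized_tcs` is `Inf` when the control TCS is zero but the TCS
#'   is positive.
#' @export
compute_tcs_table <- function(expr, callmatrix, genes, groups,
                              min_deleted = 5, tcs_cut = 0.7,
                              norm_cut = 1.5) {
  low <- dichotomize_expression(expr)
  bands <- map_genes_to_bands(genes, callmatrix$cytobands)
  gsyms <- rownames(expr)
  band_of <- bands[gsyms]
  ok <- !is.na(band_of)
  ## deletion status per gene x sample (from the band call matrix)
  del <- matrix(NA, length(gsyms), ncol(callmatrix$status),
                dimnames = list(gsyms, colnames(callmatrix$status)))
  del[ok, ] <- callmatrix$status[band_of[ok], , drop = FALSE] == "deleted"
  del <- del[, colnames(expr), drop = FALSE]
  g <- groups[colnames(expr)]
  case <- !is.na(g) & g == "case"
  ctrl <- !is.na(g) & g == "control"

  dc <- del[, case, drop = FALSE]          # deletion among cases
  lc <- low[, case, drop = FALSE]
  n_case_deleted <- rowSums(dc, na.rm = TRUE)
  tcs <- rowSums(dc & lc, na.rm = TRUE) / n_case_deleted
  tcs[n_case_deleted < min_deleted] <- NA

  dk <- del[, ctrl, drop = FALSE]          # NON-deleted controls
  lk <- low[, ctrl, drop = FALSE]
  n_ctrl_nondel <- rowSums(!dk, na.rm = TRUE)
  control_tcs <- rowSums(!dk & lk, na.rm = TRUE) / n_ctrl_nondel
  control_tcs[n_ctrl_nondel == 0] <- NA

  normalized <- tcs / control_tcs
  normalized[!is.na(tcs) & !is.na(control_tcs) &
               control_tcs == 0 & tcs > 0] <- Inf
  passes <- !is.na(tcs) & !is.na(normalized) &
    tcs > tcs_cut & normalized > norm_cut
  data.frame(gene = gsyms, band = unname(band_of),
             n_case_deleted = n_case_deleted, tcs = tcs,
             control_tcs = control_tcs, normalized_tcs = normalized,
             passes = passes, row.names = NULL, stringsAsFactors = FALSE)
}

#' Transcriptional consistency score for one gene
#'
#' Scalar interface over precomputed dichotomisation and deletion
#' status; see [compute_tcs_table()] for the cohort-wide version.
#'
#' @param gene gene symbol.
#' @param low named logical vector (sample -> below-median expression).
#' @param deletion named logical vector (sample -> gene deleted; NA =
#'   missing call).
#' @param groups named vector mapping sample id to `"case"`/`"control"`.
#' @inheritParams compute_tcs_table
#' @return one-row data.frame as in [compute_tcs_table()] (no `band`).
#' @export
compute_tcs <- function(gene, low, deletion, groups, min_deleted = 5,
                        tcs_cut = 0.7, norm_cut = 1.5) {
  ids <- names(low)
  g <- groups[ids]
  del <- deletion[ids]
  case_del <- !is.na(del) & del & !is.na(g) & g == "case"
  n_case_deleted <- sum(case_del, na.rm = TRUE)
  tcs <- if (n_case_deleted >= min_deleted)
    sum(low[case_del], na.rm = TRUE) / n_case_deleted else NA_real_
  ctrl_nondel <- !is.na(del) & !del & !is.na(g) & g == "control"
  control_tcs <- if (sum(ctrl_nondel, na.rm = TRUE) > 0)
    sum(low[ctrl_nondel], na.rm = TRUE) / sum(ctrl_nondel, na.rm = TRUE)
  else NA_real_
  normalized <- if (!is.na(tcs) && !is.na(control_tcs)) {
    if (control_tcs == 0 && tcs > 0) Inf else tcs / control_tcs
  } else NA_real_
  passes <- !is.na(tcs) && !is.na(normalized) &&
    tcs > tcs_cut && normalized > norm_cut
  data.frame(gene = gene, n_case_deleted = n_case_deleted, tcs = tcs,
             control_tcs = control_tcs, normalized_tcs = normalized,
             passes = passes, stringsAsFactors = FALSE)
}

#' Select transcriptionally consistent genes
#'
#' @param tcs_table output of [compute_tcs_table()].
#' @param restrict_to gene set to intersect with (typically
#'   [genes_in_enriched_loci()] output).
#' @return character vector of genes passing within the restriction.
#' @export
select_consistent_genes <- function(tcs_table, restrict_to) {
  sort(intersect(tcs_table$gene[tcs_table$passes], restrict_to))
}
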