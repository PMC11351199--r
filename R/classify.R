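## Cohort partitioning and mutation enrichment tests.
##
## Cases are tumors with bi-allelic BRCA1/BRCA2 inactivation.
## HR-proficient controls are BRCA wild-type tumors with little evidence
## of HRD: signature 3 not dominant and LST below 12. Everything else
## (mono-allelic carriers, HRD-like wild-types) is excluded.

#' Partition tumors into case / control / excluded
#'
#' @param samples sample data.frame (`brca_status`, `sig3_dominant`,
#'   `lst`), one row per tumor.
#' @param lst_cut LST threshold for controls (strict `<`), default 12.
#' @return data.frame with `sample_id`, `group`, `reason`.
#' @export
classify_group <- function(samples, lst_cut = 12) {
  is_case <- samples$brca_status %in% c("bBRCA1", "bBRCA2")
  is_control <- samples$brca_status == "wild_type" &
    !samples$sig3_dominant & samples$lst < lst_cut
  group <- ifelse(is_case, "case", ifelse(is_control, "control", "excluded"))
  reason <- ifelse(is_case, "bi-allelic BRCA1/2",
            ifelse(is_control, "wild-type, sig3 non-dominant, LST-low",
            ifelse(samples$brca_status == "mono_allelic", "mono-allelic BRCA1/2",
            ifelse(samples$brca_status != "wild_type", "BRCA status not classifiable",
            ifelse(samples$sig3_dominant, "dominant signature 3",
                   "LST >= cutoff")))))
  data.frame(sample_id = samples$sample_id, group = group, reason = reason,
             stringsAsFactors = FALSE)
}

#' Per-gene co-mutation test between cases and controls
#'
#' For each gene of the universe, counts mutated/unmutated samples per
#' group and applies a two-sided Fisher's exact test with BH correction
#' over the tested universe; significance is flagged at q < 0.10.
#'
#' @param mutations mutation data.frame (`sample_id`, `gene`).
#' @param groups named vector mapping sample id to `"case"`/`"control"`;
#'   every mutation's sample must be present.
#' @param gene_universe character vector of genes to test.
#' @param q_cut significance threshold on q, default 0.10.
#' @return data.frame: `gene`, `a` (case mutated), `b`, `c`, `d`, `p`,
#'   `q`, `significant`.
#' @export
comutation_test <- function(mutations, groups, gene_universe, q_cut = 0.10) {
  if (!length(gene_universe)) stop("empty gene universe")
  g <- groups[groups %in% c("case", "control")]
  if (!any(g == "case") || !any(g == "control")) stop("empty group")
  bad <- setdiff(unique(mutations$sample_id), names(groups))
  if (length(bad)) stop("mutation sample without group: ", bad[1])
  n_case <- sum(g == "case"); n_ctrl <- sum(g == "control")
  mut <- mutations[mutations$sample_id %in% names(g) &
                     mutations$gene %in% gene_universe, , drop = FALSE]
  ## count samples (not events): dedupe per gene/sample first
  mut1 <- unique(mut[, c("sample_id", "gene")])
  cnt <- table(factor(g[mut1$sample_id], c("case", "control")),
               factor(mut1$gene, gene_universe), dnn = NULL)
  a <- as.integer(cnt["case", ]); cc <- as.integer(cnt["control", ])
  b <- n_case - a; d <- n_ctrl - cc
  p <- vapply(seq_along(a),
              function(i) .fisher2_p(a[i], n_case, n_ctrl, a[i] + cc[i]),
              numeric(1))
  q <- bh_adjust(p)
  data.frame(gene = gene_universe, a = a, b = b, c = cc, d = d, p = p, q = q,
             significant = q < q_cut, stringsAsFactors = FALSE)
}

#' BRCAness flag
#'
#' A tumor is BRCAness when it is LST-high and signature 3 contributes
#' strictly more than 20% of its mutational spectrum.
#'
#' @param samples sample data.frame with `lst_class` and `sig3_exposure`.
#' @param sig3_cut exposure threshold (strict `>`), default 0.20.
#' @return logical vector.
#' @export
brcaness_flag <- function(samples, sig3_cut = 0.20) {
  if (is.null(samples$lst_class) || any(is.na(samples$lst_class)))
    stop("lst_class missing; BRCAness requires an LST-high/LST-low label")
  samples$lst_class == "LST-high" & samples$sig3_exposure > sig3_cut
}

#' Loss-of-function enrichment for one gene between two sample classes
#'
#' Counts samples carrying at least one LoF mutation in the gene per
#' flag class; two-sided Fisher's exact test, odds ratio with the
#' Haldane-Anscombe 0.5 correction when any cell is zero.
#'
#' @param mutations mutation data.frame with `is_lof`.
#' @param flags named logical vector (sample id -> class).
#' @param gene gene symbol.
#' @param universe optional gene universe; a gene outside it yields an
#'   empty-table result with p = 1 and a warning.
#' @return list with `table` (2x2 matrix), `odds_ratio`, `p`.
#' @export
lof_enrichment_test <- function(mutations, flags, gene, universe = NULL) {
  stopifnot(any(flags), any(!flags))
  if (!is.null(universe) && !(gene %in% universe)) {
    warning("gene absent from universe: ", gene)
    tab <- matrix(0L, 2, 2, dimnames = list(c("lof", "no_lof"),
                                            c("flagged", "unflagged")))
    return(list(table = tab, odds_ratio = NA_real_, p = 1))
  }
  lof_samples <- unique(mutations$sample_id[mutations$gene == gene &
                                              mutations$is_lof])
  has_lof <- names(flags) %in% lof_samples
  a <- sum(has_lof & flags); b <- sum(!has_lof & flags)
  cc <- sum(has_lof & !flags); d <- sum(!has_lof & !flags)
  tab <- matrix(c(a, b, cc, d), 2, 2,
                dimnames = list(c("lof", "no_lof"), c("flagged", "unflagged")))
  or <- if (any(tab == 0)) ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (cc + 0.5))
        else (a * d) / (b * cc)
  list(table = tab, odds_ratio = or, p = stats::fisher.test(tab)$p.value)
}
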