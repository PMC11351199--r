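## Relative proliferation score (RPS) from CRISPR-screen Bayes factors.
##
## BAGEL's Bayes factor is the log odds of gene essentiality; the RPS of
## a gene is its knockout-screen BF minus its wild-type-screen BF.
## Negative RPS means losing the gene is relatively better tolerated (or
## advantageous) in the knockout background — the signature of
## synthetic viability.

#' Compute relative proliferation scores
#'
#' @param wt,ko data.frames (`gene`, `bf`) for the wild-type and
#'   knockout screens; only shared genes are scored.
#' @return data.frame: `gene`, `bf_wt`, `bf_ko`, `rps`, `cat_wt`,
#'   `cat_ko`, `switch`.
#' @export
compute_rps <- function(wt, ko) {
  shared <- intersect(wt$gene, ko$gene)
  if (!length(shared)) stop("no genes shared between BF tables")
  dropped <- length(union(wt$gene, ko$gene)) - length(shared)
  if (dropped) message(dropped, " gene(s) absent from one table dropped")
  bf_wt <- wt$bf[match(shared, wt$gene)]
  bf_ko <- ko$bf[match(shared, ko$gene)]
  cat_wt <- categorize_essentiality(data.frame(gene = shared, bf = bf_wt))
  cat_ko <- categorize_essentiality(data.frame(gene = shared, bf = bf_ko))
  res <- data.frame(gene = shared, bf_wt = bf_wt, bf_ko = bf_ko,
                    rps = bf_ko - bf_wt,
                    cat_wt = cat_wt[shared], cat_ko = cat_ko[shared],
                    row.names = NULL, stringsAsFactors = FALSE)
  res$switch <- (res$cat_wt == "essential" &
                   res$cat_ko %in% c("neutral", "non_essential")) |
    (res$cat_wt == "neutral" & res$cat_ko == "non_essential")
  res
}

#' Categorise gene essentiality from Bayes factors
#'
#' Among genes with BF < 0 the lowest-scoring half (ceil) are
#' non-essential; among genes with BF > 0 the highest-scoring half
#' (ceil) are essential; everything else (including BF = 0) is neutral.
#' Ties are broken by gene symbol.
#'
#' @param records data.frame (`gene`, `bf`).
#' @return named character vector gene -> category.
#' @export
categorize_essentiality <- function(records) {
  stopifnot(nrow(records) >= 1)
  gene <- records$gene; bf <- records$bf
  cat <- rep("neutral", length(gene))
  neg <- which(bf < 0)
  if (length(neg)) {
    ord <- neg[order(bf[neg], gene[neg])]            # ascending, most negative first
    cat[ord[seq_len(ceiling(length(neg) / 2))]] <- "non_essential"
  }
  pos <- which(bf > 0)
  if (length(pos)) {
    ord <- pos[order(-bf[pos], gene[pos])]           # descending, highest first
    cat[ord[seq_len(ceiling(length(pos) / 2))]] <- "essential"
  }
  stats::setNames(cat, gene)
}

#' Select essentiality category-switch candidates
#'
#' Genes whose category drops from essential to neutral/non-essential,
#' or from neutral to non-essential, between the wild-type and knockout
#' backgrounds.
#'
#' @param rps output of [compute_rps()].
#' @return character vector of gene symbols.
#' @export
select_switch_candidates <- function(rps) {
  sort(rps$gene[rps$switch])
}

#' Select the most negative relative proliferation scores
#'
#' Among genes with negative RPS sorted ascending (most negative first),
#' returns the top `fraction` (ceil).
#'
#' @param rps output of [compute_rps()].
#' @param fraction fraction of negative-RPS genes to keep, default 0.5.
#' @return character vector of gene symbols.
#' @export
select_top_negative_rps <- function(rps, fraction = 0.5) {
  stopifnot(fraction > 0, fraction <= 1)
  neg <- rps[rps$rps < 0, , drop = FALSE]
  if (!nrow(neg)) {
    warning("no genes with negative RPS")
    return(character())
  }
  ord <- order(neg$rps, neg$gene)
  sort(neg$gene[ord][seq_len(ceiling(nrow(neg) * fraction))])
}

#' DepMap proliferation-permissive filter
#'
#' Genes whose mean gene-effect value across the selected cell lines is
#' strictly greater than the cutoff (default -0.5) are considered
#' proliferation-permissive when knocked out.
#'
#' @param effects gene x cell-line numeric matrix.
#' @param lines cell-line names to aggregate over.
#' @param cutoff gene-effect threshold (strict `>`), default -0.5.
#' @return character vector of gene symbols.
#' @export
depmap_proliferation_filter <- function(effects, lines = colnames(effects),
                                        cutoff = -0.5) {
  stopifnot(length(lines) >= 1)
  m <- effects[, lines, drop = FALSE]
  if (any(is.na(m)))
    message("missing effect values skipped for ",
            sum(rowSums(is.na(m)) > 0), " gene(s)")
  mu <- rowMeans(m, na.rm = TRUE)
  sort(rownames(effects)[!is.nan(mu) & mu > cutoff])
}
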