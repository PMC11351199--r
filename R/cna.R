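## Ploidy-relative cytoband copy-number assignment and status calling.
##
## A cytoband receives the integer copy number of the segment class
## contributing the greatest overlapped length within the band, provided
## segments cover more than half of the band (> 50% of the band length);
## otherwise the cell is missing. Status is called relative to the
## tumor's average ploidy: deleted when cn <= ploidy - 1, amplified when
## cn >= ploidy + 3, neutral otherwise. Ploidy is used as a real number.

#' Call ploidy-relative copy-number status
#'
#' @param cn integer copy number (vectorised; `NA` propagates).
#' @param ploidy average tumor ploidy (positive real, no rounding).
#' @param del_offset deletion threshold offset: deleted iff
#'   `cn <= ploidy - del_offset`.
#' @param amp_offset amplification threshold offset: amplified iff
#'   `cn >= ploidy + amp_offset`.
#' @return character vector in `{"deleted", "amplified", "neutral"}`.
#' @export
call_cna_status <- function(cn, ploidy, del_offset = 1, amp_offset = 3) {
  stopifnot(all(ploidy > 0))
  out <- rep(NA_character_, length(cn))
  out[!is.na(cn) & cn <= ploidy - del_offset] <- "deleted"
  out[!is.na(cn) & cn >= ploidy + amp_offset] <- "amplified"
  out[!is.na(cn) & is.na(out)] <- "neutral"
  out
}

#' Assign an integer copy number to one cytoband
#'
#' Scalar reference implementation of the band-assignment rule; the
#' matrix builder [build_call_matrix()] applies the same rule vectorised.
#'
#' @param segments data.frame of one sample's segments (chrom, start,
#'   end, cn; 0-based half-open).
#' @param band one-row data.frame (chrom, start, end).
#' @param overlap_frac minimum covered fraction of the band (strictly
#'   exceeded) for the assignment to be made; default 0.5.
#' @return integer copy number, or `NA` when coverage is insufficient.
#' @export
assign_cytoband_cn <- function(segments, band, overlap_frac = 0.5) {
  seg <- segments[segments$chrom == band$chrom, , drop = FALSE]
  os <- pmax(seg$start, band$start)
  oe <- pmin(seg$end, band$end)
  keep <- oe > os
  if (!any(keep)) return(NA_integer_)
  seg <- seg[keep, , drop = FALSE]; os <- os[keep]; oe <- oe[keep]
  covered <- sum(IRanges::width(IRanges::reduce(IRanges::IRanges(os + 1, oe))))
  if (covered / (band$end - band$start) <= overlap_frac) return(NA_integer_)
  len_by_cn <- tapply(oe - os, seg$cn, sum)
  best <- len_by_cn == max(len_by_cn)
  as.integer(min(as.integer(names(len_by_cn)[best])))  # ties -> lower cn
}

## All band x sample overlaps in one pass; returns data.frame with one
## row per (band, sample, cn) overlap contribution.
.band_overlaps <- function(segments, cytobands) {
  out <- vector("list", length(unique(cytobands$chrom)))
  k <- 0
  for (ch in unique(cytobands$chrom)) {
    cb <- which(cytobands$chrom == ch)
    sg <- which(segments$chrom == ch)
    if (!length(sg)) next
    ir_b <- IRanges::IRanges(cytobands$start[cb] + 1, cytobands$end[cb])
    ir_s <- IRanges::IRanges(segments$start[sg] + 1, segments$end[sg])
    hit <- IRanges::findOverlaps(ir_s, ir_b, minoverlap = 1)
    qh <- S4Vectors::queryHits(hit); sh <- S4Vectors::subjectHits(hit)
    os <- pmax(segments$start[sg][qh], cytobands$start[cb][sh])
    oe <- pmin(segments$end[sg][qh], cytobands$end[cb][sh])
    k <- k + 1
    out[[k]] <- data.frame(band = cb[sh], sample_id = segments$sample_id[sg][qh],
                           cn = segments$cn[sg][qh], ostart = os, oend = oe,
                           w = oe - os, stringsAsFactors = FALSE)
  }
  do.call(rbind, out[seq_len(k)])
}

#' Build the cytoband x sample call matrix
#'
#' Applies [assign_cytoband_cn()]'s rule across all bands and samples,
#' then [call_cna_status()] with each sample's ploidy.
#'
#' @param bundle an `sv_bundle` (segments, cytobands, samples required).
#' @param overlap_frac minimum covered band fraction, default 0.5.
#' @param del_offset,amp_offset status thresholds, see
#'   [call_cna_status()].
#' @return object of class `sv_callmatrix`: list with `cn` and `status`
#'   (band x sample matrices), `cytobands`, `samples`.
#' @export
build_call_matrix <- function(bundle, overlap_frac = 0.5, del_offset = 1,
                              amp_offset = 3) {
  cytobands <- bundle$cytobands
  samples <- bundle$samples
  ov <- .band_overlaps(bundle$segments, cytobands)
  nb <- nrow(cytobands); ns <- nrow(samples)
  cn <- matrix(NA_integer_, nb, ns,
               dimnames = list(cytobands$name, samples$sample_id))
  if (!is.null(ov) && nrow(ov)) {
    si <- match(ov$sample_id, samples$sample_id)
    cell <- (si - 1L) * nb + ov$band          # linear index into cn
    ## covered length per cell: union of overlap intervals (segments may
    ## overlap each other in ragged/real data)
    cov_by_cell <- .union_width_by_group(cell, ov$ostart, ov$oend)
    band_len <- cytobands$end - cytobands$start
    ok_cell <- cov_by_cell$width /
      band_len[(cov_by_cell$group - 1L) %% nb + 1L] > overlap_frac
    ok <- cov_by_cell$group[ok_cell]
    ## dominant cn per qualifying cell: greatest total overlap, ties -> lower cn
    ov2 <- ov[cell %in% ok, , drop = FALSE]
    cell2 <- cell[cell %in% ok]
    key <- paste(cell2, ov2$cn)
    w <- rowsum(ov2$w, key)
    parts <- strsplit(rownames(w), " ", fixed = TRUE)
    cc <- as.numeric(vapply(parts, `[`, "", 1))
    vv <- as.integer(vapply(parts, `[`, "", 2))
    ord <- order(cc, -w[, 1], vv)             # per cell: max width, then lower cn
    first <- !duplicated(cc[ord])
    cn[cc[ord][first]] <- vv[ord][first]
  }
  no_seg <- setdiff(samples$sample_id, unique(bundle$segments$sample_id))
  if (length(no_seg))
    warning("samples with zero segments (all-missing column): ",
            paste(no_seg, collapse = ", "))
  status <- matrix(call_cna_status(as.vector(cn),
                                   rep(samples$ploidy, each = nb),
                                   del_offset, amp_offset),
                   nb, ns, dimnames = dimnames(cn))
  structure(list(cn = cn, status = status, cytobands = cytobands,
                 samples = samples$sample_id),
            class = "sv_callmatrix")
}

## Union width of intervals grouped by `group` (one row per group).
## Fast path sums widths where no within-group overlap exists; groups
## containing overlapping intervals fall back to IRanges::reduce.
.union_width_by_group <- function(group, start, end) {
  ord <- order(group, start)
  g <- group[ord]; s <- start[ord]; e <- end[ord]
  new_g <- c(TRUE, g[-1] != g[-length(g)])
  prev_end <- c(-Inf, e[-length(e)])
  width <- e - s
  w <- rowsum(width, g)
  res <- data.frame(group = as.numeric(rownames(w)), width = w[, 1])
  overlap_prev <- !new_g & prev_end > s
  if (any(overlap_prev)) {
    for (gg in unique(g[overlap_prev])) {
      sel <- g == gg
      ir <- IRanges::reduce(IRanges::IRanges(s[sel] + 1, e[sel]))
      res$width[res$group == gg] <- sum(IRanges::width(ir))
    }
  }
  res
}

#' @export
print.sv_callmatrix <- function(x, ...) {
  tab <- table(factor(x$status, c("deleted", "neutral", "amplified")),
               useNA = "ifany")
  cat("<sv_callmatrix>", nrow(x$cn), "cytobands x", ncol(x$cn), "samples\n")
  cat("  calls:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Fraction of genome altered
#'
#' Proportion of the segmented genome whose copy number differs from the
#' rounded tumor ploidy.
#'
#' @param segments one sample's segments (0-based half-open, `cn`).
#' @param ploidy average tumor ploidy.
#' @return fraction in \[0, 1\].
#' @export
fraction_genome_altered <- function(segments, ploidy) {
  len <- segments$end - segments$start
  total <- sum(len)
  if (total <= 0) stop("zero segmented length")
  sum(len[segments$cn != round(ploidy)]) / total
}
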