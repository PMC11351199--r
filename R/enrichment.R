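## Per-cytoband case/control enrichment with FDR control, and the
## fixed row/column-margin permutation null for the count of enriched
## bands.
##
## The two-sided Fisher p-value is computed from the conditional
## hypergeometric distribution: with margins fixed, it is the sum of
## probabilities of all tables no more probable than the observed one
## (the same rule stats::fisher.test applies). Conditioning on margins
## makes the p-value a function of the case-altered count alone, which
## permits a per-band lookup table reused across permutations whose
## margins are identical by construction.

## two-sided Fisher p for a 2x2 table with cell a (case-altered),
## margins: m = a + b (cases), n = c + d (controls), k = a + c (altered)
.fisher2_p <- function(a, m, n, k) {
  support <- max(0, k - n):min(k, m)
  d <- stats::dhyper(support, m, n, k)
  min(1, sum(d[d <= d[match(a, support)] * (1 + 1e-7)]))
}

## p-value lookup over the full support for fixed margins
.fisher2_lookup <- function(m, n, k) {
  support <- max(0, k - n):min(k, m)
  d <- stats::dhyper(support, m, n, k)
  pmin(1, vapply(seq_along(support), function(i) sum(d[d <= d[i] * (1 + 1e-7)]),
                 numeric(1)))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment; a thin validated wrapper
#' around [stats::p.adjust()].
#'
#' @param pvals numeric vector of p-values in \[0, 1\].
#' @return vector of q-values, same order as the input.
#' @export
bh_adjust <- function(pvals) {
  if (any(is.na(pvals)) || any(pvals < 0) || any(pvals > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvals, method = "BH")
}

#' Per-cytoband enrichment test
#'
#' For every cytoband, tests whether the alteration (deletion or
#' amplification) occurs at a higher frequency in case than control
#' tumors: two-sided Fisher's exact test on the 2x2 table of
#' altered/unaltered by group, BH adjustment over all bands of the
#' direction, and an enrichment flag requiring both q < alpha and
#' case frequency > control frequency. Missing cells are excluded from
#' both counts; bands missing in more than half of either group are
#' flagged `low_coverage` but still tested.
#'
#' @param callmatrix an `sv_callmatrix` from [build_call_matrix()], or a
#'   band x sample 0/1 matrix.
#' @param groups named character vector (or factor) mapping sample id to
#'   `"case"`/`"control"`; samples with other labels are ignored.
#' @param direction `"deletion"` or `"amplification"`.
#' @param alpha FDR level, default 0.05.
#' @return data.frame with one row per band: `band`, `direction`, `a`,
#'   `b`, `c`, `d`, `case_freq`, `control_freq`, `odds_ratio`, `p`, `q`,
#'   `enriched`, `low_coverage`.
#' @export
fisher_cytoband_enrichment <- function(callmatrix, groups,
                                       direction = c("deletion", "amplification"),
                                       alpha = 0.05) {
  direction <- match.arg(direction)
  stopifnot(alpha > 0, alpha < 1)
  bin <- .binarize(callmatrix, direction)
  g <- groups[colnames(bin)]
  case_cols <- which(g == "case"); ctrl_cols <- which(g == "control")
  if (!length(case_cols) || !length(ctrl_cols))
    stop("need at least one case and one control")
  alt <- bin == 1
  a <- rowSums(alt[, case_cols, drop = FALSE], na.rm = TRUE)
  b <- rowSums(!is.na(bin[, case_cols, drop = FALSE])) - a
  cc <- rowSums(alt[, ctrl_cols, drop = FALSE], na.rm = TRUE)
  d <- rowSums(!is.na(bin[, ctrl_cols, drop = FALSE])) - cc
  p <- vapply(seq_along(a),
              function(i) .fisher2_p(a[i], a[i] + b[i], cc[i] + d[i],
                                     a[i] + cc[i]),
              numeric(1))
  case_freq <- ifelse(a + b > 0, a / (a + b), NA)
  control_freq <- ifelse(cc + d > 0, cc / (cc + d), NA)
  q <- bh_adjust(p)
  res <- data.frame(
    band = rownames(bin), direction = direction,
    a = a, b = b, c = cc, d = d,
    case_freq = case_freq, control_freq = control_freq,
    odds_ratio = (a * d) / (b * cc),
    p = p, q = q,
    enriched = q < alpha & !is.na(case_freq) & !is.na(control_freq) &
      case_freq > control_freq,
    low_coverage = (a + b) < length(case_cols) / 2 |
      (cc + d) < length(ctrl_cols) / 2,
    row.names = NULL, stringsAsFactors = FALSE)
  res
}

.binarize <- function(callmatrix, direction) {
  if (inherits(callmatrix, "sv_callmatrix")) {
    target <- c(deletion = "deleted", amplification = "amplified")[direction]
    bin <- (callmatrix$status == target) + 0L
    dimnames(bin) <- dimnames(callmatrix$cn)
    bin
  } else {
    stopifnot(is.matrix(callmatrix))
    callmatrix
  }
}

#' Fixed-margin permutations of a binary matrix
#'
#' Generates permuted 0/1 matrices sharing the exact row and column sums
#' of the input, via a seeded sequential checkerboard-swap Markov chain
#' (vegan's `"swap"` null model) with configurable burn-in and thinning.
#' Cells in constant rows or columns are immutable under these margins.
#'
#' @param mat 0/1 matrix.
#' @param n_perm number of matrices to draw.
#' @param seed RNG seed.
#' @param burnin swaps discarded before the first sample; default
#'   `10 * sum(mat)`.
#' @param thin swaps between successive samples; default `sum(mat)`.
#' @return list of `n_perm` matrices.
#' @export
permute_fixed_margins <- function(mat, n_perm, seed = 1, burnin = NULL,
                                  thin = NULL) {
  stopifnot(is.matrix(mat), all(mat %in% c(0, 1)), n_perm >= 1)
  nnz <- sum(mat)
  if (is.null(burnin)) burnin <- 10 * nnz
  if (is.null(thin)) thin <- max(1, nnz)
  ## no checkerboard 2x2 submatrix => the input is the unique matrix
  ## with these margins; the chain has nothing to swap
  if (vegan::nestedchecker(mat)$statistic == 0)
    return(lapply(seq_len(n_perm), function(i) mat))
  nm <- vegan::nullmodel(mat, "swap")
  sims <- stats::simulate(nm, nsim = n_perm, seed = seed, burnin = burnin,
                          thin = thin)
  lapply(seq_len(n_perm), function(i) {
    m <- sims[, , i]
    dimnames(m) <- dimnames(mat)
    m
  })
}

#' Permutation empirical p-value for the count of enriched bands
#'
#' Permutes the 0/1 cytoband alteration matrix keeping row and column
#' sums fixed, recomputes the number of significantly enriched bands in
#' each permuted matrix, and reports the add-one empirical p-value
#' `(1 + #{permuted statistic >= observed}) / (1 + n_perm)`.
#'
#' Because row and column sums (and group membership) are preserved,
#' every band's 2x2 margins are identical across permutations; per-band
#' p-values are therefore served from a precomputed margin-conditional
#' lookup table. BH adjustment is recomputed within each permutation by
#' default.
#'
#' @inheritParams fisher_cytoband_enrichment
#' @param n_perm number of permutations.
#' @param seed RNG seed for the swap chain.
#' @param recompute_bh if `FALSE`, permuted matrices are scored against
#'   the observed per-band p-value threshold instead of re-running BH.
#' @param burnin,thin chain parameters, see [permute_fixed_margins()].
#' @return list with `p` (empirical p-value), `observed` (observed count
#'   of enriched bands), `perm_stats` (per-iteration counts).
#' @export
permutation_empirical_p <- function(callmatrix, groups,
                                    direction = c("deletion", "amplification"),
                                    alpha = 0.05, n_perm = 1000, seed = 1,
                                    recompute_bh = TRUE, burnin = NULL,
                                    thin = NULL) {
  direction <- match.arg(direction)
  bin <- .binarize(callmatrix, direction)
  bin[is.na(bin)] <- 0L
  g <- groups[colnames(bin)]
  keep <- which(g %in% c("case", "control"))
  bin <- bin[, keep, drop = FALSE]
  g <- g[keep]
  case_cols <- g == "case"
  m <- sum(case_cols); n <- sum(!case_cols)
  k <- rowSums(bin)
  ## margin-conditional p lookup per band: index by a - a_min + 1
  a_min <- pmax(0, k - n)
  lookups <- lapply(seq_along(k), function(i) .fisher2_lookup(m, n, k[i]))
  lut <- unlist(lookups)                       # flat lookup with offsets
  offs <- cumsum(c(0, lengths(lookups)[-length(lookups)]))

  stat_of_a <- function(a) {                   # a: bands x draws matrix
    p <- matrix(lut[offs + (a - a_min) + 1], nrow(a), ncol(a))
    dirn <- a / m > (k - a) / n                # case_freq > control_freq
    if (recompute_bh) {
      vapply(seq_len(ncol(a)),
             function(j) sum(bh_adjust(p[, j]) < alpha & dirn[, j]),
             numeric(1))
    } else {
      colSums(p <= p_cut & dirn)
    }
  }
  a_obs <- rowSums(bin[, case_cols, drop = FALSE])
  if (!recompute_bh) {
    p_obs <- lut[offs + (a_obs - a_min) + 1]
    sig <- bh_adjust(p_obs) < alpha
    p_cut <- if (any(sig)) max(p_obs[sig]) else -1
  }
  observed <- as.numeric(stat_of_a(cbind(a_obs)))
  perms <- permute_fixed_margins(bin, n_perm, seed = seed, burnin = burnin,
                                 thin = thin)
  a_perm <- vapply(perms, function(mm) rowSums(mm[, case_cols, drop = FALSE]),
                   numeric(length(k)))
  perm_stats <- stat_of_a(a_perm)
  list(p = (1 + sum(perm_stats >= observed)) / (1 + n_perm),
       observed = observed, perm_stats = perm_stats)
}

#' Gene-set over-representation test
#'
#' Hypergeometric upper-tail p for the overlap of two gene sets within a
#' finite universe, plus the two-sided Fisher p for the same table.
#'
#' @param set_a,set_b character vectors, subsets of `universe`.
#' @param universe character vector of all eligible genes.
#' @return list with `overlap`, `p_hyper` (one-sided over-representation)
#'   and `p_fisher` (two-sided).
#' @export
geneset_overlap_test <- function(set_a, set_b, universe) {
  if (!length(universe)) stop("empty universe")
  set_a <- intersect(set_a, universe)
  set_b <- intersect(set_b, universe)
  ov <- length(intersect(set_a, set_b))
  u <- length(unique(universe))
  p_hyper <- stats::phyper(ov - 1, length(set_a), u - length(set_a),
                           length(set_b), lower.tail = FALSE)
  tab <- matrix(c(ov, length(set_a) - ov, length(set_b) - ov,
                  u - length(set_a) - length(set_b) + ov), 2, 2)
  list(overlap = ov, p_hyper = p_hyper,
       p_fisher = stats::fisher.test(tab)$p.value)
}

#' Genes located in enriched loci
#'
#' Returns every gene whose interval overlaps (by at least 1 bp) a
#' cytoband flagged `enriched` in the results table.
#'
#' @param results output of [fisher_cytoband_enrichment()].
#' @param genes gene annotation data.frame (gene, chrom, start, end).
#' @param cytobands cytoband data.frame (chrom, start, end, name).
#' @return character vector of gene symbols.
#' @export
genes_in_enriched_loci <- function(results, genes, cytobands) {
  eb <- cytobands[cytobands$name %in% results$band[results$enriched], ,
                  drop = FALSE]
  if (!nrow(eb)) return(character())
  off <- setdiff(genes$chrom, cytobands$chrom)
  if (length(off))
    warning("genes on chromosomes absent from the band table skipped: ",
            paste(off, collapse = ", "))
  hits <- logical(nrow(genes))
  for (ch in unique(eb$chrom)) {
    gi <- which(genes$chrom == ch)
    bi <- which(eb$chrom == ch)
    if (!length(gi)) next
    ov <- IRanges::findOverlaps(
      IRanges::IRanges(genes$start[gi] + 1, genes$end[gi]),
      IRanges::IRanges(eb$start[bi] + 1, eb$end[bi]), minoverlap = 1)
    hits[gi[unique(S4Vectors::queryHits(ov))]] <- TRUE
  }
  sort(unique(genes$gene[hits]))
}
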