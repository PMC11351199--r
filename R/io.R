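## Input/output for the cohort data model.
##
## Internal coordinate convention: 0-based, half-open, per chromosome.
## SEG input (FACETS-style) is 1-based inclusive and converted on read;
## BED input already matches the internal convention and passes through.
## Chromosome names are normalised to the "chr"-prefixed dialect;
## chromosome Y, mitochondrial and unplaced contigs are dropped.

.canonical_chroms <- paste0("chr", c(1:22, "X"))

#' Normalise chromosome tokens
#'
#' Adds the `chr` prefix where absent and classifies each token as
#' canonical (chr1-chr22, chrX), droppable (chrY, chrM/chrMT, unplaced
#' contigs such as `GL000220` or `chr6_ssto_hap7`), or unknown.
#'
#' @param x character vector of chromosome tokens.
#' @return list with `chrom` (normalised names), `keep` (logical), and
#'   `unknown` (logical).
#' @keywords internal
.normalize_chrom <- function(x) {
  x <- as.character(x)
  bare <- sub("^chr", "", x)
  chrom <- paste0("chr", bare)
  canonical <- chrom %in% .canonical_chroms
  droppable <- bare %in% c("Y", "M", "MT") | grepl("_", bare) |
    grepl("^(GL|KI|NC|NT)", bare)
  list(chrom = chrom, keep = canonical, unknown = !canonical & !droppable)
}

.filter_chroms <- function(df, what) {
  nc <- .normalize_chrom(df$chrom)
  if (any(nc$unknown)) {
    bad <- which(nc$unknown)[1]
    stop(sprintf("unknown chromosome token '%s' in %s (line %d)",
                 df$chrom[bad], what, bad))
  }
  df$chrom <- nc$chrom
  dropped <- df$chrom[!nc$keep]
  if (length(dropped)) {
    non_y <- setdiff(unique(dropped), "chrY")
    if (length(non_y))
      warning(sprintf("%s: dropped %d records on non-canonical contigs (%s)",
                      what, sum(!nc$keep & df$chrom != "chrY"),
                      paste(non_y, collapse = ", ")))
  }
  df[nc$keep, , drop = FALSE]
}

.read_tsv <- function(path, ...) {
  if (!file.exists(path)) stop("missing file: ", path)
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE, ...)
}

.read_bed <- function(path, name_col, what) {
  if (!file.exists(path)) stop("missing file: ", path)
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 4) stop(what, ": BED file needs at least 4 columns: ", path)
  out <- data.frame(chrom = df[[1]], start = as.numeric(df[[2]]),
                    end = as.numeric(df[[3]]), stringsAsFactors = FALSE)
  out[[name_col]] <- as.character(df[[4]])
  if (ncol(df) >= 5) out$stain <- as.character(df[[5]])
  out <- .filter_chroms(out, what)
  if (any(out$end <= out$start)) stop(what, ": interval with end <= start")
  out
}

.read_samples <- function(path) {
  df <- .read_tsv(path)
  need <- c("sample_id", "cancer_type", "brca_status", "ploidy", "lst",
            "sig3_exposure", "sig3_dominant")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("sample table missing columns: ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample identifier: ",
         df$sample_id[duplicated(df$sample_id)][1])
  df$sig3_dominant <- as.logical(df$sig3_dominant)
  stopifnot(all(df$ploidy > 0), all(df$sig3_exposure >= 0),
            all(df$sig3_exposure <= 1))
  df
}

.read_seg <- function(path) {
  df <- .read_tsv(path)
  need <- c("sample", "chrom", "start", "end", "cn")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("segment table missing columns: ",
                         paste(miss, collapse = ", "))
  out <- data.frame(sample_id = as.character(df$sample), chrom = df$chrom,
                    start = as.numeric(df$start) - 1,   # 1-based incl -> 0-based half-open
                    end = as.numeric(df$end),
                    cn = as.integer(round(df$cn)), stringsAsFactors = FALSE)
  out <- .filter_chroms(out, "segments")
  if (any(out$end <= out$start)) {
    bad <- which(out$end <= out$start)[1]
    stop(sprintf("segment with end <= start after conversion (%s:%s-%s)",
                 out$chrom[bad], out$start[bad], out$end[bad]))
  }
  if (any(out$cn < 0)) stop("negative copy number in segment table")
  out
}

.read_expression <- function(path) {
  df <- .read_tsv(path)
  genes <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- genes
  if (any(m < 0)) stop("negative expression values")
  m
}

.read_mutations <- function(path) {
  df <- .read_tsv(path)
  need <- c("sample", "gene", "variant_class")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("mutation table missing columns: ",
                         paste(miss, collapse = ", "))
  data.frame(sample_id = as.character(df$sample), gene = as.character(df$gene),
             variant_class = as.character(df$variant_class),
             is_lof = is_lof_class(df$variant_class), stringsAsFactors = FALSE)
}

.read_bf <- function(path) {
  df <- .read_tsv(path)
  if (!all(c("gene", "bf") %in% names(df)))
    stop("BF table must have columns gene, bf: ", path)
  stopifnot(all(is.finite(df$bf)))
  data.frame(gene = as.character(df$gene), bf = as.numeric(df$bf),
             stringsAsFactors = FALSE)
}

.read_gene_effects <- function(path) {
  df <- .read_tsv(path)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(df[[1]])
  m
}

#' Loss-of-function variant classes
#'
#' Truncating classes count as loss-of-function: nonsense, frameshift
#' indels and canonical splice-site variants. Missense is excluded.
#'
#' @param variant_class character vector of MAF-style variant classes.
#' @return logical vector.
#' @export
is_lof_class <- function(variant_class) {
  variant_class %in% c("Nonsense_Mutation", "Frame_Shift_Del",
                       "Frame_Shift_Ins", "Splice_Site", "Nonstop_Mutation")
}

#' Read a cohort dataset bundle
#'
#' Reads all tabular inputs into the internal data model. Genomic
#' intervals are converted to 0-based half-open coordinates (SEG input is
#' treated as 1-based inclusive; BED passes through), chromosome names are
#' normalised to the `chr` dialect, and chromosome Y records are dropped.
#'
#' @param paths named list of file paths with elements `samples`,
#'   `segments`, `cytobands`, `genes`, `expression`, and optionally
#'   `mutations`, `bf` (a named character vector of BF tables, e.g.
#'   `c(wt = ..., ko = ...)`) and `gene_effects`.
#' @return an object of class `sv_bundle`: list with elements `samples`,
#'   `segments`, `cytobands`, `genes`, `expression`, `mutations`,
#'   `bf_tables`, `gene_effects`.
#' @export
read_dataset <- function(paths) {
  need <- c("samples", "segments", "cytobands", "genes", "expression")
  miss <- setdiff(need, names(paths))
  if (length(miss)) stop("paths missing: ", paste(miss, collapse = ", "))
  bundle <- list(
    samples = .read_samples(paths$samples),
    segments = .read_seg(paths$segments),
    cytobands = .read_bed(paths$cytobands, "name", "cytobands"),
    genes = .read_bed(paths$genes, "gene", "genes"),
    expression = .read_expression(paths$expression),
    mutations = if (!is.null(paths$mutations)) .read_mutations(paths$mutations),
    bf_tables = if (!is.null(paths$bf)) lapply(as.list(paths$bf), .read_bf),
    gene_effects = if (!is.null(paths$gene_effects))
      .read_gene_effects(paths$gene_effects)
  )
  class(bundle) <- "sv_bundle"
  validate_bundle(bundle)
  bundle
}

#' Validate a dataset bundle
#'
#' Checks referential integrity (every sample referenced by segments,
#' expression or mutations exists in the sample table), the interval
#' convention (half-open, non-empty) and cytoband sortedness.
#'
#' @param bundle an `sv_bundle`.
#' @return the bundle, invisibly; errors on violation.
#' @export
validate_bundle <- function(bundle) {
  ids <- bundle$samples$sample_id
  if (anyDuplicated(ids)) stop("duplicate sample identifier")
  if (!all(bundle$segments$sample_id %in% ids))
    stop("segment table references unknown sample")
  if (!all(colnames(bundle$expression) %in% ids))
    stop("expression columns are not a subset of sample identifiers")
  if (!is.null(bundle$mutations) &&
      !all(bundle$mutations$sample_id %in% ids))
    stop("mutation table references unknown sample")
  for (tab in list(bundle$segments, bundle$cytobands, bundle$genes))
    if (any(tab$end <= tab$start)) stop("empty or inverted interval")
  cb <- bundle$cytobands
  for (ch in unique(cb$chrom)) {
    b <- cb[cb$chrom == ch, ]
    b <- b[order(b$start), ]
    if (any(b$start[-1] < b$end[-nrow(b)]))
      stop("overlapping cytobands on ", ch)
  }
  if ("chrY" %in% c(bundle$cytobands$chrom, bundle$segments$chrom))
    stop("chromosome Y must be excluded")
  invisible(bundle)
}

#' @export
print.sv_bundle <- function(x, ...) {
  cat("<sv_bundle>", nrow(x$samples), "samples,",
      nrow(x$segments), "segments,", nrow(x$cytobands), "cytobands,",
      nrow(x$genes), "genes\n")
  cat("  expression:", nrow(x$expression), "x", ncol(x$expression), "\n")
  if (!is.null(x$mutations)) cat("  mutations:", nrow(x$mutations), "\n")
  if (!is.null(x$bf_tables))
    cat("  BF tables:", paste(names(x$bf_tables), collapse = ", "), "\n")
  invisible(x)
}

#' Load the bundled hg19 cytoband annotation
#'
#' The standard UCSC hg19 cytoBand table shipped with the package;
#' chromosome Y is excluded on read, leaving 851 bands.
#'
#' @return data.frame with columns chrom, start, end, name, stain
#'   (0-based half-open coordinates).
#' @export
hg19_cytobands <- function() {
  path <- system.file("extdata", "cytoBand_hg19.txt", package = "synviab")
  .read_bed(path, "name", "cytobands")
}

#' Write result tables and a run manifest
#'
#' Writes one TSV per named table (header, stable column order, full
#' floating-point precision) plus `manifest.tsv` recording the
#' configuration, seed and input checksums.
#'
#' @param tables named list of data.frames.
#' @param out_dir output directory, created if needed.
#' @param config optional named list recorded in the manifest.
#' @param seed optional seed recorded in the manifest.
#' @param inputs optional character vector of input file paths; MD5
#'   checksums are recorded.
#' @return character vector of written file paths, invisibly.
#' @export
write_results <- function(tables, out_dir, config = list(), seed = NA,
                          inputs = character()) {
  ok <- dir.exists(out_dir) || dir.create(out_dir, recursive = TRUE,
                                          showWarnings = FALSE)
  if (!ok || file.access(out_dir, 2) != 0)
    stop("output directory not writable: ", out_dir)
  paths <- character()
  for (nm in names(tables)) {
    p <- file.path(out_dir, paste0(nm, ".tsv"))
    df <- as.data.frame(tables[[nm]])
    num <- vapply(df, is.numeric, logical(1))
    df[num] <- lapply(df[num], function(v) format(v, digits = 17, trim = TRUE))
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, p)
  }
  manifest <- c(
    list(seed = seed),
    config,
    if (length(inputs)) as.list(stats::setNames(
      unname(tools::md5sum(inputs)), paste0("md5.", basename(inputs))))
  )
  mp <- file.path(out_dir, "manifest.tsv")
  utils::write.table(
    data.frame(key = names(manifest),
               value = vapply(manifest, function(v) paste(format(v), collapse = ","),
                              character(1))),
    mp, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(paths, mp))
}

#' Write a dataset bundle to disk in the standard input formats
#'
#' The inverse of [read_dataset()]: segments are written 1-based
#' inclusive (SEG dialect), cytobands and genes as BED, expression as a
#' genes x samples TSV.
#'
#' @param bundle an `sv_bundle`.
#' @param out_dir output directory.
#' @return named list of file paths suitable for [read_dataset()].
#' @export
write_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- list(
    samples = file.path(out_dir, "samples.tsv"),
    segments = file.path(out_dir, "segments.tsv"),
    cytobands = file.path(out_dir, "cytobands.bed"),
    genes = file.path(out_dir, "genes.bed"),
    expression = file.path(out_dir, "expression.tsv")
  )
  utils::write.table(bundle$samples, p$samples, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  seg <- data.frame(sample = bundle$segments$sample_id,
                    chrom = bundle$segments$chrom,
                    start = bundle$segments$start + 1,  # back to 1-based inclusive
                    end = bundle$segments$end,
                    cn = bundle$segments$cn)
  utils::write.table(seg, p$segments, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  cb <- bundle$cytobands[, c("chrom", "start", "end", "name")]
  utils::write.table(cb, p$cytobands, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  gn <- bundle$genes[, c("chrom", "start", "end", "gene")]
  utils::write.table(gn, p$genes, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  expr <- data.frame(gene = rownames(bundle$expression),
                     bundle$expression, check.names = FALSE)
  utils::write.table(expr, p$expression, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(bundle$mutations)) {
    p$mutations <- file.path(out_dir, "mutations.tsv")
    mut <- data.frame(sample = bundle$mutations$sample_id,
                      gene = bundle$mutations$gene,
                      variant_class = bundle$mutations$variant_class)
    utils::write.table(mut, p$mutations, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  if (!is.null(bundle$bf_tables)) {
    p$bf <- vapply(names(bundle$bf_tables), function(nm) {
      f <- file.path(out_dir, paste0("bf_", nm, ".tsv"))
      utils::write.table(bundle$bf_tables[[nm]], f, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      f
    }, character(1))
  }
  if (!is.null(bundle$gene_effects)) {
    p$gene_effects <- file.path(out_dir, "gene_effects.tsv")
    ge <- data.frame(gene = rownames(bundle$gene_effects),
                     bundle$gene_effects, check.names = FALSE)
    utils::write.table(ge, p$gene_effects, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  p
}
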