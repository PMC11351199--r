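## Synthetic cohort generator with planted ground truth.
##
## Emulates the structure of an HRD copy-number/expression/screen cohort:
## two groups (bi-allelic BRCA cases vs HR-proficient controls), a toy
## genome tiled by cytobands, planted deletion-enriched bands, a subset of
## genes whose expression tracks the deletion, and planted
## essential -> non-essential Bayes-factor switches.

#' Simulation configuration
#'
#' Defaults mirror the cohort scale used throughout the package's
#' recovery tests: 90 cases vs 140 controls, 200 cytobands of which 20
#' are deletion-enriched at probability 0.6 against a 0.15 background.
#'
#' @param seed integer RNG seed.
#' @param n_case,n_control numbers of bi-allelic BRCA case and
#'   HR-proficient control tumors.
#' @param n_cytobands,n_genes toy-genome sizes.
#' @param baseline_del_prob,enriched_del_prob per-band per-tumor deletion
#'   probabilities outside and inside enriched bands.
#' @param n_enriched_cytobands number of planted enriched bands.
#' @param frac_coupled_genes fraction of genes in enriched bands whose
#'   expression tracks deletion.
#' @param expr_effect mean downward shift (log2 FPKM units) for coupled
#'   genes in deletion-bearing tumors.
#' @param expr_sd log2-scale expression noise standard deviation.
#' @param n_switch_genes number of planted essential-to-non-essential
#'   Bayes-factor switches.
#' @param bf_noise_sd Gaussian noise added to planted Bayes factors.
#' @param ploidy_options integer ploidies sampled per tumor.
#' @param mut_prob uniform per-gene per-sample mutation probability.
#' @param ragged if `TRUE`, deletion segment boundaries are jittered by
#'   up to 20% of the band width to exercise the >50% overlap rule.
#' @param case_status BRCA status label assigned to case tumors.
#' @param cancer_type cohort histology label.
#' @return validated `sv_simconfig` list.
#' @export
sim_config <- function(seed = 1, n_case = 90, n_control = 140,
                       n_cytobands = 200, n_genes = 400,
                       baseline_del_prob = 0.15, enriched_del_prob = 0.6,
                       n_enriched_cytobands = 20, frac_coupled_genes = 0.7,
                       expr_effect = 2, expr_sd = 0.5, n_switch_genes = 30,
                       bf_noise_sd = 0.5, ploidy_options = c(2L, 3L, 4L),
                       mut_prob = 0.03, ragged = FALSE,
                       case_status = "bBRCA1", cancer_type = "OV") {
  cfg <- as.list(environment())
  stopifnot(cfg$n_case > 0, cfg$n_control > 0, cfg$n_cytobands > 0,
            cfg$n_genes > 0, cfg$n_switch_genes >= 0)
  if (!(baseline_del_prob >= 0 && baseline_del_prob <= enriched_del_prob &&
        enriched_del_prob <= 1))
    stop("need 0 <= baseline_del_prob <= enriched_del_prob <= 1")
  if (n_enriched_cytobands > n_cytobands)
    stop("n_enriched_cytobands exceeds n_cytobands")
  if (frac_coupled_genes < 0 || frac_coupled_genes > 1)
    stop("frac_coupled_genes must lie in [0, 1]")
  if (n_switch_genes > n_genes) stop("n_switch_genes exceeds n_genes")
  if (!all(ploidy_options == round(ploidy_options)) || any(ploidy_options < 2))
    stop("ploidy_options must be integers >= 2")
  class(cfg) <- "sv_simconfig"
  cfg
}

.with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  }
  set.seed(seed)
  expr
}

## Toy genome: bands of 1 Mb tiled contiguously over 4 chromosomes.
.sim_cytobands <- function(n_cytobands) {
  band_w <- 1e6
  chrom_of <- rep(paste0("chr", 1:4), length.out = n_cytobands)
  chrom_of <- sort(chrom_of)  # contiguous runs per chromosome
  idx <- stats::ave(seq_along(chrom_of), chrom_of, FUN = seq_along)
  data.frame(chrom = chrom_of,
             start = (idx - 1) * band_w,
             end = idx * band_w,
             name = paste0(sub("chr", "", chrom_of), "q", idx),
             stringsAsFactors = FALSE)
}

.sim_genes <- function(n_genes, cytobands) {
  band_i <- rep(seq_len(nrow(cytobands)), length.out = n_genes)
  slot <- (seq_len(n_genes) - 1) %/% nrow(cytobands)
  start <- cytobands$start[band_i] + 1000 + slot * 20000
  data.frame(gene = sprintf("G%04d", seq_len(n_genes)),
             chrom = cytobands$chrom[band_i],
             start = start, end = start + 10000,
             band = cytobands$name[band_i], stringsAsFactors = FALSE)
}

#' Simulate a cohort dataset with planted truth
#'
#' Generates a complete [read_dataset()]-compatible bundle: a cytoband
#' call structure realised as absolute copy-number segments (deletions at
#' ploidy − 1, neutral elsewhere), copy-number-coupled expression for a
#' planted subset of genes, uniform-rate mutations, Bayes-factor tables
#' for a wild-type and a knockout screen with planted essentiality
#' switches, and DepMap-style gene effects.
#'
#' @param config an `sv_simconfig` from [sim_config()].
#' @return list with elements `bundle` (an `sv_bundle`) and `truth`
#'   (list with `enriched_cytobands`, `coupled_genes`, `switch_genes`,
#'   `viable_genes`).
#' @export
simulate_dataset <- function(config = sim_config()) {
  stopifnot(inherits(config, "sv_simconfig"))
  .with_seed(config$seed, .simulate_impl(config))
}

#' Simulate a null cohort (no planted enrichment)
#'
#' As [simulate_dataset()] with `n_enriched_cytobands` forced to zero and
#' empty truth sets; used for permutation-null and FDR calibration tests.
#'
#' @inheritParams simulate_dataset
#' @return as [simulate_dataset()]; all truth sets empty.
#' @export
simulate_null_dataset <- function(config = sim_config()) {
  config$n_enriched_cytobands <- 0L
  simulate_dataset(config)
}

.simulate_impl <- function(cfg) {
  n_s <- cfg$n_case + cfg$n_control
  ids <- sprintf("T%03d", seq_len(n_s))
  group <- rep(c("case", "control"), c(cfg$n_case, cfg$n_control))
  cytobands <- .sim_cytobands(cfg$n_cytobands)
  genes <- .sim_genes(cfg$n_genes, cytobands)
  enriched <- sort(sample(cytobands$name, cfg$n_enriched_cytobands))

  ploidy <- sample(cfg$ploidy_options, n_s, replace = TRUE)

  ## deletion indicator matrix, bands x samples
  p <- matrix(cfg$baseline_del_prob, nrow(cytobands), n_s,
              dimnames = list(cytobands$name, ids))
  p[enriched, group == "case"] <- cfg$enriched_del_prob
  del <- matrix(stats::runif(length(p)) < p, nrow(p), ncol(p),
                dimnames = dimnames(p))

  segments <- .sim_segments(cytobands, ids, ploidy, del, cfg$ragged)

  ## expression: per-gene log2 baseline; coupled genes shift down when
  ## their band is deleted
  genes_enriched <- genes$gene[genes$band %in% enriched]
  n_coupled <- round(cfg$frac_coupled_genes * length(genes_enriched))
  coupled <- sort(sample(genes_enriched, n_coupled))
  base <- stats::runif(cfg$n_genes, 3, 8)
  shift <- (genes$gene %in% coupled) * cfg$expr_effect
  del_g <- del[genes$band, , drop = FALSE]           # genes x samples
  log2e <- base + matrix(stats::rnorm(cfg$n_genes * n_s, 0, cfg$expr_sd),
                         cfg$n_genes, n_s) - del_g * shift
  expression <- 2^log2e
  dimnames(expression) <- list(genes$gene, ids)

  mutations <- .sim_mutations(genes$gene, ids, cfg$mut_prob)

  ## planted BF categories: switch genes essential in WT, non-essential
  ## in KO; the rest concordant (20/20/60 essential/non-essential/neutral
  ## so planted ranges fill their ceil-half categories)
  switch_genes <- .pick_switch_genes(genes$gene, coupled, cfg$n_switch_genes)
  bf <- .sim_bf(genes$gene, switch_genes, cfg$bf_noise_sd)

  effects <- cbind(L1 = stats::rnorm(cfg$n_genes, -0.6, 0.3),
                   L2 = stats::rnorm(cfg$n_genes, -0.6, 0.3),
                   L3 = stats::rnorm(cfg$n_genes, -0.6, 0.3))
  rownames(effects) <- genes$gene
  effects[switch_genes, ] <- stats::rnorm(3 * length(switch_genes), 0, 0.1)

  samples <- data.frame(
    sample_id = ids, cancer_type = cfg$cancer_type,
    brca_status = ifelse(group == "case", cfg$case_status, "wild_type"),
    ploidy = ploidy,
    lst = ifelse(group == "case", 12 + stats::rpois(n_s, 15),
                 sample(0:11, n_s, replace = TRUE)),
    sig3_exposure = ifelse(group == "case", stats::runif(n_s, 0.3, 0.8),
                           stats::runif(n_s, 0, 0.15)),
    sig3_dominant = group == "case",
    stringsAsFactors = FALSE)

  bundle <- list(samples = samples, segments = segments,
                 cytobands = cytobands,
                 genes = genes[, c("chrom", "start", "end", "gene")],
                 expression = expression, mutations = mutations,
                 bf_tables = bf, gene_effects = effects)
  class(bundle) <- "sv_bundle"
  validate_bundle(bundle)

  truth <- list(enriched_cytobands = enriched,
                coupled_genes = coupled,
                switch_genes = switch_genes,
                viable_genes = sort(intersect(coupled, switch_genes)),
                deletion_matrix = del)
  list(bundle = bundle, truth = truth)
}

.sim_segments <- function(cytobands, ids, ploidy, del, ragged) {
  nb <- nrow(cytobands)
  n_s <- length(ids)
  band_w <- cytobands$end - cytobands$start
  start <- rep(cytobands$start, n_s)
  end <- rep(cytobands$end, n_s)
  if (ragged) {
    ## jitter interior boundaries by up to 20% of band width; every
    ## band keeps >= 60% coverage by its own segment
    js <- stats::runif(nb * n_s, -0.2, 0.2) * rep(band_w, n_s)
    je <- stats::runif(nb * n_s, -0.2, 0.2) * rep(band_w, n_s)
    interior_s <- rep(cytobands$start > 0, n_s)
    chrom_ends <- stats::ave(cytobands$end, cytobands$chrom, FUN = max)
    interior_e <- rep(cytobands$end < chrom_ends, n_s)
    start <- pmax(0, start + js * interior_s)
    end <- end + je * interior_e
  }
  data.frame(
    sample_id = rep(ids, each = nb),
    chrom = rep(cytobands$chrom, n_s),
    start = round(start), end = round(end),
    cn = rep(ploidy, each = nb) - as.integer(del),
    stringsAsFactors = FALSE)
}

.sim_mutations <- function(genes, ids, mut_prob) {
  hit <- which(matrix(stats::runif(length(genes) * length(ids)) < mut_prob,
                      length(genes), length(ids)), arr.ind = TRUE)
  if (!nrow(hit))
    return(data.frame(sample_id = character(), gene = character(),
                      variant_class = character(), is_lof = logical()))
  classes <- c("Missense_Mutation", "Nonsense_Mutation", "Frame_Shift_Del",
               "Splice_Site", "Silent")
  vc <- sample(classes, nrow(hit), replace = TRUE,
               prob = c(0.5, 0.15, 0.15, 0.1, 0.1))
  data.frame(sample_id = ids[hit[, 2]], gene = genes[hit[, 1]],
             variant_class = vc, is_lof = is_lof_class(vc),
             stringsAsFactors = FALSE)
}

.pick_switch_genes <- function(all_genes, coupled, n_switch) {
  if (n_switch == 0) return(character())
  from_coupled <- min(ceiling(n_switch / 2), length(coupled))
  rest <- setdiff(all_genes, coupled)
  picked <- c(sample(coupled, from_coupled),
              sample(rest, n_switch - from_coupled))
  sort(picked)
}

.sim_bf <- function(genes, switch_genes, noise_sd) {
  n <- length(genes)
  is_switch <- genes %in% switch_genes
  cat3 <- sample(c("essential", "non_essential", "neutral"), n,
                 replace = TRUE, prob = c(0.2, 0.2, 0.6))
  draw <- function(category) {
    lo <- c(essential = 5, non_essential = -15, neutral = -1)[category]
    hi <- c(essential = 15, non_essential = -5, neutral = 1)[category]
    stats::runif(length(category), lo, hi)
  }
  bf_wt <- draw(ifelse(is_switch, "essential", cat3)) +
    stats::rnorm(n, 0, noise_sd)
  bf_ko <- ifelse(is_switch, draw(rep("non_essential", n)), NA)
  bf_ko[!is_switch] <- draw(cat3[!is_switch])
  bf_ko <- bf_ko + stats::rnorm(n, 0, noise_sd)
  list(wt = data.frame(gene = genes, bf = bf_wt, stringsAsFactors = FALSE),
       ko = data.frame(gene = genes, bf = bf_ko, stringsAsFactors = FALSE))
}
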