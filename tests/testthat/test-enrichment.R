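test_that("two-sided Fisher p matches exact enumeration on all small margins", {
  ## every 2x2 table with row and column margins <= 12
  for (m in 0:12) for (n in 0:12) {
    if (m + n == 0) next
    for (k in 0:min(12, m + n)) {
      if (m + n - k > 12) next   # fourth margin
      for (a in max(0, k - n):min(k, m)) {
        p_fast <- synviab:::.fisher2_p(a, m, n, k)
        expect_equal(p_fast, oracle_fisher_p(a, m - a, k - a, n - k + a),
                     tolerance = 1e-10)
      }
    }
  }
})

test_that("internal Fisher p agrees with stats::fisher.test", {
  set.seed(3)
  for (rep in 1:200) {
    m <- sample(1:40, 1); n <- sample(1:40, 1)
    k <- sample(0:(m + n), 1)
    rng <- max(0, k - n):min(k, m)
    a <- if (length(rng) == 1) rng else sample(rng, 1)
    expect_equal(synviab:::.fisher2_p(a, m, n, k),
                 fisher.test(matrix(c(a, m - a, k - a, n - k + a), 2))$p.value,
                 tolerance = 1e-9)
  }
})

test_that("BH adjustment matches the step-up oracle and its invariances", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.5)), c(0.04, 0.04, 0.04, 0.5))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(11)
  for (rep in 1:1000) {
    p <- runif(sample(1:50, 1))
    q <- bh_adjust(p)
    expect_equal(q, oracle_bh(p), tolerance = 1e-12)
    ## monotone in sorted-p order
    expect_true(all(diff(q[order(p)]) >= -1e-15))
    ## q >= p, permutation-invariant
    expect_true(all(q >= p - 1e-15))
    perm <- sample(length(p))
    expect_equal(bh_adjust(p[perm]), q[perm], tolerance = 1e-15)
  }
})

test_that("per-band enrichment recovers planted bands with exact p-values", {
  sim <- simulate_dataset(sim_config(seed = 21))
  cm <- build_call_matrix(sim$bundle)
  groups <- groups_of(sim$bundle)
  res <- fisher_cytoband_enrichment(cm, groups, "deletion")
  planted <- res[res$band %in% sim$truth$enriched_cytobands, ]
  expect_true(all(planted$case_freq > planted$control_freq))
  ## p-values match the brute-force oracle on a sample of bands
  for (i in sample(nrow(res), 12))
    expect_equal(res$p[i],
                 oracle_fisher_p(res$a[i], res$b[i], res$c[i], res$d[i]),
                 tolerance = 1e-10)
  ## enrichment invariant: enriched => q < alpha and directional
  expect_true(all(res$q[res$enriched] < 0.05))
  expect_true(all(res$case_freq[res$enriched] > res$control_freq[res$enriched]))
  expect_true(all(res$q >= res$p - 1e-15))
})

test_that("an unaltered band gives p = 1 and no enrichment", {
  bin <- rbind(zero = rep(0L, 20),
               hot = rep(c(1L, 0L, 1L, 0L), c(8, 2, 2, 8)))
  colnames(bin) <- paste0("S", 1:20)
  groups <- stats::setNames(rep(c("case", "control"), each = 10),
                            colnames(bin))
  res <- fisher_cytoband_enrichment(bin, groups, "deletion")
  expect_equal(res$p[res$band == "zero"], 1)
  expect_false(res$enriched[res$band == "zero"])
  ## 8/10 vs 2/10 worked example
  expect_equal(res$p[res$band == "hot"], oracle_fisher_p(8, 2, 2, 8),
               tolerance = 1e-10)
  expect_equal(res$p[res$band == "hot"], 0.0230, tolerance = 1e-2)
})

test_that("missing cells are excluded from both counts", {
  st <- matrix("neutral", 2, 8,
               dimnames = list(c("b1", "b2"), paste0("S", 1:8)))
  st["b1", 1:3] <- "deleted"
  st["b1", 4] <- NA
  cm <- structure(list(cn = matrix(2L, 2, 8, dimnames = dimnames(st)),
                       status = st, cytobands = NULL,
                       samples = colnames(st)), class = "sv_callmatrix")
  groups <- stats::setNames(rep(c("case", "control"), each = 4),
                            colnames(st))
  res <- fisher_cytoband_enrichment(cm, groups, "deletion")
  expect_equal(res$a[1] + res$b[1], 3)  # one case cell missing
  expect_equal(res$c[1] + res$d[1], 4)
})

test_that("fixed-margin permutations preserve margins exactly", {
  set.seed(5)
  mat <- matrix(rbinom(100 * 50, 1, 0.25), 100, 50)
  perms <- permute_fixed_margins(mat, 50, seed = 9)
  rs <- rowSums(mat); cs <- colSums(mat)
  for (p in perms) {
    expect_identical(rowSums(p), rs)
    expect_identical(colSums(p), cs)
  }
  ## the chain moves: not every draw equals the input
  expect_gt(length(unique(lapply(perms, paste, collapse = ""))), 1)
})

test_that("2x2 diagonal matrix has exactly two states, both visited", {
  m <- matrix(c(1, 0, 0, 1), 2, 2)
  perms <- permute_fixed_margins(m, 1000, seed = 1, burnin = 10, thin = 3)
  keys <- vapply(perms, function(x) paste(x, collapse = ""), character(1))
  expect_setequal(unique(keys), c("1001", "0110"))
})

test_that("all-ones matrix is immutable and gives empirical p = 1", {
  m <- matrix(1L, 6, 9, dimnames = list(paste0("b", 1:6), paste0("S", 1:9)))
  perms <- permute_fixed_margins(m, 20, seed = 2)
  expect_true(all(vapply(perms, function(x) all(x == 1), logical(1))))
  groups <- stats::setNames(rep(c("case", "control"), c(4, 5)),
                            colnames(m))
  pe <- permutation_empirical_p(m, groups, n_perm = 99, seed = 3)
  expect_equal(pe$p, 1)
})

test_that("empirical p follows the add-one formula", {
  sim <- simulate_dataset(small_config(seed = 31))
  cm <- build_call_matrix(sim$bundle)
  groups <- groups_of(sim$bundle)
  pe <- permutation_empirical_p(cm, groups, n_perm = 99, seed = 7)
  expect_equal(pe$p,
               (1 + sum(pe$perm_stats >= pe$observed)) / (1 + 99))
  ## planted enrichment stands far above the fixed-margin null
  expect_gt(pe$observed, max(pe$perm_stats))
  expect_equal(pe$p, 1 / 100)
  ## threshold-reuse mode agrees on the observed statistic
  pe2 <- permutation_empirical_p(cm, groups, n_perm = 20, seed = 7,
                                 recompute_bh = FALSE)
  expect_equal(pe2$observed, pe$observed)
})

test_that("gene-set over-representation matches the hypergeometric tail", {
  res <- geneset_overlap_test(paste0("G", 1:10), paste0("G", c(1:5, 11:25)),
                              paste0("G", 1:100))
  expect_equal(res$overlap, 5)
  expect_equal(res$p_hyper, oracle_hyper_tail(5, 10, 20, 100),
               tolerance = 1e-12)
  ## identical sets spanning the universe
  u <- paste0("G", 1:8)
  expect_equal(geneset_overlap_test(u, u, u)$p_hyper, 1)
  ## disjoint sets: observed overlap 0 -> tail p = 1
  expect_equal(geneset_overlap_test(paste0("G", 1:5), paste0("G", 6:10),
                                    paste0("G", 1:100))$p_hyper, 1)
  expect_error(geneset_overlap_test("a", "b", character()), "empty universe")
})

test_that("genes in enriched loci follow the any-overlap rule", {
  cytobands <- data.frame(chrom = "chr1", start = c(0, 100), end = c(100, 200),
                          name = c("b1", "b2"))
  genes <- data.frame(gene = c("inside", "straddle", "outside"),
                      chrom = "chr1", start = c(10, 90, 150),
                      end = c(20, 110, 160))
  res <- data.frame(band = c("b1", "b2"), enriched = c(TRUE, FALSE))
  got <- genes_in_enriched_loci(res, genes, cytobands)
  expect_setequal(got, c("inside", "straddle"))
  ## no enriched bands -> empty set
  res$enriched <- FALSE
  expect_length(genes_in_enriched_loci(res, genes, cytobands), 0)
})
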