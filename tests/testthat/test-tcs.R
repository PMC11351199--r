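test_that("dichotomisation is strictly below the all-sample median", {
  m <- rbind(g1 = c(1, 2, 3, 4), g2 = c(5, 5, 5, 5), g3 = c(0, 10, 7, 8))
  colnames(m) <- paste0("S", 1:4)
  low <- dichotomize_expression(m)
  expect_equal(unname(low["g1", ]), c(TRUE, TRUE, FALSE, FALSE))  # median 2.5
  expect_equal(unname(low["g2", ]), rep(FALSE, 4))                # ties at median
  m2 <- matrix(c(0, 10), 1, dimnames = list("g", c("A", "B")))
  expect_equal(unname(dichotomize_expression(m2)[1, ]), c(TRUE, FALSE))
})

test_that("fewer than half of samples are low under ties, exactly half otherwise", {
  set.seed(2)
  for (rep in 1:20) {
    n <- 2 * sample(3:20, 1)
    vals <- sample(1:8, n, replace = TRUE)           # ties likely
    low <- dichotomize_expression(matrix(vals, 1,
                                         dimnames = list("g", seq_len(n))))
    expect_lte(sum(low), n / 2)
    distinct <- sample(seq_len(1000), n)             # distinct values
    low2 <- dichotomize_expression(matrix(distinct, 1,
                                          dimnames = list("g", seq_len(n))))
    expect_equal(sum(low2), n / 2)
  }
})

mk_tcs_fixture <- function(n_case_del = 5, n_low_among_del = 4) {
  ## 20 samples: 10 cases, 10 controls; gene deleted in the first
  ## n_case_del cases; expression set so that exactly n_low_among_del of
  ## the deleted cases fall strictly below the all-sample median
  ids <- paste0("S", 1:20)
  groups <- stats::setNames(rep(c("case", "control"), each = 10), ids)
  expr <- rep(10, 20)
  expr[seq_len(n_low_among_del)] <- 1          # deleted & low
  names(expr) <- ids
  low <- expr < stats::median(expr)
  deletion <- stats::setNames(c(rep(TRUE, n_case_del),
                                rep(FALSE, 20 - n_case_del)), ids)
  list(low = low, deletion = deletion, groups = groups)
}

test_that("the 4-of-5 worked example gives TCS 0.8", {
  f <- mk_tcs_fixture(5, 4)
  res <- compute_tcs("g", f$low, f$deletion, f$groups)
  expect_identical(res$tcs, 0.8)
  expect_equal(res$n_case_deleted, 5)
})

test_that("fewer than five deleted cases leaves TCS missing", {
  f <- mk_tcs_fixture(4, 3)
  res <- compute_tcs("g", f$low, f$deletion, f$groups)
  expect_true(is.na(res$tcs))
  expect_false(res$passes)
})

test_that("normalized TCS is the ratio to non-deleted controls", {
  ids <- paste0("S", 1:20)
  groups <- stats::setNames(rep(c("case", "control"), each = 10), ids)
  deletion <- stats::setNames(c(rep(TRUE, 5), rep(FALSE, 15)), ids)
  ## 4/5 deleted cases low; 3/10 non-deleted controls low
  low <- stats::setNames(c(rep(TRUE, 4), FALSE, rep(FALSE, 5),
                           rep(TRUE, 3), rep(FALSE, 7)), ids)
  res <- compute_tcs("g", low, deletion, groups)
  expect_equal(res$tcs, 0.8)
  expect_equal(res$control_tcs, 0.3)
  expect_equal(res$normalized_tcs, 0.8 / 0.3)
  expect_true(res$passes)                       # 2.667 > 1.5, 0.8 > 0.7
  ## control TCS of zero with positive TCS -> infinity sentinel
  low[11:20] <- FALSE
  res0 <- compute_tcs("g", low, deletion, groups)
  expect_identical(res0$normalized_tcs, Inf)
  expect_true(res0$passes)
})

test_that("pass thresholds are strict inequalities", {
  mk <- function(tcs, ctl) {
    ids <- paste0("S", seq_len(120))
    groups <- stats::setNames(rep(c("case", "control"), each = 60), ids)
    deletion <- stats::setNames(c(rep(TRUE, 60), rep(FALSE, 60)), ids)
    low <- stats::setNames(c(seq_len(60) <= round(tcs * 60),
                             seq_len(60) <= round(ctl * 60)), ids)
    compute_tcs("g", low, deletion, groups)
  }
  r <- mk(0.75, 0.5)   # normalized 1.5 exactly -> fail
  expect_equal(r$normalized_tcs, 1.5)
  expect_false(r$passes)
  r <- mk(0.70, 0.2)   # tcs 0.7 exactly -> fail
  expect_false(r$passes)
  r <- mk(0.75, 0.45)  # 0.75 > 0.7 and 1.667 > 1.5 -> pass
  expect_true(r$passes)
})

test_that("gene deletion status follows the midpoint cytoband", {
  cytobands <- data.frame(chrom = "chr1", start = c(0, 100),
                          end = c(100, 200), name = c("b1", "b2"))
  genes <- data.frame(gene = c("in_b1", "straddle", "orphan"),
                      chrom = c("chr1", "chr1", "chr2"),
                      start = c(10, 80, 0), end = c(20, 160, 10))
  st <- matrix(c("deleted", "neutral"), 2, 2,
               dimnames = list(c("b1", "b2"), c("S1", "S2")))
  st["b1", "S2"] <- NA
  cm <- structure(list(cn = NULL, status = st, cytobands = cytobands,
                       samples = c("S1", "S2")), class = "sv_callmatrix")
  d <- gene_deletion_status("in_b1", cm, genes[1:2, ])
  expect_identical(unname(d), c(TRUE, NA))
  ## midpoint of straddle = 120 -> band b2
  d2 <- gene_deletion_status("straddle", cm, genes[1:2, ])
  expect_identical(unname(d2), c(FALSE, FALSE))
  expect_warning(d3 <- gene_deletion_status("orphan", cm, genes),
                 "no cytoband")
  expect_true(all(is.na(d3)))
})

test_that("table and scalar TCS computations agree on a simulated cohort", {
  sim <- simulate_dataset(small_config(seed = 13))
  cm <- build_call_matrix(sim$bundle)
  groups <- groups_of(sim$bundle)
  tab <- compute_tcs_table(sim$bundle$expression, cm, sim$bundle$genes,
                           groups)
  low <- dichotomize_expression(sim$bundle$expression)
  for (g in sample(tab$gene, 8)) {
    d <- suppressWarnings(gene_deletion_status(g, cm, sim$bundle$genes))
    one <- compute_tcs(g, low[g, ], d, groups)
    row <- tab[tab$gene == g, ]
    expect_equal(row$tcs, one$tcs)
    expect_equal(row$control_tcs, one$control_tcs)
    expect_equal(row$passes, one$passes)
  }
  ## scores are proportions whenever defined
  expect_true(all(tab$tcs >= 0 & tab$tcs <= 1, na.rm = TRUE))
  expect_true(all(tab$control_tcs >= 0 & tab$control_tcs <= 1, na.rm = TRUE))
})

test_that("planted coupled genes pass and uncoupled genes do not", {
  sim <- simulate_dataset(noiseless_config(seed = 17))
  cm <- build_call_matrix(sim$bundle)
  groups <- groups_of(sim$bundle)
  tab <- compute_tcs_table(sim$bundle$expression, cm, sim$bundle$genes,
                           groups)
  enr <- fisher_cytoband_enrichment(cm, groups, "deletion")
  in_enr <- genes_in_enriched_loci(enr, sim$bundle$genes,
                                   sim$bundle$cytobands)
  got <- select_consistent_genes(tab, in_enr)
  expect_setequal(got, intersect(sim$truth$coupled_genes, in_enr))
  ## empty restriction -> empty selection
  expect_length(select_consistent_genes(tab, character()), 0)
})

test_that("uncoupled expression keeps the pass rate near zero", {
  ## no planted expression effect: passing is a false positive
  sim <- simulate_dataset(sim_config(seed = 23, expr_effect = 0))
  cm <- build_call_matrix(sim$bundle)
  groups <- groups_of(sim$bundle)
  tab <- compute_tcs_table(sim$bundle$expression, cm, sim$bundle$genes,
                           groups)
  expect_lt(mean(tab$passes), 0.05)
})
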