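test_that("carrier collapsing is dominant and per model", {
  q <- dplyr::bind_rows(
    qvar(sample = "P1", gene = "G1", pos = 100L),
    qvar(sample = "P1", gene = "G1", pos = 200L),
    qvar(sample = "P1", gene = "G1", pos = 300L),
    qvar(sample = "P2", gene = "G2", pos = 400L,
         category = "high_impact_other", consequence = "inframe_deletion"),
    qvar(sample = "P3", gene = "G3", pos = 500L,
         category = "missense_high_cadd", consequence = "missense"))
  cc <- collapse_carriers(q, "ptv_only")
  expect_equal(cc$case_carriers[cc$gene == "G1"], 1L)    # 3 PTVs, 1 carrier
  expect_false("G2" %in% cc$gene)
  cc2 <- collapse_carriers(q, "ptv_plus_high_impact")
  expect_true("G2" %in% cc2$gene)
  expect_false("G3" %in% cc2$gene)  # plain missense never enters the burden

  # disjoint carrier sets of 8 and 7 for two variants of one gene -> 15
  big <- dplyr::bind_rows(
    lapply(sprintf("A%02d", 1:8), function(p) qvar(sample = p, gene = "GX", pos = 100L)),
    lapply(sprintf("B%02d", 1:7), function(p) qvar(sample = p, gene = "GX", pos = 200L)))
  expect_equal(collapse_carriers(big)$case_carriers, 15L)
})

test_that("control carriers are summed allele counts capped at cohort size", {
  cc <- control_carrier_estimate(tibble::tibble(
    gene = "G1", ac = c(3, 5), an = 30000), n_controls = 15708)
  expect_equal(cc$control_carriers, 8)
  capped <- control_carrier_estimate(tibble::tibble(
    gene = "G1", ac = 20000, an = 40000), n_controls = 15708)
  expect_equal(capped$control_carriers, 15708)
  expect_warning(miss <- control_carrier_estimate(tibble::tibble(
    gene = "G1", ac = c(3, 5), an = c(30000, NA))), "missing allele number")
  expect_equal(miss$control_carriers, 3)
})

test_that("the one-sided burden p-value matches its exact closed forms", {
  expect_equal(fisher_burden(3, 10, 1, 50), 0.01273493, tolerance = 1e-6)
  expect_equal(fisher_burden(0, 10, 5, 50), 1)
  expect_equal(fisher_burden(0, 1000, 0, 15708), 1)     # zero margin
  # all cases carriers, no controls: single-table probability
  expect_equal(fisher_burden(5, 5, 0, 7), 1 / choose(12, 5))
  expect_equal(fisher_burden(3, 3, 0, 10), 1 / choose(13, 3))
  expect_error(fisher_burden(5, 3, 0, 10), "inconsistent")
})

test_that("burden p-values agree with the independent Fisher oracle", {
  set.seed(21)
  for (i in 1:60) {
    k <- sample(0:12, 1); nc <- k + sample(1:40, 1)
    m <- sample(0:30, 1); nm <- m + sample(1:150, 1)
    mine <- fisher_burden(k, nc, m, nm)
    oracle <- fisher.test(matrix(c(k, nc - k, m, nm - m), 2, byrow = TRUE),
                          alternative = "greater")$p.value
    expect_equal(mine, oracle, tolerance = 1e-10)
  }
})

test_that("Benjamini-Hochberg adjustment matches the hand computation", {
  expect_equal(fdr_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(fdr_adjust(0.5), 0.5)
  expect_equal(fdr_adjust(numeric(0)), numeric(0))
  set.seed(5)
  p <- runif(50)
  q <- fdr_adjust(p)
  expect_true(all(q >= p))
  expect_true(all(diff(q[order(p)]) >= -1e-12))  # monotone in sorted order
})

test_that("genomic lambda behaves at its reference points", {
  expect_equal(genomic_lambda(0.5), 1)
  expect_warning(expect_equal(genomic_lambda(rep(1, 5)), 0), "lambda = 0")
  expect_gt(genomic_lambda(runif(2000) / 50), 1)  # systematic inflation
  set.seed(8)
  expect_equal(genomic_lambda(runif(10000)), 1, tolerance = 0.05)
})

test_that("adding a variant to a gene never decreases its carrier count", {
  set.seed(31)
  q <- dplyr::bind_rows(lapply(1:40, function(i)
    qvar(sample = sprintf("P%02d", sample(1:15, 1)), gene = "G1",
         pos = sample(c(100L, 200L, 300L), 1)))) |>
    dplyr::distinct(sample, pos, .keep_all = TRUE)
  for (i in seq(5, nrow(q), by = 5)) {
    expect_lte(collapse_carriers(q[1:(i - 1), ])$case_carriers,
               collapse_carriers(q[1:i, ])$case_carriers)
  }
})

test_that("the collapsing test is level-valid on null count cohorts", {
  cnt <- simulate_burden_counts(500, 500, 15708, seed = 77)
  b <- burden_from_counts(cnt, 500, 15708)
  # an exact test never exceeds its nominal level (it is conservative)
  frac <- mean(b$p < 0.05)
  expect_lte(frac, 0.05 + 2.576 * sqrt(0.05 * 0.95 / nrow(b)))
  expect_true(all(b$p > 0 & b$p <= 1))
  expect_true(all(b$q >= b$p))
})

test_that("a strongly enriched gene is flagged at q < 0.1", {
  cnt <- simulate_burden_counts(200, 500, 15708,
                                enriched = c(GENE0001 = 10), seed = 13)
  b <- burden_from_counts(cnt, 500, 15708)
  expect_true(b$gene[1] == "GENE0001")
  expect_lt(b$q[1], 0.1)
  expect_true(b$significant[1])
})

test_that("burden results carry tidy/glance summaries and a QQ autoplot", {
  cnt <- simulate_burden_counts(50, 200, 2000, seed = 3)
  b <- burden_from_counts(cnt, 200, 2000)
  td <- tidy(b)
  expect_false(inherits(td, "rg_burden"))
  expect_true(all(c("gene", "p", "q") %in% names(td)))
  gl <- glance(b)
  expect_equal(gl$n_genes, nrow(b))
  expect_equal(gl$lambda, attr(b, "lambda"))
  expect_s3_class(autoplot(b), "ggplot")
})
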