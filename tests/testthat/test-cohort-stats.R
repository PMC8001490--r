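test_that("carrier percentages reproduce printed cohort figures", {
  expect_equal(carrier_percentage(113, 726), 15.56)
  expect_equal(carrier_percentage(693, 726), 95.45)
  expect_equal(carrier_percentage(0, 726), 0)
  expect_equal(carrier_percentage(726, 726), 100)
  expect_equal(carrier_percentage(22, 726, decimals = 0), 3)
  expect_error(carrier_percentage(1, 0), "positive")
  expect_error(carrier_percentage(10, 5), "carrier_count")
  # scale invariance
  for (c_ in c(2L, 5L, 10L)) {
    expect_equal(carrier_percentage(113, 726), carrier_percentage(113 * c_, 726 * c_))
  }
})

test_that("rounding is half-up, not banker's", {
  expect_equal(carrier_percentage(1, 8, 0), 13)   # 12.5 -> 13
  expect_equal(carrier_percentage(25, 1000, 1), 2.5)
  expect_equal(carrier_percentage(125, 10000, 1), 1.3)  # 1.25 -> 1.3
})

test_that("mutation rates use explicit denominators and recompose", {
  expect_equal(mutation_rate(100, 100, 10), 0.1)
  expect_equal(mutation_rate(0, 50, 10), 0)
  expect_error(mutation_rate(10, 0, 10), "positive")
  # panel and background rates recompose to the overall rate
  n_p <- 899; n_b <- 17000; pts <- 726; m_p <- 1665; m_b <- 44000
  overall <- mutation_rate(m_p + m_b, n_p + n_b, pts)
  weighted <- (mutation_rate(m_p, n_p, pts) * n_p +
                 mutation_rate(m_b, n_b, pts) * n_b) / (n_p + n_b)
  expect_equal(overall, weighted)
})

test_that("fold enrichment handles observed, zero and novel variants", {
  fe <- fold_enrichment(4, 1452, 0.0001)
  expect_equal(round_half_up(fe$fold, 2), 27.55)
  expect_false(fe$novel)
  expect_equal(fold_enrichment(0, 1452, 0.001)$fold, 0)
  nv <- fold_enrichment(4, 1452, 0)
  expect_true(nv$novel)
  expect_true(is.na(nv$fold))
  expect_error(fold_enrichment(4, 0, 0.1), "positive")
})

test_that("subgroup Fisher tests match exhaustive table enumeration", {
  # independent oracle: sum point probabilities <= observed over all tables
  # with the observed margins
  enum_two_sided <- function(a, b, c_, d) {
    K <- a + c_; N <- a + b + c_ + d; n <- a + b
    lo <- max(0, n - (N - K)); hi <- min(n, K)
    probs <- vapply(lo:hi, function(x) {
      choose(K, x) * choose(N - K, n - x) / choose(N, n)
    }, numeric(1))
    obs <- probs[a - lo + 1]
    sum(probs[probs <= obs * (1 + 1e-7)])
  }
  expect_equal(subgroup_fisher(tibble::tibble(
    gene = "g", carriers_a = 0, n_a = 10, carriers_b = 0, n_b = 20))$p, 1)
  expect_equal(subgroup_fisher(tibble::tibble(
    gene = "g", carriers_a = 5, n_a = 10, carriers_b = 5, n_b = 10))$p, 1)
  exclusive <- subgroup_fisher(tibble::tibble(
    gene = "TSC2", carriers_a = 8, n_a = 504, carriers_b = 0, n_b = 222))
  expect_equal(exclusive$p, enum_two_sided(8, 496, 0, 222), tolerance = 1e-9)
  set.seed(14)
  for (i in 1:25) {
    a <- sample(0:12, 1); na <- a + sample(0:48, 1)
    b <- sample(0:12, 1); nb <- b + sample(0:48, 1)
    if (a + b == 0 || na + nb == 0) next
    got <- subgroup_fisher(tibble::tibble(
      gene = "g", carriers_a = a, n_a = na, carriers_b = b, n_b = nb))$p
    if ((a == 0 && b == 0) || (a == na && b == nb)) {
      expect_equal(got, 1)
    } else {
      expect_equal(got, enum_two_sided(a, na - a, b, nb - b), tolerance = 1e-7)
    }
  }
})

test_that("variant type percentages sum to 100 within rounding", {
  set.seed(2)
  q <- tibble::tibble(consequence = sample(names(default_type_mix()), 5000,
                                           TRUE, default_type_mix()))
  d <- variant_type_distribution(q)
  expect_lte(abs(sum(d$percent) - 100), 0.5)
  expect_equal(sum(d$n), 5000L)
})

test_that("gene annotation joins report curation verbatim, never fabricated", {
  ann <- readr::read_tsv(raregerm_example("gene_annotations.tsv"),
                         show_col_types = FALSE)
  counts <- tibble::tibble(gene = c("ATM", "NOVELGENE"), n_cases = c(25, 3))
  out <- annotate_genes(counts, flags = ann$gene[ann$flags == "Yes"],
                        plof = ann[, c("gene", "plof_oe", "plof_oe_ci")])
  expect_equal(out$plof_oe[out$gene == "ATM"], 0.6)
  expect_equal(out$plof_oe_ci[out$gene == "ATM"], "0.51-0.71")
  expect_equal(out$flags[out$gene == "ATM"], "No")
  expect_true(is.na(out$plof_oe[out$gene == "NOVELGENE"]))
  bare <- annotate_genes(counts)
  expect_equal(bare$flags, c("No", "No"))
})

test_that("distinct carriers deduplicate shared patients across variants", {
  wrn <- readr::read_tsv(raregerm_example("wrn_cll_variants.tsv"),
                         show_col_types = FALSE)
  expect_equal(sum(wrn$cll_cases), 9)
  expect_equal(distinct_carriers(wrn$cll_cases, wrn$patient_group), 8)
  expect_equal(distinct_carriers(c(3, 2)), 5)
})
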