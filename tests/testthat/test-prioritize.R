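test_that("gene panels are non-redundant unions with provenance", {
  p <- build_gene_panel(list(L1 = c("A", "B"), L2 = c("B", "C")))
  expect_setequal(p$gene, c("A", "B", "C"))
  expect_setequal(p$sources[p$gene == "B"][[1]], c("L1", "L2"))
  expect_equal(build_gene_panel(list(only = c("x", "Y")))$gene, c("X", "Y"))
  expect_error(build_gene_panel(list(L1 = character())), "empty gene panel")
})

test_that("six overlapping source lists of realistic sizes union to 899 genes", {
  universe <- sprintf("g%03d", 1:899)
  lists <- list(
    mendelian = universe[1:162],
    census = universe[100:822],          # 723
    target = universe[700:834],          # 135
    cll = universe[820:878],             # 59
    dlbcl = c(universe[879:899], universe[1:129]),   # 150, brings in the tail
    burkitt = universe[400:471]          # 72
  )
  expect_equal(lengths(lists), c(mendelian = 162, census = 723, target = 135,
                                 cll = 59, dlbcl = 150, burkitt = 72))
  panel <- build_gene_panel(lists)
  expect_equal(nrow(panel), 899L)
})

test_that("popmax uses strict thresholds and population exclusions", {
  r <- popmax(c(NFE = 0.004, FIN = 0.02, ASJ = 0.01, AFR = 0.001))
  expect_equal(r$popmax, 0.004)
  expect_true(r$passes)
  r2 <- popmax(c(NFE = 0.005))
  expect_equal(r2$popmax, 0.005)
  expect_false(r2$passes)                      # strict inequality
  r3 <- popmax(numeric(0))                     # unobserved variant
  expect_equal(r3$popmax, 0)
  expect_true(r3$passes)
  r4 <- popmax(c(FIN = 0.02, ASJ = 0.01))      # only excluded populations
  expect_equal(r4$popmax, 0)
  # no-exclusion behavior used for cohort characterization
  r5 <- popmax(c(NFE = 0.004, FIN = 0.02), exclude = character())
  expect_false(r5$passes)
})

test_that("impact classification keeps PTVs, strict-CADD missense and extras", {
  expect_equal(classify_variant("stop_gained", 5), "PTV")
  expect_equal(classify_variant("missense", 20.0), NA_character_)  # boundary
  expect_equal(classify_variant("missense", 20.1), "missense_high_cadd")
  expect_equal(classify_variant("inframe_deletion", 15, high_impact_extra = TRUE),
               "high_impact_other")
  expect_equal(classify_variant("synonymous", 35), NA_character_)
  expect_warning(res <- classify_variant("missense", NA_real_), "without a")
  expect_equal(res, NA_character_)
})

test_that("panel restriction partitions exhaustively and disjointly", {
  v <- tibble::tibble(gene = c("ATM", "ZZZ9", NA), id = 1:3)
  out <- restrict_to_panel(v, c("ATM"))
  expect_equal(out$stream, c("qualifying", "background", "background"))
  allbg <- restrict_to_panel(v, character())
  expect_true(all(allbg$stream == "background"))
})

make_cascade_inputs <- function() {
  cons <- dplyr::bind_rows(lapply(1:8, function(i)
    caller_obs(sample = "P1", pos = 100L * i)))[, c("sample", "chrom", "pos",
                                                    "ref", "alt", "vaf")]
  cons$zygosity <- "het"
  csq <- tibble::tibble(
    chrom = "chr1", pos = 100L * (1:8), ref = "A", alt = "T",
    gene = c("G1", "G1", "G2", "G2", "G3", "G3", NA, "G4"),
    consequence = c("stop_gained", "missense", "missense", "missense",
                    "synonymous", "inframe_deletion", "missense", "missense"),
    high_impact_extra = c(FALSE, FALSE, FALSE, FALSE, FALSE, TRUE, FALSE, FALSE))
  cadd <- tibble::tibble(chrom = "chr1", pos = 100L * (1:8), ref = "A", alt = "T",
                         cadd_phred = c(10, 25, 30, 19, 40, 12, 30, 30))
  af <- tibble::tibble(chrom = "chr1", pos = rep(100L * (1:8), each = 2),
                       ref = "A", alt = "T",
                       population = rep(c("NFE", "FIN"), 8),
                       af = c(0.001, 0.001,  0.002, 0.001,  0.01, 0.001,
                              0.001, 0.001,  0.001, 0.001,  0.0001, 0.02,
                              0.001, 0.001,  0.002, 0.001))
  list(cons = cons, csq = csq, cadd = cadd, af = af,
       panel = c("G1", "G2", "G3"))
}

test_that("the cascade filters by rarity, impact and panel, in any order", {
  inp <- make_cascade_inputs()
  q <- prioritize_variants(inp$cons, inp$csq, inp$cadd, inp$af, inp$panel)
  # pos 100: PTV low CADD kept; 200: missense 25 kept; 300: popmax 0.01 out;
  # 400: CADD 19 out; 500: synonymous out; 600: inframe extra kept (FIN spike
  # not excluded by default characterization popmax -> out unless excluded)
  expect_setequal(q$pos, c(100L, 200L))
  q2 <- prioritize_variants(inp$cons, inp$csq, inp$cadd, inp$af, inp$panel,
                            exclude_pops = c("FIN", "ASJ", "OTH"))
  expect_setequal(q2$pos, c(100L, 200L, 600L))
  expect_equal(q2$category[q2$pos == 600L], "high_impact_other")

  # order independence: panel restriction before vs after classification
  kept <- prioritize_variants(inp$cons, inp$csq, inp$cadd, inp$af, NULL,
                              keep_background = TRUE)
  manual <- kept[kept$stream == "qualifying" &
                   !is.na(kept$gene) & kept$gene %in% inp$panel, ]
  expect_setequal(manual$pos, q$pos)
})

test_that("relaxing CADD or popmax thresholds never shrinks the qualifying set", {
  inp <- make_cascade_inputs()
  base <- prioritize_variants(inp$cons, inp$csq, inp$cadd, inp$af, inp$panel)
  lower_cadd <- prioritize_variants(inp$cons, inp$csq, inp$cadd, inp$af,
                                    inp$panel, cadd_min = 15)
  higher_pm <- prioritize_variants(inp$cons, inp$csq, inp$cadd, inp$af,
                                   inp$panel, popmax_max = 0.05)
  expect_true(all(base$pos %in% lower_cadd$pos))
  expect_true(all(base$pos %in% higher_pm$pos))
  expect_gte(nrow(higher_pm), nrow(base))
})

test_that("each qualifying variant traces to exactly one consensus record", {
  cc <- noise_free_cohort()
  q <- cc$result$qualifying
  cons <- cc$result$consensus
  joined <- dplyr::inner_join(
    q, dplyr::mutate(cons, .cid = dplyr::row_number()),
    by = c("sample", "chrom", "pos", "ref", "alt"))
  expect_equal(nrow(joined), nrow(q))       # no orphans
  expect_equal(anyDuplicated(joined$.cid), 0L)  # no duplication
})

test_that("novelty is absence from the supplied known-variant table", {
  inp <- make_cascade_inputs()
  known <- tibble::tibble(chrom = "chr1", pos = 100L, ref = "A", alt = "T")
  q <- prioritize_variants(inp$cons, inp$csq, inp$cadd, inp$af, inp$panel,
                           known_variants = known)
  expect_false(q$novel[q$pos == 100L])
  expect_true(q$novel[q$pos == 200L])
})
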