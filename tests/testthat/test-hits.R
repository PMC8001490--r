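test_that("homozygote events are emitted per patient and variant", {
  q <- dplyr::bind_rows(
    qvar(sample = "P1", gene = "ZC1", pos = 100L, zygosity = "hom_alt"),
    qvar(sample = "P2", gene = "ZC1", pos = 100L, zygosity = "hom_alt"),
    qvar(sample = "P3", gene = "ZC1", pos = 100L, zygosity = "het"))
  ev <- detect_homozygotes(q)
  expect_equal(nrow(ev), 2L)                       # same variant, two patients
  expect_setequal(ev$patient, c("P1", "P2"))
  expect_equal(unique(unlist(ev$variants)), "chr1:100:A:T")
})

test_that("germline double hits cover het pairs and het+hom combinations", {
  two_het <- dplyr::bind_rows(
    qvar(sample = "P1", gene = "FAT1", pos = 100L),
    qvar(sample = "P1", gene = "FAT1", pos = 200L))
  ev <- detect_germline_double_hits(two_het)
  expect_equal(nrow(ev), 1L)
  expect_equal(lengths(ev$variants), 2L)
  expect_equal(ev$phase, "unknown")

  # het + hom_alt in the same gene: homozygote event AND double-hit event
  mixed <- dplyr::bind_rows(
    qvar(sample = "P1", gene = "GLI1", pos = 100L, zygosity = "het"),
    qvar(sample = "P1", gene = "GLI1", pos = 200L, zygosity = "hom_alt"))
  all_ev <- detect_double_hits(mixed)
  expect_setequal(all_ev$kind, c("homozygote", "germline_double_hit"))
  expect_equal(nrow(all_ev), 2L)

  # a single het yields nothing
  expect_equal(nrow(detect_germline_double_hits(qvar())), 0L)
})

test_that("phase tables resolve compound candidates to cis or trans", {
  q <- dplyr::bind_rows(
    qvar(sample = "P1", gene = "ARID1B", pos = 100L),
    qvar(sample = "P1", gene = "ARID1B", pos = 200L))
  cis <- tibble::tibble(patient = "P1", chrom = "chr1", pos = c(100L, 200L),
                        ref = "A", alt = "T", haplotype = c(1L, 1L))
  expect_equal(detect_germline_double_hits(q, cis)$phase, "cis")
  trans <- dplyr::mutate(cis, haplotype = c(1L, 2L))
  expect_equal(detect_germline_double_hits(q, trans)$phase, "trans")
  partial <- cis[1, ]
  expect_equal(detect_germline_double_hits(q, partial)$phase, "unknown")
})

test_that("somatic and LOH second hits require the same patient and gene/locus", {
  q <- qvar(sample = "P1", gene = "KMT2D", chrom = "chr12", pos = 500L)
  som <- tibble::tibble(patient = c("P1", "P2"), gene = c("KMT2D", "MYC"))
  ev <- detect_somatic_second_hits(q, somatic = som)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$kind, "germline_somatic")
  expect_equal(ev$patient, "P1")
  # somatic mutation in a gene with no germline qualifying variant: no event
  ev2 <- detect_somatic_second_hits(q, somatic = tibble::tibble(
    patient = "P1", gene = "MYC"))
  expect_equal(nrow(ev2), 0L)

  loh <- tibble::tibble(patient = "P1", chrom = "chr12",
                        start = 400L, end = 600L, type = "CN-LOH")
  ev3 <- detect_somatic_second_hits(q, loh = loh)
  expect_equal(ev3$kind, "loh_second_hit")
  outside <- dplyr::mutate(loh, start = 600L, end = 700L)
  expect_equal(nrow(detect_somatic_second_hits(q, loh = outside)), 0L)
  malformed <- dplyr::mutate(loh, start = 600L, end = 500L)
  expect_warning(ev4 <- detect_somatic_second_hits(q, loh = malformed),
                 "malformed")
  expect_equal(nrow(ev4), 0L)
})

test_that("CHIP verdicts follow the tumor-compartment allele fraction", {
  q <- dplyr::bind_rows(
    qvar(sample = "P1", gene = "DNMT3A", pos = 100L, vaf = 0.42),
    qvar(sample = "P2", gene = "TET2", pos = 200L, vaf = 0.48),
    qvar(sample = "P3", gene = "NOTCH1", pos = 300L, vaf = 0.50))
  tv <- tibble::tibble(patient = c("P1", "P2"), chrom = "chr1",
                       pos = c(100L, 200L), ref = "A", alt = "T",
                       tumor_vaf = c(0.00, 0.47))
  chip <- assess_chip(q, chip_genes = c("DNMT3A", "TET2"), tumor_vaf = tv)
  expect_equal(nrow(chip), 2L)                  # NOTCH1 not assessed
  expect_equal(chip$verdict[chip$gene == "DNMT3A"], "likely_chip")
  expect_equal(chip$verdict[chip$gene == "TET2"], "germline")

  # missing tumor data: kept as germline, flagged not assessable
  chip2 <- assess_chip(q, chip_genes = "DNMT3A", tumor_vaf = NULL)
  expect_equal(chip2$verdict, "germline")
  expect_false(chip2$assessable)

  filtered <- remove_chip(q, chip)
  expect_false("P1" %in% filtered$sample)
  expect_true(all(c("P2", "P3") %in% filtered$sample))
})

test_that("event detection is stable under input row permutations", {
  set.seed(9)
  q <- dplyr::bind_rows(lapply(1:30, function(i)
    qvar(sample = sample(paste0("P", 1:5), 1),
         gene = sample(c("G1", "G2"), 1),
         pos = sample(c(100L, 200L, 300L), 1),
         zygosity = sample(c("het", "hom_alt"), 1, prob = c(0.8, 0.2))))) |>
    dplyr::distinct(sample, gene, chrom, pos, ref, alt, .keep_all = TRUE)
  som <- tibble::tibble(patient = c("P1", "P3"), gene = c("G1", "G2"))
  a <- detect_double_hits(q, somatic = som)
  b <- detect_double_hits(q[sample.int(nrow(q)), ], somatic = som)
  expect_equal(a, b)
})

test_that("planted structures are recovered exactly on a noise-free cohort", {
  cc <- noise_free_cohort()
  truth <- cc$cohort$truth$events
  res <- cc$result

  detected <- dplyr::bind_rows(
    dplyr::transmute(flatten_events(res$events), patient, gene, kind = kind),
    res$chip |>
      dplyr::filter(verdict == "likely_chip") |>
      dplyr::transmute(patient, gene, kind = "chip"))
  truth_pg <- dplyr::distinct(truth, patient, gene, kind)
  det_pg <- dplyr::distinct(detected, patient, gene, kind)
  expect_gte(nrow(truth_pg), 10)    # the planted structure is non-trivial
  missed <- dplyr::anti_join(truth_pg, det_pg, by = c("patient", "gene", "kind"))
  spurious <- dplyr::anti_join(det_pg, truth_pg, by = c("patient", "gene", "kind"))
  expect_equal(nrow(missed), 0L)      # recall 1
  expect_equal(nrow(spurious), 0L)    # precision 1
})

test_that("removing CHIP variants never touches genes outside the CHIP list", {
  cc <- noise_free_cohort()
  chip_genes <- cc$cohort$truth$chip_genes
  q <- cc$result$qualifying   # already CHIP-filtered by the pipeline
  qual_all <- dplyr::bind_rows(q, q[0, ])
  refiltered <- remove_chip(qual_all, cc$result$chip)
  outside_before <- dplyr::filter(qual_all, !gene %in% chip_genes)
  outside_after <- dplyr::filter(refiltered, !gene %in% chip_genes)
  expect_equal(outside_before, outside_after)
})
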