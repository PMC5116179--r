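test_that("somatic rule: inclusive thresholds, reasons, indeterminate cases", {
  th <- filter_thresholds()
  rec <- tibble::tibble(
    chrom = "chr1", pos = c(1, 2, 3, 4) * 100L, ref = "A", alt = "G",
    gene = c("TOE1", "A", "B", "C"), consequence = "missense",
    maf = NA_real_,
    tumor_dp = c(15, 100, 9, 30), tumor_alt = c(3, 19, 4, 12),
    tumor_vaf = c(0.20, 0.19, 0.43, 0.40),
    patient_dp = c(18, 50, 30, NA), patient_alt = c(0, 0, 0, NA),
    patient_vaf = c(0, 0, 0, NA)
  )
  out <- call_somatic(rec, th)
  # boundary VAF of exactly 20% at 15x/18x passes
  expect_true(out$somatic[1])
  expect_false(out$somatic[2]); expect_equal(out$somatic_reason[2], "low_vaf")
  expect_false(out$somatic[3]); expect_equal(out$somatic_reason[3], "low_tumor_depth")
  expect_true(is.na(out$somatic[4]))
  expect_equal(out$somatic_reason[4], "missing_call")
})

test_that("de novo rule needs a clean trio and finds none in the case tables", {
  rec <- tibble::tibble(
    chrom = "chr1", pos = c(1, 2) * 100L, ref = "A", alt = "G",
    gene = c("X", "Y"), consequence = "missense", maf = NA_real_,
    patient_dp = 30, patient_alt = c(14, 14), patient_vaf = 0.45,
    mother_dp = 40, mother_alt = c(0, 12), mother_vaf = c(0, 0.30),
    father_dp = 40, father_alt = 0, father_vaf = 0
  )
  out <- call_de_novo(rec)
  expect_true(out$de_novo[1])
  expect_false(out$de_novo[2])
  expect_equal(out$de_novo_reason[2], "parent_support")

  combined <- dplyr::bind_rows(build_fixture("table1"), build_fixture("table2"),
                               build_fixture("table3"))
  cls <- classify_variants(combined)
  expect_identical(unname(cls$summary["n_de_novo"]), 0L)
})

test_that("rare-homozygous rule follows genotypes and the MAF ceiling", {
  base <- tibble::tibble(
    chrom = "chr3", pos = 100L, ref = "G", alt = "T", gene = "RASSF1",
    consequence = "missense", maf = 0.0711,
    patient_dp = 12, patient_alt = 10, patient_vaf = 0.833,
    mother_dp = 40, mother_alt = 11, mother_vaf = 0.275,
    father_dp = 32, father_alt = 17, father_vaf = 0.531
  )
  expect_true(call_rare_homozygous(base)$rare_homozygous)
  common <- dplyr::mutate(base, maf = 0.25)
  out <- call_rare_homozygous(common)
  expect_false(out$rare_homozygous)
  expect_equal(out$rare_homozygous_reason, "common_maf")
  het <- dplyr::mutate(base, patient_vaf = 0.5, patient_alt = 6)
  expect_false(call_rare_homozygous(het)$rare_homozygous)

  t2 <- build_fixture("table2")
  cls <- classify_variants(t2)
  called <- tidy(cls) |> dplyr::filter(rare_homozygous %in% TRUE)
  expect_setequal(called$gene, c("VEZT", "ISX", "RASSF1", "ADAMTS12"))
})

test_that("compound-het rule needs opposite-parent exclusivity within a gene", {
  t3 <- build_fixture("table3")  # includes same-parent / ambiguous decoys
  res <- call_compound_het(t3)
  expect_identical(nrow(res$genes), 11L)
  expect_false(any(grepl("^DEC3", res$genes$gene)))
  expect_identical(nrow(res$pairs), 11L)  # one maternal x paternal pair each
  # derived parental origin matches the printed origin on every real row
  mem <- res$members |> dplyr::filter(!is_decoy)
  expect_identical(mem$comphet_origin, mem$printed_origin)

  # a planted compound-het pair at depth 50x is recovered from simulation
  cfg <- sim_config(seed = 21, depth_mean = 50,
                    planted = plant_variants(1, classes = c("comphet_maternal",
                                                            "comphet_paternal")))
  sim <- simulate_trio(cfg)
  expect_identical(call_compound_het(sim$records)$genes$gene, "CHGENE001")
})

test_that("classify_variants matches the brute-force oracle on random cases", {
  for (seed in 1:8) {
    rec <- random_records(20, seed)
    cls <- classify_variants(rec)
    orc <- oracle_classify(rec)
    v <- tidy(cls)
    expect_identical(v$somatic, orc$somatic)
    expect_identical(v$de_novo, orc$de_novo)
    expect_identical(v$rare_homozygous, orc$rare_homozygous)
    expect_identical(v$comphet_origin, orc$comphet_origin)
    expect_identical(sort(cls$genes$gene), orc$comphet_genes)
  }
})

test_that("raising thresholds never increases calls (monotonicity)", {
  rec <- random_records(200, 99)
  base <- classify_variants(rec)$summary
  tighter <- list(
    filter_thresholds(min_depth = 20),
    filter_thresholds(somatic_min_tumor_vaf = 0.4),
    filter_thresholds(denovo_min_vaf = 0.6),
    filter_thresholds(rare_maf_max = 0.01)
  )
  for (th in tighter) {
    s <- classify_variants(rec, th)$summary
    expect_lte(s[["n_somatic"]], base[["n_somatic"]])
    expect_lte(s[["n_de_novo"]], base[["n_de_novo"]])
    expect_lte(s[["n_rare_homozygous"]], base[["n_rare_homozygous"]])
    expect_lte(s[["n_comphet_genes"]], base[["n_comphet_genes"]])
  }
})

test_that("swapping parents preserves all class sets, flipping origins", {
  rec <- random_records(150, 7)
  a <- classify_variants(rec)
  b <- classify_variants(swap_parents(rec))
  expect_identical(tidy(a)$somatic, tidy(b)$somatic)
  expect_identical(tidy(a)$de_novo, tidy(b)$de_novo)
  expect_identical(tidy(a)$rare_homozygous, tidy(b)$rare_homozygous)
  expect_identical(sort(a$genes$gene), sort(b$genes$gene))
  flip <- c(maternal = "paternal", paternal = "maternal")
  expect_identical(unname(flip[tidy(a)$comphet_origin]),
                   tidy(b)$comphet_origin)
})

test_that("somatic calls are disjoint from germline classes", {
  for (seed in c(3, 11, 29)) {
    v <- tidy(classify_variants(random_records(200, seed)))
    som <- v$somatic %in% TRUE
    expect_false(any(som & v$rare_homozygous %in% TRUE))
    expect_false(any(som & v$compound_het_member))
  }
})

test_that("empty input yields zero counts everywhere", {
  s <- classify_variants(tibble::tibble())$summary
  expect_true(all(s == 0))
})

test_that("simulated trios are recovered with high sensitivity and low FDR", {
  # depth 30x, 1000 background variants, 20 planted per class, pooled over
  # a fixed set of seeds
  stats <- recovery_suite(seeds = 2024:2033, depth_mean = 30,
                          n_background = 1000, n_per_class = 20)
  expect_identical(nrow(stats), 4L)
  expect_true(all(stats$sensitivity >= 0.95))
  expect_true(all(stats$fdr <= 0.05))
})
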