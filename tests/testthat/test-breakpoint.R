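test_that("discordance is decided by chromosome and insert distance", {
  pairs <- tibble::tibble(
    pair_id = c("a", "b", "c"),
    chrom1 = c("chr11", "chr1", "chr1"),
    pos1 = c(100L, 1000L, 1000L), strand1 = "+",
    chrom2 = c("chr22", "chr1", "chr1"),
    pos2 = c(200L, 1000L + 2000L - 60L, 500000L), strand2 = "-"
  )
  disc <- find_discordant(pairs, insert_mean = 2000, insert_sd = 150)
  expect_setequal(disc$pair_id, c("a", "c"))
  expect_identical(disc$discordant_type[disc$pair_id == "a"], "interchromosomal")
  expect_identical(disc$discordant_type[disc$pair_id == "c"], "distance")
})

test_that("simulated junction libraries give exactly the planted discordants", {
  cfg <- sim_config(seed = 31, n_matepairs = 50, n_concordant = 10000)
  pairs <- simulate_matepairs(cfg, junction = list("chr2", 6e6, "chr3", 3e6))
  disc <- find_discordant(pairs, cfg$insert_size_mean, cfg$insert_size_sd)
  inter <- disc[disc$discordant_type == "interchromosomal", ]
  expect_identical(nrow(inter), 50L)
  expect_true(all(inter$origin == "junction"))
})

test_that("clustering recovers the junction and respects min_support", {
  cfg <- sim_config(seed = 17, n_matepairs = 50, n_concordant = 5000)
  pairs <- simulate_matepairs(cfg, junction = list("chr1", 5e6, "chr2", 2e6))
  disc <- find_discordant(pairs, cfg$insert_size_mean, cfg$insert_size_sd)
  calls <- cluster_breakpoints(disc, insert_mean = cfg$insert_size_mean,
                               insert_sd = cfg$insert_size_sd)
  expect_identical(nrow(calls), 1L)
  expect_identical(calls$supporting_pairs, 50L)
  expect_true(calls$start1 <= 5e6 && 5e6 <= calls$end1)
  expect_true(calls$start2 <= 2e6 && 2e6 <= calls$end2)
  span <- cfg$insert_size_mean + 3 * cfg$insert_size_sd
  expect_lte(calls$end1 - calls$start1, span)
  expect_lte(calls$end2 - calls$start2, span)
  # below min_support: no call
  expect_identical(nrow(cluster_breakpoints(disc, min_support = 51)), 0L)
})

test_that("junctions far apart give separate calls; pair order is irrelevant", {
  cfg1 <- sim_config(seed = 4, n_matepairs = 20, n_concordant = 0)
  cfg2 <- sim_config(seed = 5, n_matepairs = 20, n_concordant = 0)
  pairs <- dplyr::bind_rows(
    simulate_matepairs(cfg1, junction = list("chr1", 2e6, "chr2", 2e6)),
    simulate_matepairs(cfg2, junction = list("chr1", 8e6, "chr2", 8e6))
  )
  calls <- cluster_breakpoints(pairs, window = 10000)
  expect_identical(nrow(calls), 2L)
  set.seed(1)
  shuffled <- pairs[sample.int(nrow(pairs)), ]
  calls2 <- cluster_breakpoints(shuffled, window = 10000)
  expect_identical(dplyr::arrange(calls, start1),
                   dplyr::arrange(calls2, start1))
})

test_that("junction recovery holds across 100 random libraries", {
  hits <- 0L
  for (seed in 1:100) {
    cfg <- sim_config(seed = seed, n_matepairs = 50, n_concordant = 2000)
    pairs <- simulate_matepairs(cfg, junction = list("chr1", 5e6, "chr3", 4e6))
    disc <- find_discordant(pairs, cfg$insert_size_mean, cfg$insert_size_sd)
    calls <- cluster_breakpoints(disc, insert_mean = cfg$insert_size_mean,
                                 insert_sd = cfg$insert_size_sd)
    top <- calls[1, ]
    if (nrow(calls) >= 1 && top$chrom1 == "chr1" && top$chrom2 == "chr3" &&
        top$start1 <= 5e6 && 5e6 <= top$end1 &&
        top$start2 <= 4e6 && 4e6 <= top$end2) {
      hits <- hits + 1L
    }
  }
  expect_gte(hits, 99L)
})

test_that("assay regions fuse the two junction flanks", {
  set.seed(2)
  genome <- c(chrA = paste(sample(c("A", "C", "G", "T"), 10000, TRUE), collapse = ""),
              chrB = paste(sample(c("A", "C", "G", "T"), 10000, TRUE), collapse = ""))
  call <- tibble::tibble(chrom1 = "chrA", start1 = 5000, end1 = 7450,
                         chrom2 = "chrB", start2 = 1550, end2 = 4000,
                         supporting_pairs = 10L, orientation = "+/-")
  assay <- assay_region(call, genome, flank = 400)
  expect_identical(nchar(assay$fused), 800L)
  expect_identical(assay$left_flank, substr(genome[["chrA"]], 4601, 5000))
  expect_identical(assay$right_flank, substr(genome[["chrB"]], 4000, 4399))
  expect_identical(assay$fused, paste0(assay$left_flank, assay$right_flank))

  edge <- dplyr::mutate(call, start1 = 200)
  expect_error(assay_region(edge, genome), "outside")
  empty <- assay_region(call[0, ], genome)
  expect_identical(nrow(empty), 0L)

  # FASTA path input works identically
  f <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">chrA", genome[["chrA"]], ">chrB", genome[["chrB"]]), f)
  expect_identical(assay_region(call, f, flank = 400)$fused, assay$fused)
})

test_that("pair tables round-trip through BEDPE", {
  cfg <- sim_config(seed = 6, n_matepairs = 5, n_concordant = 20)
  pairs <- simulate_matepairs(cfg, junction = list("chr1", 5e6, "chr2", 2e6))
  f <- withr::local_tempfile(fileext = ".bedpe")
  write_bedpe(pairs, f)
  back <- read_bedpe(f)
  expect_identical(back$pos1, pairs$pos1)
  expect_identical(back$chrom2, pairs$chrom2)
  expect_identical(back$strand1, pairs$strand1)
})
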