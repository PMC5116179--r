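test_that("a flat noisy series yields one neutral segment per chromosome", {
  set.seed(1)
  probes <- tibble::tibble(chrom = "chr1", pos = seq(1, 1e6, by = 5000),
                           log2 = rnorm(200, 0, 0.1))
  segs <- segment_probes(probes)
  expect_identical(nrow(segs), 1L)
  expect_identical(segs$call, "neutral")
  expect_identical(segs$n_probes, 200L)
})

test_that("unsorted probes are rejected", {
  probes <- tibble::tibble(chrom = "chr1", pos = c(100, 50, 200),
                           log2 = c(0, 0, 0))
  expect_error(segment_probes(probes), "increasing")
})

test_that("synthetic whole-chromosome gain is called as one covering segment", {
  truth <- tibble::tibble(chrom = "chr1", start = 1, end = 1e7, copy = 3)
  cfg <- sim_config(seed = 8, cna_truth = truth, cna_noise_sd = 0.1)
  probes <- simulate_cna_profile(cfg, 15000)
  ev <- cna_events(segment_probes(probes))
  chr1 <- ev[ev$chrom == "chr1", ]
  expect_identical(nrow(chr1), 1L)
  expect_identical(chr1$call, "gain")
  expect_equal(chr1$start, min(probes$pos[probes$chrom == "chr1"]))
  expect_equal(chr1$end, max(probes$pos[probes$chrom == "chr1"]))
  expect_identical(nrow(ev[ev$chrom != "chr1", ]), 0L)
})

test_that("a 1.3 Mb homozygous deletion is delimited to one probe spacing", {
  spacing <- 15000
  truth <- tibble::tibble(chrom = "chr2", start = 4e6, end = 5.3e6, copy = 0)
  cfg <- sim_config(seed = 12, cna_truth = truth, cna_noise_sd = 0.15)
  probes <- simulate_cna_profile(cfg, spacing)
  ev <- cna_events(segment_probes(probes))
  expect_identical(nrow(ev), 1L)
  expect_identical(ev$call, "homozygous_loss")
  expect_lte(abs(ev$start - 4e6), spacing)
  expect_lte(abs(ev$end - 5.3e6), spacing)
})

test_that("segments partition each chromosome and calls are pure in mean_log2", {
  truth <- tibble::tibble(chrom = c("chr1", "chr2"), start = c(2e6, 1),
                          end = c(8e6, 1e7), copy = c(3, 1))
  cfg <- sim_config(seed = 3, cna_truth = truth, cna_noise_sd = 0.15)
  probes <- simulate_cna_profile(cfg, 15000)
  segs <- segment_probes(probes)
  for (cc in unique(segs$chrom)) {
    s <- segs[segs$chrom == cc, ]
    p <- probes$pos[probes$chrom == cc]
    expect_equal(s$start[1], min(p))
    expect_equal(s$end[nrow(s)], max(p))
    expect_identical(sum(s$n_probes), length(p))
    if (nrow(s) > 1) expect_true(all(s$start[-1] > s$end[-nrow(s)]))
  }
  params <- cna_params()
  reclass <- with(segs, ifelse(mean_log2 >= params$high_gain, "high_gain",
                        ifelse(mean_log2 >= params$gain, "gain",
                        ifelse(mean_log2 <= params$hom_loss, "homozygous_loss",
                        ifelse(mean_log2 <= params$loss, "loss", "neutral")))))
  big <- segs$n_probes >= params$min_probes
  expect_identical(segs$call[big], reclass[big])
  expect_true(all(segs$call[!big] == "neutral"))
})

test_that("read-depth ratios reproduce closed-form log2 calls", {
  # 400 regions, mostly diploid, so median centering leaves events untouched
  regions <- tidyr::expand_grid(chrom = c("chr1", "chr2"), i = 0:199) |>
    dplyr::mutate(start = i * 10000 + 1, end = (i + 1) * 10000) |>
    dplyr::select(-i)
  normal <- regions |> dplyr::mutate(depth = 100)
  gained <- regions$chrom == "chr1" & regions$start <= 5e5
  # tumor = 1.5x normal on a 50-region stretch -> gain at log2(1.5) ~ 0.58
  tumor <- regions |> dplyr::mutate(depth = ifelse(gained, 150, 100))
  ev <- cna_events(call_depth_cna(tumor, normal))
  expect_identical(ev$chrom, "chr1")
  expect_identical(ev$call, "gain")
  expect_lt(abs(ev$mean_log2 - log2(1.5)), 0.01)
  expect_lte(ev$end, 5e5 + 10000)

  # tumor == normal -> nothing
  ev0 <- cna_events(call_depth_cna(normal, normal))
  expect_identical(nrow(ev0), 0L)

  # planted ratio 0.5 -> loss at ~ -1
  lost <- regions$chrom == "chr2" & regions$start > 1e6 & regions$start <= 1.5e6
  tumor2 <- regions |> dplyr::mutate(depth = ifelse(lost, 50, 100))
  ev2 <- cna_events(call_depth_cna(tumor2, normal))
  expect_identical(ev2$call, "loss")
  expect_lt(abs(ev2$mean_log2 + 1), 0.01)

  # low-coverage normal regions are excluded; disjoint sets are an error
  nlow <- normal |> dplyr::mutate(depth = ifelse(start == 1, 5, depth))
  segs <- call_depth_cna(tumor, nlow)
  expect_identical(sum(segs$n_probes), 398L)
  other <- regions |> dplyr::mutate(chrom = "chrZ", depth = 100)
  expect_error(call_depth_cna(tumor, other), "disjoint")
})

test_that("concordance counts same-sign overlaps and uncovered events drop out", {
  ev <- tibble::tibble(chrom = c("chr1", "chr2"), start = c(1, 100),
                       end = c(50, 500), call = c("gain", "loss"))
  expect_equal(cna_concordance(ev, ev)$fraction_validated, 1.0)
  far <- ev |> dplyr::mutate(start = start + 1e6, end = end + 1e6)
  expect_equal(cna_concordance(ev, far)$fraction_validated, 0.0)
  # same interval, opposite sign, never validates
  flip <- ev |> dplyr::mutate(call = c("loss", "gain"))
  expect_equal(cna_concordance(ev, flip)$fraction_validated, 0.0)

  # events placed in regions the second platform does not cover are exactly
  # the ones that fail validation
  arr <- tibble::tibble(chrom = paste0("chr", 1:5),
                        start = 1e6, end = 2e6,
                        call = c("gain", "gain", "loss", "loss", "gain"))
  wes <- arr[1:3, ]  # chr4/chr5 outside the covered region set
  rep <- cna_concordance(arr, wes)
  expect_identical(rep$n_validated, 3L)
  expect_equal(rep$fraction_validated, 3 / 5)
  expect_identical(tidy(rep)$validated, c(TRUE, TRUE, TRUE, FALSE, FALSE))
})
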