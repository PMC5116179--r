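test_that("Poisson quantification inverts the partition model", {
  # zero positives -> zero concentration, not detected
  q0 <- quantify_droplets(tibble::tibble(n_positive = 0L, n_total = 15000L))
  expect_equal(q0$lambda_hat, 0)
  expect_false(q0$detected)
  # closed form: positive fraction 1 - e^-1 -> lambda exactly 1
  n <- 100000L
  q1 <- quantify_droplets(tibble::tibble(
    n_positive = as.integer(round(n * (1 - exp(-1)))), n_total = n))
  expect_equal(q1$lambda_hat, 1, tolerance = 1e-4)
  # simulation round trip at lambda 0.2: CI covers the truth
  q2 <- quantify_droplets(simulate_droplets(0.2, 20000, seed = 5))
  expect_gte(0.2, q2$lambda_low)
  expect_lte(0.2, q2$lambda_high)
  # saturation: point estimate infinite, finite lower bound
  qs <- quantify_droplets(tibble::tibble(n_positive = 100L, n_total = 100L))
  expect_true(qs$saturated)
  expect_true(is.infinite(qs$lambda_hat))
  expect_true(is.finite(qs$lambda_low))
  expect_error(quantify_droplets(tibble::tibble(n_positive = 0L, n_total = 0L)),
               "positive")
})

test_that("replicates pool before estimation and volume scales concentration", {
  reps <- tibble::tibble(channel = "fusion", replicate = 1:2,
                         n_positive = c(50L, 70L), n_total = c(10000L, 10000L))
  q <- quantify_droplets(reps)
  expect_identical(q$n_positive, 120L)
  expect_identical(q$n_total, 20000L)
  expect_equal(quantify_droplets(reps, droplet_volume = 0.425)$copies_per_ul,
               2 * q$copies_per_ul)
})

test_that("estimator is unbiased within 1% at a million droplets", {
  q <- quantify_droplets(simulate_droplets(0.5, 1e6, seed = 11))
  expect_lt(abs(q$lambda_hat - 0.5) / 0.5, 0.01)
})

test_that("detection calls depend on wild-type signal and controls", {
  mk <- function(fus_pos, wt_pos) quantify_droplets(tibble::tibble(
    channel = c("fusion", "wildtype"),
    n_positive = c(fus_pos, wt_pos), n_total = 15000L))
  clean <- tibble::tibble(n_positive = c(0L, 0L), n_total = 15000L)
  # patient follow-up scenario: cfDNA present, no fusion signal
  neg <- detection_call(mk(0L, 400L), controls = clean)
  expect_identical(neg$call, "negative")
  # no template
  expect_identical(detection_call(mk(0L, 0L), controls = clean)$call, "invalid")
  # contaminated control
  dirty <- tibble::tibble(n_positive = 5L, n_total = 15000L)
  expect_identical(detection_call(mk(100L, 400L), controls = dirty)$call,
                   "invalid")
  # real signal
  pos <- detection_call(mk(100L, 400L), controls = clean)
  expect_identical(pos$call, "positive")
  expect_true(pos$fusion_fraction$fusion_fraction > 0)
  # missing controls: warn but proceed
  expect_warning(detection_call(mk(0L, 400L)), "control")
})

test_that("fusion fraction recovers planted spike-in mixtures within its CI", {
  for (frac in c(0.01, 0.001)) {
    copies <- 1000 / 3.3          # 1 ng input in genome equivalents
    n <- 20000L
    set.seed(round(1e5 * frac))
    fus <- simulate_droplets(copies * frac / n, n)
    wt <- simulate_droplets(copies * (1 - frac) / n, n)
    q <- quantify_droplets(tibble::tibble(
      channel = c("fusion", "wildtype"),
      n_positive = c(fus$n_positive, wt$n_positive), n_total = n),
      min_positive = 1)
    ff <- fusion_fraction(q)
    expect_true(is.na(ff$frac_low) || ff$frac_low <= frac)
    expect_true(frac <= ff$frac_high || is.na(ff$frac_high))
    expect_gte(ff$fusion_fraction, 0)
    expect_lte(ff$fusion_fraction, 1)
  }
})

test_that("detection probability is monotone in input mass and tumor fraction", {
  # monotone up to Monte Carlo error: an observed decrease must stay within
  # three binomial standard errors of the two estimates
  mono_ok <- function(p, R) {
    se <- sqrt((p[-1] * (1 - p[-1]) + p[-length(p)] * (1 - p[-length(p)])) / R)
    all(diff(p) >= -3 * se - 1e-9)
  }
  R <- 500
  lod <- lod_simulation(replicates = R, seed = 42)
  expect_equal(lod$detect_prob[lod$mass_ng == 60 & lod$fraction == 1], 1)
  by_frac <- split(lod, lod$fraction)
  for (d in by_frac) {
    d <- d[order(d$mass_ng), ]
    expect_true(mono_ok(d$detect_prob, R))
  }
  by_mass <- split(lod, lod$mass_ng)
  for (d in by_mass) {
    d <- d[order(d$fraction), ]
    expect_true(mono_ok(d$detect_prob, R))
  }
  # single-molecule regime: 6 pg of pure tumor DNA is detectable but not always
  tiny <- lod[lod$mass_ng == 0.006 & lod$fraction == 1, ]
  expect_gt(tiny$detect_prob, 0.5)
  expect_lt(tiny$detect_prob, 1)
  # closed form agrees with simulation
  expect_true(all(abs(lod$detect_prob - lod$detect_prob_expected) < 0.1))
  # zero fraction -> never detected
  z <- lod_simulation(tumor_fractions = 0, replicates = 50, seed = 1)
  expect_true(all(z$detect_prob == 0))
})
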