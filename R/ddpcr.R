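#' Poisson quantification of droplet digital PCR counts
#'
#' Estimates template concentration from partition counts: with droplets
#' holding Poisson-distributed copies, the positive fraction `p` gives the
#' mean copies per droplet `lambda = -ln(1 - p)`. The 95% interval comes from
#' the exact (Clopper-Pearson) binomial interval of `p` propagated through
#' the same transform. Replicate wells of a channel are pooled before
#' estimation. A saturated well (all droplets positive) yields an infinite
#' point estimate and a finite lower bound only.
#'
#' @param assays Tibble with columns `n_positive`, `n_total` and optionally
#'   `channel` (default `"fusion"`) and `replicate`.
#' @param droplet_volume Droplet volume in nanoliters (QX200-class default
#'   0.85 nL).
#' @param min_positive Minimum positive droplets to declare the channel
#'   detected (default 2: a single positive droplet is inconclusive).
#' @return A `ddpcr_quant` tibble, one row per channel: pooled counts,
#'   `lambda_hat` with `lambda_low`/`lambda_high`, concentration in copies
#'   per microliter of droplet-partitioned volume (`copies_per_ul` with CI),
#'   `detected`, `saturated`.
#' @examples
#' quantify_droplets(simulate_droplets(0.5, 20000, seed = 1))
#' @export
quantify_droplets <- function(assays, droplet_volume = 0.85,
                              min_positive = 2) {
  stopifnot(is.data.frame(assays))
  if (any(assays$n_total <= 0)) abort("`n_total` must be positive")
  if (any(assays$n_positive < 0 | assays$n_positive > assays$n_total)) {
    abort("need 0 <= n_positive <= n_total")
  }
  if (!"channel" %in% names(assays)) assays$channel <- "fusion"
  pooled <- assays |>
    group_by(.data$channel) |>
    summarise(n_positive = sum(.data$n_positive),
              n_total = sum(.data$n_total), .groups = "drop")
  lam <- function(p) -log(1 - p)
  res <- purrr::pmap(pooled, function(channel, n_positive, n_total) {
    p <- n_positive / n_total
    ci <- stats::binom.test(n_positive, n_total)$conf.int
    tibble(
      channel = channel, n_positive = n_positive, n_total = n_total,
      lambda_hat = lam(p), lambda_low = lam(ci[1]), lambda_high = lam(ci[2]),
      saturated = n_positive == n_total,
      detected = n_positive >= min_positive
    )
  }) |> bind_rows()
  # copies/uL of partitioned volume: lambda per droplet over droplet volume
  to_conc <- function(l) l / (droplet_volume * 1e-3)
  res <- res |>
    mutate(copies_per_ul = to_conc(.data$lambda_hat),
           conc_low = to_conc(.data$lambda_low),
           conc_high = to_conc(.data$lambda_high))
  class(res) <- c("ddpcr_quant", class(res))
  res
}

#' Fraction of fusion-bearing genomes in a quantified well
#'
#' Ratio of the fusion-channel concentration to total (fusion + wild-type),
#' with a conservative interval obtained by pairing each channel's binomial
#' CI bounds.
#'
#' @param quant A `ddpcr_quant` tibble holding `fusion` and `wildtype` rows.
#' @return One-row tibble: `fusion_fraction`, `frac_low`, `frac_high`.
#' @export
fusion_fraction <- function(quant) {
  f <- quant |> filter(.data$channel == "fusion")
  w <- quant |> filter(.data$channel == "wildtype")
  if (nrow(f) != 1 || nrow(w) != 1) {
    abort("`quant` must hold exactly one fusion and one wildtype row")
  }
  frac <- function(a, b) if (a + b == 0) NA_real_ else a / (a + b)
  tibble(
    fusion_fraction = frac(f$lambda_hat, w$lambda_hat),
    frac_low = frac(f$lambda_low, w$lambda_high),
    frac_high = frac(f$lambda_high, w$lambda_low)
  )
}

#' Call ctDNA marker detection against controls
#'
#' A sample is `invalid` when its wild-type channel is undetected (no
#' amplifiable cell-free DNA in the well) or when any negative control shows
#' fusion signal at or above `min_positive` droplets (contamination);
#' `negative` when valid with an undetected fusion channel; `positive`
#' otherwise.
#'
#' @param quant A `ddpcr_quant` tibble for the sample (channels `fusion` and
#'   `wildtype`).
#' @param controls Optional tibble of negative-control fusion-channel counts
#'   (`n_positive`, `n_total`). An empty/missing set logs a warning and the
#'   call proceeds.
#' @param min_positive Positive-droplet floor defining detection.
#' @return A list of class `ddpcr_call`: `call` in
#'   `c("positive", "negative", "invalid")`, `reason`, `fusion_fraction`,
#'   and the input `quant`.
#' @export
detection_call <- function(quant, controls = NULL, min_positive = 2) {
  f <- quant |> filter(.data$channel == "fusion")
  w <- quant |> filter(.data$channel == "wildtype")
  if (nrow(f) != 1 || nrow(w) != 1) {
    abort("`quant` must hold one fusion and one wildtype channel")
  }
  if (is.null(controls) || nrow(controls) == 0) {
    warn("no negative controls supplied; detection call is uncontrolled")
    contaminated <- FALSE
  } else {
    contaminated <- any(controls$n_positive >= min_positive)
  }
  out <- if (!w$detected) {
    list(call = "invalid", reason = "no_wildtype_signal")
  } else if (contaminated) {
    list(call = "invalid", reason = "control_contamination")
  } else if (!f$detected) {
    list(call = "negative", reason = "fusion_undetected")
  } else {
    list(call = "positive", reason = "fusion_detected")
  }
  structure(c(out, list(fusion_fraction = fusion_fraction(quant),
                        quant = quant)),
            class = "ddpcr_call")
}

#' @export
print.ddpcr_call <- function(x, ...) {
  cat(sprintf("<ddpcr_call> %s (%s)\n", x$call, x$reason))
  invisible(x)
}

#' Limit-of-detection simulation over input mass and tumor fraction
#'
#' Simulates the assay's dilution/spike-in characterisation: for each input
#' DNA mass and tumor fraction, the number of amplifiable fusion copies is
#' `mass / pg_per_genome * fraction` haploid genome equivalents, droplets are
#' partitioned and counted per replicate, and the detection probability is
#' the fraction of replicates reaching `min_positive` positive droplets. The
#' closed-form expectation `1 - exp(-fusion copies)` (for `min_positive = 1`)
#' is reported alongside.
#'
#' @param input_mass_ng Input masses in ng; default 60 ng down five tenfold
#'   dilutions to 6 pg.
#' @param tumor_fractions Fusion-genome fractions of the input.
#' @param n_droplets Droplets per well.
#' @param replicates Simulated wells per condition.
#' @param seed Seed.
#' @param pg_per_genome Mass of one haploid genome (pg).
#' @param min_positive Positive droplets required to score detection.
#' @return Tibble: `mass_ng, fraction, fusion_copies, lambda, detect_prob,
#'   detect_prob_expected`.
#' @examples
#' lod_simulation(replicates = 50, seed = 1)
#' @export
lod_simulation <- function(input_mass_ng = 60 / 10^(0:5),
                           tumor_fractions = c(1, 0.01, 0.001),
                           n_droplets = 20000, replicates = 200, seed = 1,
                           pg_per_genome = 3.3, min_positive = 1) {
  if (any(input_mass_ng <= 0)) abort("input masses must be positive")
  if (any(tumor_fractions < 0 | tumor_fractions > 1)) {
    abort("tumor fractions must lie in [0, 1]")
  }
  set.seed(seed)
  grid <- tidyr::expand_grid(mass_ng = input_mass_ng,
                             fraction = tumor_fractions)
  purrr::pmap(grid, function(mass_ng, fraction) {
    copies <- mass_ng * 1000 / pg_per_genome * fraction
    lambda <- copies / n_droplets
    pos <- rbinom(replicates, n_droplets, 1 - exp(-lambda))
    tibble(
      mass_ng = mass_ng, fraction = fraction, fusion_copies = copies,
      lambda = lambda,
      detect_prob = mean(pos >= min_positive),
      detect_prob_expected = 1 - exp(-copies)
    )
  }) |> bind_rows()
}
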