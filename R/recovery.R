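#' Parameter-recovery suite on simulated trios
#'
#' Simulates trio + tumor variant sets with planted variants of every
#' inheritance class plus Mendelian background polymorphisms, classifies them
#' with [classify_variants()], and scores per-class sensitivity and false
#' discovery rate against the planted truth, pooling counts across seeds.
#'
#' @param seeds Integer vector of simulation seeds (one trio per seed).
#' @param depth_mean Mean sequencing depth.
#' @param n_background Background variants per trio.
#' @param n_per_class Planted variants per inheritance class.
#' @param thresholds A [filter_thresholds()].
#' @return Tibble with one row per class: `class, n_truth, n_called, tp,
#'   sensitivity, fdr`.
#' @examples
#' recovery_suite(seeds = 1, n_background = 100, n_per_class = 5)
#' @export
recovery_suite <- function(seeds = 1:10, depth_mean = 30, n_background = 1000,
                           n_per_class = 20,
                           thresholds = filter_thresholds()) {
  classes <- list(
    somatic = "somatic", de_novo = "de_novo", rare_homozygous = "rare_hom",
    compound_het = c("comphet_maternal", "comphet_paternal")
  )
  tal <- purrr::map(seeds, function(s) {
    cfg <- sim_config(seed = s, depth_mean = depth_mean,
                      n_background_variants = n_background,
                      planted = plant_variants(n_per_class))
    sim <- simulate_trio(cfg)
    v <- tidy(classify_variants(sim$records, thresholds))
    key <- function(d) paste(d$chrom, d$pos)
    called <- list(
      somatic = key(v[v$somatic %in% TRUE, ]),
      de_novo = key(v[v$de_novo %in% TRUE, ]),
      rare_homozygous = key(v[v$rare_homozygous %in% TRUE, ]),
      compound_het = key(v[v$compound_het_member %in% TRUE, ])
    )
    purrr::imap(classes, function(truth_classes, cl) {
      truth <- key(sim$truth[sim$truth$inheritance_class %in% truth_classes, ])
      tibble(class = cl, n_truth = length(truth),
             n_called = length(called[[cl]]),
             tp = sum(called[[cl]] %in% truth))
    }) |> bind_rows()
  }) |> bind_rows()
  tal |>
    group_by(.data$class) |>
    summarise(across(c("n_truth", "n_called", "tp"), sum), .groups = "drop") |>
    mutate(sensitivity = .data$tp / .data$n_truth,
           fdr = if_else(.data$n_called == 0, 0,
                         1 - .data$tp / .data$n_called))
}
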