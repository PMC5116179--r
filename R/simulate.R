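#' Simulation configuration
#'
#' Collects every knob of the synthetic-data generators: a seed, a small
#' synthetic genome, the sequencing depth model, the planted variants, the
#' copy-number truth segments, the mate-pair library geometry and the droplet
#' partitioning. Defaults emulate the study conditions of a trio + tumor exome
#' case: mean depth 30x with a 10x analysis floor downstream, ~2 kb mate-pair
#' inserts, and a 20,000-partition droplet assay.
#'
#' @param seed Integer seed; a fixed seed makes every generator byte-identical.
#' @param chrom_lengths Named integer vector of chromosome lengths (bp).
#'   Default: three 10 Mb chromosomes.
#' @param n_background_variants Number of common, Mendelian-consistent
#'   background variants to scatter across the genome.
#' @param depth_mean Mean per-sample read depth; per-variant depths are drawn
#'   Poisson around it.
#' @param planted Tibble of planted variants, e.g. from [plant_variants()].
#' @param cna_truth Tibble `(chrom, start, end, copy)` of true copy-number
#'   segments (diploid background has copy 2).
#' @param cna_noise_sd Gaussian noise sd of simulated probe log2 ratios.
#' @param insert_size_mean,insert_size_sd Mate-pair insert length (bp).
#' @param read_length Mate-pair read length (bp).
#' @param n_matepairs Discordant (junction-spanning) pairs to simulate.
#' @param n_concordant Background concordant pairs to simulate.
#' @param droplet_count Droplet partitions per well.
#' @param droplet_volume Droplet volume in nanoliters.
#'
#' @return An object of class `sim_config` (named list).
#' @examples
#' cfg <- sim_config(seed = 7, n_background_variants = 100)
#' @export
sim_config <- function(seed = 1L,
                       chrom_lengths = c(chr1 = 1e7, chr2 = 1e7, chr3 = 1e7),
                       n_background_variants = 0L,
                       depth_mean = 30,
                       planted = NULL,
                       cna_truth = NULL,
                       cna_noise_sd = 0.15,
                       insert_size_mean = 2000,
                       insert_size_sd = 150,
                       read_length = 60,
                       n_matepairs = 50L,
                       n_concordant = 10000L,
                       droplet_count = 20000L,
                       droplet_volume = 0.85e-3) {
  if (!is.numeric(depth_mean) || depth_mean <= 0) {
    abort("`depth_mean` must be positive")
  }
  if (insert_size_sd < 0) abort("`insert_size_sd` must be non-negative")
  if (is.null(names(chrom_lengths)) || any(chrom_lengths <= 0)) {
    abort("`chrom_lengths` must be a named vector of positive lengths")
  }
  if (!is.null(planted)) {
    if (anyDuplicated(planted[c("chrom", "pos")]) > 0) {
      abort("duplicate planted positions")
    }
    bad <- !planted$chrom %in% names(chrom_lengths) |
      planted$pos < 1 | planted$pos > chrom_lengths[planted$chrom]
    if (any(bad)) abort("planted coordinates outside declared chromosomes")
  }
  structure(list(
    seed = as.integer(seed), chrom_lengths = chrom_lengths,
    n_background_variants = as.integer(n_background_variants),
    depth_mean = depth_mean, planted = planted, cna_truth = cna_truth,
    cna_noise_sd = cna_noise_sd, insert_size_mean = insert_size_mean,
    insert_size_sd = insert_size_sd, read_length = read_length,
    n_matepairs = as.integer(n_matepairs),
    n_concordant = as.integer(n_concordant),
    droplet_count = as.integer(droplet_count),
    droplet_volume = droplet_volume
  ), class = "sim_config")
}

# per-role true VAFs implied by an inheritance class
class_true_vafs <- function(class, tumor_vaf = 0.4) {
  switch(class,
    somatic          = c(tumor = tumor_vaf, patient = 0,   mother = 0,   father = 0),
    de_novo          = c(tumor = 0.5,       patient = 0.5, mother = 0,   father = 0),
    rare_hom         = c(tumor = 1,         patient = 1,   mother = 0.5, father = 0.5),
    comphet_maternal = c(tumor = 0.5,       patient = 0.5, mother = 0.5, father = 0),
    comphet_paternal = c(tumor = 0.5,       patient = 0.5, mother = 0,   father = 0.5),
    common_benign    = c(tumor = 0.5,       patient = 0.5, mother = 0.5, father = 0.5),
    abort(paste0("unknown inheritance class: ", class))
  )
}

#' Plant variants of each inheritance class
#'
#' Builds a planted-variant table with `n_per_class` variants of each requested
#' class, placed deterministically on the synthetic genome. Compound-het
#' variants are planted in maternal/paternal pairs sharing a gene
#' (`n_per_class` of each origin, i.e. `n_per_class` compound-het genes).
#'
#' @param n_per_class Variants per inheritance class.
#' @param classes Character vector of classes to plant, a subset of
#'   `c("somatic", "de_novo", "rare_hom", "comphet_maternal",
#'   "comphet_paternal", "common_benign")`.
#' @param chrom_lengths Genome as in [sim_config()].
#' @param tumor_vaf True tumor alt fraction for somatic plants.
#' @return Tibble with one row per planted variant: coordinates, alleles,
#'   gene, consequence, population MAF, inheritance class and true per-role
#'   VAFs.
#' @examples
#' plant_variants(3, classes = c("somatic", "rare_hom"))
#' @export
plant_variants <- function(n_per_class = 20,
                           classes = c("somatic", "de_novo", "rare_hom",
                                       "comphet_maternal", "comphet_paternal"),
                           chrom_lengths = c(chr1 = 1e7, chr2 = 1e7, chr3 = 1e7),
                           tumor_vaf = 0.4) {
  if (length(classes) == 0 || n_per_class == 0) {
    return(planted_skeleton())
  }
  # comphet pairs share a gene; everything else gets a private gene
  classes <- unique(classes)
  rows <- purrr::imap(classes, function(cl, i) {
    tibble(
      inheritance_class = cl,
      idx = seq_len(n_per_class),
      gene = if (grepl("^comphet", cl)) {
        sprintf("CHGENE%03d", seq_len(n_per_class))
      } else {
        sprintf("%sGENE%03d", toupper(substr(cl, 1, 3)), seq_len(n_per_class))
      },
      maf = if (cl == "common_benign") 0.30 else round(0.001 + 0.004 * seq_len(n_per_class), 4),
      consequence = "missense"
    )
  }) |> bind_rows()
  # deterministic, collision-free placement: stripe classes across chromosomes
  n <- nrow(rows)
  chroms <- names(chrom_lengths)
  rows <- rows |>
    mutate(
      chrom = chroms[((row_number() - 1) %% length(chroms)) + 1],
      pos = 10000 + 5000 * row_number(),
      ref = c("A", "C", "G", "T")[((row_number() - 1) %% 4) + 1],
      alt = c("G", "T", "A", "C")[((row_number() - 1) %% 4) + 1]
    )
  vafs <- purrr::map(rows$inheritance_class, class_true_vafs, tumor_vaf = tumor_vaf)
  rows |>
    mutate(
      vaf_tumor = purrr::map_dbl(vafs, "tumor"),
      vaf_patient = purrr::map_dbl(vafs, "patient"),
      vaf_mother = purrr::map_dbl(vafs, "mother"),
      vaf_father = purrr::map_dbl(vafs, "father")
    ) |>
    select(-"idx") |>
    select("chrom", "pos", "ref", "alt", "gene", "consequence", "maf",
           "inheritance_class", dplyr::starts_with("vaf_"))
}

planted_skeleton <- function() {
  tibble(
    chrom = character(), pos = integer(), ref = character(), alt = character(),
    gene = character(), consequence = character(), maf = double(),
    inheritance_class = character(), vaf_tumor = double(),
    vaf_patient = double(), vaf_mother = double(), vaf_father = double()
  )
}

#' Simulate a trio + tumor variant set
#'
#' Draws per-sample read counts for every planted and background variant:
#' depth is Poisson around `depth_mean` and the alt-read count is
#' Binomial(depth, true VAF) in each sample. Background variants are common
#' polymorphisms drawn under Hardy-Weinberg in the parents and transmitted
#' Mendelianly to the patient (tumor mirrors the patient germline), so they
#' exercise every downstream filter without belonging to any reported class.
#'
#' @param config A [sim_config()]; its `planted` table supplies ground truth.
#' @return A list with class `trio_simulation`:
#'   \describe{
#'     \item{records}{wide trio table, one row per variant with
#'       `<role>_dp`, `<role>_alt`, `<role>_vaf` columns for roles
#'       tumor/patient/mother/father — the input format of the classifier}
#'     \item{truth}{planted-variant truth table (class, true VAFs)}
#'   }
#' @examples
#' cfg <- sim_config(seed = 1, planted = plant_variants(2))
#' sim <- simulate_trio(cfg)
#' sim$records
#' @export
simulate_trio <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  planted <- config$planted %||% planted_skeleton()
  truth <- as_tibble(planted)

  bg <- simulate_background(config, avoid = truth)
  all <- bind_rows(truth, bg)
  if (nrow(all) == 0) {
    return(structure(list(records = trio_record_skeleton(), truth = truth),
                     class = "trio_simulation"))
  }

  rec <- all |> select("chrom", "pos", "ref", "alt", "gene", "consequence", "maf")
  for (role in c("tumor", "patient", "mother", "father")) {
    dp <- rpois(nrow(all), config$depth_mean)
    alt <- rbinom(nrow(all), dp, all[[paste0("vaf_", role)]])
    rec[[paste0(role, "_dp")]] <- dp
    rec[[paste0(role, "_alt")]] <- alt
    rec[[paste0(role, "_vaf")]] <- ifelse(dp > 0, alt / dp, NA_real_)
  }
  rec <- rec |> arrange(.data$chrom, .data$pos)
  structure(list(records = as_tibble(rec), truth = truth),
            class = "trio_simulation")
}

simulate_background <- function(config, avoid) {
  n <- config$n_background_variants
  if (n == 0) return(planted_skeleton())
  chroms <- names(config$chrom_lengths)
  repeat {
    chrom <- sample(chroms, n, replace = TRUE)
    pos <- floor(runif(n, 1, config$chrom_lengths[chrom])) + 0
    key <- paste(chrom, pos)
    if (!anyDuplicated(key) && !any(key %in% paste(avoid$chrom, avoid$pos))) break
  }
  maf <- round(runif(n, 0.15, 0.5), 4)
  # HWE parents, Mendelian transmission to the patient
  gt_mother <- rbinom(n, 2, maf)
  gt_father <- rbinom(n, 2, maf)
  gt_patient <- rbinom(n, 1, gt_mother / 2) + rbinom(n, 1, gt_father / 2)
  keep <- (gt_mother + gt_father + gt_patient) > 0
  genes <- sprintf("BGGENE%03d", sample.int(max(1L, n %/% 3L), n, replace = TRUE))
  tibble(
    chrom = chrom, pos = as.integer(pos),
    ref = sample(c("A", "C", "G", "T"), n, replace = TRUE),
    alt = sample(c("A", "C", "G", "T"), n, replace = TRUE),
    gene = genes,
    consequence = sample(c("synonymous", "missense"), n, replace = TRUE),
    maf = maf,
    inheritance_class = "common_benign",
    vaf_tumor = gt_patient / 2, vaf_patient = gt_patient / 2,
    vaf_mother = gt_mother / 2, vaf_father = gt_father / 2
  )[keep, ] |>
    mutate(alt = if_else(.data$alt == .data$ref,
                         c(A = "C", C = "G", G = "T", T = "A")[.data$ref],
                         .data$alt))
}

trio_record_skeleton <- function() {
  rec <- tibble(
    chrom = character(), pos = integer(), ref = character(), alt = character(),
    gene = character(), consequence = character(), maf = double()
  )
  for (role in c("tumor", "patient", "mother", "father")) {
    rec[[paste0(role, "_dp")]] <- double()
    rec[[paste0(role, "_alt")]] <- double()
    rec[[paste0(role, "_vaf")]] <- double()
  }
  rec
}

#' Simulate a probe-level copy-number profile
#'
#' Lays probes every `probe_spacing` bp along the synthetic genome and draws
#' their log2 ratios: probes inside a truth segment get mean
#' `log2(copy/2)` (floored at -3 for homozygous losses, where the array signal
#' saturates), all others mean 0, plus Gaussian noise of sd
#' `config$cna_noise_sd`.
#'
#' @param config A [sim_config()] whose `cna_truth` is a tibble
#'   `(chrom, start, end, copy)`; segments must not overlap.
#' @param probe_spacing Distance between consecutive probes (bp).
#' @return Tibble `(chrom, pos, log2)` sorted by position, one row per probe.
#' @examples
#' cfg <- sim_config(seed = 1,
#'   cna_truth = tibble::tibble(chrom = "chr1", start = 1, end = 1e7, copy = 3))
#' probes <- simulate_cna_profile(cfg, probe_spacing = 50000)
#' @export
simulate_cna_profile <- function(config, probe_spacing = 15000) {
  stopifnot(inherits(config, "sim_config"))
  if (probe_spacing <= 0) abort("`probe_spacing` must be positive")
  truth <- config$cna_truth
  if (!is.null(truth) && nrow(truth) > 1) {
    t2 <- truth |> arrange(.data$chrom, .data$start)
    same <- t2$chrom[-1] == t2$chrom[-nrow(t2)]
    if (any(same & t2$start[-1] <= t2$end[-nrow(t2)])) {
      abort("overlapping truth segments")
    }
  }
  set.seed(config$seed)
  probes <- purrr::imap(config$chrom_lengths, function(len, chrom) {
    tibble(chrom = chrom, pos = as.integer(seq(probe_spacing %/% 2, len, by = probe_spacing)))
  }) |> bind_rows()
  mu <- rep(0, nrow(probes))
  if (!is.null(truth)) {
    for (i in seq_len(nrow(truth))) {
      hit <- probes$chrom == truth$chrom[i] &
        probes$pos >= truth$start[i] & probes$pos <= truth$end[i]
      mu[hit] <- max(log2(truth$copy[i] / 2), -3)
    }
  }
  probes$log2 <- mu + rnorm(nrow(probes), 0, config$cna_noise_sd)
  probes
}

#' Simulate a mate-pair library spanning a translocation junction
#'
#' Generates `n_concordant` ordinary pairs (both reads on one chromosome,
#' separated by an insert drawn from the library distribution) and
#' `n_matepairs` junction-spanning pairs whose two reads fall on either side
#' of an interchromosomal junction, as a mate-pair library over a
#' translocation produces. Junction-side reads face the breakpoint: plus
#' strand upstream on the first partner, minus strand downstream on the
#' second.
#'
#' @param config A [sim_config()] (insert geometry, counts, genome).
#' @param junction Length-4 vector/list `(chromA, posA, chromB, posB)` giving
#'   the fused coordinates, or NULL for a junction-free library.
#' @return Tibble in BEDPE-like layout: `pair_id, chrom1, pos1, strand1,
#'   chrom2, pos2, strand2, origin` (`origin` records ground truth and is
#'   never used by detection).
#' @examples
#' cfg <- sim_config(seed = 3, n_matepairs = 20, n_concordant = 500)
#' pairs <- simulate_matepairs(cfg, junction = list("chr1", 5e6, "chr2", 2e6))
#' @export
simulate_matepairs <- function(config, junction = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  rl <- config$read_length
  lens <- config$chrom_lengths

  conc <- NULL
  if (config$n_concordant > 0) {
    n <- config$n_concordant
    chrom <- sample(names(lens), n, replace = TRUE)
    ins <- pmax(rl * 2 + 10, round(rnorm(n, config$insert_size_mean, config$insert_size_sd)))
    pos1 <- floor(runif(n, 1, pmax(2, lens[chrom] - ins))) + 0
    conc <- tibble(
      chrom1 = chrom, pos1 = as.integer(pos1), strand1 = "+",
      chrom2 = chrom, pos2 = as.integer(pos1 + ins - rl), strand2 = "-",
      origin = "background"
    )
  }

  disc <- NULL
  if (!is.null(junction) && config$n_matepairs > 0) {
    junction <- as.list(junction)
    chromA <- as.character(junction[[1]]); posA <- as.numeric(junction[[2]])
    chromB <- as.character(junction[[3]]); posB <- as.numeric(junction[[4]])
    for (cc in c(chromA, chromB)) {
      if (!cc %in% names(lens)) abort("junction chromosome not in genome")
    }
    if (posA < 1 || posA > lens[chromA] || posB < 1 || posB > lens[chromB]) {
      abort("junction coordinates outside chromosome")
    }
    n <- config$n_matepairs
    ins <- pmax(rl * 2 + 10, round(rnorm(n, config$insert_size_mean, config$insert_size_sd)))
    # split the insert at the junction; each read stays wholly on one side
    u <- floor(runif(n, rl, ins - rl))
    disc <- tibble(
      chrom1 = chromA, pos1 = as.integer(round(posA - u)), strand1 = "+",
      chrom2 = chromB, pos2 = as.integer(round(posB + (ins - u) - rl)), strand2 = "-",
      origin = "junction"
    )
  }

  out <- bind_rows(conc, disc)
  if (is.null(out) || nrow(out) == 0) {
    out <- tibble(chrom1 = character(), pos1 = integer(), strand1 = character(),
                  chrom2 = character(), pos2 = integer(), strand2 = character(),
                  origin = character())
  }
  out |> mutate(pair_id = sprintf("pair%06d", row_number())) |>
    select("pair_id", dplyr::everything())
}

#' Simulate a droplet digital PCR well
#'
#' Template molecules partition into droplets at `lambda` mean copies per
#' droplet; a droplet reads positive when it received at least one copy, i.e.
#' with probability `1 - exp(-lambda)`.
#'
#' @param lambda Mean template copies per droplet (>= 0).
#' @param n_droplets Number of accepted droplets (> 0).
#' @param seed Optional seed for this draw alone.
#' @return Tibble with columns `n_positive`, `n_total` (one row).
#' @examples
#' simulate_droplets(0.5, 20000, seed = 1)
#' @export
simulate_droplets <- function(lambda, n_droplets, seed = NULL) {
  if (!is.numeric(lambda) || any(lambda < 0)) abort("`lambda` must be >= 0")
  if (n_droplets <= 0) abort("`n_droplets` must be positive")
  if (!is.null(seed)) set.seed(seed)
  p <- 1 - exp(-lambda)
  tibble(n_positive = rbinom(length(lambda), n_droplets, p),
         n_total = as.integer(n_droplets))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
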