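# Rule-by-rule brute-force checker, written as literal per-record ifs so it
# stays independent of the vectorised implementation it cross-checks.
oracle_gt <- function(vaf, dp, gt, th) {
  if (!is.na(gt)) return(gt)
  if (is.na(vaf) || is.na(dp) || dp == 0) return("missing")
  if (vaf < th$het_low) return("hom_ref")
  if (vaf < th$hom_min) return("het")
  "hom_alt"
}

oracle_classify <- function(records, th = filter_thresholds()) {
  n <- nrow(records)
  get <- function(col) if (col %in% names(records)) records[[col]] else rep(NA, n)
  somatic <- de_novo <- rare_hom <- rep(NA, n)
  origin <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    tdp <- get("tumor_dp")[i]; tv <- get("tumor_vaf")[i]
    pdp <- get("patient_dp")[i]; pv <- get("patient_vaf")[i]
    mdp <- get("mother_dp")[i]; mv <- get("mother_vaf")[i]
    fdp <- get("father_dp")[i]; fv <- get("father_vaf")[i]
    maf <- get("maf")[i]
    pgt <- oracle_gt(pv, pdp, get("patient_gt")[i], th)
    mgt <- oracle_gt(mv, mdp, get("mother_gt")[i], th)
    fgt <- oracle_gt(fv, fdp, get("father_gt")[i], th)
    rare <- if (is.na(maf)) th$maf_missing_rare else maf <= th$rare_maf_max

    if (!is.na(tdp) && !is.na(tv) && !is.na(pdp) && !is.na(pv)) {
      somatic[i] <- tdp >= th$min_depth && pdp >= th$min_depth &&
        tv >= th$somatic_min_tumor_vaf && pv <= th$max_normal_vaf
    }
    if (!is.na(pdp) && !is.na(pv) && !is.na(mdp) && !is.na(mv) &&
        !is.na(fdp) && !is.na(fv)) {
      de_novo[i] <- pdp >= th$min_depth && mdp >= th$min_depth &&
        fdp >= th$min_depth && pv >= th$denovo_min_vaf &&
        mv <= th$max_normal_vaf && fv <= th$max_normal_vaf
    }
    if (!is.na(pdp) && !is.na(mdp) && !is.na(fdp) &&
        pgt != "missing" && mgt != "missing" && fgt != "missing") {
      rare_hom[i] <- pdp >= th$min_depth && mdp >= th$min_depth &&
        fdp >= th$min_depth && pgt == "hom_alt" && mgt == "het" &&
        fgt == "het" && rare
    }
    depth_ok <- !is.na(pdp) && !is.na(mdp) && !is.na(fdp) &&
      pdp >= th$min_depth && mdp >= th$min_depth && fdp >= th$min_depth
    if (depth_ok && pgt == "het" && rare) {
      mat <- mgt == "het" && !is.na(fv) && fv <= th$max_normal_vaf
      pat <- fgt == "het" && !is.na(mv) && mv <= th$max_normal_vaf
      if (mat && !pat) origin[i] <- "maternal"
      if (pat && !mat) origin[i] <- "paternal"
    }
  }
  genes <- character(0)
  for (g in unique(stats::na.omit(get("gene")))) {
    idx <- which(get("gene") == g)
    if (any(origin[idx] == "maternal", na.rm = TRUE) &&
        any(origin[idx] == "paternal", na.rm = TRUE)) {
      genes <- c(genes, g)
    }
  }
  list(somatic = somatic, de_novo = de_novo, rare_homozygous = rare_hom,
       comphet_origin = origin, comphet_genes = sort(genes))
}

# random wide trio records for property tests
random_records <- function(n, seed) {
  set.seed(seed)
  rec <- tibble::tibble(
    chrom = "chr1", pos = seq_len(n) * 100L,
    ref = "A", alt = "G",
    gene = sprintf("G%02d", sample.int(max(1, n %/% 2), n, replace = TRUE)),
    consequence = sample(c("missense", "synonymous"), n, replace = TRUE),
    maf = ifelse(runif(n) < 0.3, NA, round(runif(n, 0, 0.4), 3))
  )
  for (role in c("tumor", "patient", "mother", "father")) {
    dp <- ifelse(runif(n) < 0.1, NA, rpois(n, 25))
    vaf <- ifelse(is.na(dp) | dp == 0, NA,
                  sample(c(0, 0.1, 0.25, 0.5, 0.9, 1), n, replace = TRUE))
    rec[[paste0(role, "_dp")]] <- dp
    rec[[paste0(role, "_alt")]] <- ifelse(is.na(vaf), NA, round(vaf * dp))
    rec[[paste0(role, "_vaf")]] <- vaf
  }
  rec
}

swap_parents <- function(records) {
  nm <- names(records)
  to_f <- grep("^mother_", nm)
  to_m <- grep("^father_", nm)
  nm[to_f] <- sub("^mother_", "father_", nm[to_f])
  nm[to_m] <- sub("^father_", "mother_", nm[to_m])
  names(records) <- nm
  records
}
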