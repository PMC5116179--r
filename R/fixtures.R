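#' In-report variant-table fixtures
#'
#' Rebuilds, as wide trio tables, the three variant tables of the case report
#' this package operationalises: `"table1"` — the 15 somatic point mutations
#' with their printed tumor variant frequency/coverage and leukocyte coverage;
#' `"table2"` — the 4 rare polymorphisms homozygous in the patient and
#' heterozygous in both parents, with per-sample frequency and coverage;
#' `"table3"` — the 22 compound-heterozygous variants (11 genes, one maternal
#' and one paternal allele each) with per-sample genotypes and variant
#' frequencies.
#'
#' Printed values are stored verbatim. Values the report does not print are
#' filled with documented synthetic stand-ins: leukocyte alt fraction 0 for
#' the somatic table (those variants are somatic, hence absent from the
#' germline), parental calls absent for table1, depth 50 for every table3
#' call (coverage is unprinted there; 50 clears the 10x analysis floor), and
#' synthetic genomic positions for tables 2-3 (only genes and cDNA changes
#' are printed).
#'
#' With `decoys = TRUE` each fixture carries deterministic negative controls,
#' one per filter criterion (low coverage, sub-threshold VAF, leukocyte
#' support, common MAF, same-parent variant pair, ...), flagged by
#' `is_decoy`/`decoy_reason`.
#'
#' @param name One of `"table1"`, `"table2"`, `"table3"`.
#' @param decoys Include the spiked decoy records?
#' @return A wide trio tibble (see [read_trio_vcf()] layout) with extra
#'   columns `variant`, `protein`, `dbsnp`, `is_decoy`, `decoy_reason`.
#' @examples
#' t1 <- build_fixture("table1")
#' sum(!t1$is_decoy)  # 15 printed somatic rows
#' @export
build_fixture <- function(name = c("table1", "table2", "table3"),
                          decoys = TRUE) {
  name <- match.arg(name)
  fx <- switch(name,
    table1 = fixture_table1(),
    table2 = fixture_table2(),
    table3 = fixture_table3()
  )
  if (!decoys) fx <- fx |> filter(!.data$is_decoy)
  fx
}

# split a cDNA substitution like "c.1486G>A" into ref/alt
cdna_alleles <- function(cdna) {
  m <- stringr::str_match(cdna, "([ACGT])>([ACGT])")
  list(ref = m[, 2], alt = m[, 3])
}

fixture_row <- function(chrom, pos, cdna, gene, protein, consequence,
                        dbsnp = NA_character_, maf = NA_real_,
                        tumor_vaf = NA_real_, tumor_dp = NA_real_,
                        patient_vaf = NA_real_, patient_dp = NA_real_,
                        patient_gt = NA_character_,
                        mother_vaf = NA_real_, mother_dp = NA_real_,
                        mother_gt = NA_character_,
                        father_vaf = NA_real_, father_dp = NA_real_,
                        father_gt = NA_character_,
                        is_decoy = FALSE, decoy_reason = NA_character_) {
  al <- cdna_alleles(cdna)
  tibble(
    chrom = chrom, pos = as.integer(pos), ref = al$ref, alt = al$alt,
    gene = gene, variant = cdna, protein = protein,
    consequence = consequence, dbsnp = dbsnp, maf = maf,
    tumor_dp = tumor_dp,
    tumor_alt = round(dplyr::coalesce(tumor_vaf, 0) * dplyr::coalesce(tumor_dp, 0)),
    tumor_vaf = tumor_vaf,
    tumor_gt = NA_character_,
    patient_dp = patient_dp,
    patient_alt = round(dplyr::coalesce(patient_vaf, 0) * dplyr::coalesce(patient_dp, 0)),
    patient_vaf = patient_vaf, patient_gt = patient_gt,
    mother_dp = mother_dp,
    mother_alt = round(dplyr::coalesce(mother_vaf, 0) * dplyr::coalesce(mother_dp, 0)),
    mother_vaf = mother_vaf, mother_gt = mother_gt,
    father_dp = father_dp,
    father_alt = round(dplyr::coalesce(father_vaf, 0) * dplyr::coalesce(father_dp, 0)),
    father_vaf = father_vaf, father_gt = father_gt,
    is_decoy = is_decoy, decoy_reason = decoy_reason
  )
}

# make rows where tumor absent come out NA for alt counts
tidy_fixture <- function(fx) {
  for (role in c("tumor", "patient", "mother", "father")) {
    dpc <- paste0(role, "_dp"); altc <- paste0(role, "_alt")
    fx[[altc]][is.na(fx[[dpc]])] <- NA_real_
  }
  fx
}

fixture_table1 <- function() {
  # gene, chrom, pos, cdna, protein, type, tumor VAF, tumor DP, leukocyte DP, dbSNP
  r <- list(
    list("CHL1",    "chr3",  436494,    "c.3033A>G",   "p.A111A",   "synonymous",  0.35, 55, 53, NA),
    list("TBPL1",   "chr6",  134305546, "c.315T>G",    "p.V105V",   "synonymous",  0.23, 31, 28, NA),
    list("ALG10",   "chr12", 34179763,  "c.1335A>T",   "p.A445A",   "synonymous",  0.43, 82, 66, NA),
    list("TOE1",    "chr1",  45808899,  "c.1058C>T",   "p.P353L",   "missense",    0.20, 15, 18, "rs145913038"),
    list("DPP4",    "chr2",  162875307, "c.1352C>T",   "p.P451L",   "missense",    0.37, 41, 46, NA),
    list("MEGF10",  "chr5",  126753368, "c.1169G>C",   "p.G390C",   "missense",    0.22, 82, 39, NA),
    list("CDH9",    "chr5",  26915867,  "c.394G>C",    "p.D132Y",   "missense",    0.25, 71, 75, NA),
    list("CLVS2",   "chr6",  123319098, "c.176G>A",    "p.R59Q",    "missense",    0.40, 25, 20, NA),
    list("ZFPM2",   "chr8",  106813312, "c.1002T>A",   "p.S334R",   "missense",    0.28, 36, 44, NA),
    list("TRPA1",   "chr8",  72983969,  "c.245T>C",    "p.I82T",    "missense",    0.36, 45, 35, NA),
    list("MEIS2",   "chr15", 37385900,  "c.521G>A",    "p.R86Q",    "missense",    0.26, 31, 23, NA),
    list("CNTNAP4", "chr16", 76495948,  "c.1210G>T",   "p.A404S",   "missense",    0.33, 42, 43, NA),
    list("MYH8",    "chr17", 10300120,  "c.4362G>T",   "p.K1454N",  "missense",    0.26, 38, 33, NA),
    list("ZNF808",  "chr19", 53057457,  "c.1288G>T",   "p.E430Ter", "nonsense",    0.43, 30, 27, NA),
    list("RIMS4",   "chr20", 43385680,  "c.455-2T>A",  NA,          "splice_site", 0.28, 29, 37, NA)
  )
  rows <- purrr::map(r, function(x) {
    fixture_row(chrom = x[[2]], pos = x[[3]], cdna = x[[4]], gene = x[[1]],
                protein = x[[5]], consequence = x[[6]], dbsnp = x[[10]],
                tumor_vaf = x[[7]], tumor_dp = x[[8]],
                patient_vaf = 0, patient_dp = x[[9]])
  }) |> bind_rows()
  dec <- bind_rows(
    fixture_row("chr1", 100, "c.1A>G", "DEC1LOWTUMDP", NA, "missense",
                tumor_vaf = 0.40, tumor_dp = 9, patient_vaf = 0, patient_dp = 40,
                is_decoy = TRUE, decoy_reason = "tumor_depth_below_floor"),
    fixture_row("chr1", 200, "c.2C>T", "DEC1LOWLEUDP", NA, "missense",
                tumor_vaf = 0.40, tumor_dp = 40, patient_vaf = 0, patient_dp = 9,
                is_decoy = TRUE, decoy_reason = "leukocyte_depth_below_floor"),
    fixture_row("chr1", 300, "c.3G>A", "DEC1LOWVAF", NA, "missense",
                tumor_vaf = 0.19, tumor_dp = 100, patient_vaf = 0, patient_dp = 50,
                is_decoy = TRUE, decoy_reason = "tumor_vaf_below_threshold"),
    fixture_row("chr1", 400, "c.4T>C", "DEC1GERMLINE", NA, "missense",
                tumor_vaf = 0.45, tumor_dp = 60, patient_vaf = 0.48, patient_dp = 55,
                is_decoy = TRUE, decoy_reason = "leukocyte_support")
  )
  tidy_fixture(bind_rows(rows, dec))
}

fixture_table2 <- function() {
  r <- list(
    # gene, chrom, cdna, protein, dbsnp, MAF, patient vaf/dp, mother vaf/dp, father vaf/dp
    list("VEZT",     "chr12", "c.1486G>A", "p.V496I",  "rs10507051", 0.0302, 1.000, 17, 0.179, 28, 0.350, 80),
    list("ISX",      "chr22", "c.248G>A",  "p.R83Q",   "rs8140287",  0.0308, 1.000, 13, 0.375, 24, 0.500, 70),
    list("RASSF1",   "chr3",  "c.409G>T",  "p.A137S",  "rs2073498",  0.0711, 0.833, 12, 0.275, 40, 0.531, 32),
    list("ADAMTS12", "chr5",  "c.3529T>C", "p.W1177R", "rs3813474",  0.0513, 1.000, 51, 0.420, 88, 0.450, 40)
  )
  rows <- purrr::imap(r, function(x, i) {
    fixture_row(chrom = x[[2]], pos = 1e6 + 1000 * i, cdna = x[[3]],
                gene = x[[1]], protein = x[[4]], consequence = "missense",
                dbsnp = x[[5]], maf = x[[6]],
                patient_vaf = x[[7]], patient_dp = x[[8]],
                mother_vaf = x[[9]], mother_dp = x[[10]],
                father_vaf = x[[11]], father_dp = x[[12]])
  }) |> bind_rows()
  dec <- bind_rows(
    fixture_row("chr2", 100, "c.5A>G", "DEC2COMMON", NA, "missense", maf = 0.25,
                patient_vaf = 1.0, patient_dp = 20, mother_vaf = 0.45, mother_dp = 30,
                father_vaf = 0.50, father_dp = 30,
                is_decoy = TRUE, decoy_reason = "common_maf"),
    fixture_row("chr2", 200, "c.6C>T", "DEC2PATHET", NA, "missense", maf = 0.05,
                patient_vaf = 0.50, patient_dp = 30, mother_vaf = 0.45, mother_dp = 30,
                father_vaf = 0.50, father_dp = 30,
                is_decoy = TRUE, decoy_reason = "patient_not_homozygous"),
    fixture_row("chr2", 300, "c.7G>A", "DEC2PARHOM", NA, "missense", maf = 0.05,
                patient_vaf = 1.0, patient_dp = 30, mother_vaf = 1.0, mother_dp = 30,
                father_vaf = 0.50, father_dp = 30,
                is_decoy = TRUE, decoy_reason = "parent_not_heterozygous"),
    fixture_row("chr2", 400, "c.8T>C", "DEC2LOWDP", NA, "missense", maf = 0.05,
                patient_vaf = 1.0, patient_dp = 9, mother_vaf = 0.45, mother_dp = 30,
                father_vaf = 0.50, father_dp = 30,
                is_decoy = TRUE, decoy_reason = "depth_below_floor")
  )
  tidy_fixture(bind_rows(rows, dec))
}

fixture_table3 <- function() {
  DP <- 50  # coverage unprinted; synthetic depth clearing the 10x floor
  # gene, chrom, cdna, protein, dbsnp, MAF, origin,
  # mother gt, mother freq(%), father gt, father freq(%), patient gt, patient freq(%)
  r <- list(
    list("C2CD3",  "chr11", "c.5653T>C",   "p.S1885P",  "rs142277857", 0.0010, "maternal", "T/C", 43.10, "T/T", NA,    "T/C", 53.57),
    list("C2CD3",  "chr11", "c.3223A>C",   "p.S1075R",  NA,            NA,     "paternal", "A/A", NA,    "A/C", 50.91, "A/C", 41.67),
    list("FAM13C", "chr10", "c.1361G>A",   "p.R454H",   "rs369226393", NA,     "maternal", "G/A", 56.40, "G/G", NA,    "G/A", 50.00),
    list("FAM13C", "chr10", "c.439C>T",    "p.P147S",   "rs73299227",  0.0092, "paternal", "C/C", NA,    "C/T", 51.43, "C/T", 36.36),
    list("GOLGA3", "chr12", "c.209G>A",    "p.G70E",    "rs2291256",   0.0581, "maternal", "G/A", 52.30, "G/G", NA,    "G/A", 47.06),
    list("GOLGA3", "chr12", "c.3728G>A",   "p.R1243Q",  "rs140646528", 0.0134, "paternal", "G/G", NA,    "G/A", 60.00, "G/A", 25.00),
    list("LAMB2",  "chr3",  "c.1424G>A",   "p.R475Q",   "rs370565848", NA,     "maternal", "G/A", 36.40, "G/G", NA,    "G/A", 60.00),
    list("LAMB2",  "chr3",  "c.5293G>A",   "p.A1765T",  "rs74951356",  0.0130, "paternal", "G/G", NA,    "G/A", 55.81, "G/A", 41.18),
    list("MTMR6",  "chr13", "c.685C>G",    "p.P229A",   "rs149526134", 0.0002, "maternal", "C/G", 60.90, "C/C", NA,    "C/G", 26.32),
    list("MTMR6",  "chr13", "c.1795G>A",   "p.A599T",   "rs62619824",  0.0571, "paternal", "G/G", NA,    "G/A", 35.09, "G/A", 51.85),
    list("RSPH1",  "chr21", "c.742G>A",    "p.G248R",   "rs117385282", 0.0839, "maternal", "G/A", 50.00, "G/G", NA,    "G/A", 31.25),
    list("RSPH1",  "chr21", "c.733G>A",    "p.G245R",   "rs151158140", 0.0026, "paternal", "G/G", NA,    "G/A", 50.77, "G/A", 58.33),
    list("SLC9A9", "chr3",  "c.1765A>G",   "p.I589V",   "rs2289491",   0.0290, "maternal", "A/G", 31.10, "A/A", NA,    "A/G", 28.00),
    list("SLC9A9", "chr3",  "c.1618A>G",   "p.I540V",   "rs16853300",  0.0066, "paternal", "A/A", NA,    "A/G", 48.62, "A/G", 36.36),
    list("SPICE1", "chr3",  "c.2470A>C",   "p.T824P",   "rs57006145",  0.0313, "maternal", "A/C", 40.40, "A/A", NA,    "A/C", 62.16),
    list("SPICE1", "chr3",  "c.850G>A",    "p.V284M",   "rs73239152",  0.0078, "paternal", "G/G", NA,    "G/A", 47.54, "G/A", 29.27),
    list("SYNE1",  "chr6",  "c.16277C>T",  "p.T5426M",  "rs2306914",   0.0463, "maternal", "C/T", 39.10, "C/C", NA,    "C/T", 41.07),
    list("SYNE1",  "chr6",  "c.12442G>C",  "p.D4148H",  "rs117501809", 0.0124, "paternal", "G/G", NA,    "G/C", 49.15, "G/C", 28.57),
    list("TAF5L",  "chr1",  "c.721G>A",    "p.V241I",   "rs55655740",  0.0042, "maternal", "G/A", 36.00, "G/G", NA,    "G/A", 48.00),
    list("TAF5L",  "chr1",  "c.1123A>G",   "p.T375A",   "rs41304137",  0.0008, "paternal", "A/A", NA,    "A/G", 20.00, "A/G", 40.00),
    list("TTN",    "chr2",  "c.106619T>C", "p.I35540T", "rs55880440",  0.0046, "maternal", "T/C", 40.00, "T/T", NA,    "T/C", 57.69),
    list("TTN",    "chr2",  "c.65147C>T",  "p.S21716L", "rs13021201",  0.0108, "paternal", "C/C", NA,    "C/T", 42.86, "C/T", 58.14)
  )
  gt_class_from_string <- function(gt, ref) {
    al <- stringr::str_split_fixed(gt, "/", 2)
    n_alt <- rowSums(al != ref)
    c("hom_ref", "het", "hom_alt")[n_alt + 1]
  }
  rows <- purrr::imap(r, function(x, i) {
    al <- cdna_alleles(x[[3]])
    fixture_row(
      chrom = x[[2]], pos = 2e6 + 1000 * i, cdna = x[[3]], gene = x[[1]],
      protein = x[[4]], consequence = "missense", dbsnp = x[[5]], maf = x[[6]],
      patient_vaf = x[[13]] / 100, patient_dp = DP,
      patient_gt = gt_class_from_string(x[[12]], al$ref),
      mother_vaf = dplyr::coalesce(x[[9]], 0) / 100, mother_dp = DP,
      mother_gt = gt_class_from_string(x[[8]], al$ref),
      father_vaf = dplyr::coalesce(x[[11]], 0) / 100, father_dp = DP,
      father_gt = gt_class_from_string(x[[10]], al$ref)
    )
  }) |> bind_rows()
  rows$printed_origin <- purrr::map_chr(r, 7)
  dec <- bind_rows(
    # two maternal-only variants: a cis candidate, never compound het
    fixture_row("chr4", 100, "c.10G>A", "DEC3CIS", NA, "missense", maf = 0.01,
                patient_vaf = 0.5, patient_dp = DP, patient_gt = "het",
                mother_vaf = 0.5, mother_dp = DP, mother_gt = "het",
                father_vaf = 0, father_dp = DP, father_gt = "hom_ref",
                is_decoy = TRUE, decoy_reason = "same_parent_pair"),
    fixture_row("chr4", 200, "c.11C>T", "DEC3CIS", NA, "missense", maf = 0.01,
                patient_vaf = 0.5, patient_dp = DP, patient_gt = "het",
                mother_vaf = 0.5, mother_dp = DP, mother_gt = "het",
                father_vaf = 0, father_dp = DP, father_gt = "hom_ref",
                is_decoy = TRUE, decoy_reason = "same_parent_pair"),
    # one allele het in both parents: origin ambiguous, ineligible
    fixture_row("chr4", 300, "c.12A>G", "DEC3AMBIG", NA, "missense", maf = 0.01,
                patient_vaf = 0.5, patient_dp = DP, patient_gt = "het",
                mother_vaf = 0.5, mother_dp = DP, mother_gt = "het",
                father_vaf = 0.5, father_dp = DP, father_gt = "het",
                is_decoy = TRUE, decoy_reason = "both_parents_carry"),
    fixture_row("chr4", 400, "c.13G>C", "DEC3AMBIG", NA, "missense", maf = 0.01,
                patient_vaf = 0.5, patient_dp = DP, patient_gt = "het",
                mother_vaf = 0, mother_dp = DP, mother_gt = "hom_ref",
                father_vaf = 0.5, father_dp = DP, father_gt = "het",
                is_decoy = TRUE, decoy_reason = "both_parents_carry"),
    # valid geometry but one allele too common in the population
    fixture_row("chr4", 500, "c.14T>A", "DEC3COMMON", NA, "missense", maf = 0.01,
                patient_vaf = 0.5, patient_dp = DP, patient_gt = "het",
                mother_vaf = 0.5, mother_dp = DP, mother_gt = "het",
                father_vaf = 0, father_dp = DP, father_gt = "hom_ref",
                is_decoy = TRUE, decoy_reason = "common_maf"),
    fixture_row("chr4", 600, "c.15A>T", "DEC3COMMON", NA, "missense", maf = 0.30,
                patient_vaf = 0.5, patient_dp = DP, patient_gt = "het",
                mother_vaf = 0, mother_dp = DP, mother_gt = "hom_ref",
                father_vaf = 0.5, father_dp = DP, father_gt = "het",
                is_decoy = TRUE, decoy_reason = "common_maf"),
    # a lone maternal variant: no partner allele
    fixture_row("chr4", 700, "c.16C>G", "DEC3SINGLE", NA, "missense", maf = 0.01,
                patient_vaf = 0.5, patient_dp = DP, patient_gt = "het",
                mother_vaf = 0.5, mother_dp = DP, mother_gt = "het",
                father_vaf = 0, father_dp = DP, father_gt = "hom_ref",
                is_decoy = TRUE, decoy_reason = "single_variant_gene")
  )
  tidy_fixture(bind_rows(rows, dec))
}

#' Copy-number event spectrum of the case
#'
#' The somatic copy-number landscape reported for the tumor, as a truth
#' table for [simulate_cna_profile()]: whole-chromosome gains of 5 and 18,
#' arm-level losses of 11p, 13q and 22q, and one focal homozygous deletion
#' of ~1.3 Mb at 9p (chr9:17,106,384-18,449,088, the only event with printed
#' base-pair coordinates; arm boundaries are approximate hg19 centromere
#' positions).
#'
#' @return A list: `truth` tibble `(chrom, start, end, copy)` and
#'   `chrom_lengths` (hg19-scale lengths of the involved chromosomes).
#' @examples
#' build_cna_truth()$truth
#' @export
build_cna_truth <- function() {
  chrom_lengths <- c(chr5 = 180915260, chr9 = 141213431, chr11 = 135006516,
                     chr13 = 115169878, chr18 = 78077248, chr22 = 51304566)
  truth <- tibble(
    chrom = c("chr5", "chr18", "chr11", "chr13", "chr22", "chr9"),
    start = c(1, 1, 1, 17900000, 14700000, 17106384),
    end = c(180915260, 78077248, 53700000, 115169878, 51304566, 18449088),
    copy = c(3, 3, 1, 1, 1, 0)
  )
  list(truth = truth, chrom_lengths = chrom_lengths)
}

#' Write a fixture (or any wide trio table) as TSV
#'
#' @param records Wide trio tibble.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_trio_tsv <- function(records, path) {
  readr::write_tsv(records, path)
  invisible(path)
}
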