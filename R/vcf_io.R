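#' Read a multi-sample VCF into a wide trio table
#'
#' Parses a VCF v4.x file (via vcfR) holding tumor, patient-leukocyte and
#' parental samples and joins the per-sample calls of each site into one row:
#' the wide trio-record layout consumed by the classifier. Depth is taken from
#' FORMAT/DP; the alt fraction from FORMAT/AD (alt/DP) or, when AD is absent,
#' FORMAT/AF; the genotype class from GT when present. Annotations come from
#' INFO keys whose names are configurable.
#'
#' @param path VCF file.
#' @param roles Named character vector mapping roles to VCF sample IDs, e.g.
#'   `c(tumor = "TUMOR", patient = "PATIENT", mother = "MOTHER",
#'   father = "FATHER")`. Roles absent from the mapping yield all-NA columns;
#'   a mapped sample missing from the file is an error.
#' @param info_keys Named vector mapping `gene`, `consequence`, `maf` to the
#'   INFO keys carrying them.
#' @return Tibble with one row per biallelic site: `chrom, pos, ref, alt,
#'   gene, consequence, maf`, plus `<role>_dp`, `<role>_alt`, `<role>_vaf`,
#'   `<role>_gt` for each role.
#' @seealso [write_trio_vcf()] for the inverse.
#' @export
read_trio_vcf <- function(path,
                          roles = c(tumor = "TUMOR", patient = "PATIENT",
                                    mother = "MOTHER", father = "FATHER"),
                          info_keys = c(gene = "GENE", consequence = "CSQ",
                                        maf = "MAF")) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  samples <- colnames(v@gt)[-1]
  missing_samples <- setdiff(unname(roles), samples)
  if (length(missing_samples) > 0) {
    abort(paste0("sample(s) not in VCF: ", paste(missing_samples, collapse = ", ")))
  }
  info_get <- function(key) {
    if (is.na(key)) return(rep(NA_character_, nrow(fix)))
    unname(vcfR::extract.info(v, element = key))
  }
  out <- tibble(
    chrom = fix$CHROM,
    pos = as.integer(fix$POS),
    ref = fix$REF,
    alt = fix$ALT,
    gene = info_get(info_keys[["gene"]]),
    consequence = info_get(info_keys[["consequence"]]),
    maf = suppressWarnings(as.numeric(info_get(info_keys[["maf"]])))
  )

  gt <- vcfR::extract.gt(v, element = "GT")
  dp <- suppressWarnings(vcfR::extract.gt(v, element = "DP", as.numeric = TRUE))
  ad <- tryCatch(vcfR::extract.gt(v, element = "AD"), error = function(e) NULL)
  af <- tryCatch(
    suppressWarnings(vcfR::extract.gt(v, element = "AF", as.numeric = TRUE)),
    error = function(e) NULL
  )

  for (role in c("tumor", "patient", "mother", "father")) {
    sid <- if (role %in% names(roles)) roles[[role]] else NA_character_
    if (is.na(sid)) {
      out[[paste0(role, "_dp")]] <- NA_real_
      out[[paste0(role, "_alt")]] <- NA_real_
      out[[paste0(role, "_vaf")]] <- NA_real_
      out[[paste0(role, "_gt")]] <- NA_character_
      next
    }
    rdp <- unname(dp[, sid])
    alt_n <- rep(NA_real_, nrow(out))
    if (!is.null(ad)) {
      # AD is "ref,alt"; malformed entries leave the sample's call missing
      parts <- stringr::str_split(ad[, sid], stringr::fixed(","))
      alt_n <- purrr::map_dbl(parts, function(p) {
        if (length(p) == 2 && !anyNA(suppressWarnings(as.numeric(p)))) {
          as.numeric(p[2])
        } else NA_real_
      })
    }
    vaf <- ifelse(!is.na(alt_n) & !is.na(rdp) & rdp > 0, alt_n / rdp, NA_real_)
    if (!is.null(af)) vaf <- ifelse(is.na(vaf), unname(af[, sid]), vaf)
    gts <- unname(gt_to_class(gt[, sid]))
    gts[is.na(rdp) | rdp == 0] <- "missing"
    out[[paste0(role, "_dp")]] <- as.numeric(rdp)
    out[[paste0(role, "_alt")]] <- alt_n
    out[[paste0(role, "_vaf")]] <- vaf
    out[[paste0(role, "_gt")]] <- gts
  }
  out
}

gt_to_class <- function(gt) {
  g <- stringr::str_replace_all(gt, "\\|", "/")
  dplyr::case_when(
    is.na(g) | g %in% c("./.", ".") ~ NA_character_,
    g == "0/0" ~ "hom_ref",
    g %in% c("0/1", "1/0") ~ "het",
    g == "1/1" ~ "hom_alt",
    TRUE ~ NA_character_
  )
}

class_to_gt <- function(cls) {
  dplyr::case_when(
    cls == "hom_ref" ~ "0/0",
    cls == "het" ~ "0/1",
    cls == "hom_alt" ~ "1/1",
    TRUE ~ "./."
  )
}

#' Write a wide trio table as a minimal multi-sample VCF
#'
#' Emits VCF v4.2 with FORMAT `GT:DP:AD` and the package's annotation INFO
#' keys (GENE, CSQ, MAF). Sites round-trip through [read_trio_vcf()]
#' unchanged. Only biallelic SNV-style records are supported.
#'
#' @param records Wide trio table (see [read_trio_vcf()] for the layout);
#'   `<role>_gt` columns are used when present, otherwise genotypes are
#'   classed from alt fraction and depth.
#' @param path Output file.
#' @param thresholds [filter_thresholds()] supplying genotype-class bounds
#'   when genotypes must be derived.
#' @return `path`, invisibly.
#' @export
write_trio_vcf <- function(records, path, thresholds = filter_thresholds()) {
  roles <- c("tumor", "patient", "mother", "father")
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene symbol\">",
    "##INFO=<ID=CSQ,Number=1,Type=String,Description=\"Functional consequence\">",
    "##INFO=<ID=MAF,Number=1,Type=Float,Description=\"Population minor allele frequency\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", toupper(roles)), collapse = "\t")
  )
  fmt_sample <- function(role) {
    dp <- records[[paste0(role, "_dp")]]
    alt <- records[[paste0(role, "_alt")]]
    vaf <- records[[paste0(role, "_vaf")]]
    gtc <- records[[paste0(role, "_gt")]] %||% rep(NA_character_, nrow(records))
    gtc <- ifelse(is.na(gtc), genotype_class(vaf, dp, thresholds), gtc)
    ifelse(
      is.na(dp),
      "./.:.:.",
      sprintf("%s:%d:%d,%d", class_to_gt(gtc), as.integer(dp),
              as.integer(dp - dplyr::coalesce(alt, 0)),
              as.integer(dplyr::coalesce(alt, 0)))
    )
  }
  info <- paste0(
    ifelse(is.na(records$gene), "", paste0("GENE=", records$gene, ";")),
    ifelse(is.na(records$consequence), "", paste0("CSQ=", records$consequence, ";")),
    ifelse(is.na(records$maf), "", paste0("MAF=", records$maf, ";"))
  )
  info <- sub(";$", "", info)
  info[info == ""] <- "."
  body <- paste(
    records$chrom, records$pos, ".", records$ref, records$alt, ".", "PASS",
    info, "GT:DP:AD",
    fmt_sample("tumor"), fmt_sample("patient"),
    fmt_sample("mother"), fmt_sample("father"),
    sep = "\t"
  )
  writeLines(c(hdr, body), path)
  invisible(path)
}
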