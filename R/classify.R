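#' @title Trio variant-selection rules
#' @description
#' The four selection procedures applied to a trio + tumor exome:
#'
#' * **somatic** — depth at least `min_depth` in tumor and patient leukocyte,
#'   tumor VAF at least `somatic_min_tumor_vaf`, and no alternate-allele
#'   support in the leukocyte (at most `max_normal_vaf`).
#' * **de novo** — depth at least `min_depth` in all three leukocyte samples,
#'   patient VAF at least `denovo_min_vaf`, neither parent carrying the
#'   alternate allele.
#' * **rare homozygous** — patient homozygous-alt, both parents heterozygous,
#'   all three leukocytes at depth, population MAF at most `rare_maf_max`.
#' * **compound heterozygous** — a gene with at least one maternal-only and
#'   one paternal-only heterozygous variant, each heterozygous in the
#'   patient, at depth in all three leukocytes, and rare; "maternal-only"
#'   means the mother is heterozygous and the father carries no alternate
#'   allele (and vice versa). A variant heterozygous in both parents has
#'   ambiguous phase and is ineligible, but does not invalidate the gene.
#'
#' Each `call_*` function is vectorised over the rows of a wide trio table
#' and returns the call plus a machine-readable failure reason; `NA` calls
#' mean indeterminate (a required sample has no call), distinct from `FALSE`.
#' @name trio-rules
NULL

role_col <- function(records, role, what) {
  col <- paste0(role, "_", what)
  if (col %in% names(records)) records[[col]] else rep(NA_real_, nrow(records))
}

# genotype class of a role: explicit *_gt when given, else classed from VAF
role_gt <- function(records, role, thresholds) {
  gt <- records[[paste0(role, "_gt")]] %||% rep(NA_character_, nrow(records))
  derived <- genotype_class(role_col(records, role, "vaf"),
                            role_col(records, role, "dp"), thresholds)
  if_else(is.na(gt), derived, gt)
}

first_reason <- function(...) {
  checks <- list(...)  # named logical vectors; TRUE = this check failed
  n <- length(checks[[1]])
  reason <- rep("pass", n)
  for (nm in rev(names(checks))) {
    reason <- if_else(checks[[nm]] %in% TRUE, nm, reason)
  }
  reason
}

#' @rdname trio-rules
#' @param records Wide trio table (see [read_trio_vcf()]).
#' @param thresholds A [filter_thresholds()].
#' @return `call_somatic()`, `call_de_novo()`, `call_rare_homozygous()`:
#'   the input with a logical call column and a reason column appended.
#' @examples
#' build_fixture("table1") |> call_somatic() |> dplyr::count(somatic)
#' @export
call_somatic <- function(records, thresholds = filter_thresholds()) {
  t_dp <- role_col(records, "tumor", "dp")
  t_vaf <- role_col(records, "tumor", "vaf")
  p_dp <- role_col(records, "patient", "dp")
  p_vaf <- role_col(records, "patient", "vaf")
  present <- !is.na(t_dp) & !is.na(p_dp) & !is.na(t_vaf) & !is.na(p_vaf)
  ok <- t_dp >= thresholds$min_depth & p_dp >= thresholds$min_depth &
    t_vaf >= thresholds$somatic_min_tumor_vaf &
    p_vaf <= thresholds$max_normal_vaf
  reason <- first_reason(
    low_tumor_depth = t_dp < thresholds$min_depth,
    low_leukocyte_depth = p_dp < thresholds$min_depth,
    low_vaf = t_vaf < thresholds$somatic_min_tumor_vaf,
    leukocyte_support = p_vaf > thresholds$max_normal_vaf
  )
  records |>
    mutate(somatic = if_else(present, ok, NA),
           somatic_reason = if_else(present, reason, "missing_call"))
}

#' @rdname trio-rules
#' @export
call_de_novo <- function(records, thresholds = filter_thresholds()) {
  p_dp <- role_col(records, "patient", "dp")
  p_vaf <- role_col(records, "patient", "vaf")
  m_dp <- role_col(records, "mother", "dp")
  m_vaf <- role_col(records, "mother", "vaf")
  f_dp <- role_col(records, "father", "dp")
  f_vaf <- role_col(records, "father", "vaf")
  present <- !is.na(p_dp) & !is.na(m_dp) & !is.na(f_dp) &
    !is.na(p_vaf) & !is.na(m_vaf) & !is.na(f_vaf)
  ok <- p_dp >= thresholds$min_depth & m_dp >= thresholds$min_depth &
    f_dp >= thresholds$min_depth & p_vaf >= thresholds$denovo_min_vaf &
    m_vaf <= thresholds$max_normal_vaf & f_vaf <= thresholds$max_normal_vaf
  reason <- first_reason(
    low_depth = p_dp < thresholds$min_depth | m_dp < thresholds$min_depth |
      f_dp < thresholds$min_depth,
    low_vaf = p_vaf < thresholds$denovo_min_vaf,
    parent_support = m_vaf > thresholds$max_normal_vaf |
      f_vaf > thresholds$max_normal_vaf
  )
  records |>
    mutate(de_novo = if_else(present, ok, NA),
           de_novo_reason = if_else(present, reason, "missing_call"))
}

#' @rdname trio-rules
#' @export
call_rare_homozygous <- function(records, thresholds = filter_thresholds()) {
  p_dp <- role_col(records, "patient", "dp")
  m_dp <- role_col(records, "mother", "dp")
  f_dp <- role_col(records, "father", "dp")
  p_gt <- role_gt(records, "patient", thresholds)
  m_gt <- role_gt(records, "mother", thresholds)
  f_gt <- role_gt(records, "father", thresholds)
  maf <- records$maf %||% rep(NA_real_, nrow(records))
  present <- !is.na(p_dp) & !is.na(m_dp) & !is.na(f_dp) &
    p_gt != "missing" & m_gt != "missing" & f_gt != "missing"
  rare <- maf_is_rare(maf, thresholds)
  ok <- p_dp >= thresholds$min_depth & m_dp >= thresholds$min_depth &
    f_dp >= thresholds$min_depth & p_gt == "hom_alt" &
    m_gt == "het" & f_gt == "het" & rare
  reason <- first_reason(
    low_depth = p_dp < thresholds$min_depth | m_dp < thresholds$min_depth |
      f_dp < thresholds$min_depth,
    patient_not_hom_alt = p_gt != "hom_alt",
    parent_not_het = m_gt != "het" | f_gt != "het",
    common_maf = !rare
  )
  records |>
    mutate(rare_homozygous = if_else(present, ok, NA),
           rare_homozygous_reason = if_else(present, reason, "missing_call"))
}

# per-variant compound-het eligibility and parental origin
comphet_members <- function(records, thresholds) {
  p_dp <- role_col(records, "patient", "dp")
  m_dp <- role_col(records, "mother", "dp")
  f_dp <- role_col(records, "father", "dp")
  m_vaf <- role_col(records, "mother", "vaf")
  f_vaf <- role_col(records, "father", "vaf")
  p_gt <- role_gt(records, "patient", thresholds)
  m_gt <- role_gt(records, "mother", thresholds)
  f_gt <- role_gt(records, "father", thresholds)
  maf <- records$maf %||% rep(NA_real_, nrow(records))
  depth_ok <- !is.na(p_dp) & !is.na(m_dp) & !is.na(f_dp) &
    p_dp >= thresholds$min_depth & m_dp >= thresholds$min_depth &
    f_dp >= thresholds$min_depth
  base <- depth_ok & p_gt == "het" & maf_is_rare(maf, thresholds)
  maternal <- base & m_gt == "het" &
    !is.na(f_vaf) & f_vaf <= thresholds$max_normal_vaf
  paternal <- base & f_gt == "het" &
    !is.na(m_vaf) & m_vaf <= thresholds$max_normal_vaf
  dplyr::case_when(maternal & !paternal ~ "maternal",
                   paternal & !maternal ~ "paternal",
                   TRUE ~ NA_character_)
}

#' Compound-heterozygosity by gene
#'
#' @inheritParams call_somatic
#' @return A list with `members` (the records plus `comphet_origin` and
#'   `compound_het_member`), `genes` (one row per reported gene with
#'   maternal/paternal allele counts), and `pairs` (every eligible maternal x
#'   paternal variant pair per reported gene).
#' @examples
#' call_compound_het(build_fixture("table3"))$genes
#' @export
call_compound_het <- function(records, thresholds = filter_thresholds()) {
  origin <- comphet_members(records, thresholds)
  members <- records |> mutate(comphet_origin = origin)
  gene <- records$gene %||% rep(NA_character_, nrow(records))
  tab <- tibble(gene = gene, origin = origin,
                key = paste0(records$chrom, ":", records$pos, records$ref, ">",
                             records$alt)) |>
    filter(!is.na(.data$origin), !is.na(.data$gene))
  genes <- tab |>
    group_by(.data$gene) |>
    summarise(n_maternal = sum(.data$origin == "maternal"),
              n_paternal = sum(.data$origin == "paternal"),
              .groups = "drop") |>
    filter(.data$n_maternal >= 1, .data$n_paternal >= 1) |>
    arrange(.data$gene)
  pairs <- if (nrow(genes) == 0) {
    tibble(gene = character(), maternal = character(), paternal = character())
  } else {
    tab |>
      filter(.data$gene %in% genes$gene) |>
      (\(d) {
        mat <- d |> filter(.data$origin == "maternal") |>
          select("gene", maternal = "key")
        pat <- d |> filter(.data$origin == "paternal") |>
          select("gene", paternal = "key")
        left_join(mat, pat, by = "gene", relationship = "many-to-many")
      })() |>
      arrange(.data$gene, .data$maternal, .data$paternal)
  }
  members <- members |>
    mutate(compound_het_member = !is.na(.data$comphet_origin) &
             gene %in% genes$gene)
  list(members = members, genes = genes, pairs = pairs)
}

#' Classify every variant of a trio case
#'
#' Runs all four selection rules over a wide trio table and aggregates the
#' per-class calls, compound-het genes and summary counts.
#'
#' @inheritParams call_somatic
#' @return An object of class `trio_classification`: a list with `variants`
#'   (the input plus call/reason columns and `comphet_origin` /
#'   `compound_het_member`), `genes` (compound-het genes), `pairs`,
#'   `thresholds`, and `summary` (named counts). [tidy()][tidy.trio_classification]
#'   returns the variant table; [glance()][glance.trio_classification] the
#'   one-row count summary.
#' @examples
#' cls <- classify_variants(build_fixture("table1"))
#' glance(cls)
#' @export
classify_variants <- function(records, thresholds = filter_thresholds()) {
  stopifnot(is.data.frame(records))
  if (nrow(records) == 0) {
    records <- trio_record_skeleton()
  }
  v <- records |>
    call_somatic(thresholds) |>
    call_de_novo(thresholds) |>
    call_rare_homozygous(thresholds)
  ch <- call_compound_het(records, thresholds)
  v <- v |>
    mutate(comphet_origin = ch$members$comphet_origin,
           compound_het_member = ch$members$compound_het_member)
  csq <- v$consequence %||% rep(NA_character_, nrow(v))
  protein_affecting <- !(csq %in% "synonymous")
  summary <- c(
    n_variants = nrow(v),
    n_somatic = sum(v$somatic, na.rm = TRUE),
    n_somatic_protein_affecting = sum(v$somatic & protein_affecting, na.rm = TRUE),
    n_de_novo = sum(v$de_novo, na.rm = TRUE),
    n_rare_homozygous = sum(v$rare_homozygous, na.rm = TRUE),
    n_comphet_genes = nrow(ch$genes),
    n_comphet_members = sum(v$compound_het_member, na.rm = TRUE)
  )
  structure(list(variants = v, genes = ch$genes, pairs = ch$pairs,
                 thresholds = thresholds, summary = summary),
            class = "trio_classification")
}

#' @export
print.trio_classification <- function(x, ...) {
  s <- x$summary
  cat("<trio_classification> of", s[["n_variants"]], "variants\n")
  cat(sprintf("  somatic            : %d (%d protein-affecting)\n",
              s[["n_somatic"]], s[["n_somatic_protein_affecting"]]))
  cat(sprintf("  de novo            : %d\n", s[["n_de_novo"]]))
  cat(sprintf("  rare homozygous    : %d\n", s[["n_rare_homozygous"]]))
  cat(sprintf("  compound-het genes : %d (%d member variants)\n",
              s[["n_comphet_genes"]], s[["n_comphet_members"]]))
  invisible(x)
}
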