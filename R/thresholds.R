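#' Variant-selection thresholds
#'
#' Bundle of the depth, allele-fraction and population-frequency cutoffs used
#' by the trio classification rules. The defaults implement the selection
#' criteria used throughout the package: a 10x coverage floor in every sample a
#' rule looks at, tumor variant-allele fraction (VAF) of at least 20% for a
#' somatic call, patient VAF of at least 30% for a de novo call, and a
#' population minor-allele-frequency ceiling of 10% for the germline
#' (rare-homozygous and compound-heterozygous) rules. All stated thresholds are
#' inclusive.
#'
#' Genotype-class bounds: when no genotype string is available a call is
#' classed from its alt fraction as `hom_ref` below `het_low`, `het` in
#' `[het_low, hom_min)` and `hom_alt` at or above `hom_min`. The defaults
#' (0.15 and 0.80) keep an 83.3% call homozygous and a 17.9% call
#' heterozygous, matching how tumor-board reports read such tables.
#'
#' `max_normal_vaf` is the alternate-allele support tolerated in a sample that
#' a rule requires to be negative (the patient leukocyte for somatic calls,
#' both parents for de novo calls, the opposite parent for compound-het
#' exclusivity). The default 0 demands strict absence.
#'
#' @param min_depth Minimum read depth (reads) in every sample a rule uses.
#' @param somatic_min_tumor_vaf Minimum tumor alt fraction for a somatic call.
#' @param denovo_min_vaf Minimum patient alt fraction for a de novo call.
#' @param rare_maf_max Maximum population minor-allele frequency for the
#'   germline rules.
#' @param max_normal_vaf Maximum alt fraction tolerated in a sample required
#'   to lack the variant.
#' @param het_low Lower alt-fraction bound (inclusive) of a heterozygous call.
#' @param hom_min Lower alt-fraction bound (inclusive) of a homozygous-alt
#'   call; also the exclusive upper bound of a het call.
#' @param maf_missing_rare Treat an absent population MAF as rare? Default
#'   TRUE: variants never seen in population databases are the rarest of all.
#'
#' @return An object of class `filter_thresholds` (a named list).
#' @examples
#' filter_thresholds()
#' filter_thresholds(somatic_min_tumor_vaf = 0.25)
#' @export
filter_thresholds <- function(min_depth = 10,
                              somatic_min_tumor_vaf = 0.20,
                              denovo_min_vaf = 0.30,
                              rare_maf_max = 0.10,
                              max_normal_vaf = 0,
                              het_low = 0.15,
                              hom_min = 0.80,
                              maf_missing_rare = TRUE) {
  th <- list(
    min_depth = min_depth,
    somatic_min_tumor_vaf = somatic_min_tumor_vaf,
    denovo_min_vaf = denovo_min_vaf,
    rare_maf_max = rare_maf_max,
    max_normal_vaf = max_normal_vaf,
    het_low = het_low,
    hom_min = hom_min,
    maf_missing_rare = isTRUE(maf_missing_rare)
  )
  num <- unlist(th[setdiff(names(th), c("min_depth", "maf_missing_rare"))])
  if (any(!is.finite(num)) || any(num < 0) || any(num > 1)) {
    abort("all fraction thresholds must lie in [0, 1]")
  }
  if (!is.numeric(min_depth) || min_depth < 0) {
    abort("`min_depth` must be a non-negative number of reads")
  }
  if (!(0 < th$het_low && th$het_low < th$hom_min && th$hom_min <= 1)) {
    abort("need 0 < het_low < hom_min <= 1")
  }
  structure(th, class = "filter_thresholds")
}

#' @export
print.filter_thresholds <- function(x, ...) {
  cat("<filter_thresholds>\n")
  cat(sprintf("  min depth            : %gx\n", x$min_depth))
  cat(sprintf("  somatic tumor VAF    : >= %g\n", x$somatic_min_tumor_vaf))
  cat(sprintf("  de novo patient VAF  : >= %g\n", x$denovo_min_vaf))
  cat(sprintf("  rare MAF ceiling     : <= %g\n", x$rare_maf_max))
  cat(sprintf("  tolerated normal VAF : <= %g\n", x$max_normal_vaf))
  cat(sprintf("  het / hom_alt bounds : [%g, %g) / >= %g\n",
              x$het_low, x$hom_min, x$hom_min))
  invisible(x)
}

#' Class a genotype from its alt fraction
#'
#' Vectorised genotype classing used whenever a VCF record carries no usable GT
#' string: `hom_ref` below `het_low`, `het` up to (excluding) `hom_min`,
#' `hom_alt` above, `missing` at zero depth or missing alt fraction.
#'
#' @param vaf Numeric vector of alt fractions (NA allowed).
#' @param depth Read depths matching `vaf`.
#' @param thresholds A [filter_thresholds()] object.
#' @return Character vector in
#'   `c("hom_ref", "het", "hom_alt", "missing")`.
#' @examples
#' genotype_class(c(0.02, 0.45, 0.95, NA), c(30, 30, 30, 0))
#' @export
genotype_class <- function(vaf, depth, thresholds = filter_thresholds()) {
  out <- rep("missing", length(vaf))
  ok <- !is.na(vaf) & !is.na(depth) & depth > 0
  out[ok & vaf < thresholds$het_low] <- "hom_ref"
  out[ok & vaf >= thresholds$het_low & vaf < thresholds$hom_min] <- "het"
  out[ok & vaf >= thresholds$hom_min] <- "hom_alt"
  out
}

# MAF eligibility for the germline rules; NA handled per maf_missing_rare.
maf_is_rare <- function(maf, thresholds) {
  if_else(is.na(maf), thresholds$maf_missing_rare, maf <= thresholds$rare_maf_max)
}
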