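#' Case configuration
#'
#' One configuration object drives [run_case()]. Besides inline defaults it
#' can be loaded from a YAML file with the same field names
#' ([read_case_config()]); explicit arguments override file values.
#'
#' Input files are all optional: each analysis stage runs only when its
#' inputs are present, so a case without parental exomes still yields the
#' somatic, copy-number and breakpoint sections, with the germline stages
#' marked skipped.
#'
#' @param vcf Multi-sample VCF path (variant stages).
#' @param roles Named vector mapping roles to VCF sample IDs.
#' @param probes Probe log2-ratio TSV `(chrom, pos, log2)` (array CNA stage).
#' @param tumor_depth,normal_depth Region-depth TSVs `(chrom, start, end,
#'   depth)` (read-depth CNA + concordance stage).
#' @param pairs BEDPE of mate pairs (breakpoint stage).
#' @param genome FASTA for junction assay design (optional).
#' @param droplets CSV of droplet counts with columns `sample, channel,
#'   n_positive, n_total, replicate, is_control` (monitoring stage).
#' @param thresholds [filter_thresholds()].
#' @param cna [cna_params()].
#' @param insert_mean,insert_sd,min_support Mate-pair stage settings.
#' @param droplet_volume,min_positive Droplet stage settings.
#' @param out_dir Output directory (created); NULL writes nothing.
#' @param seed Seed for any stage that samples.
#' @return A `case_config` list.
#' @export
case_config <- function(vcf = NULL,
                        roles = c(tumor = "TUMOR", patient = "PATIENT",
                                  mother = "MOTHER", father = "FATHER"),
                        probes = NULL, tumor_depth = NULL, normal_depth = NULL,
                        pairs = NULL, genome = NULL, droplets = NULL,
                        thresholds = filter_thresholds(), cna = cna_params(),
                        insert_mean = 2000, insert_sd = 150, min_support = 3,
                        droplet_volume = 0.85, min_positive = 2,
                        out_dir = NULL, seed = 1L) {
  structure(as.list(environment()), class = "case_config")
}

#' Load a case configuration from YAML
#'
#' Scalar fields map 1:1 to [case_config()] arguments; `roles` is a mapping
#' block, `thresholds` and `cna` are blocks of the respective constructor
#' arguments.
#'
#' @param path YAML file.
#' @return A `case_config`.
#' @export
read_case_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- y[setdiff(names(y), c("roles", "thresholds", "cna"))]
  if (!is.null(y$roles)) args$roles <- unlist(y$roles)
  if (!is.null(y$thresholds)) args$thresholds <- do.call(filter_thresholds, y$thresholds)
  if (!is.null(y$cna)) args$cna <- do.call(cna_params, y$cna)
  do.call(case_config, args)
}

#' Run a full case analysis
#'
#' Orchestrates every stage available from the configured inputs: variant
#' classification (somatic always; de novo / rare-homozygous / compound-het
#' only when both parents are mapped), probe segmentation, read-depth CNA
#' and cross-platform concordance, discordant-pair breakpoint calling (plus
#' junction assay design when a genome is given), and ddPCR monitoring
#' calls. Deterministic given identical inputs and seed.
#'
#' @param config A [case_config()] or path to its YAML file.
#' @return A `case_report` list: per-stage results (`status` one of `"ok"`,
#'   `"skipped"`) and a `summary` of headline counts. With `out_dir` set,
#'   per-stage tables (TSV), a SEG file and `report.json` are written.
#' @export
run_case <- function(config) {
  if (is.character(config)) config <- read_case_config(config)
  stopifnot(inherits(config, "case_config"))
  set.seed(config$seed)
  report <- list()

  out <- config$out_dir
  if (!is.null(out)) dir.create(out, recursive = TRUE, showWarnings = FALSE)
  emit <- function(d, name) {
    if (!is.null(out)) readr::write_tsv(d, file.path(out, name))
  }

  # --- variant classification ---------------------------------------------
  if (!is.null(config$vcf)) {
    records <- read_trio_vcf(config$vcf, roles = config$roles)
    have_parents <- all(c("mother", "father") %in% names(config$roles)) &&
      any(!is.na(records$mother_dp)) && any(!is.na(records$father_dp))
    cls <- classify_variants(records, config$thresholds)
    v <- tidy(cls)
    emit(v |> filter(.data$somatic %in% TRUE), "somatic_variants.tsv")
    if (have_parents) {
      emit(v |> filter(.data$rare_homozygous %in% TRUE), "rare_homozygous.tsv")
      emit(v |> filter(.data$compound_het_member), "compound_het_members.tsv")
    }
    report$variants <- list(
      status = "ok",
      germline = if (have_parents) "ok" else "skipped",
      summary = as.list(cls$summary),
      classification = cls
    )
  } else {
    report$variants <- list(status = "skipped")
  }

  # --- copy number ---------------------------------------------------------
  array_segs <- NULL
  if (!is.null(config$probes)) {
    probes <- readr::read_tsv(config$probes, col_types = "cid")
    array_segs <- segment_probes(probes, config$cna)
    emit(array_segs, "array_segments.tsv")
    if (!is.null(out)) write_seg(array_segs, file.path(out, "array_segments.seg"))
    report$cna_array <- list(status = "ok", segments = array_segs,
                             events = cna_events(array_segs))
  } else {
    report$cna_array <- list(status = "skipped")
  }
  if (!is.null(config$tumor_depth) && !is.null(config$normal_depth)) {
    td <- readr::read_tsv(config$tumor_depth, col_types = "ciid")
    nd <- readr::read_tsv(config$normal_depth, col_types = "ciid")
    wes_segs <- call_depth_cna(td, nd, config$cna,
                               min_normal_depth = config$thresholds$min_depth)
    emit(wes_segs, "wes_segments.tsv")
    conc <- NULL
    if (!is.null(array_segs)) {
      conc <- cna_concordance(cna_events(array_segs), cna_events(wes_segs))
      emit(tidy(conc), "cna_concordance.tsv")
    }
    report$cna_wes <- list(status = "ok", segments = wes_segs,
                           events = cna_events(wes_segs), concordance = conc)
  } else {
    report$cna_wes <- list(status = "skipped")
  }

  # --- breakpoint ----------------------------------------------------------
  if (!is.null(config$pairs)) {
    pairs <- read_bedpe(config$pairs)
    disc <- find_discordant(pairs, config$insert_mean, config$insert_sd)
    calls <- cluster_breakpoints(disc, min_support = config$min_support,
                                 insert_mean = config$insert_mean,
                                 insert_sd = config$insert_sd)
    emit(calls, "breakpoints.tsv")
    assay <- NULL
    if (!is.null(config$genome) && nrow(calls) > 0) {
      assay <- assay_region(calls, config$genome)
      if (!is.null(out)) {
        Biostrings::writeXStringSet(
          Biostrings::DNAStringSet(setNames(
            assay$fused, sprintf("fused_%s_%s", assay$chrom1, assay$chrom2))),
          file.path(out, "fused_contigs.fasta"))
      }
    }
    report$breakpoint <- list(status = "ok", n_discordant = nrow(disc),
                              calls = calls, assay = assay)
  } else {
    report$breakpoint <- list(status = "skipped")
  }

  # --- ctDNA monitoring ----------------------------------------------------
  if (!is.null(config$droplets)) {
    dd <- readr::read_csv(config$droplets, col_types = readr::cols())
    if (!"is_control" %in% names(dd)) dd$is_control <- FALSE
    controls <- dd |> filter(.data$is_control, .data$channel == "fusion")
    cases <- dd |> filter(!.data$is_control)
    calls <- cases |>
      group_by(.data$sample) |>
      dplyr::group_map(function(d, key) {
        q <- quantify_droplets(d, droplet_volume = config$droplet_volume,
                               min_positive = config$min_positive)
        dc <- detection_call(q, controls = controls,
                             min_positive = config$min_positive)
        tibble(sample = key$sample, call = dc$call, reason = dc$reason,
               fusion_fraction = dc$fusion_fraction$fusion_fraction)
      }) |> bind_rows()
    emit(calls, "monitoring_calls.tsv")
    report$monitoring <- list(status = "ok", calls = calls)
  } else {
    report$monitoring <- list(status = "skipped")
  }

  report$summary <- case_summary(report)
  if (!is.null(out)) {
    jsonlite::write_json(report$summary, file.path(out, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  structure(report, class = "case_report")
}

case_summary <- function(report) {
  s <- list()
  if (report$variants$status == "ok") {
    s <- c(s, report$variants$summary)
  }
  if (report$cna_array$status == "ok") {
    s$n_array_cna_events <- nrow(report$cna_array$events)
  }
  if (report$cna_wes$status == "ok") {
    s$n_wes_cna_events <- nrow(report$cna_wes$events)
    if (!is.null(report$cna_wes$concordance)) {
      s$cna_fraction_validated <- report$cna_wes$concordance$fraction_validated
    }
  }
  if (report$breakpoint$status == "ok") {
    s$n_breakpoints <- nrow(report$breakpoint$calls)
  }
  if (report$monitoring$status == "ok") {
    s$monitoring_calls <- setNames(as.list(report$monitoring$calls$call),
                                   report$monitoring$calls$sample)
  }
  s
}

#' @export
print.case_report <- function(x, ...) {
  cat("<case_report>\n")
  for (stage in c("variants", "cna_array", "cna_wes", "breakpoint", "monitoring")) {
    cat(sprintf("  %-10s : %s\n", stage, x[[stage]]$status))
  }
  invisible(x)
}
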