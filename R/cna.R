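#' Copy-number calling parameters
#'
#' Settings of the segmentation and classification step. Defaults follow
#' common array-CGH practice for a 180K oligonucleotide platform: a call
#' needs at least five consecutive probes, change-points must reach a
#' t-statistic significance of 1e-8, and segment means are classed against
#' log2-ratio thresholds 0.33 (gain), -0.3 (loss), 1.2 (high-copy gain) and
#' -1.1 (homozygous loss).
#'
#' @param min_probes Minimum probes for a non-neutral call.
#' @param alpha Significance threshold of the change-point t-test.
#' @param gain,loss,high_gain,hom_loss log2-ratio thresholds (all inclusive;
#'   `loss` and `hom_loss` are negative).
#' @return An object of class `cna_params`.
#' @examples
#' cna_params(min_probes = 8)
#' @export
cna_params <- function(min_probes = 5, alpha = 1e-8,
                       gain = 0.33, loss = -0.3,
                       high_gain = 1.2, hom_loss = -1.1) {
  if (min_probes < 2) abort("`min_probes` must be at least 2")
  if (!(hom_loss <= loss && loss < 0 && 0 < gain && gain <= high_gain)) {
    abort("need hom_loss <= loss < 0 < gain <= high_gain")
  }
  if (alpha <= 0 || alpha >= 1) abort("`alpha` must be in (0, 1)")
  structure(list(min_probes = min_probes, alpha = alpha, gain = gain,
                 loss = loss, high_gain = high_gain, hom_loss = hom_loss),
            class = "cna_params")
}

classify_log2 <- function(mean_log2, params) {
  dplyr::case_when(
    mean_log2 >= params$high_gain ~ "high_gain",
    mean_log2 >= params$gain ~ "gain",
    mean_log2 <= params$hom_loss ~ "homozygous_loss",
    mean_log2 <= params$loss ~ "loss",
    TRUE ~ "neutral"
  )
}

# best single change-point of x by two-sample t statistic; O(n) via cumsums
best_split <- function(x, minlen) {
  n <- length(x)
  if (n < 2 * minlen) return(NULL)
  ks <- minlen:(n - minlen)  # last index of the left segment
  cs <- cumsum(x); cs2 <- cumsum(x^2)
  nl <- ks; nr <- n - ks
  sl <- cs[ks]; sr <- cs[n] - sl
  ml <- sl / nl; mr <- sr / nr
  ssl <- cs2[ks] - sl^2 / nl
  ssr <- (cs2[n] - cs2[ks]) - sr^2 / nr
  pooled <- (ssl + ssr) / (n - 2)
  pooled <- pmax(pooled, .Machine$double.eps)
  tstat <- (ml - mr) / sqrt(pooled * (1 / nl + 1 / nr))
  i <- which.max(abs(tstat))
  p <- 2 * pt(-abs(tstat[i]), df = n - 2)
  list(k = ks[i], p = p)
}

segment_indices <- function(x, minlen, alpha) {
  n <- length(x)
  sp <- best_split(x, minlen)
  if (is.null(sp) || sp$p >= alpha) return(n)
  left <- segment_indices(x[1:sp$k], minlen, alpha)
  right <- segment_indices(x[(sp$k + 1):n], minlen, alpha)
  c(left, right + sp$k)  # cumulative end indices
}

#' Segment a probe-level log2-ratio series
#'
#' Recursive binary segmentation: each interval is split at the position
#' maximising the two-sample t statistic between the flanking means, the
#' split is kept when its p-value clears `alpha`, and the two halves are
#' segmented recursively (a CBS-style mean-shift model). Segments partition
#' each chromosome exactly; each is classed from its mean log2 ratio, and
#' non-neutral calls with fewer than `min_probes` probes are demoted to
#' neutral.
#'
#' @param probes Tibble `(chrom, pos, log2)`; positions must be strictly
#'   increasing within a chromosome.
#' @param params A [cna_params()].
#' @return Tibble of segments: `chrom, start, end, n_probes, mean_log2,
#'   call`, where start/end are the first/last probe positions covered.
#' @examples
#' cfg <- sim_config(seed = 1, cna_noise_sd = 0.1,
#'   cna_truth = tibble::tibble(chrom = "chr1", start = 1, end = 1e7, copy = 3))
#' segment_probes(simulate_cna_profile(cfg, 50000))
#' @export
segment_probes <- function(probes, params = cna_params()) {
  stopifnot(all(c("chrom", "pos", "log2") %in% names(probes)))
  segs <- probes |>
    group_by(.data$chrom) |>
    dplyr::group_map(function(d, key) {
      if (is.unsorted(d$pos, strictly = TRUE)) {
        abort("probe positions must be strictly increasing within chromosome")
      }
      ends <- segment_indices(d$log2, params$min_probes, params$alpha)
      starts <- c(1, head(ends, -1) + 1)
      tibble(
        chrom = key$chrom,
        start = d$pos[starts], end = d$pos[ends],
        n_probes = as.integer(ends - starts + 1),
        mean_log2 = purrr::map2_dbl(starts, ends, ~ mean(d$log2[.x:.y]))
      )
    }) |> bind_rows()
  segs |>
    mutate(call = classify_log2(.data$mean_log2, params),
           call = if_else(.data$call != "neutral" &
                            .data$n_probes < params$min_probes,
                          "neutral", .data$call)) |>
    arrange(.data$chrom, .data$start)
}

#' Collapse segments into copy-number events
#'
#' Filters non-neutral segments and merges adjacent same-call runs into one
#' event per alteration (probe-count-weighted mean log2).
#'
#' @param segments Output of [segment_probes()] or [call_depth_cna()].
#' @return Tibble of events with the same columns.
#' @export
cna_events <- function(segments) {
  if (nrow(segments) == 0) return(segments)
  segments |>
    arrange(.data$chrom, .data$start) |>
    group_by(.data$chrom) |>
    mutate(run = cumsum(c(TRUE, .data$call[-1] != .data$call[-dplyr::n()]))) |>
    group_by(.data$chrom, .data$run, .data$call) |>
    summarise(start = min(.data$start), end = max(.data$end),
              mean_log2 = sum(.data$mean_log2 * .data$n_probes) / sum(.data$n_probes),
              n_probes = as.integer(sum(.data$n_probes)), .groups = "drop") |>
    filter(.data$call != "neutral") |>
    select("chrom", "start", "end", "n_probes", "mean_log2", "call") |>
    arrange(.data$chrom, .data$start)
}

#' Copy-number calls from paired tumor/normal read depth
#'
#' Turns per-region exome depths into a pseudo-probe log2-ratio series:
#' regions with normal depth under `min_normal_depth` are dropped, the
#' log2(tumor/normal) ratios are median-centered (absorbing library-size
#' differences), and the series is segmented at region midpoints with
#' [segment_probes()].
#'
#' @param tumor,normal Tibbles `(chrom, start, end, depth)` over the same
#'   region set (an error otherwise).
#' @param params A [cna_params()].
#' @param min_normal_depth Minimum normal-sample depth for a usable region.
#' @return Segment tibble as in [segment_probes()].
#' @export
call_depth_cna <- function(tumor, normal, params = cna_params(),
                           min_normal_depth = 10) {
  key_t <- paste(tumor$chrom, tumor$start, tumor$end)
  key_n <- paste(normal$chrom, normal$start, normal$end)
  if (length(intersect(key_t, key_n)) == 0) {
    abort("tumor and normal region sets are disjoint")
  }
  d <- dplyr::inner_join(
    tumor |> rename(tumor_depth = "depth"),
    normal |> rename(normal_depth = "depth"),
    by = c("chrom", "start", "end")
  ) |>
    filter(.data$normal_depth >= min_normal_depth, .data$tumor_depth > 0) |>
    mutate(log2 = log2(.data$tumor_depth / .data$normal_depth),
           log2 = .data$log2 - median(.data$log2),
           pos = (.data$start + .data$end) %/% 2) |>
    arrange(.data$chrom, .data$pos)
  segment_probes(d |> select("chrom", "pos", "log2"), params)
}

#' Cross-platform concordance of copy-number events
#'
#' Scores how many events of one platform (e.g. array CGH) are validated by
#' another (e.g. exome read-depth calls): an event is validated when an event
#' of the same sign (gain-like vs loss-like) overlaps it.
#'
#' @param array_events,wes_events Event tibbles (`chrom, start, end, call`),
#'   e.g. from [cna_events()].
#' @param overlap `"any"` (default, >= 1 bp) or `"reciprocal"`.
#' @param min_reciprocal Minimum reciprocal overlap fraction when
#'   `overlap = "reciprocal"`.
#' @return An object of class `cna_concordance`: list with `events` (each
#'   array event with its `validated` flag), `n_array_events`, `n_validated`,
#'   `fraction_validated`.
#' @examples
#' ev <- tibble::tibble(chrom = "chr1", start = 1, end = 100, call = "gain")
#' cna_concordance(ev, ev)$fraction_validated
#' @export
cna_concordance <- function(array_events, wes_events,
                            overlap = c("any", "reciprocal"),
                            min_reciprocal = 0.5) {
  overlap <- match.arg(overlap)
  sign_of <- function(call) if_else(call %in% c("gain", "high_gain"), 1L, -1L)
  a <- array_events |> mutate(.sign = sign_of(.data$call))
  w <- wes_events |> mutate(.sign = sign_of(.data$call))
  validated <- purrr::map_lgl(seq_len(nrow(a)), function(i) {
    cand <- w |> filter(.data$chrom == a$chrom[i], .data$.sign == a$.sign[i])
    if (nrow(cand) == 0) return(FALSE)
    ov <- pmin(cand$end, a$end[i]) - pmax(cand$start, a$start[i]) + 1
    if (overlap == "any") return(any(ov >= 1))
    len_a <- a$end[i] - a$start[i] + 1
    any(ov >= 1 & ov / len_a >= min_reciprocal &
          ov / (cand$end - cand$start + 1) >= min_reciprocal)
  })
  events <- a |> select(-".sign") |> mutate(validated = validated)
  structure(list(
    events = events,
    n_array_events = nrow(a),
    n_validated = sum(validated),
    fraction_validated = if (nrow(a) == 0) NA_real_ else mean(validated)
  ), class = "cna_concordance")
}

#' @export
print.cna_concordance <- function(x, ...) {
  cat(sprintf("<cna_concordance> %d / %d events validated (%.1f%%)\n",
              x$n_validated, x$n_array_events, 100 * x$fraction_validated))
  invisible(x)
}

#' Write segments in SEG format
#'
#' @param segments Segment tibble.
#' @param path Output file.
#' @param sample_id Sample column value.
#' @return `path`, invisibly.
#' @export
write_seg <- function(segments, path, sample_id = "sample") {
  seg <- tibble(
    ID = sample_id, chrom = segments$chrom,
    loc.start = segments$start, loc.end = segments$end,
    num.mark = segments$n_probes, seg.mean = round(segments$mean_log2, 4)
  )
  readr::write_tsv(seg, path)
  invisible(path)
}
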