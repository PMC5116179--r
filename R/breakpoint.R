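#' Flag discordant mate-pairs
#'
#' A pair is discordant when its two reads map to different chromosomes, or
#' to the same chromosome at a separation incompatible with the library
#' insert (outside `insert_mean` +/- `k * insert_sd`, measuring separation as
#' read-start distance plus one read length).
#'
#' @param pairs Pair tibble (`pair_id, chrom1, pos1, strand1, chrom2, pos2,
#'   strand2`), e.g. from [simulate_matepairs()] or [read_bedpe()].
#' @param insert_mean,insert_sd Library insert length stats (bp).
#' @param k Width of the concordant window in sds.
#' @param read_length Read length (bp).
#' @return The discordant subset of `pairs` with a `discordant_type` column
#'   (`"interchromosomal"` or `"distance"`).
#' @export
find_discordant <- function(pairs, insert_mean = 2000, insert_sd = 150,
                            k = 3, read_length = 60) {
  inter <- pairs$chrom1 != pairs$chrom2
  span <- abs(pairs$pos2 - pairs$pos1) + read_length
  far <- !inter & (span < insert_mean - k * insert_sd |
                     span > insert_mean + k * insert_sd)
  pairs |>
    mutate(discordant_type = dplyr::case_when(
      inter ~ "interchromosomal", far ~ "distance", TRUE ~ NA_character_)) |>
    filter(!is.na(.data$discordant_type))
}

#' Cluster discordant pairs into breakpoint calls
#'
#' Groups interchromosomal discordant pairs by chromosome pair, single-links
#' pairs whose read positions fall within `window` on both sides, and reports
#' every cluster with at least `min_support` pairs as a breakpoint call. The
#' junction interval on each side spans one maximal insert from the innermost
#' read start, directed by the cluster's strand class: for plus-strand reads
#' (facing down-coordinate ends) the junction lies within `span` after the
#' rightmost read start; for minus-strand reads within `span` before the
#' leftmost.
#'
#' @param discordant Discordant pair tibble (see [find_discordant()]).
#' @param window Single-linkage distance (bp); default one maximal insert,
#'   `insert_mean + 3 * insert_sd`.
#' @param min_support Minimum supporting pairs per call.
#' @param insert_mean,insert_sd Library insert stats, defining the insert
#'   span that bounds the junction interval width.
#' @return Tibble of breakpoint calls: `chrom1, start1, end1, chrom2,
#'   start2, end2, supporting_pairs, orientation`, ordered by support then
#'   leftmost coordinate.
#' @export
cluster_breakpoints <- function(discordant, window = NULL, min_support = 3,
                                insert_mean = 2000, insert_sd = 150) {
  span <- insert_mean + 3 * insert_sd
  window <- window %||% span
  inter <- discordant |> filter(.data$chrom1 != .data$chrom2)
  if (nrow(inter) == 0) {
    return(tibble(chrom1 = character(), start1 = double(), end1 = double(),
                  chrom2 = character(), start2 = double(), end2 = double(),
                  supporting_pairs = integer(), orientation = character()))
  }
  # canonical orientation of the chromosome pair, so clustering is
  # invariant to which read was reported first
  flip <- inter$chrom1 > inter$chrom2
  inter2 <- inter |>
    mutate(
      cA = if_else(flip, .data$chrom2, .data$chrom1),
      pA = if_else(flip, .data$pos2, .data$pos1),
      sA = if_else(flip, .data$strand2, .data$strand1),
      cB = if_else(flip, .data$chrom1, .data$chrom2),
      pB = if_else(flip, .data$pos1, .data$pos2),
      sB = if_else(flip, .data$strand1, .data$strand2)
    ) |>
    arrange(.data$cA, .data$cB, .data$pA, .data$pB)
  side_interval <- function(pos, strand) {
    if (strand == "+") c(max(pos), max(pos) + span) else c(min(pos) - span, min(pos))
  }
  inter2 |>
    group_by(.data$cA, .data$cB) |>
    dplyr::group_map(function(d, key) {
      cl <- sl_cluster(d$pA, d$pB, window)
      purrr::map(sort(unique(cl)), function(ci) {
        dd <- d[cl == ci, ]
        sA <- names(sort(table(dd$sA), decreasing = TRUE))[1]
        sB <- names(sort(table(dd$sB), decreasing = TRUE))[1]
        iA <- side_interval(dd$pA, sA)
        iB <- side_interval(dd$pB, sB)
        tibble(chrom1 = key$cA, start1 = iA[1], end1 = iA[2],
               chrom2 = key$cB, start2 = iB[1], end2 = iB[2],
               supporting_pairs = nrow(dd),
               orientation = paste0(sA, "/", sB))
      }) |> bind_rows()
    }) |>
    bind_rows() |>
    filter(.data$supporting_pairs >= min_support) |>
    arrange(dplyr::desc(.data$supporting_pairs), .data$chrom1, .data$start1)
}

# iterative single-linkage on two coordinates with a shared window
sl_cluster <- function(p1, p2, window) {
  n <- length(p1)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  ord <- order(p1, p2)
  for (a in seq_len(max(0, n - 1))) {
    i <- ord[a]
    for (b in (a + 1):n) {
      j <- ord[b]
      if (p1[j] - p1[i] > window) break
      if (abs(p2[j] - p2[i]) <= window) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, sort(unique(roots)))
}

#' Extract junction-flanking sequence and a fused reference contig
#'
#' For each breakpoint call, pulls `flank` bases of reference sequence
#' immediately upstream of the first-side junction interval and downstream of
#' the second-side interval (the amplifiable arms of a junction PCR assay,
#' sized for ~400 bp amplicons), and concatenates them into a synthetic fused
#' contig emulating the rearranged allele.
#'
#' @param calls Breakpoint-call tibble from [cluster_breakpoints()].
#' @param genome A named character vector of sequences, a
#'   `Biostrings::DNAStringSet`, or a FASTA path.
#' @param flank Flank length (bp) per side.
#' @return Tibble with one row per call: flank coordinates, `left_flank`,
#'   `right_flank` and `fused` sequences (characters). Zero calls give a
#'   zero-row tibble.
#' @export
assay_region <- function(calls, genome, flank = 400) {
  seqs <- load_genome(genome)
  if (nrow(calls) == 0) {
    return(tibble(chrom1 = character(), left_start = double(),
                  left_end = double(), chrom2 = character(),
                  right_start = double(), right_end = double(),
                  left_flank = character(), right_flank = character(),
                  fused = character()))
  }
  purrr::map(seq_len(nrow(calls)), function(i) {
    c1 <- calls$chrom1[i]; c2 <- calls$chrom2[i]
    for (cc in c(c1, c2)) {
      if (!cc %in% names(seqs)) abort(paste0("no sequence for ", cc))
    }
    jA <- calls$start1[i]  # innermost read boundary on the first side
    jB <- calls$end2[i]
    ls <- jA - flank + 1; le <- jA
    rs <- jB; re <- jB + flank - 1
    if (ls < 1 || rs < 1 || re > nchar(seqs[[c2]]) || le > nchar(seqs[[c1]])) {
      abort("flank extends outside the reference sequence")
    }
    left <- substr(seqs[[c1]], ls, le)
    right <- substr(seqs[[c2]], rs, re)
    tibble(chrom1 = c1, left_start = ls, left_end = le,
           chrom2 = c2, right_start = rs, right_end = re,
           left_flank = left, right_flank = right,
           fused = paste0(left, right))
  }) |> bind_rows()
}

load_genome <- function(genome) {
  if (inherits(genome, "DNAStringSet")) {
    setNames(as.character(genome), names(genome))
  } else if (is.character(genome) && length(genome) == 1 && file.exists(genome)) {
    x <- Biostrings::readDNAStringSet(genome)
    names(x) <- sub("\\s.*$", "", names(x))
    setNames(as.character(x), names(x))
  } else if (is.character(genome) && !is.null(names(genome))) {
    genome
  } else {
    abort("`genome` must be a named character vector, DNAStringSet or FASTA path")
  }
}

#' Read / write pair tables as BEDPE
#'
#' Minimal BEDPE support for discordant-pair exchange: columns chrom1,
#' start1, end1, chrom2, start2, end2, name, score, strand1, strand2 with
#' 0-based half-open read intervals of one read length.
#'
#' @param pairs Pair tibble.
#' @param path File path.
#' @param read_length Read length used for interval ends.
#' @return `read_bedpe()`: a pair tibble; `write_bedpe()`: `path`, invisibly.
#' @export
write_bedpe <- function(pairs, path, read_length = 60) {
  out <- tibble(
    chrom1 = pairs$chrom1, start1 = pairs$pos1 - 1,
    end1 = pairs$pos1 - 1 + read_length,
    chrom2 = pairs$chrom2, start2 = pairs$pos2 - 1,
    end2 = pairs$pos2 - 1 + read_length,
    name = pairs$pair_id %||% paste0("pair", seq_len(nrow(pairs))),
    score = 0L,
    strand1 = pairs$strand1, strand2 = pairs$strand2
  )
  readr::write_tsv(out, path, col_names = FALSE)
  invisible(path)
}

#' @rdname write_bedpe
#' @export
read_bedpe <- function(path) {
  d <- readr::read_tsv(
    path,
    col_names = c("chrom1", "start1", "end1", "chrom2", "start2", "end2",
                  "name", "score", "strand1", "strand2"),
    col_types = "ciiciicicc"
  )
  tibble(pair_id = d$name,
         chrom1 = d$chrom1, pos1 = d$start1 + 1L, strand1 = d$strand1,
         chrom2 = d$chrom2, pos2 = d$start2 + 1L, strand2 = d$strand2)
}
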