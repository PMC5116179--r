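#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a trio classification
#'
#' @param x A `trio_classification` from [classify_variants()].
#' @param ... Unused.
#' @return The per-variant call table (tibble).
#' @exportS3Method generics::tidy
tidy.trio_classification <- function(x, ...) as_tibble(x$variants)

#' One-row summary of a trio classification
#'
#' @inheritParams tidy.trio_classification
#' @return Tibble with the per-class counts.
#' @exportS3Method generics::glance
glance.trio_classification <- function(x, ...) {
  as_tibble(as.list(x$summary))
}

#' Tidy a concordance report
#'
#' @param x A `cna_concordance` from [cna_concordance()].
#' @param ... Unused.
#' @return Per-event tibble with `validated` flags.
#' @exportS3Method generics::tidy
tidy.cna_concordance <- function(x, ...) as_tibble(x$events)

#' @rdname tidy.cna_concordance
#' @exportS3Method generics::glance
glance.cna_concordance <- function(x, ...) {
  tibble(n_array_events = x$n_array_events, n_validated = x$n_validated,
         fraction_validated = x$fraction_validated)
}
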