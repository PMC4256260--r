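#' Tidiers for pipeline result objects
#'
#' Broom-style accessors: `tidy()` returns the per-observation table of
#' a result object and `glance()` a one-row summary tibble.
#'
#' @param x A `splice_event_set`, `target_regulation` or
#'   `pipeline_report`.
#' @param ... Unused.
#' @return A tibble.
#' @name spliceindel-tidiers
NULL

#' @rdname spliceindel-tidiers
#' @export
tidy.splice_event_set <- function(x, ...) {
  x$events
}

#' @rdname spliceindel-tidiers
#' @export
glance.splice_event_set <- function(x, ...) {
  as_tibble(x$summary[c("n_events", "n_isoforms", "n_genes",
                        "n_isoforms_considered", "n_unmatched")])
}

#' @rdname spliceindel-tidiers
#' @export
tidy.target_regulation <- function(x, ...) {
  x$regulation
}

#' @rdname spliceindel-tidiers
#' @export
glance.target_regulation <- function(x, ...) {
  tidyr::pivot_wider(x$counts, names_from = "direction", values_from = "n",
                     names_prefix = "n_")
}

#' @rdname spliceindel-tidiers
#' @export
tidy.splice_alignment <- function(x, ...) {
  tibble(standard_id = x$standard_id, variant_id = x$variant_id,
         columns = nchar(x$aligned_standard), score = x$score,
         identity = x$identity)
}
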