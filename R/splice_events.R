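#' Global alignment of a variant isoform against its standard form
#'
#' Needleman-Wunsch global alignment with affine gap penalties, via
#' [Biostrings::pairwiseAlignment()]. The defaults (match +2, mismatch
#' -3, gap open -10, gap extend -0.5) penalize gap opening strongly so a
#' whole spliced-out block surfaces as a single gap run rather than
#' scattered gaps.
#'
#' @param standard_seq,variant_seq Sequences (character or
#'   [Biostrings::DNAString]) over A/C/G/T/N; must be non-empty.
#' @param match,mismatch,gap_open,gap_extend Scoring parameters
#'   (penalties negative).
#' @param standard_id,variant_id Optional identifiers carried through to
#'   the result.
#' @return An object of class `splice_alignment`: a list with
#'   `aligned_standard` and `aligned_variant` (gapped strings of equal
#'   length), `score`, and `identity` (matching columns over alignment
#'   columns). Removing the gaps recovers the input sequences; no column
#'   has a gap in both rows.
#' @export
global_align <- function(standard_seq, variant_seq,
                         match = 2, mismatch = -3,
                         gap_open = -10, gap_extend = -0.5,
                         standard_id = NA_character_,
                         variant_id = NA_character_) {
  standard_seq <- toupper(as.character(standard_seq))
  variant_seq <- toupper(as.character(variant_seq))
  if (nchar(standard_seq) == 0 || nchar(variant_seq) == 0) {
    abort("sequences must be non-empty")
  }
  mat <- Biostrings::nucleotideSubstitutionMatrix(
    match = match, mismatch = mismatch, baseOnly = FALSE)
  aln <- Biostrings::pairwiseAlignment(
    pattern = variant_seq, subject = standard_seq,
    substitutionMatrix = mat,
    gapOpening = abs(gap_open), gapExtension = abs(gap_extend),
    type = "global")
  a_var <- as.character(Biostrings::alignedPattern(aln))
  a_std <- as.character(Biostrings::alignedSubject(aln))
  cs <- strsplit(a_std, "")[[1]]
  cv <- strsplit(a_var, "")[[1]]
  ident <- sum(cs == cv & cs != "-") / length(cs)
  structure(
    list(standard_id = standard_id, variant_id = variant_id,
         aligned_standard = a_std, aligned_variant = a_var,
         score = Biostrings::score(aln), identity = ident),
    class = "splice_alignment")
}

#' @export
print.splice_alignment <- function(x, ...) {
  cat(sprintf("<splice_alignment> %s vs %s: %d columns, score %.1f, identity %.3f\n",
              x$standard_id %na% "standard", x$variant_id %na% "variant",
              nchar(x$aligned_standard), x$score, x$identity))
  invisible(x)
}

#' Extract insertion/deletion splicing events from an alignment
#'
#' Each maximal run of gap columns in the standard row becomes one
#' insertion (positive signed size: novel sequence present in the
#' variant) and each maximal run in the variant row one deletion
#' (negative signed size). Anchors are 0-based offsets on the standard
#' transcript; for insertions, the offset of the standard base that
#' follows the insertion point. Every event is left-normalized: it is
#' shifted to the leftmost equivalent position on the standard sequence
#' (without crossing the preceding event), so anchors are canonical
#' regardless of where the aligner happened to place an ambiguous gap.
#' Events are returned sorted by anchor.
#'
#' @param alignment A `splice_alignment` from [global_align()].
#' @return A tibble `(type, signed_size, size, anchor, inserted_seq)`;
#'   zero rows for a gapless alignment.
#' @export
gaps_to_events <- function(alignment) {
  stopifnot(inherits(alignment, "splice_alignment"))
  cs <- strsplit(alignment$aligned_standard, "")[[1]]
  cv <- strsplit(alignment$aligned_variant, "")[[1]]
  if (any(cs == "-" & cv == "-")) abort("alignment has a column gapped in both rows")
  status <- ifelse(cs == "-", "S", ifelse(cv == "-", "V", "M"))
  r <- rle(status)
  std_seq <- paste(cs[cs != "-"], collapse = "")

  events <- list()
  std_pos <- 0L
  col <- 0L
  for (i in seq_along(r$lengths)) {
    len <- r$lengths[i]
    if (r$values[i] == "M") {
      std_pos <- std_pos + len
    } else if (r$values[i] == "V") {
      events[[length(events) + 1]] <- list(
        type = "deletion", size = len, anchor = std_pos,
        inserted_seq = NA_character_)
      std_pos <- std_pos + len
    } else {
      ins <- paste(cv[(col + 1):(col + len)], collapse = "")
      events[[length(events) + 1]] <- list(
        type = "insertion", size = len, anchor = std_pos,
        inserted_seq = ins)
    }
    col <- col + len
  }
  if (length(events) == 0) {
    return(tibble(type = character(), signed_size = integer(),
                  size = integer(), anchor = integer(),
                  inserted_seq = character()))
  }
  floor <- 0L
  rows <- purrr::map(events, function(ev) {
    norm <- left_normalize_event(std_seq, ev$type, ev$anchor, ev$size,
                                 ev$inserted_seq, floor = floor)
    floor <<- norm$anchor + if (ev$type == "deletion") ev$size else 0L
    tibble(type = ev$type,
           signed_size = as.integer(if (ev$type == "insertion") ev$size else -ev$size),
           size = as.integer(ev$size),
           anchor = norm$anchor,
           inserted_seq = norm$inserted_seq)
  })
  arrange(bind_rows(rows), .data$anchor)
}

#' Locate an event along the standard transcript
#'
#' Converts an anchor offset to a location percentage of the standard
#' transcript length. Under the `five_prime` origin (the default), 0%
#' is the very 5' end and 100% the very 3' end; under the `three_prime`
#' origin the axis is reversed, so the two conventions sum to 100 for
#' any anchor.
#'
#' @param anchor 0-based offset on the standard transcript (0 to
#'   `standard_length` inclusive; terminal anchors are permitted).
#' @param standard_length Standard transcript length (bp, positive).
#' @param origin `"five_prime"` or `"three_prime"`.
#' @return Location percentage in \[0, 100\].
#' @export
locate_event <- function(anchor, standard_length,
                         origin = c("five_prime", "three_prime")) {
  origin <- match.arg(origin)
  if (any(standard_length <= 0)) abort("standard_length must be positive")
  if (any(anchor < 0 | anchor > standard_length)) {
    abort("anchor must lie in [0, standard_length]")
  }
  if (origin == "five_prime") 100 * anchor / standard_length
  else 100 * (standard_length - anchor) / standard_length
}

#' Assign the transcript region of an event
#'
#' Partitions the standard transcript by its CDS offsets: anchors before
#' `cds_start_tx` are `FIVE_UTR`, anchors from `cds_start_tx` up to (but
#' excluding) `cds_end_tx` are `GENE_BODY`, and anchors at or beyond
#' `cds_end_tx` are `THREE_UTR` (half-open boundaries). A deletion is
#' labelled by its start anchor even when it spans a boundary. With
#' missing CDS offsets the region is `UNASSIGNED`.
#'
#' @param anchor 0-based anchor offset(s).
#' @param cds_start_tx,cds_end_tx CDS boundaries in transcript
#'   coordinates (0-based half-open), possibly `NA`.
#' @return Character vector of region labels.
#' @export
assign_region <- function(anchor, cds_start_tx, cds_end_tx) {
  out <- ifelse(is.na(cds_start_tx) | is.na(cds_end_tx), "UNASSIGNED",
                region_of_anchor(anchor, cds_start_tx, cds_end_tx))
  if (any(out == "UNASSIGNED")) {
    inform("standard transcript without CDS annotation: region UNASSIGNED")
  }
  out
}

#' Match a unique isoform to a standard form by homology
#'
#' Fallback matcher for isoforms without a usable gene assignment: the
#' isoform is aligned against every standard-form sequence and matched
#' to the best-scoring one whose alignment identity reaches
#' `min_identity`; `NA` when none qualifies.
#'
#' @param variant_seq The isoform sequence.
#' @param standard_seqs Named character vector (or
#'   [Biostrings::DNAStringSet]) of standard-form sequences, named by
#'   transcript ID.
#' @param min_identity Minimum fraction of matching alignment columns.
#' @inheritParams global_align
#' @return The matched standard transcript ID, or `NA_character_`.
#' @export
match_homolog <- function(variant_seq, standard_seqs, min_identity = 0.7,
                          match = 2, mismatch = -3,
                          gap_open = -10, gap_extend = -0.5) {
  seqs <- as_seq_chr(standard_seqs)
  if (length(seqs) == 0) return(NA_character_)
  alns <- purrr::map(seqs, function(s) {
    global_align(s, variant_seq, match = match, mismatch = mismatch,
                 gap_open = gap_open, gap_extend = gap_extend)
  })
  scores <- purrr::map_dbl(alns, "score")
  idents <- purrr::map_dbl(alns, "identity")
  ok <- idents >= min_identity
  if (!any(ok)) return(NA_character_)
  names(seqs)[ok][which.max(scores[ok])]
}

#' Call all splicing events for a set of condition-unique isoforms
#'
#' For every unique isoform, finds its standard form (same gene by
#' default; homology fallback via [match_homolog()] when the gene has no
#' standard form), aligns the pair with [global_align()], extracts
#' left-normalized insertion/deletion events with [gaps_to_events()],
#' and annotates each event with its location percentage (under the
#' chosen coordinate origin) and its 5'UTR / gene-body / 3'UTR region
#' from the standard form's CDS offsets. Isoforms without a sequence are
#' skipped with a warning; an isoform that is itself the gene's standard
#' form is skipped with a message.
#'
#' @param unique_calls Tibble from [call_unique_isoforms()] (any subset
#'   of rows, e.g. one condition's direction).
#' @param standard_forms Tibble from [select_standard_form()].
#' @param sequences Named [Biostrings::DNAStringSet] or character vector
#'   with variant and standard sequences.
#' @param models Model table (as from [read_gtf()]) supplying
#'   `cds_start_tx`/`cds_end_tx` and `length` of the standard forms.
#' @param origin Coordinate origin for location percentages.
#' @param min_identity Identity floor for the homology fallback.
#' @inheritParams global_align
#' @return An object of class `splice_event_set`: list with `events`
#'   (tibble: `gene_id`, `standard_id`, `variant_id`, `type`,
#'   `signed_size`, `anchor`, `location_pct`, `region`,
#'   `spans_boundary`, `inserted_seq`), `summary` (event, isoform and
#'   gene counts), and `params`. Use [tidy()] / [glance()] /
#'   [autoplot()] on it.
#' @export
call_splice_events <- function(unique_calls, standard_forms, sequences, models,
                               origin = c("five_prime", "three_prime"),
                               min_identity = 0.7,
                               match = 2, mismatch = -3,
                               gap_open = -10, gap_extend = -0.5) {
  origin <- match.arg(origin)
  check_columns(unique_calls, c("transcript_id", "gene_id"), "unique_calls")
  check_columns(standard_forms, c("gene_id", "transcript_id"), "standard_forms")
  check_columns(models, c("transcript_id", "length", "cds_start_tx", "cds_end_tx"),
                "models")
  seqs <- as_seq_chr(sequences)
  std_by_gene <- setNames(standard_forms$transcript_id, standard_forms$gene_id)
  std_seqs <- seqs[intersect(standard_forms$transcript_id, names(seqs))]
  mrow <- function(id) models[match(id, models$transcript_id), ]

  ev_rows <- list()
  n_skipped_noseq <- 0L
  n_unmatched <- 0L
  for (i in seq_len(nrow(unique_calls))) {
    var_id <- unique_calls$transcript_id[i]
    gene <- unique_calls$gene_id[i]
    if (!var_id %in% names(seqs)) {
      warn(sprintf("isoform %s has no sequence; skipped", var_id))
      n_skipped_noseq <- n_skipped_noseq + 1L
      next
    }
    std_id <- if (!is.na(gene) && gene %in% names(std_by_gene)) {
      std_by_gene[[gene]]
    } else {
      match_homolog(seqs[[var_id]], std_seqs, min_identity = min_identity,
                    match = match, mismatch = mismatch,
                    gap_open = gap_open, gap_extend = gap_extend)
    }
    if (is.na(std_id)) {
      n_unmatched <- n_unmatched + 1L
      next
    }
    if (identical(std_id, var_id)) {
      inform(sprintf("isoform %s is its gene's standard form; skipped", var_id))
      next
    }
    if (!std_id %in% names(seqs)) {
      warn(sprintf("standard form %s has no sequence; %s skipped", std_id, var_id))
      n_skipped_noseq <- n_skipped_noseq + 1L
      next
    }
    aln <- global_align(seqs[[std_id]], seqs[[var_id]],
                        match = match, mismatch = mismatch,
                        gap_open = gap_open, gap_extend = gap_extend,
                        standard_id = std_id, variant_id = var_id)
    evs <- gaps_to_events(aln)
    if (nrow(evs) == 0) next
    sm <- mrow(std_id)
    L <- sm$length
    del_end_region <- assign_region(
      pmin(evs$anchor + ifelse(evs$type == "deletion", evs$size - 1L, 0L), L - 1L),
      sm$cds_start_tx, sm$cds_end_tx)
    evs <- evs |>
      mutate(
        gene_id = if (is.na(gene)) sm$gene_id else gene,
        standard_id = std_id,
        variant_id = var_id,
        location_pct = locate_event(.data$anchor, L, origin),
        region = assign_region(.data$anchor, sm$cds_start_tx, sm$cds_end_tx),
        spans_boundary = .data$type == "deletion" & .data$region != del_end_region
      )
    ev_rows[[length(ev_rows) + 1]] <- evs
  }
  events <- if (length(ev_rows) > 0) bind_rows(ev_rows) else
    tibble(type = character(), signed_size = integer(), size = integer(),
           anchor = integer(), inserted_seq = character(),
           gene_id = character(), standard_id = character(),
           variant_id = character(), location_pct = numeric(),
           region = character(), spans_boundary = logical())
  events <- events |>
    select("gene_id", "standard_id", "variant_id", "type", "signed_size",
           "size", "anchor", "location_pct", "region", "spans_boundary",
           "inserted_seq") |>
    arrange(.data$gene_id, .data$variant_id, .data$anchor)
  structure(
    list(
      events = events,
      summary = list(
        n_events = nrow(events),
        n_isoforms = dplyr::n_distinct(events$variant_id),
        n_genes = dplyr::n_distinct(events$gene_id),
        n_isoforms_considered = nrow(unique_calls),
        n_unmatched = n_unmatched,
        n_skipped_no_sequence = n_skipped_noseq
      ),
      params = list(origin = origin, min_identity = min_identity,
                    match = match, mismatch = mismatch,
                    gap_open = gap_open, gap_extend = gap_extend)
    ),
    class = "splice_event_set")
}

#' @export
print.splice_event_set <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "<splice_event_set> %d events in %d isoforms across %d genes (origin: %s)\n",
    s$n_events, s$n_isoforms, s$n_genes, x$params$origin))
  invisible(x)
}

#' Reconstruct a variant sequence from its event list
#'
#' Applies a set of called events (insertions and deletions at recorded
#' anchors on the standard transcript) to the standard sequence. For any
#' correctly called isoform pair this reproduces the variant sequence
#' exactly.
#'
#' @param standard_seq Standard-form sequence (character or
#'   [Biostrings::DNAString]).
#' @param events Tibble with `type`, `size`, `anchor` and (for
#'   insertions) `inserted_seq`, as produced by [gaps_to_events()] or
#'   [call_splice_events()] for a single isoform pair.
#' @return The reconstructed variant sequence (character).
#' @export
apply_splice_events <- function(standard_seq, events) {
  seq <- as.character(standard_seq)
  if (nrow(events) == 0) return(seq)
  events <- arrange(events, dplyr::desc(.data$anchor))
  for (i in seq_len(nrow(events))) {
    a <- events$anchor[i]
    s <- events$size[i]
    if (events$type[i] == "insertion") {
      seq <- paste0(substr(seq, 1, a), events$inserted_seq[i],
                    substr(seq, a + 1, nchar(seq)))
    } else {
      seq <- paste0(substr(seq, 1, a), substr(seq, a + s + 1, nchar(seq)))
    }
  }
  seq
}
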