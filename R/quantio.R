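#' Read transcript models from a GTF file
#'
#' Parses a GTF 2.2 file (1-based, inclusive coordinates; `exon` and `CDS`
#' features carrying `gene_id`/`transcript_id` attributes) and assembles one
#' transcript model per `transcript_id`: the exon chain ordered 5' to 3' in
#' transcript orientation, the transcript length, and the CDS boundaries
#' converted to transcript coordinates (0-based, half-open). Minus-strand
#' transcripts are reported 5' to 3' along the mRNA, so transcript
#' coordinate 0 is the genomically rightmost exon base.
#'
#' @param path Path to a GTF file (optionally gzip-compressed).
#' @return A tibble with one row per transcript: `transcript_id`, `gene_id`,
#'   `seqname`, `strand`, `length`, `cds_start_tx`, `cds_end_tx` (both
#'   `NA` when the transcript has no CDS feature), and `exons`, a
#'   list-column of tibbles with 0-based half-open genomic `start`/`end`
#'   ordered in transcript (5' to 3') order.
#' @export
read_gtf <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  meta <- S4Vectors::mcols(gr)
  keep <- meta$type %in% c("exon", "CDS")
  gr <- gr[keep]
  meta <- S4Vectors::mcols(gr)
  if (is.null(meta$transcript_id) || anyNA(meta$transcript_id)) {
    bad <- if (is.null(meta$transcript_id)) 1L else which(is.na(meta$transcript_id))[1]
    abort(sprintf(
      "GTF feature %d (%s) has no transcript_id attribute",
      bad, as.character(meta$type[bad])))
  }
  df <- tibble(
    seqname = as.character(GenomicRanges::seqnames(gr)),
    # convert to 0-based half-open internally
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    type = as.character(meta$type),
    gene_id = as.character(meta$gene_id),
    transcript_id = as.character(meta$transcript_id)
  )
  build_models(df)
}

build_models <- function(df) {
  by_tx <- split(df, df$transcript_id)
  rows <- purrr::map(by_tx, function(d) {
    tx <- d$transcript_id[1]
    strand <- d$strand[1]
    if (!strand %in% c("+", "-")) {
      abort(sprintf("transcript %s has unstranded features", tx))
    }
    ex <- d[d$type == "exon", ]
    if (nrow(ex) == 0) abort(sprintf("transcript %s has no exon features", tx))
    ex <- ex[order(ex$start), ]
    if (nrow(ex) > 1 && any(ex$end[-nrow(ex)] > ex$start[-1])) {
      abort(sprintf("transcript %s has overlapping exons", tx))
    }
    exons <- tibble(start = ex$start, end = ex$end)
    if (strand == "-") exons <- exons[rev(seq_len(nrow(exons))), ]
    len <- sum(exons$end - exons$start)

    cds <- d[d$type == "CDS", ]
    if (nrow(cds) > 0) {
      inside <- vapply(seq_len(nrow(cds)), function(i) {
        any(cds$start[i] >= exons$start & cds$end[i] <= exons$end)
      }, logical(1))
      if (!all(inside)) {
        abort(sprintf("transcript %s has CDS outside its exons", tx))
      }
      gmin <- min(cds$start)
      gmax <- max(cds$end)
      if (strand == "+") {
        cds_start_tx <- genomic_to_tx(exons, strand, gmin)
        cds_end_tx <- genomic_to_tx(exons, strand, gmax - 1L) + 1L
      } else {
        cds_start_tx <- genomic_to_tx(exons, strand, gmax - 1L)
        cds_end_tx <- genomic_to_tx(exons, strand, gmin) + 1L
      }
    } else {
      cds_start_tx <- NA_integer_
      cds_end_tx <- NA_integer_
    }
    tibble(
      transcript_id = tx, gene_id = d$gene_id[1],
      seqname = d$seqname[1], strand = strand, length = len,
      cds_start_tx = cds_start_tx, cds_end_tx = cds_end_tx,
      exons = list(exons)
    )
  })
  arrange(bind_rows(rows), .data$gene_id, .data$transcript_id)
}

#' Convert between genomic and transcript coordinates
#'
#' Positions are 0-based. Transcript coordinates run 5' to 3' along the
#' mRNA; for minus-strand transcripts position 0 is the genomically
#' rightmost exonic base. The mapping is a bijection between transcript
#' positions `[0, length)` and exonic genomic bases.
#'
#' @param exons Tibble of 0-based half-open genomic `start`/`end` intervals
#'   in transcript (5' to 3') order, as stored in the `exons` list-column of
#'   a model table.
#' @param strand `"+"` or `"-"`.
#' @param pos Integer vector of positions to convert.
#' @return Integer vector of converted positions.
#' @export
tx_to_genomic <- function(exons, strand, pos) {
  widths <- exons$end - exons$start
  offsets <- cumsum(c(0L, widths[-length(widths)]))
  total <- sum(widths)
  vapply(pos, function(p) {
    if (p < 0 || p >= total) abort(sprintf("transcript position %d out of range", p))
    i <- max(which(offsets <= p))
    o <- p - offsets[i]
    if (strand == "+") exons$start[i] + o else exons$end[i] - 1L - o
  }, numeric(1)) |> as.integer()
}

#' @rdname tx_to_genomic
#' @export
genomic_to_tx <- function(exons, strand, pos) {
  widths <- exons$end - exons$start
  offsets <- cumsum(c(0L, widths[-length(widths)]))
  vapply(pos, function(g) {
    i <- which(g >= exons$start & g < exons$end)
    if (length(i) != 1) abort(sprintf("genomic position %d is not exonic", g))
    o <- if (strand == "+") g - exons$start[i] else exons$end[i] - 1L - g
    offsets[i] + o
  }, numeric(1)) |> as.integer()
}

# Map a transcript-coordinate half-open interval back to genomic intervals
# (one per overlapped exon), 0-based half-open, sorted by genomic start.
tx_interval_to_genomic <- function(exons, strand, tx_start, tx_end) {
  widths <- exons$end - exons$start
  offsets <- cumsum(c(0L, widths[-length(widths)]))
  pieces <- list()
  for (i in seq_len(nrow(exons))) {
    lo <- max(tx_start, offsets[i])
    hi <- min(tx_end, offsets[i] + widths[i])
    if (lo >= hi) next
    if (strand == "+") {
      gs <- exons$start[i] + (lo - offsets[i])
      pieces[[length(pieces) + 1]] <- c(gs, gs + (hi - lo))
    } else {
      ge <- exons$end[i] - (lo - offsets[i])
      pieces[[length(pieces) + 1]] <- c(ge - (hi - lo), ge)
    }
  }
  out <- do.call(rbind, pieces)
  out <- tibble(start = as.integer(out[, 1]), end = as.integer(out[, 2]))
  arrange(out, .data$start)
}

#' Write transcript models to a GTF file
#'
#' Emits `exon` and `CDS` features with `gene_id` and `transcript_id`
#' attributes, converting internal 0-based half-open coordinates to the
#' GTF's 1-based inclusive convention. Round-trips through [read_gtf()].
#'
#' @param models Model table as returned by [read_gtf()] or
#'   [simulate_transcriptome()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(models, path) {
  check_columns(models, c("transcript_id", "gene_id", "seqname", "strand",
                          "length", "cds_start_tx", "cds_end_tx", "exons"),
                "models")
  feats <- purrr::pmap(models, function(transcript_id, gene_id, seqname,
                                        strand, length, cds_start_tx,
                                        cds_end_tx, exons, ...) {
    ex <- arrange(exons, .data$start)
    out <- tibble(seqname = seqname, start = ex$start, end = ex$end,
                  type = "exon", strand = strand, phase = NA_integer_,
                  gene_id = gene_id, transcript_id = transcript_id)
    if (!is.na(cds_start_tx)) {
      cds <- tx_interval_to_genomic(exons, strand, cds_start_tx, cds_end_tx)
      # frame of each CDS piece, walking pieces 5'->3' along the mRNA
      tx_ord <- if (strand == "+") seq_len(nrow(cds)) else rev(seq_len(nrow(cds)))
      widths <- (cds$end - cds$start)[tx_ord]
      phase_tx <- (3L - cumsum(c(0L, widths[-length(widths)])) %% 3L) %% 3L
      phase <- integer(nrow(cds))
      phase[tx_ord] <- phase_tx
      out <- bind_rows(out, tibble(
        seqname = seqname, start = cds$start, end = cds$end,
        type = "CDS", strand = strand, phase = phase,
        gene_id = gene_id, transcript_id = transcript_id))
    }
    out
  })
  df <- bind_rows(feats)
  gr <- GenomicRanges::GRanges(
    seqnames = df$seqname,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end),
    strand = df$strand
  )
  S4Vectors::mcols(gr)$type <- df$type
  S4Vectors::mcols(gr)$phase <- df$phase
  S4Vectors::mcols(gr)$gene_id <- df$gene_id
  S4Vectors::mcols(gr)$transcript_id <- df$transcript_id
  rtracklayer::export(gr, path, format = "gtf")
  invisible(path)
}

#' Read and write transcript sequences (FASTA)
#'
#' `read_fasta()` uppercases sequences on read and rejects duplicate
#' record IDs; `write_fasta()` writes a named [Biostrings::DNAStringSet]
#' (or named character vector). Writing then reading returns identical
#' records.
#'
#' @param path FASTA path (optionally gzip-compressed).
#' @return `read_fasta()`: a [Biostrings::DNAStringSet] named by
#'   transcript ID.
#' @export
read_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(names(seqs))) {
    dup <- names(seqs)[duplicated(names(seqs))][1]
    abort(sprintf("duplicate FASTA record ID: %s", dup))
  }
  Biostrings::DNAStringSet(toupper(as.character(seqs)))
}

#' @rdname read_fasta
#' @param records Named character vector or [Biostrings::DNAStringSet].
#' @export
write_fasta <- function(records, path) {
  if (!methods::is(records, "DNAStringSet")) {
    records <- Biostrings::DNAStringSet(records)
  }
  if (is.null(names(records)) || anyDuplicated(names(records))) {
    abort("records must have unique names")
  }
  Biostrings::writeXStringSet(records, path, width = 70L)
  invisible(path)
}

#' Check that sequences match their transcript models
#'
#' @param models Model table.
#' @param sequences Named [Biostrings::DNAStringSet].
#' @return `TRUE` invisibly; errors on a missing sequence or a length
#'   mismatch.
#' @export
validate_sequences <- function(models, sequences) {
  missing <- setdiff(models$transcript_id, names(sequences))
  if (length(missing) > 0) {
    abort(sprintf("no sequence for transcript(s): %s",
                  paste(head(missing, 5), collapse = ", ")))
  }
  lens <- Biostrings::width(sequences)[match(models$transcript_id, names(sequences))]
  bad <- which(lens != models$length)
  if (length(bad) > 0) {
    abort(sprintf(
      "sequence length mismatch for %s: model %d bp, sequence %d bp",
      models$transcript_id[bad[1]], models$length[bad[1]], lens[bad[1]]))
  }
  invisible(TRUE)
}

#' Read isoform quantification and RIP tables
#'
#' `read_quant()` expects a TSV with columns `transcript_id`, `gene_id`,
#' `condition`, `replicate`, `FPKM`; `read_rip()` expects `transcript_id`,
#' `assay` (`IP` or `IgG`), `replicate`, `FPKM`. Both reject missing,
#' negative or non-finite FPKM values and duplicated
#' (transcript, condition/assay, replicate) keys, reporting the offending
#' row.
#'
#' @param path TSV path (optionally gzip-compressed).
#' @return A tibble with the same columns, FPKM renamed to `fpkm`.
#' @export
read_quant <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  df <- normalize_fpkm_col(df)
  check_columns(df, c("transcript_id", "gene_id", "condition", "replicate", "fpkm"),
                "quant table")
  validate_measurements(df, c("transcript_id", "condition", "replicate"))
  as_tibble(df)
}

#' @rdname read_quant
#' @export
read_rip <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  df <- normalize_fpkm_col(df)
  check_columns(df, c("transcript_id", "assay", "replicate", "fpkm"), "RIP table")
  bad_assay <- setdiff(unique(df$assay), c("IP", "IgG"))
  if (length(bad_assay) > 0) {
    abort(sprintf("unknown assay label(s): %s", paste(bad_assay, collapse = ", ")))
  }
  validate_measurements(df, c("transcript_id", "assay", "replicate"))
  as_tibble(df)
}

normalize_fpkm_col <- function(df) {
  if ("FPKM" %in% names(df) && !"fpkm" %in% names(df)) {
    names(df)[names(df) == "FPKM"] <- "fpkm"
  }
  df
}

validate_measurements <- function(df, key) {
  if (anyNA(df$fpkm)) {
    abort(sprintf("missing FPKM at row %d", which(is.na(df$fpkm))[1]))
  }
  if (any(!is.finite(df$fpkm))) {
    abort(sprintf("non-finite FPKM at row %d", which(!is.finite(df$fpkm))[1]))
  }
  if (any(df$fpkm < 0)) {
    abort(sprintf("negative FPKM at row %d", which(df$fpkm < 0)[1]))
  }
  dup <- duplicated(df[key])
  if (any(dup)) {
    abort(sprintf("duplicated %s key at row %d",
                  paste(key, collapse = "/"), which(dup)[1]))
  }
  invisible(df)
}

#' @rdname read_quant
#' @param quant,rip Tables to write (columns as produced by the
#'   simulators); the FPKM column is emitted under the header `FPKM`.
#' @export
write_quant <- function(quant, path) {
  out <- rename(quant, FPKM = "fpkm")
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' @rdname read_quant
#' @export
write_rip <- function(rip, path) {
  out <- rename(rip, FPKM = "fpkm")
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}
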