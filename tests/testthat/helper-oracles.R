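# Independent oracles used to check the pipeline. Deliberately written
# with different primitives than the package (character vectors, prefix/
# suffix checks) so they do not share a code path with what they verify.

# Apply one insertion/deletion edit to a sequence (string-edit oracle).
oracle_apply_edit <- function(seq, type, anchor, size, inserted = NULL) {
  v <- strsplit(seq, "")[[1]]
  if (type == "insertion") {
    paste(c(head(v, anchor), strsplit(inserted, "")[[1]],
            tail(v, length(v) - anchor)), collapse = "")
  } else {
    paste(c(head(v, anchor), tail(v, length(v) - anchor - size)), collapse = "")
  }
}

# Apply a whole event table (rows sorted by anchor) right to left.
oracle_apply_events <- function(seq, events) {
  ord <- order(events$anchor, decreasing = TRUE)
  for (i in ord) {
    seq <- oracle_apply_edit(seq, events$type[i], events$anchor[i],
                             events$size[i], events$inserted_seq[i])
  }
  seq
}

# Leftmost equivalent anchor of an edit, characterized directly on the
# variant string: anchor a is valid iff the variant agrees with the
# standard on the first a bases and, beyond the edited block, on the rest.
oracle_leftmost_anchor <- function(std, variant, type, anchor, size) {
  valid <- function(a) {
    if (type == "deletion") {
      substr(variant, 1, a) == substr(std, 1, a) &&
        substr(variant, a + 1, nchar(variant)) ==
          substr(std, a + size + 1, nchar(std))
    } else {
      substr(variant, 1, a) == substr(std, 1, a) &&
        substr(variant, a + size + 1, nchar(variant)) ==
          substr(std, a + 1, nchar(std))
    }
  }
  a <- anchor
  while (a > 0 && valid(a - 1)) a <- a - 1
  a
}

# Exon-chain fixture: a standard transcript made of labeled blocks and a
# variant differing by one whole block, with the expected event computed
# by block arithmetic (then left-normalized with the oracle above).
rand_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                              collapse = "")

make_exon_chain_case <- function(n_blocks = NULL, block_len_range = c(20, 120)) {
  n <- n_blocks %||% sample(3:6, 1)
  lens <- sample(block_len_range[1]:block_len_range[2], n, replace = TRUE)
  blocks <- vapply(lens, rand_seq, character(1))
  std <- paste(blocks, collapse = "")
  type <- sample(c("insertion", "deletion"), 1)
  if (type == "deletion") {
    k <- sample(2:(n - 1), 1)  # interior block: matched flanks both sides
    anchor <- sum(lens[seq_len(k - 1)])
    size <- lens[k]
    variant <- paste(blocks[-k], collapse = "")
    inserted <- NA_character_
  } else {
    k <- sample(seq_len(n - 1), 1)  # between blocks k and k+1
    anchor <- sum(lens[seq_len(k)])
    size <- sample(block_len_range[1]:block_len_range[2], 1)
    inserted <- rand_seq(size)
    variant <- paste(c(blocks[seq_len(k)], inserted, blocks[(k + 1):n]),
                     collapse = "")
  }
  norm_anchor <- oracle_leftmost_anchor(std, variant, type, anchor, size)
  list(std = std, variant = variant, type = type, size = size,
       anchor = norm_anchor,
       signed_size = if (type == "insertion") size else -size)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
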