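#' Anchor alignment columns to a reference residue numbering
#'
#' Columns where the reference sequence carries a residue are numbered
#' consecutively from 1 (reference numbering, e.g. the A. vinelandii
#' numbering used by the crystal structures). Columns where the reference is
#' gapped are insertion columns: they carry no number, only the reference
#' residue number immediately preceding them (0 before the first reference
#' residue), until the register is re-established.
#'
#' @param aln an [aa_alignment].
#' @param reference_id seq_id of the reference sequence.
#' @return object of class `reference_map` with elements `reference_id`,
#'   `column_to_ref` (integer per column, `NA` at insertion columns),
#'   `insertion_anchor` (preceding reference number, `NA` at numbered
#'   columns), `ref_to_column` (inverse map) and `n_ref` (reference length).
#' @export
build_reference_map <- function(aln, reference_id) {
  if (!reference_id %in% seq_ids(aln))
    stop("reference_id not in alignment: ", reference_id)
  ref <- aln$mat[reference_id, ]
  isres <- ref != GAP
  column_to_ref <- rep(NA_integer_, length(ref))
  column_to_ref[isres] <- seq_len(sum(isres))
  anchor <- rep(NA_integer_, length(ref))
  # anchor of an insertion column = number of reference residues seen so far
  anchor[!isres] <- cumsum(isres)[!isres]
  structure(list(reference_id = reference_id,
                 column_to_ref = column_to_ref,
                 insertion_anchor = anchor,
                 ref_to_column = which(isres),
                 n_ref = sum(isres),
                 n_columns = length(ref)),
            class = "reference_map")
}

#' Alignment column of a reference residue number
#' @param refmap a `reference_map`.
#' @param ref reference residue number(s), 1-based.
#' @return alignment column index (integer vector).
#' @export
ref_to_col <- function(refmap, ref) {
  if (any(ref < 1L | ref > refmap$n_ref))
    stop("reference number out of range 1..", refmap$n_ref)
  refmap$ref_to_column[ref]
}

#' Reference residue number of an alignment column
#' @param refmap a `reference_map`.
#' @param col alignment column index/indices.
#' @return reference number, `NA` for insertion columns.
#' @export
col_to_ref <- function(refmap, col) {
  if (any(col < 1L | col > refmap$n_columns)) stop("column out of range")
  refmap$column_to_ref[col]
}

#' @export
print.reference_map <- function(x, ...) {
  cat("reference_map on", x$reference_id, ":", x$n_ref, "residues over",
      x$n_columns, "columns (", sum(is.na(x$column_to_ref)),
      "insertion columns )\n")
  invisible(x)
}

#' Delimit the co-aligned (gap-free) core of an alignment
#'
#' A column is co-aligned when no sequence has a gap in it; terminal
#' extensions, insertions and deletions are thereby excluded alike. Maximal
#' runs of co-aligned columns form the blocks that all downstream column
#' statistics are computed over.
#'
#' @param aln an [aa_alignment].
#' @return object of class `coaligned_blocks` with `columns` (integer vector
#'   of gap-free columns), `blocks` (data.frame `start`,`end`, inclusive
#'   column bounds) and `total_columns`.
#' @export
coaligned_columns <- function(aln) {
  if (nrow(aln$mat) == 0L) stop("empty alignment")
  gapfree <- colSums(aln$mat == GAP) == 0L
  cols <- which(gapfree)
  if (length(cols)) {
    brk <- c(0L, which(diff(cols) != 1L), length(cols))
    blocks <- data.frame(start = cols[brk[-length(brk)] + 1L],
                         end = cols[brk[-1L]])
  } else {
    blocks <- data.frame(start = integer(), end = integer())
  }
  structure(list(columns = cols, blocks = blocks,
                 total_columns = length(cols)),
            class = "coaligned_blocks")
}

#' @export
print.coaligned_blocks <- function(x, ...) {
  cat("coaligned_blocks:", x$total_columns, "columns in",
      nrow(x$blocks), "blocks\n")
  invisible(x)
}

#' Report co-aligned blocks in reference numbering
#' @param blocks a `coaligned_blocks`.
#' @param refmap a `reference_map` for the same alignment.
#' @return data.frame with block bounds as columns and reference numbers.
#' @export
blocks_report <- function(blocks, refmap) {
  data.frame(block_start_col = blocks$blocks$start,
             block_end_col = blocks$blocks$end,
             block_start_ref = col_to_ref(refmap, blocks$blocks$start),
             block_end_ref = col_to_ref(refmap, blocks$blocks$end),
             length = blocks$blocks$end - blocks$blocks$start + 1L)
}
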