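#' Read coding sequences from a nucleotide FASTA keyed by seq_id
#' @param path FASTA file of coding DNA sequences.
#' @return named character vector of uppercase nucleotide strings.
#' @export
read_cds_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(toupper(as.character(x)), names(x))
}

# invert the standard genetic code once at load time
codon_table <- function() Biostrings::GENETIC_CODE

codons_for <- function(aa) {
  gc <- codon_table()
  names(gc)[gc == aa]
}

# split a cds (from frame offset) into codons covering n residues
cds_codons <- function(cds, n, frame = 0L) {
  if (nchar(cds) < frame + 3L * n)
    stop("coding sequence too short: need ", frame + 3L * n, " nt, have ",
         nchar(cds))
  substring(cds, frame + 3L * (seq_len(n) - 1L) + 1L,
            frame + 3L * seq_len(n))
}

# translate codons; TAG read through as U only at the given residue indices
translate_codons <- function(codons, amber_as_u = integer()) {
  gc <- codon_table()
  aa <- unname(gc[codons])
  aa[is.na(aa)] <- "?"
  ru <- intersect(which(codons == "TAG"), amber_as_u)
  aa[ru] <- "U"
  aa
}

# residue index within the ungapped sequence for an alignment column
ungapped_index <- function(row, col) {
  if (row[col] == GAP) return(NA_integer_)
  sum(row[seq_len(col)] != GAP)
}

#' Check a coding sequence against its aligned protein
#'
#' Translating the cds in frame, with amber (TAG) read-through as Sec
#' allowed only where the protein itself carries U, must reproduce the
#' ungapped protein exactly. A frame shift of one nucleotide makes this
#' check fail (negative control for position-exact amber detection).
#'
#' @param cds nucleotide string.
#' @param protein gapped protein row (character vector over alignment
#'   columns) or ungapped string.
#' @param frame frame offset in nucleotides (default 0).
#' @return `TRUE` invisibly, or an error describing the first mismatch.
#' @export
check_cds_consistency <- function(cds, protein, frame = 0L) {
  prot <- if (length(protein) > 1L) paste(protein[protein != GAP],
                                          collapse = "")
          else gsub(GAP, "", protein, fixed = TRUE)
  pres <- strsplit(prot, "")[[1L]]
  codons <- cds_codons(cds, length(pres), frame)
  aa <- translate_codons(codons, amber_as_u = which(pres == "U"))
  bad <- which(aa != pres)
  if (length(bad))
    stop("cds/protein mismatch at residue ", bad[1L], ": codon ",
         codons[bad[1L]], " -> ", aa[bad[1L]], ", protein has ",
         pres[bad[1L]])
  invisible(TRUE)
}

#' Detect amber-codon (TAG) read-through at a reference position
#'
#' Locates the codon encoding the query sequence's residue at the given
#' reference position and reports whether it is the amber stop codon with
#' the reading frame continuing past it to the annotated terminus — the
#' sequence-level selenocysteine criterion. Presence of the selA/selB/selD
#' genes and the bSECIS stem-loop are genome-scale checks not performed
#' here, and the report says so.
#'
#' @param cds nucleotide coding sequence for the protein.
#' @param protein gapped protein row (character vector) of the sequence in
#'   the alignment.
#' @param refmap the alignment's `reference_map`.
#' @param ref_position reference residue number to scan.
#' @param seq_id identifier carried into the report.
#' @param frame frame offset (default 0).
#' @return object of class `sec_scan`: `seq_id`, `ref_position`, `covered`,
#'   `residue`, `codon`, `is_amber_readthrough`, `orf_continues`,
#'   `checks_not_performed`.
#' @export
detect_amber_readthrough <- function(cds, protein, refmap, ref_position,
                                     seq_id = NA_character_, frame = 0L) {
  col <- ref_to_col(refmap, ref_position)
  k <- ungapped_index(protein, col)
  if (is.na(k)) {
    return(structure(list(seq_id = seq_id, ref_position = ref_position,
                          covered = FALSE, residue = NA_character_,
                          codon = NA_character_,
                          is_amber_readthrough = FALSE, orf_continues = NA,
                          checks_not_performed = c("selA/selB/selD",
                                                   "bSECIS")),
                     class = "sec_scan"))
  }
  check_cds_consistency(cds, protein, frame)
  pres <- protein[protein != GAP]
  codons <- cds_codons(cds, length(pres), frame)
  codon <- codons[k]
  # ORF continues: no in-frame stop at any coding position other than the
  # scanned amber itself
  aa <- translate_codons(codons, amber_as_u = which(pres == "U"))
  orf_continues <- !any(aa[-k] == "*") && k < length(pres)
  is_rt <- codon == "TAG" && pres[k] == "U" && orf_continues
  structure(list(seq_id = seq_id, ref_position = ref_position,
                 covered = TRUE, residue = pres[k], codon = codon,
                 is_amber_readthrough = is_rt,
                 orf_continues = orf_continues,
                 checks_not_performed = c("selA/selB/selD", "bSECIS")),
            class = "sec_scan")
}

#' @export
print.sec_scan <- function(x, ...) {
  cat(sprintf("sec_scan %s @ref %d: %s\n",
              x$seq_id, x$ref_position,
              if (!x$covered) "position not covered"
              else sprintf("codon %s (%s)%s", x$codon, x$residue,
                           if (x$is_amber_readthrough)
                             " AMBER READ-THROUGH" else "")))
  invisible(x)
}

#' Scan all sequences of an alignment for amber read-through
#'
#' @param cds_set named character vector of coding sequences (names are
#'   seq_ids).
#' @param aln the [aa_alignment].
#' @param refmap its `reference_map`.
#' @param ref_position reference residue number to scan.
#' @param frame frame offset (default 0).
#' @return data.frame with one row per sequence: `seq_id`, `covered`,
#'   `residue`, `codon`, `is_amber_readthrough`.
#' @export
scan_sec_positions <- function(cds_set, aln, refmap, ref_position,
                               frame = 0L) {
  ids <- intersect(seq_ids(aln), names(cds_set))
  rows <- lapply(ids, function(id) {
    r <- detect_amber_readthrough(cds_set[[id]], aln$mat[id, ], refmap,
                                  ref_position, seq_id = id, frame = frame)
    data.frame(seq_id = id, covered = r$covered,
               residue = r$residue %||% NA_character_,
               codon = r$codon %||% NA_character_,
               is_amber_readthrough = r$is_amber_readthrough,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Codon usage at a reference position across coding sequences
#'
#' Tallies the codon used at the mapped position in every covering coding
#' sequence and counts the distinct synonymous codons observed for the
#' position's consensus amino acid.
#'
#' @param cds_set named character vector of coding sequences.
#' @param aln the [aa_alignment].
#' @param refmap its `reference_map`.
#' @param ref_position reference residue number.
#' @param frame frame offset (default 0).
#' @return object of class `codon_usage`: `ref_position`, `codon_counts`
#'   (named integer), `consensus_aa`, `distinct_synonymous`, `n_covering`.
#' @export
codon_usage_at_position <- function(cds_set, aln, refmap, ref_position,
                                    frame = 0L) {
  col <- ref_to_col(refmap, ref_position)
  ids <- intersect(seq_ids(aln), names(cds_set))
  codons <- character()
  aas <- character()
  for (id in ids) {
    row <- aln$mat[id, ]
    k <- ungapped_index(row, col)
    if (is.na(k)) next
    pres <- row[row != GAP]
    codons <- c(codons, cds_codons(cds_set[[id]], k, frame)[k])
    aas <- c(aas, row[col])
  }
  counts <- sort(table(codons), decreasing = TRUE)
  counts <- setNames(as.integer(counts), names(counts))
  consensus <- if (length(aas)) names(sort(table(aas),
                                           decreasing = TRUE))[1L]
               else NA_character_
  syn <- if (is.na(consensus)) 0L else {
    syn_codons <- if (consensus == "U") "TAG" else codons_for(consensus)
    length(intersect(names(counts), syn_codons))
  }
  structure(list(ref_position = ref_position, codon_counts = counts,
                 consensus_aa = consensus, distinct_synonymous = syn,
                 n_covering = length(codons)),
            class = "codon_usage")
}

#' @export
print.codon_usage <- function(x, ...) {
  cat(sprintf("codon_usage @ref %d (%s): %s; %d synonymous codons\n",
              x$ref_position, x$consensus_aa,
              paste(names(x$codon_counts), x$codon_counts, sep = ":",
                    collapse = " "),
              x$distinct_synonymous))
  invisible(x)
}
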