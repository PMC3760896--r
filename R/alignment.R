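#' @importFrom stats setNames
#' @importFrom utils read.delim write.table head
NULL

# Alphabet: 20 amino acids + selenocysteine (U) + the gap symbol.
# "." is accepted on input and normalized to "-"; "X" and other ambiguity
# codes are rejected rather than silently kept.
AA_SYMBOLS <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y", "U")
GAP <- "-"
GROUP_LEVELS <- c("I", "II", "III", "IV", "Anf", "Vnf")

#' Construct a protein multiple alignment
#'
#' An `aa_alignment` holds equal-length gapped amino-acid sequences as a
#' character matrix (one row per sequence, one column per alignment column)
#' together with a per-sequence metadata table (species, gene family,
#' subunit, group label).
#'
#' @param seqs named character vector of gapped sequences, or a character
#'   matrix with one row per sequence and row names as sequence ids.
#' @param meta optional `data.frame` with columns `seq_id`, `species`,
#'   `gene_family`, `subunit`, `group`. Missing metadata is filled with
#'   `NA` / `"unassigned"`.
#' @return an object of class `aa_alignment` with elements `mat` (character
#'   matrix) and `meta` (data.frame).
#' @export
aa_alignment <- function(seqs, meta = NULL) {
  if (is.matrix(seqs)) {
    mat <- seqs
  } else {
    if (is.null(names(seqs)) || anyNA(names(seqs)) || any(names(seqs) == ""))
      stop("sequences must be named by seq_id")
    lens <- nchar(seqs)
    if (length(unique(lens)) != 1L)
      stop("ragged alignment: sequences have unequal lengths (",
           paste(range(lens), collapse = "-"), ")")
    mat <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
    rownames(mat) <- names(seqs)
  }
  if (is.null(rownames(mat))) stop("alignment rows must be named by seq_id")
  if (anyDuplicated(rownames(mat)))
    stop("duplicate seq_ids: ",
         paste(unique(rownames(mat)[duplicated(rownames(mat))]), collapse = ", "))
  mat[] <- toupper(mat)
  mat[mat == "."] <- GAP
  bad <- setdiff(unique(as.vector(mat)), c(AA_SYMBOLS, GAP))
  if (length(bad))
    stop("illegal alignment symbol(s): ", paste(bad, collapse = ", "),
         " (allowed: 20 amino acids, U, '-')")
  meta <- normalize_meta(meta, rownames(mat))
  structure(list(mat = mat, meta = meta), class = "aa_alignment")
}

normalize_meta <- function(meta, ids) {
  cols <- c("seq_id", "species", "gene_family", "subunit", "group")
  if (is.null(meta)) {
    meta <- data.frame(seq_id = ids, species = NA_character_,
                       gene_family = NA_character_, subunit = NA_character_,
                       group = "unassigned", stringsAsFactors = FALSE)
  } else {
    meta <- as.data.frame(meta, stringsAsFactors = FALSE)
    if (!"seq_id" %in% names(meta)) stop("metadata must have a seq_id column")
    for (cc in setdiff(cols, names(meta))) meta[[cc]] <- NA_character_
    meta <- meta[, cols]
    missing <- setdiff(ids, meta$seq_id)
    if (length(missing))
      stop("metadata missing for: ", paste(head(missing, 5), collapse = ", "))
    meta <- meta[match(ids, meta$seq_id), ]
    meta$group[is.na(meta$group)] <- "unassigned"
  }
  badg <- setdiff(unique(meta$group), c(GROUP_LEVELS, "unassigned"))
  if (length(badg))
    stop("unknown group label(s): ", paste(badg, collapse = ", "))
  rownames(meta) <- NULL
  meta
}

#' Number of alignment columns
#' @param aln an `aa_alignment`.
#' @return integer column count.
#' @export
n_columns <- function(aln) ncol(aln$mat)

#' Sequence identifiers of an alignment
#' @param aln an `aa_alignment`.
#' @return character vector of seq_ids in row order.
#' @export
seq_ids <- function(aln) rownames(aln$mat)

#' @export
print.aa_alignment <- function(x, ...) {
  cat("aa_alignment:", nrow(x$mat), "sequences x", ncol(x$mat), "columns\n")
  grp <- table(x$meta$group)
  cat("groups:", paste(names(grp), grp, sep = "=", collapse = " "), "\n")
  invisible(x)
}

#' Read a protein multiple alignment
#'
#' Reads an aligned FASTA or Clustal file via Biostrings and attaches
#' sequence metadata from a sidecar tab-separated table
#' (`seq_id  species  gene_family  subunit  group`).
#'
#' @param path alignment file.
#' @param format `"fasta"` (aligned FASTA) or `"clustal"`.
#' @param meta optional path to a metadata TSV, or a data.frame.
#' @return an [aa_alignment].
#' @export
read_alignment <- function(path, format = c("fasta", "clustal"), meta = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  sset <- tryCatch({
    if (format == "fasta") Biostrings::readAAStringSet(path)
    else Biostrings::unmasked(
      Biostrings::readAAMultipleAlignment(path, format = format))
  }, error = function(e) stop("cannot parse ", path, " as ", format, ": ",
                              conditionMessage(e)))
  seqs <- setNames(as.character(sset), names(sset))
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L)
    stop("ragged rows in ", path, ": lengths ",
         paste(range(lens), collapse = "-"))
  mat <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
  rownames(mat) <- names(seqs)
  if (is.character(meta)) meta <- read_metadata(meta)
  aa_alignment(mat, meta = meta)
}

#' Read a sequence metadata table
#' @param path TSV with columns seq_id, species, gene_family, subunit, group.
#' @return data.frame.
#' @export
read_metadata <- function(path) {
  read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
}

#' Write an alignment as aligned FASTA
#' @param aln an `aa_alignment`.
#' @param path output file.
#' @param meta_path optional path for the sidecar metadata TSV.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(aln, path, meta_path = NULL) {
  seqs <- apply(aln$mat, 1L, paste, collapse = "")
  Biostrings::writeXStringSet(Biostrings::AAStringSet(seqs), filepath = path)
  if (!is.null(meta_path))
    write.table(aln$meta, meta_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  invisible(path)
}

#' Group partition of an alignment
#'
#' Extracts the seq_id to group mapping from alignment metadata (or takes an
#' explicit named vector) and validates that every sequence is labeled.
#'
#' @param aln an `aa_alignment`.
#' @param labels optional named character vector seq_id -> group overriding
#'   the metadata.
#' @param require_assigned error if any sequence is `"unassigned"`.
#' @return named character vector (class `group_partition`) over the
#'   alignment's sequences, with a `sizes` attribute.
#' @export
group_partition <- function(aln, labels = NULL, require_assigned = TRUE) {
  if (is.null(labels)) labels <- setNames(aln$meta$group, aln$meta$seq_id)
  labels <- labels[seq_ids(aln)]
  if (anyNA(labels)) stop("partition does not cover every sequence")
  if (require_assigned && any(labels == "unassigned"))
    stop("unassigned sequences present: ",
         paste(head(names(labels)[labels == "unassigned"], 5), collapse = ", "))
  bad <- setdiff(unique(labels), c(GROUP_LEVELS, "unassigned"))
  if (length(bad)) stop("unknown group label(s): ", paste(bad, collapse = ", "))
  structure(labels, sizes = table(factor(labels, levels = GROUP_LEVELS)),
            class = "group_partition")
}
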