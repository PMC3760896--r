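#' Default amino-acid functional similarity scheme
#'
#' Partition-style scheme (classes may overlap) used to subtype
#' single-variant columns into "similar" and "dissimilar" pairs. The classes
#' follow common physicochemical groupings: beta-branched aliphatic \{I,V\},
#' aliphatic \{L,I,V,A,M\}, aromatic \{F,Y,W\}, basic \{K,R,H\}, acidic
#' \{D,E\}, amide \{N,Q\}, small \{G,A,S\}, thiol/selenol \{C,U\}, and the
#' singletons \{P\} and \{T\}. Two residues are "functionally similar" when
#' at least one class contains both; every residue belongs to at least one
#' class. The scheme in force is a run input and is recorded in all outputs.
#'
#' @return named list of character vectors (class `similarity_scheme`).
#' @export
default_similarity_scheme <- function() {
  structure(list(
    beta_branched = c("I", "V"),
    aliphatic     = c("L", "I", "V", "A", "M"),
    aromatic      = c("F", "Y", "W"),
    basic         = c("K", "R", "H"),
    acidic        = c("D", "E"),
    amide         = c("N", "Q"),
    small         = c("G", "A", "S"),
    thiol         = c("C", "U"),
    proline       = "P",
    threonine     = "T"
  ), class = "similarity_scheme")
}

#' Read a similarity scheme from a two-column TSV (class, residues)
#' @param path TSV file: first column class name, second column residues as
#'   an unseparated string (e.g. `LIVAM`).
#' @return a `similarity_scheme`.
#' @export
read_similarity_scheme <- function(path) {
  df <- read.delim(path, header = FALSE, comment.char = "#",
                   stringsAsFactors = FALSE)
  sch <- lapply(df[[2]], function(s) strsplit(toupper(s), "")[[1]])
  names(sch) <- df[[1]]
  validate_scheme(structure(sch, class = "similarity_scheme"))
}

validate_scheme <- function(scheme) {
  cov <- unique(unlist(scheme))
  missing <- setdiff(AA_SYMBOLS, cov)
  if (length(missing))
    stop("similarity scheme does not cover: ", paste(missing, collapse = ", "))
  scheme
}

#' Are two residues functionally similar under a scheme?
#' @param a,b single residues.
#' @param scheme a `similarity_scheme`.
#' @return logical.
#' @export
residues_similar <- function(a, b, scheme = default_similarity_scheme()) {
  any(vapply(scheme, function(cl) a %in% cl && b %in% cl, logical(1)))
}

#' Residue equivalence map for selenocysteine
#'
#' Sec is read through an amber codon and substitutes for Cys at designated
#' sites; merging U into C before counting makes a Cys/Sec column invariant.
#'
#' @param positions optional integer vector of reference positions the
#'   equivalence is restricted to; `NULL` applies it at every column.
#' @return named character vector (from -> to) with a `positions` attribute.
#' @export
sec_equivalence <- function(positions = NULL) {
  structure(c(U = "C"), positions = positions)
}

apply_equivalences <- function(residues, equivalences, ref_number = NA) {
  if (is.null(equivalences)) return(residues)
  pos <- attr(equivalences, "positions")
  if (!is.null(pos) && (is.na(ref_number) || !(ref_number %in% pos)))
    return(residues)
  hit <- residues %in% names(equivalences)
  residues[hit] <- unname(equivalences[residues[hit]])
  residues
}

#' Classify one co-aligned alignment column
#'
#' Conservation classes, applied in order to the distinct-residue count
#' after merging declared equivalences (e.g. Sec with Cys):
#' 1 distinct -> `invariant`; 2 distinct -> single variant, subtyped
#' `outlier` when the minority residue occurs exactly once, otherwise
#' `similar`/`dissimilar` by the similarity scheme; 3 distinct ->
#' `double_variant`; 4 or more distinct with one residue in more than 90%
#' of sequences -> `dominant`; otherwise `variable`.
#'
#' @param residues character vector, one residue per sequence (no gaps).
#' @param scheme a `similarity_scheme`.
#' @param equivalences optional equivalence map, see [sec_equivalence()].
#' @param ref_number optional reference number carried into the profile (and
#'   used to scope position-restricted equivalences).
#' @param column optional alignment column index carried into the profile.
#' @return object of class `column_profile`: `counts` (named, decreasing),
#'   `n_distinct`, `class`, `dominant_residue`, `dominant_fraction`.
#' @export
classify_column <- function(residues, scheme = default_similarity_scheme(),
                            equivalences = NULL, ref_number = NA_integer_,
                            column = NA_integer_) {
  if (any(residues == GAP))
    stop("column contains gaps; classification is defined on co-aligned columns")
  residues <- apply_equivalences(residues, equivalences, ref_number)
  counts <- sort(table(residues), decreasing = TRUE)
  counts <- setNames(as.integer(counts), names(counts))
  k <- length(counts)
  n <- sum(counts)
  dom <- names(counts)[1L]
  domfrac <- counts[[1L]] / n
  cls <- if (k == 1L) {
    "invariant"
  } else if (k == 2L) {
    if (counts[[2L]] == 1L) "single_variant_outlier"
    else if (residues_similar(names(counts)[1L], names(counts)[2L], scheme))
      "single_variant_similar"
    else "single_variant_dissimilar"
  } else if (k == 3L) {
    "double_variant"
  } else if (domfrac > 0.90) {
    "dominant"
  } else {
    "variable"
  }
  structure(list(column = column, ref_number = ref_number, counts = counts,
                 n_distinct = k, class = cls, dominant_residue = dom,
                 dominant_fraction = domfrac),
            class = "column_profile")
}

#' @export
print.column_profile <- function(x, ...) {
  cat(sprintf("column %s (ref %s): %s; %s\n",
              x$column, x$ref_number, x$class,
              paste(names(x$counts), x$counts, sep = ":", collapse = " ")))
  invisible(x)
}

CONSERVATION_CLASSES <- c("invariant", "single_variant_outlier",
                          "single_variant_similar",
                          "single_variant_dissimilar",
                          "double_variant", "dominant", "variable")

#' Per-column conservation profiles over the co-aligned core
#'
#' @param aln an [aa_alignment].
#' @param blocks [coaligned_columns()] result for `aln`.
#' @param scheme a `similarity_scheme`.
#' @param equivalences optional equivalence map.
#' @param refmap optional `reference_map`; when given, profiles carry
#'   reference numbers.
#' @return object of class `conservation_profiles`: a data.frame with one
#'   row per co-aligned column (`column`, `ref_number`, `class`,
#'   `n_distinct`, `dominant_residue`, `dominant_fraction`, `counts` as a
#'   `res:count` string) and the full profile list as attribute `profiles`.
#' @export
conservation_profiles <- function(aln, blocks,
                                  scheme = default_similarity_scheme(),
                                  equivalences = NULL, refmap = NULL) {
  cols <- blocks$columns
  refnum <- if (is.null(refmap)) rep(NA_integer_, length(cols))
            else col_to_ref(refmap, cols)
  profs <- lapply(seq_along(cols), function(i)
    classify_column(aln$mat[, cols[i]], scheme, equivalences,
                    ref_number = refnum[i], column = cols[i]))
  df <- data.frame(
    column = cols,
    ref_number = refnum,
    class = vapply(profs, `[[`, character(1), "class"),
    n_distinct = vapply(profs, `[[`, integer(1), "n_distinct"),
    dominant_residue = vapply(profs, `[[`, character(1), "dominant_residue"),
    dominant_fraction = vapply(profs, `[[`, numeric(1), "dominant_fraction"),
    counts = vapply(profs, function(p)
      paste(names(p$counts), p$counts, sep = ":", collapse = ","),
      character(1)),
    stringsAsFactors = FALSE)
  structure(df, profiles = profs, scheme = scheme,
            class = c("conservation_profiles", "data.frame"))
}

#' Table-1-style conservation summary
#'
#' Counts and percentages of conservation classes over exactly the
#' co-aligned columns; percentages are based on the total number of aligned
#' (co-aligned) residues.
#'
#' @inheritParams conservation_profiles
#' @param subunit optional label ("D" or "K") carried into the summary.
#' @return object of class `conservation_summary`.
#' @export
summarize_conservation <- function(aln, blocks,
                                   scheme = default_similarity_scheme(),
                                   equivalences = NULL, refmap = NULL,
                                   subunit = NA_character_) {
  prof <- conservation_profiles(aln, blocks, scheme, equivalences, refmap)
  cls <- factor(prof$class, levels = CONSERVATION_CLASSES)
  n_class <- table(cls)
  ncoal <- blocks$total_columns
  n_sv <- sum(n_class[c("single_variant_outlier", "single_variant_similar",
                        "single_variant_dissimilar")])
  by_class <- split(ifelse(is.na(prof$ref_number), prof$column,
                           prof$ref_number), cls)
  structure(list(
    subunit = subunit,
    n_sequences = nrow(aln$mat),
    n_coaligned = ncoal,
    n_invariant = as.integer(n_class[["invariant"]]),
    pct_invariant = 100 * n_class[["invariant"]] / ncoal,
    n_single_variant = as.integer(n_sv),
    pct_single_variant = 100 * n_sv / ncoal,
    class_counts = setNames(as.integer(n_class), names(n_class)),
    class_columns = by_class,
    n_hypervariable = sum(prof$n_distinct >= 7),
    profiles = prof
  ), class = "conservation_summary")
}

#' @export
print.conservation_summary <- function(x, ...) {
  cat("Conservation summary",
      if (!is.na(x$subunit)) paste0("(subunit ", x$subunit, ")"), "\n")
  cat(sprintf("  Sequences            %d\n", x$n_sequences))
  cat(sprintf("  Aligned residues     %d\n", x$n_coaligned))
  cat(sprintf("  Invariant residues   %d\n", x$n_invariant))
  cat(sprintf("  %% invariant          %.1f%%\n", x$pct_invariant))
  cat(sprintf("  Total single variant %d\n", x$n_single_variant))
  cat(sprintf("  %% single variant     %.1f%%\n", x$pct_single_variant))
  cat("  By class:",
      paste(names(x$class_counts), x$class_counts, sep = "=",
            collapse = " "), "\n")
  invisible(x)
}

#' Amino-acid composition within conservation classes
#'
#' For each conservation class, counts of the class-defining residue per
#' amino acid: the invariant residue for invariant columns, the dominant
#' (majority) residue for the other classes.
#'
#' @param profiles a `conservation_profiles` object.
#' @return matrix (class x amino acid) of counts, with a `ratios` helper
#'   accessible by dividing rows.
#' @export
aa_class_composition <- function(profiles) {
  if (nrow(profiles) == 0L) stop("no profiles")
  tab <- table(factor(profiles$class, levels = CONSERVATION_CLASSES),
               factor(profiles$dominant_residue, levels = AA_SYMBOLS))
  m <- matrix(as.integer(tab), nrow = nrow(tab),
              dimnames = dimnames(tab))
  m
}

#' Pairwise covariation between two reference positions
#'
#' Joint residue-pair counts and both conditional distributions for two
#' co-aligned columns, identified by reference number.
#'
#' @param aln an [aa_alignment].
#' @param blocks its `coaligned_blocks`.
#' @param refmap its `reference_map`.
#' @param ref_i,ref_j reference residue numbers of the two columns.
#' @return object of class `covariation_report`: `joint` (contingency
#'   table), `conditional_ij` (rows: residue at i, P of residue at j),
#'   `conditional_ji`, and the two marginal count vectors.
#' @export
covariation <- function(aln, blocks, refmap, ref_i, ref_j) {
  ci <- ref_to_col(refmap, ref_i)
  cj <- ref_to_col(refmap, ref_j)
  if (!(ci %in% blocks$columns) || !(cj %in% blocks$columns))
    stop("both positions must be co-aligned columns")
  ri <- aln$mat[, ci]
  rj <- aln$mat[, cj]
  joint <- table(i = ri, j = rj)
  structure(list(ref_i = ref_i, ref_j = ref_j, joint = joint,
                 marginal_i = rowSums(joint), marginal_j = colSums(joint),
                 conditional_ij = prop.table(joint, 1L),
                 conditional_ji = t(prop.table(joint, 2L))),
            class = "covariation_report")
}

#' @export
print.covariation_report <- function(x, ...) {
  cat("Covariation ref", x$ref_i, "x ref", x$ref_j, "\n")
  print(x$joint)
  invisible(x)
}
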