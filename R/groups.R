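#' Indel fingerprint of a sequence relative to the reference numbering
#'
#' Every maximal run of gap characters over numbered columns is a deletion
#' (anchored at its first deleted reference number); every maximal run of
#' residues over insertion columns is an insertion (anchored at the
#' preceding reference number); insertion runs anchored before reference
#' residue 1 or after the last reference residue are reported as N-/C-
#' terminal extensions. These chain-difference patterns are
#' group-characteristic and place a sequence in its nitrogenase group.
#'
#' @param aln an [aa_alignment].
#' @param seq_id sequence to fingerprint.
#' @param refmap a `reference_map` for this alignment.
#' @return object of class `indel_fingerprint`: data.frame with columns
#'   `anchor`, `kind` (insertion / deletion / n_terminal_extension /
#'   c_terminal_extension), `length`.
#' @export
indel_fingerprint <- function(aln, seq_id, refmap) {
  if (!seq_id %in% seq_ids(aln)) stop("unknown seq_id: ", seq_id)
  row <- aln$mat[seq_id, ]
  out <- list()
  # deletions: gap runs over numbered columns, scanned in reference order
  num_cols <- refmap$ref_to_column
  isgap <- row[num_cols] == GAP
  r <- rle(isgap)
  pos <- cumsum(c(1L, r$lengths))
  for (k in seq_along(r$values)) {
    if (r$values[k])
      out[[length(out) + 1L]] <- data.frame(
        anchor = pos[k], kind = "deletion", length = r$lengths[k])
  }
  # insertions / extensions: residue runs over consecutive insertion columns
  ins_cols <- which(is.na(refmap$column_to_ref))
  if (length(ins_cols)) {
    hasres <- row[ins_cols] != GAP
    # split insertion columns into runs that are contiguous in the alignment
    # and share presence/absence of a residue
    grp <- cumsum(c(TRUE, diff(ins_cols) != 1L |
                          hasres[-1L] != hasres[-length(hasres)]))
    for (g in split(seq_along(ins_cols), grp)) {
      if (!hasres[g[1L]]) next
      anc <- refmap$insertion_anchor[ins_cols[g[1L]]]
      kind <- if (anc == 0L) "n_terminal_extension"
              else if (anc == refmap$n_ref) "c_terminal_extension"
              else "insertion"
      out[[length(out) + 1L]] <- data.frame(
        anchor = anc, kind = kind, length = length(g))
    }
  }
  fp <- if (length(out)) do.call(rbind, out)
        else data.frame(anchor = integer(), kind = character(),
                        length = integer())
  fp <- fp[order(fp$anchor, fp$kind), , drop = FALSE]
  rownames(fp) <- NULL
  structure(fp, seq_id = seq_id,
            class = c("indel_fingerprint", "data.frame"))
}

same_fingerprint <- function(a, b) {
  ka <- paste(a$anchor, a$kind, a$length, sep = "/")
  kb <- paste(b$anchor, b$kind, b$length, sep = "/")
  setequal(ka, kb)
}

group_rows <- function(aln, partition, groups) {
  which(unclass(partition) %in% groups)
}

# per-column within-group consensus: the residue if the group is uniform at
# that column, NA otherwise. Returns a (n_coaligned x n_groups) matrix.
group_consensus_matrix <- function(aln, blocks, partition,
                                   equivalences = NULL, refmap = NULL) {
  groups <- names(attr(partition, "sizes"))
  groups <- groups[attr(partition, "sizes") > 0L]
  cols <- blocks$columns
  sub <- aln$mat[, cols, drop = FALSE]
  if (!is.null(equivalences)) {
    refnum <- if (is.null(refmap)) rep(NA_integer_, length(cols))
              else col_to_ref(refmap, cols)
    for (j in seq_along(cols))
      sub[, j] <- apply_equivalences(sub[, j], equivalences, refnum[j])
  }
  cons <- sapply(groups, function(g) {
    rows <- group_rows(aln, partition, g)
    m <- sub[rows, , drop = FALSE]
    first <- m[1L, ]
    uniform <- colSums(m != rep(first, each = nrow(m))) == 0L
    ifelse(uniform, first, NA_character_)
  })
  if (!is.matrix(cons)) cons <- matrix(cons, ncol = length(groups),
                                       dimnames = list(NULL, groups))
  cons
}

#' Between-group co-invariance matrix
#'
#' Symmetric group-by-group matrix over the co-aligned columns. The diagonal
#' entry (G,G) counts columns invariant within group G (including the
#' universally invariant columns); the off-diagonal entry (G,H) counts
#' columns invariant in both G and H with the same residue ("common
#' invariant residues"). Empty groups yield `NA` rows/columns.
#'
#' @param aln an [aa_alignment].
#' @param blocks its `coaligned_blocks`.
#' @param partition a [group_partition()].
#' @param equivalences optional equivalence map (e.g. [sec_equivalence()]).
#' @param refmap optional `reference_map` (needed only for
#'   position-restricted equivalences).
#' @return matrix of class `coinvariance_matrix` with `group_sizes`
#'   attribute.
#' @export
coinvariance_matrix <- function(aln, blocks, partition, equivalences = NULL,
                                refmap = NULL) {
  sizes <- attr(partition, "sizes")
  all_groups <- names(sizes)
  cons <- group_consensus_matrix(aln, blocks, partition, equivalences, refmap)
  m <- matrix(NA_integer_, length(all_groups), length(all_groups),
              dimnames = list(all_groups, all_groups))
  present <- colnames(cons)
  for (g in present) {
    m[g, g] <- sum(!is.na(cons[, g]))
    for (h in present) if (h != g)
      m[g, h] <- sum(!is.na(cons[, g]) & !is.na(cons[, h]) &
                       cons[, g] == cons[, h], na.rm = TRUE)
  }
  structure(m, group_sizes = sizes, class = c("coinvariance_matrix", "matrix"))
}

#' @export
print.coinvariance_matrix <- function(x, ...) {
  cat("Co-invariant residues between groups (diagonal: within-group)\n")
  print(unclass(x))
  invisible(x)
}

#' Strong motifs of a group subset
#'
#' A strong motif is a (column, residue) pair such that the residue is
#' carried by every sequence of the subset at that co-aligned column and by
#' no sequence outside the subset. With the subset equal to all groups the
#' exclusivity condition is vacuous and the result is exactly the
#' universally invariant columns.
#'
#' @param aln an [aa_alignment].
#' @param blocks its `coaligned_blocks`.
#' @param partition a [group_partition()].
#' @param subset character vector of group labels.
#' @param equivalences optional equivalence map.
#' @param refmap optional `reference_map`; adds reference numbers.
#' @return data.frame of class `strong_motifs`: `column`, `ref_number`,
#'   `subset` (comma-joined), `residue`.
#' @export
strong_motifs <- function(aln, blocks, partition, subset,
                          equivalences = NULL, refmap = NULL) {
  sizes <- attr(partition, "sizes")
  if (length(subset) == 0L) stop("subset must be non-empty")
  bad <- setdiff(subset, names(sizes))
  if (length(bad)) stop("unknown group(s): ", paste(bad, collapse = ", "))
  if (any(sizes[subset] == 0L))
    stop("empty group(s) in subset: ",
         paste(subset[sizes[subset] == 0L], collapse = ", "))
  rows_in <- group_rows(aln, partition, subset)
  rows_out <- setdiff(seq_len(nrow(aln$mat)), rows_in)
  cols <- blocks$columns
  refnum <- if (is.null(refmap)) rep(NA_integer_, length(cols))
            else col_to_ref(refmap, cols)
  hit_col <- integer(); hit_ref <- integer(); hit_res <- character()
  for (j in seq_along(cols)) {
    colres <- apply_equivalences(aln$mat[, cols[j]], equivalences, refnum[j])
    rin <- colres[rows_in]
    r <- rin[1L]
    if (all(rin == r) && !(r %in% colres[rows_out])) {
      hit_col <- c(hit_col, cols[j])
      hit_ref <- c(hit_ref, refnum[j])
      hit_res <- c(hit_res, r)
    }
  }
  structure(data.frame(column = hit_col, ref_number = hit_ref,
                       subset = rep(paste(sort(subset), collapse = ","),
                                    length(hit_col)),
                       residue = hit_res, stringsAsFactors = FALSE),
            class = c("strong_motifs", "data.frame"))
}

#' Assign a query sequence to a group by its strong-motif ensemble
#'
#' Scores each group by the number of its strong-motif sites where the
#' query (aligned into the same column space) carries the motif residue;
#' the assignment is the argmax, with ties reported rather than silently
#' broken. Optional group-characteristic indel fingerprints provide an
#' agreement flag per group, used only to break exact score ties.
#'
#' @param query a named character vector of length 1 (gapped sequence in
#'   the alignment's column space) or a 1-row character matrix.
#' @param motifs named list (one entry per group) of `strong_motifs`
#'   data.frames, e.g. precomputed with subset = each single group.
#' @param refmap the `reference_map` of the alignment frame.
#' @param group_fingerprints optional named list of `indel_fingerprint`
#'   objects characteristic of each group; compared against the query's
#'   fingerprint computed in the same frame.
#' @param aln optional alignment (required to compute the query fingerprint
#'   when `group_fingerprints` is given: the query is fingerprinted against
#'   `refmap` directly).
#' @return object of class `group_assignment`: `seq_id`, `assigned` (group
#'   label or `NA`), `scores`, `n_sites`, `fingerprint_match`, `tie`,
#'   `note`.
#' @export
assign_group <- function(query, motifs, refmap, group_fingerprints = NULL,
                         aln = NULL) {
  if (is.matrix(query)) {
    qid <- rownames(query)[1L]
    qres <- query[1L, ]
  } else {
    qid <- names(query)[1L]
    qres <- strsplit(query[[1L]], "")[[1L]]
  }
  if (length(qres) != refmap$n_columns)
    stop("query length ", length(qres), " does not match alignment frame (",
         refmap$n_columns, " columns)")
  scores <- vapply(motifs, function(mm) {
    if (nrow(mm) == 0L) return(0L)
    sum(qres[mm$column] == mm$residue)
  }, integer(1))
  n_sites <- vapply(motifs, nrow, integer(1))
  covered <- vapply(motifs, function(mm)
    sum(qres[mm$column] != GAP), integer(1))
  fp_match <- NULL
  if (!is.null(group_fingerprints)) {
    qaln <- aa_alignment(rbind(q = qres))
    rownames(qaln$mat) <- qid %||% "query"
    qfp <- indel_fingerprint(qaln, rownames(qaln$mat), refmap)
    fp_match <- vapply(group_fingerprints, same_fingerprint, logical(1),
                       a = qfp)
  }
  if (sum(covered) == 0L) {
    return(structure(list(seq_id = qid, assigned = NA_character_,
                          scores = scores, n_sites = n_sites,
                          fingerprint_match = fp_match, tie = FALSE,
                          note = "unassignable: query gapped at all motif sites"),
                     class = "group_assignment"))
  }
  best <- max(scores)
  cand <- names(scores)[scores == best]
  tie <- length(cand) > 1L
  note <- ""
  if (tie && !is.null(fp_match) && sum(fp_match[cand]) == 1L) {
    cand <- cand[fp_match[cand]]
    tie <- FALSE
    note <- "score tie broken by indel fingerprint"
  }
  if (best == 0L) note <- paste(note, "low score: no motif residue matched")
  structure(list(seq_id = qid,
                 assigned = if (tie) NA_character_ else cand[1L],
                 scores = scores, n_sites = n_sites,
                 fingerprint_match = fp_match, tie = tie,
                 note = trimws(note)),
            class = "group_assignment")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.group_assignment <- function(x, ...) {
  cat("group_assignment:", x$seq_id %||% "(query)", "->",
      if (is.na(x$assigned)) "UNASSIGNED" else x$assigned,
      if (x$tie) "(tie)" else "", "\n")
  cat("  motif matches:",
      paste(names(x$scores), paste0(x$scores, "/", x$n_sites),
            sep = "=", collapse = " "), "\n")
  if (nzchar(x$note)) cat(" ", x$note, "\n")
  invisible(x)
}
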