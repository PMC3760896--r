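# Synthetic nitrogenase-like families with fully known ground truth.
#
# The generator emulates the statistical structure of the real alignment:
# six groups of unequal size, a universal invariant core, the three single
# variant subtypes, double variant / dominant / hypervariable columns,
# group-private strong-motif columns, group-characteristic indel blocks
# (including the 52-residue Group II insertion), Sec carriers at the
# planted Cys position, and matched coding sequences and toy coordinates.

with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

SIMILAR_PAIRS <- list(c("R", "K"), c("I", "V"), c("D", "E"), c("N", "Q"),
                      c("F", "Y"), c("L", "M"), c("G", "A"), c("S", "G"),
                      c("A", "S"), c("L", "I"))

#' Specification of a synthetic sequence family
#'
#' Defaults mirror the study conditions of the real alpha-subunit data set:
#' 95 sequences in six groups of sizes 45/18/8/3/12/9, a 422-column
#' co-aligned core, 41 invariant and 39 single-variant columns, a
#' 52-residue Group II insertion anchored after reference position 391,
#' strong-motif columns whose per-subset counts mirror the published
#' group-by-group motif table (diagonal 9/7/2/32/23/15), an invariant Arg
#' at position 60, an invariant Cys at position 62 carried as Sec by three
#' Group III sequences, and a three-way nif/anf/vnf discriminator column at
#' position 69 (G/H/L).
#'
#' @param group_sizes named integer vector over the six group labels.
#' @param n_coaligned number of co-aligned core columns.
#' @param class_counts named counts of planted non-variable classes
#'   (invariant, the three single-variant subtypes, double_variant,
#'   dominant); the remainder of the core is variable.
#' @param motif_diag named counts of single-group strong-motif columns.
#' @param motif_pairs data.frame `g1`,`g2`,`n` of two-group motif columns.
#' @param indels data.frame `anchor` (core position), `kind`, `length`,
#'   `group`.
#' @param sec_position core position of the invariant Cys that Sec
#'   substitutes at; `sec_carriers` sequences of Group III carry U there.
#' @param sec_carriers number of Group III Sec carriers.
#' @param noise_rate per-cell substitution probability applied to variable
#'   columns only; planted-class columns are never touched.
#' @param subunit label recorded in metadata.
#' @return object of class `family_spec`.
#' @export
family_spec <- function(group_sizes = c(I = 45, II = 18, III = 8, IV = 3,
                                        Anf = 12, Vnf = 9),
                        n_coaligned = 422,
                        class_counts = c(invariant = 41,
                                         single_variant_outlier = 8,
                                         single_variant_similar = 20,
                                         single_variant_dissimilar = 10,
                                         double_variant = 25,
                                         dominant = 6),
                        motif_diag = c(I = 9, II = 7, III = 2, IV = 32,
                                       Anf = 23, Vnf = 15),
                        motif_pairs = data.frame(
                          g1 = c("I", "I", "II", "III", "IV", "Anf"),
                          g2 = c("II", "IV", "Anf", "IV", "Vnf", "Vnf"),
                          n = c(5, 1, 1, 1, 2, 15)),
                        indels = data.frame(
                          anchor = c(391, 400, 220, 410, 422, 0),
                          kind = c("insertion", "deletion", "insertion",
                                   "deletion", "c_terminal_extension",
                                   "n_terminal_extension"),
                          length = c(52, 3, 4, 2, 6, 5),
                          group = c("II", "III", "IV", "Vnf", "Anf", "Vnf")),
                        sec_position = 62, sec_carriers = 3,
                        noise_rate = 0, subunit = "D") {
  stopifnot(all(group_sizes > 0), n_coaligned >= 1, noise_rate >= 0,
            noise_rate <= 1)
  n <- sum(group_sizes)
  # fixed positions: Arg60-like codon-usage column, the Sec column, the
  # three-way discriminator, and the W-vs-Y Group I motif column
  fixed <- list(arg = min(60L, n_coaligned),
                sec = min(sec_position, n_coaligned),
                tri = min(69L, n_coaligned),
                wy = min(410L, n_coaligned))
  n_motif_cols <- sum(motif_diag) - 2L +  # Anf and Vnf share the tri column
    sum(motif_pairs$n)
  n_planted <- sum(class_counts) + n_motif_cols
  if (n_planted > n_coaligned)
    stop("planted column sets exceed n_coaligned (", n_planted, " > ",
         n_coaligned, ")")
  if (class_counts[["dominant"]] > 0 && n <= 30)
    stop("dominant columns (>90% with >=4 residues) need more than 30 sequences")
  if (any(indels$anchor < 0 | indels$anchor > n_coaligned))
    stop("indel anchor outside the core")
  if (sec_carriers > group_sizes[["III"]])
    stop("more Sec carriers than Group III sequences")
  structure(list(group_sizes = group_sizes, n_coaligned = n_coaligned,
                 class_counts = class_counts, motif_diag = motif_diag,
                 motif_pairs = motif_pairs, indels = indels,
                 sec_position = fixed$sec, sec_carriers = sec_carriers,
                 noise_rate = noise_rate, subunit = subunit,
                 fixed = fixed),
            class = "family_spec")
}

# does any non-exempt residue's carrier set coincide with a proper union of
# complete groups? (that would create an accidental strong motif)
carrier_union_ok <- function(colres, group_idx, exempt = character()) {
  n <- length(colres)
  for (r in setdiff(unique(colres), exempt)) {
    rows <- which(colres == r)
    if (length(rows) == n) next  # whole-column carrier: universal invariant
    all_or_none <- vapply(group_idx, function(g) {
      k <- sum(g %in% rows)
      k == 0L || k == length(g)
    }, logical(1))
    if (all(all_or_none)) return(FALSE)
  }
  TRUE
}

draw_from <- function(pool, k) pool[sample.int(length(pool), k)]

#' Generate a synthetic family with planted ground truth
#'
#' At zero noise every planted feature is realized exactly; with noise the
#' churn is confined to variable columns, so planted class labels stay
#' sharp. The same seed reproduces the family byte-identically.
#'
#' @param spec a [family_spec()].
#' @param seed integer seed.
#' @return object of class `synthetic_family`: `alignment` (an
#'   [aa_alignment] with metadata), `truth` (per-column classes, motif
#'   list, co-invariance matrix, per-group indel fingerprints, Sec
#'   carriers, co-aligned columns), `spec`.
#' @export
generate_family <- function(spec = family_spec(), seed = 1L) {
  with_seed(seed, {
    gs <- spec$group_sizes
    n <- sum(gs)
    groups <- names(gs)
    ids <- unlist(lapply(groups, function(g)
      sprintf("%s-%02d", g, seq_len(gs[[g]]))))
    glab <- rep(groups, gs)
    group_idx <- split(seq_len(n), factor(glab, levels = groups))
    nc <- spec$n_coaligned
    aa20 <- setdiff(AA_SYMBOLS, "U")

    # --- allocate core positions -------------------------------------------
    fixed <- spec$fixed
    taken <- unique(unlist(fixed))
    avail <- setdiff(seq_len(nc), taken)
    take <- function(k) {
      pos <- sort(draw_from(avail, k))
      avail <<- setdiff(avail, pos)
      pos
    }
    cc <- spec$class_counts
    pos_inv <- sort(c(fixed$arg, fixed$sec, take(cc[["invariant"]] - 2L)))
    pos_out <- take(cc[["single_variant_outlier"]])
    pos_sim <- take(cc[["single_variant_similar"]])
    pos_dis <- take(cc[["single_variant_dissimilar"]])
    pos_dbl <- take(cc[["double_variant"]])
    pos_dom <- take(cc[["dominant"]])
    # motif columns
    motif_plan <- list()
    for (g in groups) {
      k <- spec$motif_diag[[g]]
      if (g %in% c("Anf", "Vnf")) k <- k - 1L  # one slot is the tri column
      if (g == "I") k <- k - 1L                # one slot is the W/Y column
      if (k < 0L) stop("motif_diag too small for fixed motif columns")
      if (k > 0L) for (p in take(k))
        motif_plan[[length(motif_plan) + 1L]] <-
          list(position = p, subsets = list(g), residues = NA,
               background = "mixed")
    }
    mp <- spec$motif_pairs
    if (nrow(mp)) for (i in seq_len(nrow(mp))) {
      if (mp$n[i] > 0L) for (p in take(mp$n[i]))
        motif_plan[[length(motif_plan) + 1L]] <-
          list(position = p, subsets = list(c(mp$g1[i], mp$g2[i])),
               residues = NA, background = "mixed")
    }
    # fixed motif columns: the nif/anf/vnf discriminator and the W/Y column
    motif_plan[[length(motif_plan) + 1L]] <-
      list(position = fixed$tri,
           subsets = list(c("I", "II", "III", "IV"), "Anf", "Vnf"),
           residues = c("G", "H", "L"), background = "none")
    motif_plan[[length(motif_plan) + 1L]] <-
      list(position = fixed$wy, subsets = list("I"), residues = "W",
           background = "Y")
    pos_var <- avail

    # --- fill the core matrix ----------------------------------------------
    core <- matrix(NA_character_, n, nc)
    truth_class <- rep(NA_character_, nc)
    for (p in pos_inv) {
      core[, p] <- if (p == fixed$arg) "R"
                   else if (p == fixed$sec) "C"
                   else draw_from(aa20, 1L)
      truth_class[p] <- "invariant"
    }
    for (p in pos_out) {
      ab <- draw_from(aa20, 2L)
      core[, p] <- ab[1L]
      core[sample.int(n, 1L), p] <- ab[2L]
      truth_class[p] <- "single_variant_outlier"
    }
    scheme <- default_similarity_scheme()
    for (p in pos_sim) {
      repeat {
        pair <- SIMILAR_PAIRS[[sample.int(length(SIMILAR_PAIRS), 1L)]]
        m <- sample(2:max(2L, n %/% 3L), 1L)
        rows <- sample.int(n, m)
        colres <- rep(pair[1L], n)
        colres[rows] <- pair[2L]
        if (carrier_union_ok(colres, group_idx)) break
      }
      core[, p] <- colres
      truth_class[p] <- "single_variant_similar"
    }
    for (p in pos_dis) {
      repeat {
        pair <- draw_from(aa20, 2L)
        if (residues_similar(pair[1L], pair[2L], scheme)) next
        m <- sample(2:max(2L, n %/% 3L), 1L)
        rows <- sample.int(n, m)
        colres <- rep(pair[1L], n)
        colres[rows] <- pair[2L]
        if (carrier_union_ok(colres, group_idx)) break
      }
      core[, p] <- colres
      truth_class[p] <- "single_variant_dissimilar"
    }
    for (p in pos_dbl) {
      repeat {
        tri <- draw_from(aa20, 3L)
        m2 <- sample(2:max(2L, n %/% 4L), 1L)
        m3 <- sample(2:max(2L, n %/% 4L), 1L)
        if (m2 + m3 >= n - 1L) next
        rows <- sample.int(n, m2 + m3)
        colres <- rep(tri[1L], n)
        colres[rows[seq_len(m2)]] <- tri[2L]
        colres[rows[m2 + seq_len(m3)]] <- tri[3L]
        if (length(unique(colres)) == 3L &&
            carrier_union_ok(colres, group_idx)) break
      }
      core[, p] <- colres
      truth_class[p] <- "double_variant"
    }
    for (p in pos_dom) {
      # m minority rows with m < 0.1 n keeps the dominant fraction > 0.90
      m <- max(3L, min(as.integer(ceiling(n * 0.1)) - 1L, 8L))
      kmin <- min(4L, m)
      minority_counts <- c(rep(1L, kmin - 1L), m - kmin + 1L)
      repeat {
        res <- draw_from(aa20, kmin + 1L)
        rows <- sample.int(n, m)
        colres <- rep(res[1L], n)
        at <- 0L
        for (j in seq_along(minority_counts)) {
          colres[rows[at + seq_len(minority_counts[j])]] <- res[j + 1L]
          at <- at + minority_counts[j]
        }
        if (length(unique(colres)) >= 4L &&
            carrier_union_ok(colres, group_idx)) break
      }
      core[, p] <- colres
      truth_class[p] <- "dominant"
    }
    # motif columns
    truth_motifs <- list()
    for (mplan in motif_plan) {
      p <- mplan$position
      subs <- mplan$subsets
      planted_res <- mplan$residues
      if (all(is.na(planted_res)))
        planted_res <- draw_from(aa20, length(subs))
      colres <- rep(NA_character_, n)
      for (si in seq_along(subs))
        colres[unlist(group_idx[subs[[si]]])] <- planted_res[si]
      open <- which(is.na(colres))
      if (length(open)) {
        if (identical(mplan$background, "mixed")) {
          repeat {
            bg <- draw_from(setdiff(aa20, planted_res), 2L)
            colres[open] <- bg[1L + (seq_along(open) %% 2L)]
            if (carrier_union_ok(colres, group_idx, exempt = planted_res))
              break
          }
        } else {
          colres[open] <- mplan$background
        }
      }
      core[, p] <- colres
      kdist <- length(unique(colres))
      truth_class[p] <- if (kdist == 1L) "invariant"
        else if (kdist == 2L) {
          mino <- min(table(colres))
          if (mino == 1L) "single_variant_outlier"
          else if (residues_similar(names(sort(table(colres)))[1L],
                                    names(sort(table(colres)))[2L], scheme))
            "single_variant_similar" else "single_variant_dissimilar"
        } else if (kdist == 3L) "double_variant"
        else if (max(table(colres)) / n > 0.90) "dominant" else "variable"
      for (si in seq_along(subs))
        truth_motifs[[length(truth_motifs) + 1L]] <- data.frame(
          core_position = p,
          subset = paste(sort(subs[[si]]), collapse = ","),
          residue = planted_res[si], stringsAsFactors = FALSE)
    }
    # variable columns (hypervariable: 7+ distinct residues)
    var_pool <- list()
    for (p in pos_var) {
      repeat {
        k <- sample(7:12, 1L)
        pool <- draw_from(aa20, k)
        colres <- pool[sample.int(k, n, replace = TRUE)]
        tt <- table(colres)
        if (length(tt) >= max(4L, min(7L, n - 1L)) &&
            max(tt) / n <= 0.90 &&
            carrier_union_ok(colres, group_idx)) break
      }
      core[, p] <- colres
      var_pool[[as.character(p)]] <- pool
      truth_class[p] <- "variable"
    }
    # substitution noise on variable columns only
    if (spec$noise_rate > 0) for (p in pos_var) {
      pool <- var_pool[[as.character(p)]]
      repeat {
        colres <- core[, p]
        hit <- which(stats::runif(n) < spec$noise_rate)
        if (length(hit))
          colres[hit] <- pool[sample.int(length(pool), length(hit),
                                         replace = TRUE)]
        tt <- table(colres)
        if (length(tt) >= 4L && max(tt) / n <= 0.90 &&
            carrier_union_ok(colres, group_idx)) break
      }
      core[, p] <- colres
    }
    # Sec carriers: first sec_carriers Group III rows carry U at the planted
    # Cys column (invariant under the C==U equivalence)
    sec_rows <- group_idx[["III"]][seq_len(spec$sec_carriers)]
    if (spec$sec_carriers > 0) core[sec_rows, fixed$sec] <- "U"

    # --- assemble the full alignment with indel blocks ---------------------
    ind <- spec$indels
    segs <- list()
    core_col_final <- integer(nc)
    add_block <- function(width, rows_with_residue, numbered) {
      m <- matrix(GAP, n, width)
      if (length(rows_with_residue))
        m[rows_with_residue, ] <- aa20[sample.int(20L, length(rows_with_residue) * width,
                                                  replace = TRUE)]
      attr(m, "numbered") <- numbered
      m
    }
    emit_anchor_blocks <- function(a) {
      out <- list()
      rows_at <- which(ind$anchor == a)
      rows_at <- rows_at[order(ind$kind[rows_at] != "deletion")]  # deletions first
      for (i in rows_at) {
        g <- ind$group[i]
        grows <- group_idx[[g]]
        if (ind$kind[i] == "deletion") {
          out[[length(out) + 1L]] <-
            add_block(ind$length[i], setdiff(seq_len(n), grows),
                      numbered = TRUE)
        } else {
          out[[length(out) + 1L]] <-
            add_block(ind$length[i], grows, numbered = FALSE)
        }
      }
      out
    }
    segs <- c(segs, emit_anchor_blocks(0L))
    for (p in seq_len(nc)) {
      cm <- matrix(core[, p], n, 1L)
      attr(cm, "numbered") <- TRUE
      segs[[length(segs) + 1L]] <- cm
      core_col_final[p] <- NA_integer_  # fixed below
      segs <- c(segs, emit_anchor_blocks(p))
    }
    widths <- vapply(segs, ncol, integer(1))
    mat <- do.call(cbind, segs)
    rownames(mat) <- ids
    # locate final columns of core positions
    starts <- cumsum(c(0L, widths[-length(widths)]))
    is_core_seg <- vapply(segs, function(s)
      isTRUE(attr(s, "numbered")) && ncol(s) == 1L, logical(1))
    # core segments are emitted in order p = 1..nc, width 1; deletions have
    # width possibly 1 too, so track explicitly
    core_seg_ids <- integer(0)
    seg_kind <- character(length(segs))
    # rebuild kinds deterministically by replaying the emission order
    k <- 0L
    replay <- function(a) {
      rows_at <- which(ind$anchor == a)
      rows_at <- rows_at[order(ind$kind[rows_at] != "deletion")]
      rep("indel", length(rows_at))
    }
    kinds <- c(replay(0L),
               unlist(lapply(seq_len(nc), function(p) c("core", replay(p)))))
    core_seg_ids <- which(kinds == "core")
    core_col_final <- starts[core_seg_ids] + 1L

    meta <- data.frame(
      seq_id = ids,
      species = paste0("Synthsp_", ids),
      gene_family = ifelse(glab %in% c("I", "II", "III", "IV"), "nif",
                           tolower(glab)),
      subunit = spec$subunit, group = glab, stringsAsFactors = FALSE)
    aln <- aa_alignment(mat, meta = meta)

    # --- ground truth -------------------------------------------------------
    refmap <- build_reference_map(aln, ids[1L])
    ref_of_core <- refmap$column_to_ref[core_col_final]
    motifs_df <- do.call(rbind, truth_motifs)
    motifs_df$column <- core_col_final[motifs_df$core_position]
    motifs_df$ref_number <- ref_of_core[motifs_df$core_position]
    motifs_df <- motifs_df[order(motifs_df$core_position), ]
    rownames(motifs_df) <- NULL

    column_table <- data.frame(core_position = seq_len(nc),
                               column = core_col_final,
                               ref_number = ref_of_core,
                               class = truth_class)

    # brute-force co-invariance over the core (independent of the analysis
    # path: plain loops over columns and group pairs, with U merged into C)
    merged <- core
    merged[merged == "U"] <- "C"
    cons <- matrix(NA_character_, nc, length(groups),
                   dimnames = list(NULL, groups))
    for (g in groups) for (p in seq_len(nc)) {
      v <- merged[group_idx[[g]], p]
      if (all(v == v[1L])) cons[p, g] <- v[1L]
    }
    coinv <- matrix(NA_integer_, length(groups), length(groups),
                    dimnames = list(groups, groups))
    for (g in groups) for (h in groups) {
      coinv[g, h] <- if (g == h) sum(!is.na(cons[, g]))
        else sum(!is.na(cons[, g]) & !is.na(cons[, h]) &
                   cons[, g] == cons[, h], na.rm = TRUE)
    }

    # per-group indel fingerprints implied by the spec, in final reference
    # numbering (deletion columns are numbered; count those preceding each
    # anchor to convert core positions to reference numbers)
    del_shift <- function(core_pos) {
      dels <- ind[ind$kind == "deletion", , drop = FALSE]
      sum(dels$length[dels$anchor < core_pos]) # deletions fully before
    }
    ref_after <- function(a) if (a == 0L) 0L else ref_of_core[a]
    fingerprints <- setNames(lapply(groups, function(g) {
      rows <- which(ind$group == g)
      if (!length(rows)) return(data.frame(anchor = integer(),
                                           kind = character(),
                                           length = integer()))
      out <- data.frame(
        anchor = vapply(rows, function(i) {
          a <- ind$anchor[i]
          as.integer(
            if (ind$kind[i] == "deletion") ref_after(a) + del_prior(ind, i) + 1L
            else if (ind$kind[i] == "n_terminal_extension") 0L
            else if (ind$kind[i] == "c_terminal_extension") refmap$n_ref
            else ref_after(a))
        }, integer(1)),
        kind = ind$kind[rows], length = ind$length[rows])
      out <- out[order(out$anchor, out$kind), ]
      rownames(out) <- NULL
      out
    }), groups)

    sec_truth <- data.frame(seq_id = ids[sec_rows],
                            ref_position = ref_of_core[spec$sec_position],
                            stringsAsFactors = FALSE)
    if (spec$sec_carriers == 0L) sec_truth <- sec_truth[0L, ]

    truth <- list(column_table = column_table,
                  class_counts = table(factor(truth_class,
                                              levels = CONSERVATION_CLASSES)),
                  motifs = motifs_df,
                  coinvariance = coinv,
                  fingerprints = fingerprints,
                  sec = sec_truth,
                  coaligned_columns = sort(core_col_final),
                  reference_id = ids[1L],
                  arg_position = ref_of_core[spec$fixed$arg],
                  sec_position = ref_of_core[spec$sec_position])
    structure(list(alignment = aln, truth = truth, spec = spec, seed = seed),
              class = "synthetic_family")
  })
}

# deletion columns from earlier same-emission-order blocks at the SAME
# anchor do not occur with the default spec; count deletions strictly
# between the reference residue at the anchor and this block
del_prior <- function(ind, i) {
  dels <- which(ind$kind == "deletion" & ind$anchor == ind$anchor[i])
  sum(ind$length[dels[dels < i]])
}

#' @export
print.synthetic_family <- function(x, ...) {
  cat("synthetic_family (seed", x$seed, "):\n  ")
  print(x$alignment)
  cat("  planted classes:",
      paste(names(x$truth$class_counts), x$truth$class_counts, sep = "=",
            collapse = " "), "\n")
  invisible(x)
}

#' Generate coding sequences matched to an alignment
#'
#' Back-translates each protein with synonymous codons drawn from a codon
#' frequency table (uniform by default); selenocysteine residues are
#' encoded by the amber codon TAG, and a terminal TAA stop is appended.
#'
#' @param aln an [aa_alignment] (proteins may contain U).
#' @param refmap its `reference_map`.
#' @param amber optional data.frame `seq_id`, `ref_position` declaring the
#'   expected amber positions; an amber at a column whose residue is not
#'   C/U-equivalent raises a validation error.
#' @param codon_freq optional named numeric vector of codon weights.
#' @param seed integer seed.
#' @return named character vector of coding sequences (attribute
#'   `frame` = 0).
#' @export
generate_cds_for <- function(aln, refmap, amber = NULL, codon_freq = NULL,
                             seed = 1L) {
  if (!is.null(amber) && nrow(amber)) {
    for (i in seq_len(nrow(amber))) {
      col <- ref_to_col(refmap, amber$ref_position[i])
      res <- aln$mat[amber$seq_id[i], col]
      if (!res %in% c("C", "U"))
        stop("amber position ", amber$ref_position[i], " in ",
             amber$seq_id[i], " is not a C/U column (found ", res, ")")
    }
  }
  with_seed(seed, {
    gc_tab <- codon_table()
    syn <- split(names(gc_tab), unname(gc_tab))
    out <- vapply(seq_ids(aln), function(id) {
      pres <- aln$mat[id, ]
      pres <- pres[pres != GAP]
      codons <- vapply(pres, function(a) {
        if (a == "U") return("TAG")
        cand <- syn[[a]]
        w <- if (is.null(codon_freq)) rep(1, length(cand))
             else {
               ww <- codon_freq[cand]
               ww[is.na(ww)] <- 0
               if (all(ww == 0)) rep(1, length(cand)) else ww
             }
        cand[sample.int(length(cand), 1L, prob = w)]
      }, character(1))
      paste0(paste(codons, collapse = ""), "TAA")
    }, character(1))
    attr(out, "frame") <- 0L
    out
  })
}

#' Specification of a toy coordinate model
#'
#' Pseudo-residues (one CA and one polar N atom each) are placed at known
#' radial distances from a compact target cluster, optionally with
#' bridging waters that create planted water-mediated contacts and far
#' waters that create none.
#'
#' @param n_residues number of radially placed pseudo-residues.
#' @param distances optional explicit nominal distances (recycled);
#'   sampled in `dist_range` when `NULL`.
#' @param dist_range range nominal distances are drawn from.
#' @param chains chain id per residue (recycled; default "A").
#' @param n_target_atoms atoms in the target cluster (radius 0.4 ball).
#' @param n_bridging_waters planted water-mediated residues (appended
#'   beyond `n_residues`).
#' @param n_far_waters waters far from the target.
#' @return object of class `toy_structure_spec`.
#' @export
toy_structure_spec <- function(n_residues = 30, distances = NULL,
                               dist_range = c(2, 12), chains = "A",
                               n_target_atoms = 4, n_bridging_waters = 0,
                               n_far_waters = 0) {
  structure(list(n_residues = n_residues, distances = distances,
                 dist_range = dist_range, chains = chains,
                 n_target_atoms = n_target_atoms,
                 n_bridging_waters = n_bridging_waters,
                 n_far_waters = n_far_waters),
            class = "toy_structure_spec")
}

rand_unit <- function(k) {
  v <- matrix(stats::rnorm(3 * k), k, 3)
  v / sqrt(rowSums(v^2))
}

#' Generate a toy coordinate model with a brute-force expected shell
#'
#' @param spec a [toy_structure_spec()].
#' @param seed integer seed.
#' @param path optional PDB output path; a temp file when `NULL`.
#' @param cutoff shell cutoff used for the emitted expectation.
#' @param hbond_cutoff water-mediation cutoff for the emitted expectation.
#' @return list: `model` (a `structure_model`), `path`, `target` (a
#'   [target_selection()] on the cluster), `expected_shell` (data.frame
#'   `chain`, `resno`, `min_dist` from an all-pairs scan), `expected_water`
#'   (data.frame `chain`, `resno`).
#' @export
generate_toy_structure <- function(spec = toy_structure_spec(), seed = 1L,
                                   path = NULL, cutoff = 5.0,
                                   hbond_cutoff = 3.5) {
  with_seed(seed, {
    nt <- spec$n_target_atoms
    tgt <- rand_unit(nt) * stats::runif(nt, 0, 0.4)
    nres <- spec$n_residues
    d <- spec$distances
    if (is.null(d)) d <- stats::runif(nres, spec$dist_range[1L],
                                      spec$dist_range[2L])
    d <- rep_len(d, nres)
    chains <- rep_len(spec$chains, nres)
    u <- rand_unit(nres)
    rows <- list()
    add_atom <- function(chain, resno, resid, elety, elesy, xyz, hetero) {
      rows[[length(rows) + 1L]] <<- data.frame(
        chain = chain, resno = as.integer(resno), resid = resid,
        elety = elety,
        elesy = elesy, x = xyz[1L], y = xyz[2L], z = xyz[3L], o = 1,
        hetero = hetero, water = resid %in% WATER_RESIDS,
        stringsAsFactors = FALSE)
    }
    for (i in seq_len(nres)) {
      add_atom(chains[i], i, "GLY", "CA", "C", d[i] * u[i, ], FALSE)
      add_atom(chains[i], i, "GLY", "N", "N", (d[i] + 0.8) * u[i, ], FALSE)
    }
    nb <- spec$n_bridging_waters
    if (nb > 0) {
      ub <- rand_unit(nb)
      for (j in seq_len(nb)) {
        rn <- nres + j
        add_atom(chains[1L], rn, "GLY", "N", "N", 6.4 * ub[j, ], FALSE)
        add_atom(chains[1L], rn, "GLY", "CA", "C", 7.2 * ub[j, ], FALSE)
        add_atom("W", 700L + j, "HOH", "O", "O", 3.2 * ub[j, ], TRUE)
      }
    }
    if (spec$n_far_waters > 0) {
      uf <- rand_unit(spec$n_far_waters)
      for (j in seq_len(spec$n_far_waters))
        add_atom("W", 800L + j, "HOH", "O", "O", 20 * uf[j, ], TRUE)
    }
    for (t in seq_len(nt))
      add_atom("X", 900L, "CLF", paste0("FE", t), "FE", tgt[t, ], TRUE)
    model <- structure(list(atoms = do.call(rbind, rows), path = NA),
                       class = "structure_model")
    if (is.null(path)) path <- tempfile(fileext = ".pdb")
    write_structure(model, path)
    model$path <- path
    # brute-force expectation: all-pairs distances, plain loops
    at <- model$atoms
    tidx <- which(at$resid == "CLF")
    res_keys <- unique(at[!at$hetero, c("chain", "resno")])
    mind <- numeric(nrow(res_keys))
    for (i in seq_len(nrow(res_keys))) {
      ridx <- which(!at$hetero & at$chain == res_keys$chain[i] &
                      at$resno == res_keys$resno[i])
      best <- Inf
      for (a in ridx) for (b in tidx)
        best <- min(best, sqrt((at$x[a] - at$x[b])^2 +
                                 (at$y[a] - at$y[b])^2 +
                                 (at$z[a] - at$z[b])^2))
      mind[i] <- best
    }
    expected_shell <- data.frame(chain = res_keys$chain,
                                 resno = res_keys$resno,
                                 min_dist = mind)[mind <= cutoff, ]
    expected_shell <- expected_shell[order(expected_shell$chain,
                                           expected_shell$resno), ]
    rownames(expected_shell) <- NULL
    # brute-force water mediation
    widx <- which(at$water & at$elesy == "O")
    wm <- list()
    for (w in widx) {
      dw <- min(sqrt((at$x[tidx] - at$x[w])^2 + (at$y[tidx] - at$y[w])^2 +
                       (at$z[tidx] - at$z[w])^2))
      if (dw > hbond_cutoff) next
      for (i in seq_len(nrow(res_keys))) {
        ridx <- which(!at$hetero & at$chain == res_keys$chain[i] &
                        at$resno == res_keys$resno[i] &
                        at$elesy %in% c("N", "O"))
        if (!length(ridx)) next
        dr <- min(sqrt((at$x[ridx] - at$x[w])^2 + (at$y[ridx] - at$y[w])^2 +
                         (at$z[ridx] - at$z[w])^2))
        if (dr <= hbond_cutoff && mind[i] > cutoff)
          wm[[paste(res_keys$chain[i], res_keys$resno[i])]] <-
            res_keys[i, c("chain", "resno")]
      }
    }
    expected_water <- if (length(wm)) {
      ww <- do.call(rbind, wm)
      ww <- ww[order(ww$chain, ww$resno), , drop = FALSE]
      rownames(ww) <- NULL
      ww
    } else data.frame(chain = character(), resno = integer())
    tsel <- target_selection(model, "cofactor-cluster", resid = "CLF")
    list(model = model, path = path, target = tsel,
         expected_shell = expected_shell, expected_water = expected_water,
         spec = spec)
  })
}
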