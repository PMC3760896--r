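WATER_RESIDS <- c("HOH", "WAT", "H2O", "DOD")

#' Read an atomic coordinate model from a PDB-format file
#'
#' Thin wrapper over bio3d's PDB reader. Alternate locations are resolved
#' to the highest-occupancy copy per atom; hetero groups (metal clusters,
#' homocitrate, waters) are retained and flagged.
#'
#' @param path PDB file.
#' @return object of class `structure_model`: data.frame `atoms` with
#'   columns `chain`, `resno`, `resid`, `elety`, `elesy`, `x`, `y`, `z`,
#'   `o`, `hetero` (HETATM flag), `water`.
#' @export
read_structure <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  pdb <- tryCatch(bio3d::read.pdb(path, verbose = FALSE),
                  error = function(e) stop("cannot parse PDB ", path, ": ",
                                           conditionMessage(e)))
  at <- pdb$atom
  if (!all(is.finite(at$x) & is.finite(at$y) & is.finite(at$z)))
    stop("non-finite coordinates in ", path)
  # resolve altloc: keep highest occupancy per (chain, resno, insert, elety)
  if (any(!is.na(at$alt) & at$alt != "")) {
    key <- paste(at$chain, at$resno, at$insert, at$elety, sep = "|")
    occ <- ifelse(is.na(at$o), 1, at$o)
    keep <- unlist(lapply(split(seq_len(nrow(at)), key), function(idx)
      idx[which.max(occ[idx])]), use.names = FALSE)
    at <- at[sort(keep), ]
  }
  atoms <- data.frame(chain = at$chain, resno = at$resno, resid = at$resid,
                      elety = at$elety, elesy = trimws(at$elesy),
                      x = at$x, y = at$y, z = at$z,
                      o = ifelse(is.na(at$o), 1, at$o),
                      hetero = at$type == "HETATM",
                      stringsAsFactors = FALSE)
  atoms$water <- atoms$resid %in% WATER_RESIDS
  structure(list(atoms = atoms, path = path), class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  cat("structure_model:", nrow(x$atoms), "atoms;",
      sum(x$atoms$hetero & !x$atoms$water), "hetero (non-water),",
      sum(x$atoms$water), "water\n")
  invisible(x)
}

#' Select the atoms of a contact-shell target
#'
#' Targets are named groups of atoms: a hetero group selected by residue
#' name(s) (e.g. the P-cluster or cofactor cluster hetero group names, or
#' homocitrate `HCA`), or an arbitrary custom selection by atom row
#' indices — e.g. the beta-beta interface mononuclear metal site ligands.
#'
#' @param model a `structure_model`.
#' @param name label recorded in outputs (e.g. "P-cluster",
#'   "cofactor-cluster", "homocitrate", "custom").
#' @param resid residue name(s) selecting the target atoms.
#' @param atom_idx explicit row indices into `model$atoms` (overrides
#'   `resid`).
#' @param chain optional chain filter applied with `resid`.
#' @return object of class `target_selection` with `name` and `idx`.
#' @export
target_selection <- function(model, name, resid = NULL, atom_idx = NULL,
                             chain = NULL) {
  at <- model$atoms
  if (is.null(atom_idx)) {
    if (is.null(resid)) stop("give resid or atom_idx")
    atom_idx <- which(at$resid %in% resid &
                        (is.null(chain) | at$chain %in% (chain %||% at$chain)))
  }
  atom_idx <- as.integer(atom_idx)
  if (length(atom_idx) == 0L) stop("target selection '", name, "' is empty")
  if (any(atom_idx < 1L | atom_idx > nrow(at)))
    stop("atom index out of range")
  structure(list(name = name, idx = atom_idx), class = "target_selection")
}

# minimum distance from each query atom set to the target atom set
min_dist_to <- function(xyz_query, xyz_target) {
  # rows: query atoms; returns per-query-atom min distance
  d2 <- outer(rowSums(xyz_query^2), rowSums(xyz_target^2), "+") -
    2 * xyz_query %*% t(xyz_target)
  d2[d2 < 0] <- 0
  sqrt(apply(d2, 1L, min))
}

is_hydrogen <- function(atoms) {
  ifelse(nzchar(atoms$elesy), atoms$elesy == "H" | atoms$elesy == "D",
         grepl("^[0-9]*H", atoms$elety))
}

#' Residues within a distance cutoff of a target
#'
#' A residue enters the shell iff the minimum over all pairs of one of its
#' atoms and one target atom of the Euclidean distance is less than or
#' equal to the cutoff (closed boundary). Amino-acid residues only: waters
#' and the target's own residues are excluded; covalently bound protein
#' ligands are included like any other residue. Hydrogens are excluded by
#' default.
#'
#' @param model a `structure_model`.
#' @param target a [target_selection()].
#' @param cutoff distance cutoff in Angstrom (default 5.0).
#' @param include_hydrogens include hydrogen/deuterium atoms in the
#'   distance scan.
#' @return object of class `contact_shell`: `target`, `cutoff`, `entries`
#'   (data.frame `chain`, `resno`, `resid`, `min_dist`, `kind` = "direct",
#'   sorted by chain then residue number).
#' @export
contact_shell <- function(model, target, cutoff = 5.0,
                          include_hydrogens = FALSE) {
  if (cutoff <= 0) stop("cutoff must be positive")
  at <- model$atoms
  tgt <- at[target$idx, ]
  tgt_res <- unique(paste(tgt$chain, tgt$resno, tgt$resid, sep = "|"))
  cand <- which(!at$hetero & !at$water &
                  !(paste(at$chain, at$resno, at$resid, sep = "|") %in% tgt_res))
  if (!include_hydrogens) cand <- cand[!is_hydrogen(at[cand, ])]
  tidx <- target$idx
  if (!include_hydrogens) tidx <- tidx[!is_hydrogen(at[tidx, ])]
  if (length(tidx) == 0L) stop("target has no non-hydrogen atoms")
  entries <- data.frame(chain = character(), resno = integer(),
                        resid = character(), min_dist = numeric(),
                        kind = character(), stringsAsFactors = FALSE)
  if (length(cand)) {
    md <- min_dist_to(as.matrix(at[cand, c("x", "y", "z")]),
                      as.matrix(at[tidx, c("x", "y", "z")]))
    key <- paste(at$chain[cand], at$resno[cand], at$resid[cand], sep = "|")
    per_res <- tapply(md, key, min)
    hit <- per_res[per_res <= cutoff]
    if (length(hit)) {
      parts <- do.call(rbind, strsplit(names(hit), "|", fixed = TRUE))
      entries <- data.frame(chain = parts[, 1L],
                            resno = as.integer(parts[, 2L]),
                            resid = parts[, 3L],
                            min_dist = as.numeric(hit),
                            kind = "direct", stringsAsFactors = FALSE)
      entries <- entries[order(entries$chain, entries$resno), ]
      rownames(entries) <- NULL
    }
  }
  structure(list(target = target$name, cutoff = cutoff, entries = entries),
            class = "contact_shell")
}

#' @export
print.contact_shell <- function(x, ...) {
  cat(sprintf("contact_shell: %d residues within %.1f A of %s\n",
              nrow(x$entries), x$cutoff, x$target))
  if (nrow(x$entries)) print(x$entries)
  invisible(x)
}

#' Residues contacting a target only through a bridging water
#'
#' A residue is water-mediated iff one of its polar (N or O) atoms lies
#' within the hydrogen-bond cutoff of a water oxygen that is itself within
#' the cutoff of a target atom, and the residue is not already in the
#' direct shell. Distance-only criterion (no angle term).
#'
#' @param model a `structure_model`.
#' @param target a [target_selection()].
#' @param hbond_cutoff hydrogen-bond distance in Angstrom (default 3.5).
#' @param direct_shell optional precomputed [contact_shell()] whose
#'   residues are excluded; computed at 5.0 A when omitted.
#' @return data.frame `chain`, `resno`, `resid`, `via_water_min_dist`,
#'   `kind` = "water_mediated".
#' @export
water_mediated_contacts <- function(model, target, hbond_cutoff = 3.5,
                                    direct_shell = NULL) {
  at <- model$atoms
  empty <- data.frame(chain = character(), resno = integer(),
                      resid = character(), via_water_min_dist = numeric(),
                      kind = character(), stringsAsFactors = FALSE)
  wat_o <- which(at$water & at$elesy == "O")
  if (length(wat_o) == 0L) return(empty)
  if (is.null(direct_shell)) direct_shell <- contact_shell(model, target)
  tgt_xyz <- as.matrix(at[target$idx, c("x", "y", "z")])
  wd <- min_dist_to(as.matrix(at[wat_o, c("x", "y", "z")]), tgt_xyz)
  bridge <- wat_o[wd <= hbond_cutoff]
  if (length(bridge) == 0L) return(empty)
  polar <- which(!at$hetero & !at$water & at$elesy %in% c("N", "O"))
  if (length(polar) == 0L) return(empty)
  pd <- min_dist_to(as.matrix(at[polar, c("x", "y", "z")]),
                    as.matrix(at[bridge, c("x", "y", "z")]))
  key <- paste(at$chain[polar], at$resno[polar], at$resid[polar], sep = "|")
  per_res <- tapply(pd, key, min)
  hit <- per_res[per_res <= hbond_cutoff]
  if (length(hit) == 0L) return(empty)
  parts <- do.call(rbind, strsplit(names(hit), "|", fixed = TRUE))
  out <- data.frame(chain = parts[, 1L], resno = as.integer(parts[, 2L]),
                    resid = parts[, 3L], via_water_min_dist = as.numeric(hit),
                    kind = "water_mediated", stringsAsFactors = FALSE)
  direct_key <- paste(direct_shell$entries$chain, direct_shell$entries$resno)
  out <- out[!(paste(out$chain, out$resno) %in% direct_key), ]
  out <- out[order(out$chain, out$resno), ]
  rownames(out) <- NULL
  out
}

#' Overlay conservation classes onto a contact shell
#'
#' Joins shell residues to per-column conservation classes through the
#' reference numbering (structure residue numbers are assumed to be in the
#' reference numbering, with an optional per-chain offset). Classes are
#' collapsed to invariant / single_variant / multi_variant for the tally;
#' residues outside the co-aligned region are flagged `no_coverage`, not
#' dropped.
#'
#' @param shell a [contact_shell()].
#' @param profiles a `conservation_profiles` object (with reference
#'   numbers), or a named list of them keyed by subunit.
#' @param chain_to_subunit named character vector chain -> subunit key of
#'   `profiles` (e.g. `c(A = "D", B = "K")`). Ignored when `profiles` is a
#'   single object.
#' @param offset integer added to structure residue numbers to obtain
#'   reference numbers (scalar or named per chain; default 0).
#' @return object of class `shell_annotation`: `entries` (shell entries
#'   plus `ref_number`, `class`, `class_collapsed`), `tally` (named counts
#'   over invariant / single_variant / multi_variant / no_coverage).
#' @export
annotate_shell <- function(shell, profiles, chain_to_subunit = NULL,
                           offset = 0L) {
  ent <- shell$entries
  single <- inherits(profiles, "conservation_profiles")
  get_prof <- function(chain) {
    if (single) return(profiles)
    su <- chain_to_subunit[[chain]]
    if (is.null(su) || !su %in% names(profiles)) return(NULL)
    profiles[[su]]
  }
  off_for <- function(chain) {
    if (length(offset) == 1L && is.null(names(offset))) return(offset)
    o <- offset[[chain]]
    if (is.null(o)) 0L else o
  }
  cls <- character(nrow(ent))
  refn <- integer(nrow(ent))
  for (i in seq_len(nrow(ent))) {
    pr <- get_prof(ent$chain[i])
    rn <- ent$resno[i] + off_for(ent$chain[i])
    refn[i] <- rn
    if (is.null(pr) || !rn %in% pr$ref_number) {
      cls[i] <- "no_coverage"
    } else {
      cls[i] <- pr$class[match(rn, pr$ref_number)]
    }
  }
  collapsed <- ifelse(cls == "invariant", "invariant",
               ifelse(cls %in% c("single_variant_outlier",
                                 "single_variant_similar",
                                 "single_variant_dissimilar"),
                      "single_variant",
               ifelse(cls == "no_coverage", "no_coverage", "multi_variant")))
  ent$ref_number <- refn
  ent$class <- cls
  ent$class_collapsed <- collapsed
  tally <- table(factor(collapsed, levels = c("invariant", "single_variant",
                                              "multi_variant",
                                              "no_coverage")))
  structure(list(target = shell$target, cutoff = shell$cutoff,
                 entries = ent,
                 tally = setNames(as.integer(tally), names(tally))),
            class = "shell_annotation")
}

#' @export
print.shell_annotation <- function(x, ...) {
  cat(sprintf("shell_annotation (%s, %.1f A): %s\n", x$target, x$cutoff,
              paste(names(x$tally), x$tally, sep = "=", collapse = " ")))
  invisible(x)
}

#' Write a structure model to a PDB-format file
#' @param model a `structure_model`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_structure <- function(model, path) {
  at <- model$atoms
  bio3d::write.pdb(pdb = NULL, file = path,
                   xyz = as.vector(t(as.matrix(at[, c("x", "y", "z")]))),
                   type = ifelse(at$hetero, "HETATM", "ATOM"),
                   resno = at$resno, resid = at$resid, chain = at$chain,
                   elety = at$elety, o = at$o, b = rep(0, nrow(at)),
                   elesy = at$elesy)
  invisible(path)
}
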