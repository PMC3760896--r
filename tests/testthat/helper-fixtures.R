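# Fixtures and independent brute-force oracles. The oracles are written as
# plain loops over the definitions and share no code with the package
# internals they check.

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# a small six-group alignment frame used across tests
tiny_groups <- function(sizes = c(I = 4, II = 3, III = 2, IV = 2,
                                  Anf = 2, Vnf = 2)) {
  ids <- unlist(lapply(names(sizes), function(g)
    paste0(g, "-", seq_len(sizes[[g]]))))
  list(ids = ids, labels = rep(names(sizes), sizes), sizes = sizes)
}

make_aln <- function(mat, labels = NULL) {
  meta <- if (is.null(labels)) NULL else
    data.frame(seq_id = rownames(mat), species = NA, gene_family = NA,
               subunit = "D", group = labels)
  aa_alignment(mat, meta = meta)
}

random_alignment <- function(n_seq = 20, n_col = 50, seed = 1,
                             gap_rate = 0, labels = NULL,
                             alphabet = AA20) {
  set.seed(seed)
  mat <- matrix(sample(alphabet, n_seq * n_col, replace = TRUE),
                n_seq, n_col)
  if (gap_rate > 0) mat[runif(length(mat)) < gap_rate] <- "-"
  rownames(mat) <- sprintf("s%02d", seq_len(n_seq))
  if (!is.null(labels)) rownames(mat) <- paste0(labels, "-",
                                                seq_len(n_seq))
  make_aln(mat, labels)
}

# --- oracles ---------------------------------------------------------------

# reference numbering by a forward scan counting reference non-gaps
oracle_refmap <- function(mat, reference_id) {
  ref <- mat[reference_id, ]
  num <- rep(NA_integer_, length(ref))
  seen <- 0L
  for (j in seq_along(ref)) {
    if (ref[j] != "-") {
      seen <- seen + 1L
      num[j] <- seen
    }
  }
  num
}

# per-column gap scan
oracle_coaligned <- function(mat) {
  keep <- logical(ncol(mat))
  for (j in seq_len(ncol(mat))) keep[j] <- !any(mat[, j] == "-")
  which(keep)
}

# direct restatement of the classification rules
oracle_classify <- function(col, similar_fun) {
  tab <- table(col)
  k <- length(tab)
  if (k == 1) return("invariant")
  if (k == 2) {
    if (min(tab) == 1) return("single_variant_outlier")
    two <- names(tab)
    return(if (similar_fun(two[1], two[2])) "single_variant_similar"
           else "single_variant_dissimilar")
  }
  if (k == 3) return("double_variant")
  if (max(tab) / sum(tab) > 0.90) return("dominant")
  "variable"
}

# group-pair co-invariance by explicit per-column checks
oracle_coinvariance <- function(mat, labels, cols) {
  groups <- unique(labels)
  m <- matrix(0L, length(groups), length(groups),
              dimnames = list(groups, groups))
  for (g in groups) for (h in groups) {
    cnt <- 0L
    for (j in cols) {
      vg <- mat[labels == g, j]
      vh <- mat[labels == h, j]
      if (g == h) {
        if (all(vg == vg[1])) cnt <- cnt + 1L
      } else if (all(vg == vg[1]) && all(vh == vh[1]) && vg[1] == vh[1]) {
        cnt <- cnt + 1L
      }
    }
    m[g, h] <- cnt
  }
  m
}

# strong-motif definition evaluated per column
oracle_motifs <- function(mat, labels, cols, subset) {
  rows_in <- which(labels %in% subset)
  rows_out <- which(!labels %in% subset)
  hits <- data.frame(column = integer(), residue = character())
  for (j in cols) {
    rin <- mat[rows_in, j]
    if (all(rin == rin[1]) && !(rin[1] %in% mat[rows_out, j]))
      hits <- rbind(hits, data.frame(column = j, residue = rin[1]))
  }
  hits
}

# all-pairs distance scan for contact shells
oracle_shell <- function(atoms, target_idx, cutoff) {
  keys <- unique(atoms[!atoms$hetero & !atoms$water, c("chain", "resno")])
  out <- data.frame(chain = character(), resno = integer(),
                    min_dist = numeric())
  tgt_key <- unique(paste(atoms$chain[target_idx], atoms$resno[target_idx]))
  for (i in seq_len(nrow(keys))) {
    if (paste(keys$chain[i], keys$resno[i]) %in% tgt_key) next
    ridx <- which(!atoms$hetero & !atoms$water &
                    atoms$chain == keys$chain[i] &
                    atoms$resno == keys$resno[i])
    best <- Inf
    for (a in ridx) for (b in target_idx) {
      d <- sqrt((atoms$x[a] - atoms$x[b])^2 + (atoms$y[a] - atoms$y[b])^2 +
                  (atoms$z[a] - atoms$z[b])^2)
      if (d < best) best <- d
    }
    if (best <= cutoff)
      out <- rbind(out, data.frame(chain = keys$chain[i],
                                   resno = keys$resno[i], min_dist = best))
  }
  out[order(out$chain, out$resno), ]
}

# random toy structure model built directly (no file round trip)
random_toy_model <- function(n_atoms = 200, seed = 1) {
  set.seed(seed)
  n_res <- n_atoms %/% 2L
  atoms <- data.frame(
    chain = "A",
    resno = rep(seq_len(n_res), each = 2L),
    resid = "GLY",
    elety = rep(c("CA", "N"), n_res),
    elesy = rep(c("C", "N"), n_res),
    x = runif(2L * n_res, -12, 12), y = runif(2L * n_res, -12, 12),
    z = runif(2L * n_res, -12, 12), o = 1,
    hetero = FALSE, water = FALSE, stringsAsFactors = FALSE)
  tgt <- data.frame(chain = "X", resno = 900L, resid = "CLF",
                    elety = paste0("FE", 1:3), elesy = "FE",
                    x = runif(3, -1, 1), y = runif(3, -1, 1),
                    z = runif(3, -1, 1), o = 1, hetero = TRUE,
                    water = FALSE, stringsAsFactors = FALSE)
  structure(list(atoms = rbind(atoms, tgt), path = NA),
            class = "structure_model")
}

rigid_transform <- function(model, angle = 0.7, shift = c(5, -3, 2)) {
  R <- matrix(c(cos(angle), -sin(angle), 0,
                sin(angle), cos(angle), 0,
                0, 0, 1), 3, 3, byrow = TRUE)
  xyz <- as.matrix(model$atoms[, c("x", "y", "z")]) %*% t(R)
  model$atoms$x <- xyz[, 1] + shift[1]
  model$atoms$y <- xyz[, 2] + shift[2]
  model$atoms$z <- xyz[, 3] + shift[3]
  model
}

shell_key <- function(entries) paste(entries$chain, entries$resno)
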