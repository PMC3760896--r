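# Pipeline driver and table writers. Tables are TSV with a single
# commented header block recording the run configuration verbatim, so
# re-running a subcommand on identical inputs yields byte-identical output.

#' Write a data frame as a TSV report with a commented config header
#' @param df data.frame.
#' @param path output file.
#' @param header named list echoed as `# key: value` lines.
#' @return `path`, invisibly.
#' @export
write_report_tsv <- function(df, path, header = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  for (k in names(header))
    writeLines(sprintf("# %s: %s", k,
                       paste(format(header[[k]]), collapse = " ")), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

fmt_pct <- function(x) sprintf("%.1f%%", x)

#' Assemble a run configuration
#'
#' @param ... configuration fields: `alignment`, `meta`, `reference`,
#'   `scheme` (path or `similarity_scheme`), `equiv` (`"sec"` or `NULL`),
#'   `pdb`, `target`, `cutoff`, `chains`, `cds`, `position`, `subset`,
#'   `query`, `subunit`, `seed`, `out_dir`.
#' @return a named list of class `run_config`.
#' @export
run_config <- function(...) {
  cfg <- list(...)
  defaults <- list(cutoff = 5.0, seed = 1L, out_dir = ".", subunit = "D",
                   equiv = NULL)
  for (k in names(defaults)) if (is.null(cfg[[k]])) cfg[[k]] <- defaults[[k]]
  structure(cfg, class = "run_config")
}

config_header <- function(cfg, extra = list()) {
  keep <- cfg[!vapply(cfg, is.null, logical(1))]
  keep <- keep[vapply(keep, function(v)
    is.character(v) || is.numeric(v) || is.logical(v), logical(1))]
  c(keep, extra)
}

load_inputs <- function(cfg) {
  aln <- read_alignment(cfg$alignment, meta = cfg$meta)
  refmap <- build_reference_map(aln, cfg$reference)
  blocks <- coaligned_columns(aln)
  scheme <- if (is.null(cfg$scheme)) default_similarity_scheme()
            else if (is.character(cfg$scheme)) read_similarity_scheme(cfg$scheme)
            else cfg$scheme
  equiv <- if (identical(cfg$equiv, "sec")) sec_equivalence()
           else if (is.null(cfg$equiv) || identical(cfg$equiv, "none")) NULL
           else cfg$equiv
  list(aln = aln, refmap = refmap, blocks = blocks, scheme = scheme,
       equiv = equiv)
}

#' Run a pipeline subcommand
#'
#' Dispatches to the analysis modules and writes commented-header TSV
#' outputs into `config$out_dir`. Subcommands: `conserve` (Table-1-style
#' summary + per-column profiles), `coinvar` (group-by-group co-invariance
#' matrix), `motifs` (strong motifs for `config$subset`), `assign`
#' (classify `config$query` sequences), `shells` (contact shell +
#' conservation overlay), `secscan` (amber read-through scan at
#' `config$position`), `simulate` (write a default synthetic family).
#' Partial outputs are removed on failure.
#'
#' @param config a [run_config()].
#' @param subcommand one of conserve, coinvar, motifs, assign, shells,
#'   secscan, simulate.
#' @return named character vector of files written, invisibly.
#' @export
run_pipeline <- function(config,
                         subcommand = c("conserve", "coinvar", "motifs",
                                        "assign", "shells", "secscan",
                                        "simulate")) {
  subcommand <- match.arg(subcommand)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character()
  outfile <- function(name) {
    f <- file.path(config$out_dir, name)
    written <<- c(written, f)
    f
  }
  ok <- FALSE
  on.exit(if (!ok) unlink(written))
  res <- switch(subcommand,
    conserve = {
      io <- load_inputs(config)
      summ <- summarize_conservation(io$aln, io$blocks, io$scheme, io$equiv,
                                     io$refmap, subunit = config$subunit)
      hdr <- config_header(config, list(
        n_sequences = summ$n_sequences, n_coaligned = summ$n_coaligned))
      write_report_tsv(data.frame(
        statistic = c("Sequences", "Aligned residues", "Invariant residues",
                      "% invariant", "Total single variant",
                      "% single variant"),
        value = c(summ$n_sequences, summ$n_coaligned, summ$n_invariant,
                  fmt_pct(summ$pct_invariant), summ$n_single_variant,
                  fmt_pct(summ$pct_single_variant))),
        outfile("conservation_summary.tsv"), hdr)
      write_report_tsv(as.data.frame(summ$profiles),
                       outfile("column_profiles.tsv"), hdr)
      summ
    },
    coinvar = {
      io <- load_inputs(config)
      part <- group_partition(io$aln)
      m <- coinvariance_matrix(io$aln, io$blocks, part, io$equiv, io$refmap)
      df <- data.frame(group = rownames(m), as.data.frame(unclass(m)),
                       check.names = FALSE)
      write_report_tsv(df, outfile("coinvariance.tsv"),
                       config_header(config,
                                     list(n_coaligned = io$blocks$total_columns)))
      m
    },
    motifs = {
      io <- load_inputs(config)
      part <- group_partition(io$aln)
      subset <- strsplit(config$subset, ",")[[1L]]
      mm <- strong_motifs(io$aln, io$blocks, part, subset, io$equiv,
                          io$refmap)
      write_report_tsv(as.data.frame(mm), outfile("strong_motifs.tsv"),
                       config_header(config, list(
                         note = "computed over co-aligned columns only")))
      mm
    },
    assign = {
      io <- load_inputs(config)
      part <- group_partition(io$aln)
      groups <- names(attr(part, "sizes"))[attr(part, "sizes") > 0L]
      motifs <- setNames(lapply(groups, function(g)
        strong_motifs(io$aln, io$blocks, part, g, io$equiv, io$refmap)),
        groups)
      qaln <- read_alignment(config$query)
      rows <- lapply(seq_ids(qaln), function(id) {
        a <- assign_group(qaln$mat[id, , drop = FALSE], motifs, io$refmap)
        data.frame(seq_id = id,
                   assigned = a$assigned %||% NA_character_,
                   tie = a$tie,
                   scores = paste(names(a$scores), a$scores, sep = ":",
                                  collapse = ","),
                   note = a$note, stringsAsFactors = FALSE)
      })
      df <- do.call(rbind, rows)
      write_report_tsv(df, outfile("group_assignment.tsv"),
                       config_header(config))
      df
    },
    shells = {
      io <- load_inputs(config)
      model <- read_structure(config$pdb)
      if (!is.null(config$chains)) {
        keep <- model$atoms$chain %in%
          c(strsplit(config$chains, ",")[[1L]], "W", "X")
        model$atoms <- model$atoms[keep, ]
      }
      tgt <- target_selection(model, config$target,
                              resid = config$target_resid %||% "CLF")
      shell <- contact_shell(model, tgt, cutoff = config$cutoff)
      prof <- conservation_profiles(io$aln, io$blocks, io$scheme, io$equiv,
                                    io$refmap)
      ann <- annotate_shell(shell, prof)
      wm <- water_mediated_contacts(model, tgt, direct_shell = shell)
      out <- rbind(
        ann$entries[, c("chain", "resno", "resid", "min_dist", "kind",
                        "class")],
        if (nrow(wm)) data.frame(chain = wm$chain, resno = wm$resno,
                                 resid = wm$resid,
                                 min_dist = wm$via_water_min_dist,
                                 kind = wm$kind, class = NA))
      write_report_tsv(out, outfile("contact_shell.tsv"),
                       config_header(config, list(
                         tally = paste(names(ann$tally), ann$tally,
                                       sep = "=", collapse = " "))))
      ann
    },
    secscan = {
      io <- load_inputs(config)
      cds <- read_cds_fasta(config$cds)
      df <- scan_sec_positions(cds, io$aln, io$refmap, config$position)
      write_report_tsv(df, outfile("sec_scan.tsv"),
                       config_header(config, list(
                         checks_not_performed = "selA/selB/selD, bSECIS")))
      df
    },
    simulate = {
      fam <- generate_family(family_spec(), seed = config$seed)
      write_alignment(fam$alignment,
                      outfile("synthetic_alignment.fasta"),
                      meta_path = outfile("synthetic_metadata.tsv"))
      cds <- generate_cds_for(fam$alignment,
                              build_reference_map(fam$alignment,
                                                  fam$truth$reference_id),
                              amber = fam$truth$sec, seed = config$seed)
      writeLines(paste0(">", names(cds), "\n", unname(cds)),
                 outfile("synthetic_cds.fasta"))
      fam
    })
  ok <- TRUE
  attr(written, "result") <- res
  invisible(written)
}
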