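# PIR alignment emission and parsing (comparative-modelling dialect:
# structureX/sequence header lines, '/' chain breaks, entries end in '*').

#' Emit comparative-modelling input files
#'
#' Writes the three files a restraint-based modelling engine consumes:
#' the PIR alignment (template `structureX` entry referencing the template
#' PDB, chains M then P separated by `'/'`; target `sequence` entry), the
#' template PDB itself, and a plain-text restraint description listing the
#' 1-based anchor positions. The two PIR sequence rows have equal length
#' (gaps included) and end with `'*'`.
#'
#' @param target a `modelling_target`.
#' @param entry the selected `template_entry`.
#' @param pep_alignment scored `peptide_alignment`.
#' @param mhc_alignment output of [align_mhc()].
#' @param outdir output directory (created if missing).
#' @return named character vector of written file paths
#'   (`alignment`, `template`, `restraints`).
#' @export
emit_modeller_inputs <- function(target, entry, pep_alignment, mhc_alignment,
                                 outdir) {
  if (!dir.exists(outdir)) {
    ok <- dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory: ", outdir)
  }
  tid <- entry$source_id
  pdb_path <- file.path(outdir, paste0(tid, ".pdb"))
  write_pdb(entry$structure, pdb_path)

  n_m <- chain_length(entry$structure, "M")
  n_p <- chain_length(entry$structure, "P")
  tmpl_row <- paste0(mhc_alignment$template_row, "/",
                     pep_alignment$template_row, "*")
  tgt_row <- paste0(mhc_alignment$target_row, "/",
                    pep_alignment$target_row, "*")
  pir <- c(
    paste0(">P1;", tid),
    sprintf("structureX:%s:1:M:%d:P:::-1.00:-1.00", paste0(tid, ".pdb"), n_p),
    tmpl_row,
    "",
    ">P1;target",
    "sequence:target::::::::",
    tgt_row)
  pir_path <- file.path(outdir, "alignment.pir")
  writeLines(pir, pir_path)

  restr_path <- file.path(outdir, "restraints.txt")
  writeLines(c("# anchor positions (1-based) on the peptide chain P",
               paste("anchor", target$anchors)), restr_path)
  c(alignment = pir_path, template = pdb_path, restraints = restr_path)
}

#' Parse a PIR alignment file
#'
#' Reads PIR entries (`>P1;name`, a description line, then sequence lines
#' terminated by `'*'`). Round-trips the files written by
#' [emit_modeller_inputs()].
#'
#' @param text PIR text (string, lines, or a file path).
#' @return list of entries: each `list(name, description, sequence)` with
#'   the sequence gaps and chain breaks preserved (terminal `'*'` removed).
#' @export
read_pir <- function(text) {
  if (length(text) == 1 && !grepl("\n", text, fixed = TRUE) &&
      file.exists(text)) {
    text <- readLines(text, warn = FALSE)
  } else if (length(text) == 1) {
    text <- strsplit(text, "\n", fixed = TRUE)[[1]]
  }
  starts <- grep("^>", text)
  if (length(starts) == 0) stop("no PIR entries found")
  entries <- vector("list", length(starts))
  bounds <- c(starts, length(text) + 1L)
  for (k in seq_along(starts)) {
    hdr <- text[starts[k]]
    name <- sub("^>[A-Za-z0-9]+;", "", hdr)
    block <- text[(starts[k] + 1L):(bounds[k + 1L] - 1L)]
    if (length(block) < 2) stop("malformed PIR entry: ", name)
    description <- block[1]
    seq <- paste(block[-1], collapse = "")
    if (!grepl("\\*", seq)) stop("PIR entry not terminated by '*': ", name)
    seq <- sub("\\*.*$", "", seq)
    entries[[k]] <- list(name = name, description = description,
                         sequence = seq)
  }
  entries
}
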