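# PDB structure reading, normalization and writing.
#
# Structures are carried as flat atom tables (one row per atom) in author
# order, with columns: record, chain, resno, ins, resid, atom, x, y, z, occ,
# elem, line. Two classes wrap them:
#   * pdb_structure  -- raw multi-chain parse result
#   * pmhc_structure -- normalized complex: chains exactly "M" (MHC alpha
#     G-domains) and "P" (peptide), residues renumbered 1..n

new_pdb_structure <- function(atoms, source_id) {
  structure(list(atoms = atoms, source_id = source_id),
            class = "pdb_structure")
}

#' Construct a normalized pMHC structure
#'
#' @param atoms atom table with chains exactly `"M"` and `"P"`, residue
#'   numbering contiguous from 1 in each chain.
#' @param source_id provenance string (e.g. PDB ID).
#' @param numbering_map optional data.frame mapping old to new numbering.
#' @return object of class `pmhc_structure`.
#' @export
pmhc_structure <- function(atoms, source_id, numbering_map = NULL) {
  obj <- structure(list(atoms = atoms, source_id = source_id,
                        numbering_map = numbering_map),
                   class = "pmhc_structure")
  validate_pmhc_structure(obj)
  obj
}

validate_pmhc_structure <- function(x) {
  a <- x$atoms
  if (!setequal(unique(a$chain), c("M", "P"))) {
    stop("pmhc_structure must have chains exactly 'M' and 'P'")
  }
  for (ch in c("M", "P")) {
    rn <- unique(a$resno[a$chain == ch])
    if (!identical(as.integer(rn), seq_along(rn))) {
      stop("chain ", ch, " numbering is not contiguous 1..n")
    }
  }
  invisible(x)
}

#' @export
print.pmhc_structure <- function(x, ...) {
  cat("pMHC structure <", x$source_id, ">: M chain ",
      chain_length(x, "M"), " residues, peptide ",
      peptide_sequence(x), " (", chain_length(x, "P"), " aa)\n", sep = "")
  invisible(x)
}

chain_length <- function(s, chain) {
  length(unique(s$atoms$resno[s$atoms$chain == chain]))
}

#' Peptide sequence of a pMHC structure
#' @param s a `pmhc_structure`.
#' @return 1-letter peptide sequence string.
#' @export
peptide_sequence <- function(s) {
  a <- s$atoms[s$atoms$chain == "P", ]
  paste(aa3to1(a$resid[!duplicated(a$resno)]), collapse = "")
}

#' MHC chain sequence of a pMHC structure
#' @param s a `pmhc_structure`.
#' @return 1-letter M-chain sequence string.
#' @export
mhc_sequence <- function(s) {
  a <- s$atoms[s$atoms$chain == "M", ]
  paste(aa3to1(a$resid[!duplicated(a$resno)]), collapse = "")
}

empty_atoms <- function() {
  data.frame(record = character(), chain = character(), resno = integer(),
             ins = character(), resid = character(), atom = character(),
             x = double(), y = double(), z = double(), occ = double(),
             elem = character(), line = integer(), stringsAsFactors = FALSE)
}

num_field <- function(s, lineno, what) {
  v <- suppressWarnings(as.numeric(trimws(s)))
  if (is.na(v)) {
    reject("UNPARSEABLE",
           sprintf("malformed %s field at line %d: '%s'", what, lineno, s))
  }
  v
}

#' Parse PDB-format text
#'
#' Reads standard v3.3 `ATOM`/`HETATM` records from the first model of a PDB
#' file. Alternate locations are resolved by keeping the highest-occupancy
#' altloc (ties prefer `'A'`); `ANISOU` and models beyond the first are
#' ignored. Malformed coordinate fields raise a rejection carrying the
#' offending line number; text with no protein chain at all is rejected as
#' unparseable.
#'
#' @param text PDB text: a single string or a character vector of lines.
#' @param source_id provenance label attached to the result.
#' @return a `pdb_structure` (raw multi-chain atom table).
#' @export
parse_pdb <- function(text, source_id = "input") {
  if (length(text) == 1 && grepl("\n", text, fixed = TRUE)) {
    text <- strsplit(text, "\n", fixed = TRUE)[[1]]
  }
  if (length(text) == 0 || all(!nzchar(text))) {
    reject("UNPARSEABLE", "empty PDB text")
  }
  rows <- vector("list", length(text))
  n <- 0L
  for (i in seq_along(text)) {
    ln <- text[[i]]
    rec <- substr(ln, 1, 6)
    if (rec == "ENDMDL") break
    if (!(rec %in% c("ATOM  ", "HETATM"))) next
    if (nchar(ln) < 54) {
      reject("UNPARSEABLE", sprintf("truncated %s record at line %d",
                                    trimws(rec), i))
    }
    resno <- suppressWarnings(as.integer(trimws(substr(ln, 23, 26))))
    if (is.na(resno)) {
      reject("UNPARSEABLE", sprintf("malformed residue number at line %d", i))
    }
    occ <- if (nchar(ln) >= 60) {
      suppressWarnings(as.numeric(trimws(substr(ln, 55, 60))))
    } else NA_real_
    if (is.na(occ)) occ <- 1.0
    elem <- if (nchar(ln) >= 78) trimws(substr(ln, 77, 78)) else ""
    n <- n + 1L
    rows[[n]] <- data.frame(
      record = trimws(rec),
      chain  = substr(ln, 22, 22),
      resno  = resno,
      ins    = trimws(substr(ln, 27, 27)),
      resid  = trimws(substr(ln, 18, 20)),
      atom   = trimws(substr(ln, 13, 16)),
      altloc = substr(ln, 17, 17),
      x = num_field(substr(ln, 31, 38), i, "x coordinate"),
      y = num_field(substr(ln, 39, 46), i, "y coordinate"),
      z = num_field(substr(ln, 47, 54), i, "z coordinate"),
      occ = occ, elem = elem, line = i,
      stringsAsFactors = FALSE
    )
  }
  if (n == 0L) reject("UNPARSEABLE", "no ATOM/HETATM records found")
  atoms <- do.call(rbind, rows[seq_len(n)])
  atoms <- resolve_altlocs(atoms)
  atoms$altloc <- NULL
  if (!any(atoms$atom == "CA" & atoms$atom != atoms$resid)) {
    reject("UNPARSEABLE", "no protein chains (no CA atoms) in input")
  }
  new_pdb_structure(atoms, source_id)
}

#' Read a PDB file from disk
#' @param path file path.
#' @param source_id provenance label; defaults to the file name.
#' @return a `pdb_structure`.
#' @export
read_pdb <- function(path, source_id = basename(path)) {
  parse_pdb(readLines(path, warn = FALSE), source_id = source_id)
}

# Keep the highest-occupancy altloc per (chain, resno, ins, atom);
# ties broken in favour of altloc 'A' (then alphabetical).
resolve_altlocs <- function(atoms) {
  key <- paste(atoms$chain, atoms$resno, atoms$ins, atoms$resid, atoms$atom,
               sep = "\r")
  if (!anyDuplicated(key)) return(atoms)
  pref <- ifelse(atoms$altloc %in% c(" ", "", "A"), "0", atoms$altloc)
  ord <- order(match(key, unique(key)), -atoms$occ, pref)
  atoms <- atoms[ord, ]
  atoms <- atoms[!duplicated(paste(atoms$chain, atoms$resno, atoms$ins,
                                   atoms$resid, atoms$atom, sep = "\r")), ]
  atoms[order(atoms$line), ]
}

# Residue-group bookkeeping: a polymer residue is a group containing both
# N and CA atoms; other HETATM groups are non-polymer (ligands, ions, water).
residue_key <- function(atoms) paste(atoms$chain, atoms$resno, atoms$ins, sep = "\r")

polymer_mask <- function(atoms) {
  key <- residue_key(atoms)
  has_ca <- tapply(atoms$atom == "CA", key, any)
  has_n <- tapply(atoms$atom == "N", key, any)
  poly <- names(has_ca)[has_ca & has_n]
  key %in% poly
}

chain_residue_counts <- function(atoms) {
  atoms <- atoms[polymer_mask(atoms), ]
  key <- residue_key(atoms)
  first <- atoms[!duplicated(key), ]
  table(first$chain)
}

#' Extract the MHC alpha chain and its bound peptide
#'
#' From a raw multi-chain structure, selects exactly one alpha chain and one
#' peptide. When several alpha copies are present (crystallographic
#' asymmetric units), the copy with the most resolved residues wins, ties
#' broken by the lowest original chain id; the peptide is then the
#' peptide-length chain with minimal mean C-alpha distance to that alpha
#' chain's first 180 residues. Beta-2 microglobulin and other chains are
#' discarded.
#'
#' @param raw a `pdb_structure`.
#' @param min_alpha_len minimum residue count to call a chain an alpha chain.
#' @param peptide_bounds allowed peptide length range (inclusive).
#' @return list with `alpha_chain`, `peptide_chain` (original ids) and
#'   `structure`: a `pdb_structure` restricted to those two chains' polymer
#'   residues.
#' @export
extract_alpha_and_peptide <- function(raw, min_alpha_len = 150,
                                      peptide_bounds = c(7, 15)) {
  counts <- chain_residue_counts(raw$atoms)
  alpha_ids <- names(counts)[counts >= min_alpha_len]
  if (length(alpha_ids) == 0) {
    reject("NO_RECEPTOR", sprintf(
      "no chain with >= %d residues in %s", min_alpha_len, raw$source_id))
  }
  pep_ids <- names(counts)[counts >= peptide_bounds[1] &
                           counts <= peptide_bounds[2]]
  if (length(pep_ids) == 0) {
    reject("NO_PEPTIDE", sprintf(
      "no chain of peptide length %d-%d in %s",
      peptide_bounds[1], peptide_bounds[2], raw$source_id))
  }
  # most resolved residues, tie -> lowest chain id
  alpha <- alpha_ids[order(-counts[alpha_ids], alpha_ids)][1]

  poly <- raw$atoms[polymer_mask(raw$atoms), ]
  aat <- poly[poly$chain == alpha, ]
  akey <- residue_key(aat)
  first180 <- unique(akey)[seq_len(min(180, length(unique(akey))))]
  aca <- aat[aat$atom == "CA" & akey %in% first180, c("x", "y", "z")]

  mean_ca_dist <- function(pid) {
    pca <- poly[poly$chain == pid & poly$atom == "CA", c("x", "y", "z")]
    dd <- outer(seq_len(nrow(pca)), seq_len(nrow(aca)), function(i, j) {
      sqrt((pca$x[i] - aca$x[j])^2 + (pca$y[i] - aca$y[j])^2 +
           (pca$z[i] - aca$z[j])^2)
    })
    mean(apply(dd, 1, min))
  }
  dists <- vapply(pep_ids, mean_ca_dist, numeric(1))
  peptide <- pep_ids[order(dists, pep_ids)][1]

  keep <- poly[poly$chain %in% c(alpha, peptide), ]
  keep <- keep[order(keep$line), ]
  list(alpha_chain = alpha, peptide_chain = peptide,
       structure = new_pdb_structure(keep, raw$source_id))
}

#' Substitute tolerated non-canonical residues
#'
#' Canonical residues pass through unchanged. Residues listed in the
#' substitution table are renamed to their canonical parent with the listed
#' atoms deleted (coordinates of kept atoms untouched); e.g. phosphoserine
#' becomes serine by removal of the phospho group. Any other non-canonical
#' polymer residue triggers a `NONCANONICAL` rejection (the template must be
#' dropped).
#'
#' @param s a `pdb_structure` (typically the output of
#'   [extract_alpha_and_peptide()]).
#' @param table substitution table from [load_substitution_table()].
#' @return a `pdb_structure` with canonical residues only.
#' @export
substitute_noncanonical <- function(s, table = load_substitution_table()) {
  atoms <- s$atoms
  key <- residue_key(atoms)
  drop <- rep(FALSE, nrow(atoms))
  for (k in unique(key)) {
    idx <- which(key == k)
    code <- atoms$resid[idx[1]]
    if (is_canonical_aa(code)) next
    row <- match(toupper(code), table$code)
    if (is.na(row)) {
      reject("NONCANONICAL", sprintf(
        "residue %s at %s position %s is not a tolerated non-canonical residue",
        code, atoms$chain[idx[1]], atoms$resno[idx[1]]))
    }
    atoms$resid[idx] <- table$canonical[row]
    atoms$record[idx] <- "ATOM"
    drop[idx] <- atoms$atom[idx] %in% table$delete_atoms[[row]]
  }
  new_pdb_structure(atoms[!drop, ], s$source_id)
}

#' Renumber chains and relabel as M/P
#'
#' Renumbers each chain's residues from 1 in author order (insertion codes
#' flattened into the linear order) and renames the alpha chain to `"M"`,
#' the peptide chain to `"P"`. The old-to-new numbering map is retained for
#' provenance.
#'
#' @param extracted result of [extract_alpha_and_peptide()] (possibly after
#'   [substitute_noncanonical()] on its `$structure`).
#' @param s alternatively, a `pdb_structure` with exactly two chains; the
#'   longer is taken as alpha.
#' @return a `pmhc_structure`.
#' @export
renumber_structure <- function(extracted = NULL, s = NULL) {
  if (is.null(s)) {
    s <- extracted$structure
    alpha <- extracted$alpha_chain
    pep <- extracted$peptide_chain
  } else {
    counts <- chain_residue_counts(s$atoms)
    if (length(counts) != 2) stop("expected exactly two chains")
    alpha <- names(counts)[which.max(counts)]
    pep <- setdiff(names(counts), alpha)
  }
  atoms <- s$atoms
  maps <- list()
  for (spec in list(c(alpha, "M"), c(pep, "P"))) {
    sel <- atoms$chain == spec[1]
    key <- residue_key(atoms)[sel]
    new <- match(key, unique(key))
    maps[[spec[2]]] <- data.frame(
      chain = spec[2],
      old_resno = atoms$resno[sel][!duplicated(key)],
      old_ins = atoms$ins[sel][!duplicated(key)],
      new_resno = unique(new), stringsAsFactors = FALSE)
    atoms$resno[sel] <- new
    atoms$ins[sel] <- ""
    atoms$chain[sel] <- spec[2]
  }
  atoms <- atoms[order(match(atoms$chain, c("M", "P")), atoms$resno), ]
  rownames(atoms) <- NULL
  pmhc_structure(atoms, s$source_id, numbering_map = do.call(rbind, maps))
}

#' Write a pMHC structure as PDB text
#'
#' Emits standard ATOM records (8.3 coordinate fields), M chain before P
#' chain, with TER records. Writing then re-parsing reproduces the structure
#' exactly (names, numbering, coordinates at 3 decimals).
#'
#' @param s a `pmhc_structure`.
#' @param path optional output file; when `NULL` the text is returned.
#' @return character vector of PDB lines (invisibly when writing to a file).
#' @export
write_pdb <- function(s, path = NULL) {
  a <- s$atoms
  if (nrow(a) == 0 || !all(c("M", "P") %in% a$chain)) {
    stop("cannot write structure: missing or empty chain")
  }
  if (!all(is.finite(a$x) & is.finite(a$y) & is.finite(a$z))) {
    stop("cannot write structure: non-finite atom coordinate")
  }
  lines <- character(0)
  serial <- 0L
  for (ch in c("M", "P")) {
    cc <- a[a$chain == ch, ]
    for (i in seq_len(nrow(cc))) {
      serial <- serial + 1L
      nm <- cc$atom[i]
      nm_fmt <- if (nchar(nm) >= 4) substr(nm, 1, 4) else sprintf(" %-3s", nm)
      lines <- c(lines, sprintf(
        "%-6s%5d %s %-3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
        cc$record[i], serial, nm_fmt, cc$resid[i], ch, cc$resno[i],
        cc$x[i], cc$y[i], cc$z[i], cc$occ[i], 0, cc$elem[i]))
    }
    serial <- serial + 1L
    last <- cc[nrow(cc), ]
    lines <- c(lines, sprintf("TER   %5d      %-3s %s%4d",
                              serial, last$resid, ch, last$resno))
  }
  lines <- c(lines, "END")
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}

#' Re-read PDB text as a pMHC structure
#'
#' Convenience inverse of [write_pdb()]: parses text that already uses the
#' M/P chain convention with 1-based contiguous numbering.
#'
#' @param text PDB text (string or lines).
#' @param source_id provenance label.
#' @return a `pmhc_structure`.
#' @export
parse_pmhc <- function(text, source_id = "input") {
  raw <- parse_pdb(text, source_id = source_id)
  atoms <- raw$atoms[polymer_mask(raw$atoms), ]
  rownames(atoms) <- NULL
  pmhc_structure(atoms, source_id)
}

#' Read any pMHC PDB file into normalized form
#'
#' Parses a PDB file and returns a `pmhc_structure`: files already using
#' the M/P convention with 1-based numbering are taken as-is; anything else
#' goes through alpha/peptide extraction, non-canonical substitution and
#' renumbering.
#'
#' @param path PDB file path.
#' @return a `pmhc_structure`.
#' @export
read_structure_normalized <- function(path) {
  raw <- read_pdb(path)
  chains <- unique(raw$atoms$chain[polymer_mask(raw$atoms)])
  if (setequal(chains, c("M", "P"))) {
    return(tryCatch(parse_pmhc(readLines(path, warn = FALSE),
                               source_id = basename(path)),
                    error = function(e) normalize_raw(raw)))
  }
  normalize_raw(raw)
}

normalize_raw <- function(raw) {
  ex <- extract_alpha_and_peptide(raw)
  ex$structure <- substitute_noncanonical(ex$structure)
  renumber_structure(ex)
}

# xyz coordinate matrix of an atom table
atom_xyz <- function(atoms) as.matrix(atoms[, c("x", "y", "z")])
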