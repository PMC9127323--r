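# Template database: curation filters, allele bookkeeping, persistence and
# reference MHC sequence resolution.

#' Parse an MHC allele name into gene / group / protein levels
#'
#' `"HLA-A*02:01"` yields gene `"HLA-A"`, group `"HLA-A*02"`, protein
#' `"HLA-A*02:01"`. Names lacking `'*'` or `':'` degrade gracefully: only
#' the levels that can be read are populated (e.g. `"H2-Kb"` has only a
#' gene). Parsing is lossless: the raw name is retained.
#'
#' @param raw allele name string.
#' @return an `allele_name` object (fields `raw`, `gene`, `group`,
#'   `protein`; absent levels are `NA`).
#' @export
parse_allele <- function(raw) {
  if (!is.character(raw) || length(raw) != 1 || !nzchar(raw)) {
    stop("allele name must be a non-empty string")
  }
  gene <- sub("\\*.*$", "", raw)
  group <- protein <- NA_character_
  if (grepl("*", raw, fixed = TRUE)) {
    rest <- sub("^[^*]*\\*", "", raw)
    fields <- strsplit(rest, ":", fixed = TRUE)[[1]]
    if (length(fields) >= 1 && nzchar(fields[1])) {
      group <- paste0(gene, "*", fields[1])
    }
    if (length(fields) >= 2) {
      protein <- paste0(gene, "*", fields[1], ":", fields[2])
    }
  }
  structure(list(raw = raw, gene = gene, group = group, protein = protein),
            class = "allele_name")
}

#' @export
print.allele_name <- function(x, ...) {
  cat("allele", x$raw, "(gene", x$gene,
      if (!is.na(x$group)) paste("group", x$group),
      if (!is.na(x$protein)) paste("protein", x$protein), ")\n")
  invisible(x)
}

#' Construct a template database entry
#'
#' @param structure a normalized `pmhc_structure`.
#' @param peptide_seq 1-letter peptide sequence (must match the P chain).
#' @param alleles non-empty character vector of G-domain allele names
#'   (one structure can carry several).
#' @param anchors anchor positions on the peptide (>= 2, within range);
#'   default canonical `{2, length}`.
#' @param resolution resolution in Angstrom, or `NA` if unknown.
#' @param source_id unique provenance id (e.g. PDB ID).
#' @return a `template_entry`.
#' @export
template_entry <- function(structure, peptide_seq, alleles, anchors = NULL,
                           resolution = NA_real_, source_id) {
  stopifnot(inherits(structure, "pmhc_structure"))
  np <- chain_length(structure, "P")
  if (nchar(peptide_seq) != np) {
    stop("peptide_seq length does not match the P chain")
  }
  if (length(alleles) == 0) stop("alleles must be non-empty")
  if (is.null(anchors)) anchors <- c(2L, np)
  anchors <- sort(unique(as.integer(anchors)))
  if (length(anchors) < 2 || any(anchors < 1 | anchors > np)) {
    stop("anchors must be >= 2 positions within the peptide")
  }
  structure(list(structure = structure, peptide_seq = peptide_seq,
                 alleles = alleles, anchors = anchors,
                 resolution = as.numeric(resolution), source_id = source_id),
            class = "template_entry")
}

#' Construct a template database
#'
#' @param entries list of `template_entry` objects (unique `source_id`s).
#' @param ref_sequences named character vector: allele name -> MHC protein
#'   sequence.
#' @param build_metadata free-form list (build date, filter settings,
#'   rejection counts).
#' @return a `template_db`.
#' @export
template_db <- function(entries, ref_sequences = character(0),
                        build_metadata = list()) {
  ids <- vapply(entries, function(e) e$source_id, character(1))
  if (anyDuplicated(ids)) stop("duplicate source_id in template database")
  names(entries) <- ids
  structure(list(entries = entries, ref_sequences = ref_sequences,
                 build_metadata = build_metadata),
            class = "template_db")
}

#' @export
print.template_db <- function(x, ...) {
  cat("template_db:", length(x$entries), "entries,",
      length(x$ref_sequences), "reference sequences\n")
  invisible(x)
}

db_settings_defaults <- function() {
  list(peptide_bounds = c(7, 15), min_alpha_len = 150,
       groove_cutoff = 4.0, groove_min_residues = 3,
       substitution_table = load_substitution_table())
}

# Non-polymer HETATM groups excluding water; returns atom table.
ligand_atoms <- function(raw_atoms) {
  lig <- raw_atoms[!polymer_mask(raw_atoms), ]
  lig[!(lig$resid %in% c("HOH", "WAT", "DOD")), ]
}

# A non-amino-acid group sits "inside the binding groove" iff >= 1 of its
# atoms lies within `cutoff` of atoms from >= `min_res` distinct peptide
# residues.
groove_ligand_present <- function(lig, pep_atoms, cutoff = 4.0, min_res = 3) {
  if (nrow(lig) == 0 || nrow(pep_atoms) == 0) return(FALSE)
  pxyz <- atom_xyz(pep_atoms)
  for (i in seq_len(nrow(lig))) {
    p <- c(lig$x[i], lig$y[i], lig$z[i])
    d <- sqrt(rowSums(sweep(pxyz, 2, p)^2))
    if (length(unique(pep_atoms$resno[d <= cutoff])) >= min_res) return(TRUE)
  }
  FALSE
}

#' Apply the template curation filters to one candidate structure
#'
#' A candidate is accepted iff it parses, contains an alpha chain and a
#' peptide of tolerated length, carries no untolerated non-canonical
#' residue, has no non-amino-acid molecule inside the binding groove, and
#' is annotated with at least one allele. Each rejection carries one stable
#' reason code from `{NONCANONICAL, GROOVE_LIGAND, UNPARSEABLE, NO_ALLELE,
#' BAD_LENGTH}`.
#'
#' @param pdb_text PDB text for the candidate (string or lines).
#' @param alleles allele annotation (character vector, possibly empty).
#' @param source_id provenance id.
#' @param anchors optional per-entry anchor override.
#' @param resolution optional resolution annotation.
#' @param settings list of filter settings (see
#'   [build_database()]); missing fields take defaults.
#' @return list with `status` (`"accepted"`/`"rejected"`); on accept an
#'   `entry` (`template_entry`), on reject a `reason` code and `message`.
#' @export
apply_filters <- function(pdb_text, alleles, source_id = "candidate",
                          anchors = NULL, resolution = NA_real_,
                          settings = list()) {
  cfg <- utils::modifyList(db_settings_defaults(), settings)
  as_rejection <- function(cond) {
    reason <- rejection_reason(cond)
    reason <- switch(reason, NO_PEPTIDE = "BAD_LENGTH",
                     NO_RECEPTOR = "UNPARSEABLE", reason)
    list(status = "rejected", reason = reason,
         message = conditionMessage(cond), source_id = source_id)
  }
  tryCatch({
    raw <- parse_pdb(pdb_text, source_id = source_id)
    ex <- extract_alpha_and_peptide(raw, min_alpha_len = cfg$min_alpha_len,
                                    peptide_bounds = cfg$peptide_bounds)
    clean <- substitute_noncanonical(ex$structure, cfg$substitution_table)
    pep_atoms <- clean$atoms[clean$atoms$chain == ex$peptide_chain, ]
    if (groove_ligand_present(ligand_atoms(raw$atoms), pep_atoms,
                              cfg$groove_cutoff, cfg$groove_min_residues)) {
      reject("GROOVE_LIGAND", sprintf(
        "non-amino-acid molecule inside the binding groove of %s", source_id))
    }
    if (length(alleles) == 0 || all(!nzchar(alleles))) {
      reject("NO_ALLELE", sprintf("no allele annotation for %s", source_id))
    }
    ex$structure <- clean
    norm <- renumber_structure(ex)
    entry <- template_entry(norm, peptide_sequence(norm), alleles,
                            anchors = anchors, resolution = resolution,
                            source_id = source_id)
    list(status = "accepted", entry = entry, source_id = source_id)
  }, anchormod_rejection = as_rejection)
}

#' Build a cleaned template database
#'
#' Runs every input structure through [apply_filters()]; the database
#' contains exactly the accepted entries, and the build metadata partitions
#' the inputs into accepted plus one rejection reason each.
#'
#' @param structures named list of PDB texts, or a character vector of PDB
#'   file paths (names/source ids taken from file names).
#' @param annotations data.frame with columns `source_id`, `alleles`
#'   (';'-separated), and optionally `anchors` (';'-separated positions)
#'   and `resolution`.
#' @param ref_fasta optional path(s) to FASTA files of reference MHC
#'   sequences keyed by allele name.
#' @param settings filter settings overriding the defaults
#'   (`peptide_bounds`, `min_alpha_len`, `groove_cutoff`,
#'   `groove_min_residues`, `substitution_table`).
#' @return a `template_db`.
#' @export
build_database <- function(structures, annotations, ref_fasta = NULL,
                           settings = list()) {
  if (is.character(structures)) {
    paths <- structures
    structures <- lapply(paths, function(p) readLines(p, warn = FALSE))
    names(structures) <- sub("\\.pdb$", "", basename(paths))
  }
  if (length(structures) == 0) stop("no input structures")
  ids <- names(structures)
  entries <- list()
  counts <- c(accepted = 0L, NONCANONICAL = 0L, GROOVE_LIGAND = 0L,
              UNPARSEABLE = 0L, NO_ALLELE = 0L, BAD_LENGTH = 0L)
  log <- list()
  for (id in ids) {
    ann <- annotations[annotations$source_id == id, , drop = FALSE]
    alleles <- if (nrow(ann) == 1 && nzchar(ann$alleles)) {
      strsplit(ann$alleles, ";", fixed = TRUE)[[1]]
    } else character(0)
    anchors <- if (nrow(ann) == 1 && "anchors" %in% names(ann) &&
                   !is.na(ann$anchors) && nzchar(ann$anchors)) {
      as.integer(strsplit(ann$anchors, ";", fixed = TRUE)[[1]])
    } else NULL
    resolution <- if (nrow(ann) == 1 && "resolution" %in% names(ann)) {
      as.numeric(ann$resolution)
    } else NA_real_
    res <- apply_filters(structures[[id]], alleles, source_id = id,
                         anchors = anchors, resolution = resolution,
                         settings = settings)
    if (res$status == "accepted") {
      entries[[length(entries) + 1L]] <- res$entry
      counts["accepted"] <- counts["accepted"] + 1L
    } else {
      counts[res$reason] <- counts[res$reason] + 1L
    }
    log[[id]] <- res[setdiff(names(res), "entry")]
  }
  if (length(entries) == 0) stop("empty database: no structure passed the filters")
  refseqs <- character(0)
  if (!is.null(ref_fasta)) {
    for (f in ref_fasta) {
      ss <- Biostrings::readAAStringSet(f)
      refseqs[names(ss)] <- as.character(ss)
    }
  }
  template_db(entries, ref_sequences = refseqs,
              build_metadata = list(date = format(Sys.Date()),
                                    settings = settings,
                                    counts = as.list(counts),
                                    log = log))
}

DB_FORMAT_VERSION <- "anchormod-db-1"

#' Save / load a template database archive
#'
#' The archive is a single versioned JSON file; loading a file whose
#' version header does not match raises an explicit incompatibility error.
#' `load_database(save_database(db, path))` reproduces the database.
#'
#' @param db a `template_db`.
#' @param path archive path.
#' @return `save_database` the path (invisibly); `load_database` a
#'   `template_db`.
#' @export
save_database <- function(db, path) {
  ser_entry <- function(e) {
    a <- e$structure$atoms
    list(source_id = e$source_id, peptide_seq = e$peptide_seq,
         alleles = as.list(e$alleles), anchors = as.list(e$anchors),
         resolution = e$resolution,
         atoms = list(record = a$record, chain = a$chain, resno = a$resno,
                      resid = a$resid, atom = a$atom,
                      x = round(a$x, 3), y = round(a$y, 3), z = round(a$z, 3),
                      occ = a$occ, elem = a$elem))
  }
  payload <- list(
    format = DB_FORMAT_VERSION,
    entries = lapply(unname(db$entries), ser_entry),
    ref_sequences = as.list(db$ref_sequences),
    build_metadata = db$build_metadata)
  json <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA,
                           null = "null", na = "null")
  writeLines(json, path)
  invisible(path)
}

#' @rdname save_database
#' @export
load_database <- function(path) {
  payload <- tryCatch(
    jsonlite::read_json(path, simplifyVector = FALSE),
    error = function(e) stop("incompatible or corrupt database file: ",
                             conditionMessage(e)))
  if (!identical(payload$format, DB_FORMAT_VERSION)) {
    stop("incompatible database file: expected format '", DB_FORMAT_VERSION,
         "', found '", payload$format %||% "<missing>", "'")
  }
  de_entry <- function(x) {
    a <- x$atoms
    n <- length(a$atom)
    atoms <- data.frame(
      record = unlist(a$record), chain = unlist(a$chain),
      resno = as.integer(unlist(a$resno)), ins = rep("", n),
      resid = unlist(a$resid), atom = unlist(a$atom),
      x = as.numeric(unlist(a$x)), y = as.numeric(unlist(a$y)),
      z = as.numeric(unlist(a$z)), occ = as.numeric(unlist(a$occ)),
      elem = unlist(a$elem), line = rep(NA_integer_, n),
      stringsAsFactors = FALSE)
    template_entry(pmhc_structure(atoms, x$source_id),
                   peptide_seq = x$peptide_seq,
                   alleles = unlist(x$alleles),
                   anchors = as.integer(unlist(x$anchors)),
                   resolution = if (is.null(x$resolution)) NA_real_ else
                     as.numeric(x$resolution),
                   source_id = x$source_id)
  }
  template_db(lapply(payload$entries, de_entry),
              ref_sequences = unlist(payload$ref_sequences) %||% character(0),
              build_metadata = payload$build_metadata)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Resolve the MHC sequence for a modelling target
#'
#' Priority: a user-provided sequence on the target; else the reference
#' sequence for the exact allele; else a reference sequence from any allele
#' in the same allele group (with a warning).
#'
#' @param db a `template_db` with reference sequences.
#' @param target a `modelling_target`.
#' @return MHC protein sequence string.
#' @export
resolve_mhc_sequence <- function(db, target) {
  if (!is.null(target$mhc_seq) && nzchar(target$mhc_seq)) {
    return(target$mhc_seq)
  }
  refs <- db$ref_sequences
  al <- parse_allele(target$allele)
  hit <- which(names(refs) == al$raw)
  if (length(hit) == 0 && !is.na(al$protein)) {
    hit <- which(names(refs) == al$protein)
  }
  if (length(hit) >= 1) return(unname(refs[hit[1]]))
  if (!is.na(al$group)) {
    groups <- vapply(names(refs), function(a) parse_allele(a)$group,
                     character(1))
    gh <- which(!is.na(groups) & groups == al$group)
    if (length(gh) >= 1) {
      warning("no reference sequence for allele ", al$raw,
              "; using group representative ", names(refs)[gh[1]])
      return(unname(refs[gh[1]]))
    }
  }
  stop("no MHC sequence resolvable for allele ", al$raw,
       "; available alleles: ",
       paste(utils::head(sort(names(refs)), 10), collapse = ", "))
}

#' Contact-based anchor heuristic (synthetic stand-in)
#'
#' Estimates the two anchor positions of a bound peptide as the positions
#' with the largest count of side-chain heavy atoms within `cutoff` of
#' M-chain atoms, restricted to windows `{1,2,3}` and `{len-2,len-1,len}`.
#' This is a documented heuristic stand-in for anchor assignment from a
#' structure; curation defaults remain the canonical `{2, len}`.
#'
#' @param s a `pmhc_structure`.
#' @param cutoff contact distance in Angstrom.
#' @return integer vector of two anchor positions.
#' @export
anchors_from_contacts <- function(s, cutoff = 4.5) {
  a <- s$atoms
  m_xyz <- atom_xyz(a[a$chain == "M", ])
  pep <- a[a$chain == "P", ]
  len <- max(pep$resno)
  contacts <- vapply(seq_len(len), function(p) {
    sc <- pep[pep$resno == p & !(pep$atom %in% c("N", "CA", "C", "O")), ]
    if (nrow(sc) == 0) return(0L)
    sum(vapply(seq_len(nrow(sc)), function(i) {
      d <- sqrt(rowSums(sweep(m_xyz, 2, c(sc$x[i], sc$y[i], sc$z[i]))^2))
      sum(d <= cutoff)
    }, integer(1)))
  }, integer(1))
  w1 <- 1:3
  w2 <- (len - 2):len
  c(w1[which.max(contacts[w1])], w2[which.max(contacts[w2])])
}
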