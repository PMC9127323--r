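# Deterministic synthetic pMHC fixtures.
#
# The pseudo-MHC scaffold is NOT a real fold: it is 180 numbered residues
# assembled from ideally-built segments (two groove walls, a floor strand,
# and two compact pocket clusters beneath the anchor side chains) so that
# chain extraction, renumbering, G-domain superposition, the groove-ligand
# filter and the contact-based anchor heuristic can all be exercised with
# no downloads. Everything here is synthetic by construction and labelled
# as such.

#' Build an ideal-geometry peptide chain
#'
#' Constructs backbone atoms (N, CA, C, O) plus CB (absent for glycine)
#' from ideal bond lengths (N-CA 1.46, CA-C 1.52, C-N 1.33 A) and canonical
#' backbone dihedrals for the requested conformation.
#'
#' @param sequence 1-letter amino-acid string (1-20 residues).
#' @param conformation `"extended"` (beta-like) or `"helix"` (alpha helix).
#' @param chain chain id for the emitted atoms.
#' @return atom table (one row per atom) in the package's internal layout.
#' @export
make_ideal_peptide <- function(sequence, conformation = c("extended", "helix"),
                               chain = "P") {
  if (nchar(sequence) < 1 || nchar(sequence) > 20) {
    stop("sequence must have 1-20 residues")
  }
  build_ideal_chain(sequence, conformation, chain)
}

# unbounded-length ideal chain builder (scaffold segments exceed 20 residues)
build_ideal_chain <- function(sequence, conformation = c("extended", "helix"),
                              chain = "P") {
  conformation <- match.arg(conformation)
  letters1 <- strsplit(toupper(sequence), "")[[1]]
  res3 <- aa1to3(letters1)  # errors on invalid letters
  g <- IDEAL_GEOM
  pp <- g$phi_psi[[conformation]]
  phi <- pp[1]; psi <- pp[2]
  n <- length(res3)

  N <- CA <- CC <- matrix(NA_real_, n, 3)
  N[1, ] <- c(0, 0, 0)
  CA[1, ] <- c(g$b_n_ca, 0, 0)
  CC[1, ] <- place_atom(c(0, 0, 1), N[1, ], CA[1, ], g$b_ca_c, g$a_n_ca_c, 0)
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      N[i + 1, ] <- place_atom(N[i, ], CA[i, ], CC[i, ], g$b_c_n, g$a_ca_c_n, psi)
      CA[i + 1, ] <- place_atom(CA[i, ], CC[i, ], N[i + 1, ], g$b_n_ca,
                                g$a_c_n_ca, g$omega)
      CC[i + 1, ] <- place_atom(CC[i, ], N[i + 1, ], CA[i + 1, ], g$b_ca_c,
                                g$a_n_ca_c, phi)
    }
  }
  rows <- list()
  for (i in seq_len(n)) {
    O <- place_atom(N[i, ], CA[i, ], CC[i, ], g$b_c_o, g$a_ca_c_o, psi + 180)
    at <- rbind(N = N[i, ], CA = CA[i, ], C = CC[i, ], O = O)
    if (res3[i] != "GLY") {
      CB <- place_atom(N[i, ], CC[i, ], CA[i, ], g$b_ca_cb, g$a_c_ca_cb,
                       g$t_n_c_ca_cb)
      at <- rbind(at, CB = CB)
    }
    rows[[i]] <- data.frame(
      record = "ATOM", chain = chain, resno = i, ins = "",
      resid = res3[i], atom = rownames(at),
      x = at[, 1], y = at[, 2], z = at[, 3], occ = 1,
      elem = substr(rownames(at), 1, 1), line = NA_integer_,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Evaluate expr with a temporary RNG state seeded from `seed`.
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Deterministic pseudo-MHC scaffold sequence for an allele name.
allele_scaffold_sequence <- function(allele) {
  seed <- sum(utf8ToInt(allele)) %% 100000L + 17L
  with_local_seed(seed, paste(sample(AA1, 180, replace = TRUE), collapse = ""))
}

# Rigid placement helpers for scaffold segments
translate_atoms <- function(atoms, dx) {
  atoms$x <- atoms$x + dx[1]; atoms$y <- atoms$y + dx[2]
  atoms$z <- atoms$z + dx[3]; atoms
}

center_atoms <- function(atoms) {
  ca <- atoms[atoms$atom == "CA", ]
  translate_atoms(atoms, -c(mean(ca$x), mean(ca$y), mean(ca$z)))
}

rotate_atoms <- function(atoms, rot) {
  xyz <- atom_xyz(atoms) %*% t(rot)
  atoms$x <- xyz[, 1]; atoms$y <- xyz[, 2]; atoms$z <- xyz[, 3]
  atoms
}

# projection of the atom closest to the origin along direction u
pocket_near_end <- function(atoms, u) {
  proj <- atom_xyz(atoms) %*% u
  u * min(proj)
}

# Assemble the 180-residue pseudo-MHC scaffold around a placed peptide.
# Residues 1-60 wall A, 61-120 wall B, 121-140 floor strand,
# 141-160 pocket cluster under anchor 1, 161-180 under anchor 2.
build_scaffold <- function(mhc_seq, pep_atoms, anchors, chain = "A") {
  stopifnot(nchar(mhc_seq) == 180)
  seg <- function(from, to, conf) {
    build_ideal_chain(substr(mhc_seq, from, to), conf, chain = chain)
  }
  wall_a <- translate_atoms(center_atoms(seg(1, 60, "extended")), c(0, -6, 1))
  wall_b <- translate_atoms(center_atoms(seg(61, 120, "extended")), c(0, 6, 1))
  floorS <- translate_atoms(center_atoms(seg(121, 140, "extended")), c(0, 0, -8))
  pocket <- function(from, to, anchor_pos) {
    h <- center_atoms(seg(from, to, "helix"))
    res <- pep_atoms[pep_atoms$resno == anchor_pos, ]
    ca <- as.numeric(res[res$atom == "CA", c("x", "y", "z")])
    cb <- res[res$atom == "CB", c("x", "y", "z")]
    tip <- if (nrow(cb) == 1) as.numeric(cb) else ca
    u <- tip - ca
    u <- if (sqrt(sum(u^2)) < 1e-6) c(0, 0, -1) else u / sqrt(sum(u^2))
    # orient the pocket helix axis along u so it extends away from the
    # peptide: its footprint stays local to the anchor position
    hca <- atom_xyz(h[h$atom == "CA", ])
    axis <- svd(scale(hca, scale = FALSE))$v[, 1]
    ends <- hca[nrow(hca), ] - hca[1, ]
    if (sum(axis * ends) < 0) axis <- -axis
    h <- rotate_atoms(h, rotation_to(axis, u))
    h <- translate_atoms(h, -pocket_near_end(h, u))
    translate_atoms(h, tip + 2.5 * u)
  }
  anchors <- sort(anchors)
  p1 <- pocket(141, 160, anchors[1])
  p2 <- pocket(161, 180, anchors[length(anchors)])
  parts <- list(wall_a, wall_b, floorS, p1, p2)
  offs <- c(0, 60, 120, 140, 160)
  for (k in seq_along(parts)) parts[[k]]$resno <- parts[[k]]$resno + offs[k]
  do.call(rbind, parts)
}

# Find a point that the groove-ligand filter must flag: within `cutoff` of
# atoms from >= 3 distinct peptide residues. Grid search near the backbone.
groove_ligand_site <- function(pep_atoms, cutoff = 3.6) {
  ca <- pep_atoms[pep_atoms$atom == "CA", ]
  mid <- floor(nrow(ca) / 2)
  base <- as.numeric(ca[mid, c("x", "y", "z")])
  dirv <- as.numeric(ca[mid + 1, c("x", "y", "z")]) - base
  dirv <- dirv / sqrt(sum(dirv^2))
  xyz <- atom_xyz(pep_atoms)
  best <- NULL; best_n <- 0
  for (t in seq(-2, 5.8, by = 0.2)) {
    for (zoff in seq(0.8, 2.4, by = 0.2)) {
      p <- base + t * dirv + c(0, 0, zoff)
      d <- sqrt(rowSums(sweep(xyz, 2, p)^2))
      nres <- length(unique(pep_atoms$resno[d <= cutoff]))
      if (nres > best_n) { best_n <- nres; best <- p }
    }
  }
  if (best_n < 3) stop("internal: could not place groove ligand")
  best
}

FIXTURE_DEFECTS <- c("noncanonical_residue", "groove_ligand", "corrupt_record",
                     "missing_allele", "short_peptide")

#' Generate a synthetic pMHC PDB fixture
#'
#' Emits author-style PDB text (MHC alpha as chain `"A"` numbered from 3,
#' peptide as chain `"C"` numbered from 1001, optionally a 30-residue decoy
#' chain `"B"` standing in for beta-2 microglobulin) together with
#' ground-truth metadata. Defect flags inject exactly one curation failure
#' each; the expected filter outcome is returned alongside.
#'
#' @param peptide_seq 1-letter peptide sequence.
#' @param anchors anchor positions; default canonical `{2, length}`.
#' @param alleles character vector of allele names annotated for the entry.
#' @param source_id provenance id embedded in the metadata.
#' @param defects subset of
#'   `c("noncanonical_residue","groove_ligand","corrupt_record",
#'   "missing_allele","short_peptide")`.
#' @param seed integer seed controlling the coordinate noise.
#' @param conformation peptide conformation passed to [make_ideal_peptide()].
#' @param noise standard deviation (Angstrom) of Gaussian coordinate noise.
#' @param tolerated_noncanonical if `TRUE`, turn one peptide serine-slot
#'   residue into phosphoserine (tolerated; exercises substitution).
#' @param include_decoy_chain include the beta-2-microglobulin-like decoy.
#' @return list with `pdb_text`, `peptide_seq`, `anchors`, `alleles`,
#'   `source_id`, `resolution`, `expected` (`"ACCEPT"` or a reason code).
#' @export
make_toy_pmhc <- function(peptide_seq, anchors = NULL,
                          alleles = "HLA-A*02:01", source_id = "FIX001",
                          defects = character(), seed = 1,
                          conformation = "extended", noise = 0,
                          tolerated_noncanonical = FALSE,
                          include_decoy_chain = TRUE) {
  stopifnot(all(defects %in% FIXTURE_DEFECTS))
  np <- nchar(peptide_seq)
  if ("short_peptide" %in% defects && np >= 7) {
    stop("contradictory flags: short_peptide requires a peptide of < 7 residues")
  }
  if (!("short_peptide" %in% defects) && (np < 7 || np > 15)) {
    stop("peptide length must be 7-15 (or flag short_peptide)")
  }
  if (is.null(anchors)) anchors <- c(2, np)
  anchors <- sort(unique(as.integer(anchors)))
  stopifnot(all(anchors >= 1 & anchors <= np), length(anchors) >= 2)

  with_local_seed(seed, {
    pep <- center_atoms(make_ideal_peptide(peptide_seq, conformation, chain = "C"))
    mhc_seq <- allele_scaffold_sequence(alleles[1])
    mhc <- build_scaffold(mhc_seq, pep, anchors, chain = "A")

    if (tolerated_noncanonical) {
      pos <- setdiff(seq_len(np), anchors)
      pos <- pos[pos > 1][1]
      sel <- pep$resno == pos
      pep$resid[sel] <- "SEP"
      pep$record[sel] <- "HETATM"
      cb <- pep[sel & pep$atom == "CB", c("x", "y", "z")]
      org <- if (nrow(cb) == 1) as.numeric(cb) else
        as.numeric(pep[sel & pep$atom == "CA", c("x", "y", "z")])
      ph <- data.frame(record = "HETATM", chain = "C", resno = pos, ins = "",
                       resid = "SEP", atom = c("P", "O1P", "O2P", "O3P"),
                       x = org[1] + c(0, 1.2, -1.2, 0),
                       y = org[2] + c(0, 0.8, 0.8, -1.2),
                       z = org[3] + c(1.6, 2.4, 2.4, 2.4),
                       occ = 1, elem = c("P", "O", "O", "O"),
                       line = NA_integer_, stringsAsFactors = FALSE)
      pep <- rbind(pep, ph)
    }
    if ("noncanonical_residue" %in% defects) {
      pos <- setdiff(seq_len(np), anchors)
      pos <- pos[pos > 1][1]
      sel <- pep$resno == pos
      pep$resid[sel] <- "ABA"
      pep$record[sel] <- "HETATM"
    }

    lig <- NULL
    if ("groove_ligand" %in% defects) {
      p <- groove_ligand_site(pep)
      lig <- data.frame(record = "HETATM", chain = "X", resno = 1, ins = "",
                        resid = "LIG", atom = c("C1", "O1", "O2"),
                        x = p[1] + c(0, 0.8, -0.8), y = p[2] + c(0, 0.5, 0.5),
                        z = p[3] + c(0, 0.6, 0.6),
                        occ = 1, elem = c("C", "O", "O"),
                        line = NA_integer_, stringsAsFactors = FALSE)
    }

    decoy <- NULL
    if (include_decoy_chain) {
      dseq <- paste(sample(AA1, 30, replace = TRUE), collapse = "")
      decoy <- translate_atoms(center_atoms(
        build_ideal_chain(dseq, "extended", chain = "B")), c(0, 0, -20))
    }

    # author-style numbering offsets
    mhc$resno <- mhc$resno + 2L
    pep$resno <- pep$resno + 1000L
    atoms <- rbind(mhc, if (!is.null(decoy)) decoy, pep, lig)
    if (noise > 0) {
      atoms$x <- atoms$x + stats::rnorm(nrow(atoms), 0, noise)
      atoms$y <- atoms$y + stats::rnorm(nrow(atoms), 0, noise)
      atoms$z <- atoms$z + stats::rnorm(nrow(atoms), 0, noise)
    }

    text <- write_raw_pdb(atoms)
    if ("corrupt_record" %in% defects) {
      atom_lines <- grep("^(ATOM|HETATM)", text)
      k <- atom_lines[min(10, length(atom_lines))]
      substr(text[k], 31, 38) <- " 12.3x45"
    }

    expected <- "ACCEPT"
    if ("corrupt_record" %in% defects) expected <- "UNPARSEABLE"
    else if ("noncanonical_residue" %in% defects) expected <- "NONCANONICAL"
    else if ("groove_ligand" %in% defects) expected <- "GROOVE_LIGAND"
    else if ("short_peptide" %in% defects) expected <- "BAD_LENGTH"
    if ("missing_allele" %in% defects) {
      alleles <- character(0)
      if (expected == "ACCEPT") expected <- "NO_ALLELE"
    }

    list(pdb_text = text, peptide_seq = peptide_seq, anchors = anchors,
         alleles = alleles, source_id = source_id,
         resolution = round(stats::runif(1, 1.2, 3.0), 2),
         mhc_seq = mhc_seq, expected = expected)
  })
}

# Generic author-style PDB writer for fixture atom tables (any chains).
write_raw_pdb <- function(atoms) {
  lines <- character(nrow(atoms))
  for (i in seq_len(nrow(atoms))) {
    nm <- atoms$atom[i]
    nm_fmt <- if (nchar(nm) >= 4) substr(nm, 1, 4) else sprintf(" %-3s", nm)
    lines[i] <- sprintf(
      "%-6s%5d %s %-3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      atoms$record[i], i, nm_fmt, atoms$resid[i], atoms$chain[i],
      atoms$resno[i], atoms$x[i], atoms$y[i], atoms$z[i], atoms$occ[i], 0,
      atoms$elem[i])
  }
  c(lines, "END")
}

# Smooth, chain-correlated coordinate perturbation: every atom of a residue
# shares one displacement vector, and the per-residue vectors are a moving
# average of iid Gaussians along the chain, rescaled so the per-component
# RMS displacement equals `sd`. This emulates a conformational difference
# between two structures (what cross-docking noise is) while preserving
# covalent geometry within residues and keeping junction-bond strain small
# -- unlike iid per-atom noise, which would break bond lengths in a way no
# crystal structure does.
perturb_structure_smooth <- function(s, sd, window = 5, max_disp = 0.95) {
  if (sd <= 0) return(s)
  a <- s$atoms
  for (ch in unique(a$chain)) {
    sel <- a$chain == ch
    resnos <- sort(unique(a$resno[sel]))
    nr <- length(resnos)
    raw <- matrix(stats::rnorm(nr * 3), nr, 3)
    if (nr >= window) {
      pad <- (window - 1) / 2
      padded <- rbind(raw[rep(1, pad), , drop = FALSE], raw,
                      raw[rep(nr, pad), , drop = FALSE])
      sm <- apply(padded, 2, function(v)
        stats::filter(v, rep(1 / window, window), sides = 2))
      sm <- sm[(pad + 1):(pad + nr), , drop = FALSE]
    } else sm <- raw
    sm <- sm * (sd / max(sqrt(mean(sm^2)), 1e-12))
    worst <- max(sqrt(rowSums(sm^2)))
    if (worst > max_disp) sm <- sm * (max_disp / worst)  # keep it sub-Angstrom
    ri <- match(a$resno[sel], resnos)
    a$x[sel] <- a$x[sel] + sm[ri, 1]
    a$y[sel] <- a$y[sel] + sm[ri, 2]
    a$z[sel] <- a$z[sel] + sm[ri, 3]
  }
  s$atoms <- a
  s
}

# Build a normalized pmhc_structure fixture directly (no text round trip).
fixture_structure <- function(peptide_seq, anchors, allele, source_id,
                              conformation = "extended", seed = 1, noise = 0) {
  with_local_seed(seed, {
    pep <- center_atoms(make_ideal_peptide(peptide_seq, conformation, chain = "P"))
    mhc_seq <- allele_scaffold_sequence(allele)
    mhc <- build_scaffold(mhc_seq, pep, anchors, chain = "M")
    atoms <- rbind(mhc, pep)
    if (noise > 0) {
      atoms$x <- atoms$x + stats::rnorm(nrow(atoms), 0, noise)
      atoms$y <- atoms$y + stats::rnorm(nrow(atoms), 0, noise)
      atoms$z <- atoms$z + stats::rnorm(nrow(atoms), 0, noise)
    }
    rownames(atoms) <- NULL
    pmhc_structure(atoms, source_id)
  })
}

#' Generate a synthetic cross-docking cohort
#'
#' Builds `n_cases` matched (target, reference, template) triples: each
#' reference is a synthetic pMHC complex and its template is a seeded
#' perturbation of it (peptide point mutations plus sub-Angstrom coordinate
#' noise), giving cross-docking-style cases with known ground truth. Each
#' case uses its own synthetic allele so template selection resolves at the
#' exact-allele tier.
#'
#' @param n_cases number of cases (>= 1).
#' @param seed master seed; all case-level seeds derive from it.
#' @param peptide_lengths candidate peptide lengths, sampled per case.
#' @param n_mutations peptide point mutations applied to the template
#'   (never at anchor positions).
#' @param coord_noise sd (Angstrom) of template coordinate noise; `0` makes
#'   template and reference identical (self-docking).
#' @param anchor_mode `"canonical"` for anchors `{2, len}`,
#'   `"noncanonical"` for anchors `{1, len - 1}`.
#' @param conformation peptide conformation for the references.
#' @param n_models,preset run parameters stored on each target.
#' @return list with `cases` (each: `target`, `reference`, `template_id`)
#'   and `db` (a `template_db` holding one template per case).
#' @export
make_benchmark_cohort <- function(n_cases, seed = 1,
                                  peptide_lengths = 8:10,
                                  n_mutations = 2, coord_noise = 0.3,
                                  anchor_mode = c("canonical", "noncanonical"),
                                  conformation = "extended",
                                  n_models = 5, preset = "default") {
  stopifnot(n_cases >= 1)
  anchor_mode <- match.arg(anchor_mode)
  cases <- vector("list", n_cases)
  entries <- list()
  refseqs <- character(0)
  for (i in seq_len(n_cases)) {
    cseed <- (seed * 131L + i * 1013L) %% 2147483600L
    parms <- with_local_seed(cseed, {
      len <- if (length(peptide_lengths) > 1) sample(peptide_lengths, 1) else
        peptide_lengths
      pep <- paste(sample(AA1, len, replace = TRUE), collapse = "")
      list(len = len, pep = pep,
           res = round(stats::runif(1, 1.2, 3.0), 2))
    })
    len <- parms$len
    anchors <- if (anchor_mode == "canonical") c(2L, len) else
      c(1L, len - 1L)
    allele <- sprintf("SYN-A*%02d:01", i)
    ref <- fixture_structure(parms$pep, anchors, allele,
                             source_id = sprintf("REF%03d", i),
                             conformation = conformation, seed = cseed)
    tmpl <- with_local_seed(cseed + 7L, {
      s <- ref
      s$source_id <- sprintf("TMP%03d", i)
      pseq <- strsplit(parms$pep, "")[[1]]
      if (n_mutations > 0) {
        mutable <- setdiff(seq_len(len), anchors)
        pos <- sample(mutable, min(n_mutations, length(mutable)))
        for (p in pos) {
          new1 <- sample(setdiff(setdiff(AA1, "G"), pseq[p]), 1)
          pseq[p] <- new1
          s$atoms$resid[s$atoms$chain == "P" & s$atoms$resno == p] <- aa1to3(new1)
        }
      }
      s <- perturb_structure_smooth(s, coord_noise)
      list(structure = s, peptide_seq = paste(pseq, collapse = ""))
    })
    entries[[i]] <- template_entry(
      structure = tmpl$structure, peptide_seq = tmpl$peptide_seq,
      alleles = allele, anchors = anchors, resolution = parms$res,
      source_id = tmpl$structure$source_id)
    refseqs[allele] <- allele_scaffold_sequence(allele)
    cases[[i]] <- list(
      target = modelling_target(parms$pep, allele, anchors = anchors,
                                n_models = n_models, seed = cseed,
                                preset = preset),
      reference = ref,
      template_id = tmpl$structure$source_id)
  }
  db <- template_db(entries, ref_sequences = refseqs,
                    build_metadata = list(built = "synthetic-cohort",
                                          seed = seed, n_cases = n_cases))
  list(cases = cases, db = db)
}

#' Write reference MHC sequences for synthetic alleles as FASTA
#'
#' @param alleles character vector of allele names.
#' @param path output FASTA path.
#' @return the path, invisibly.
#' @export
write_fixture_ref_fasta <- function(alleles, path) {
  lines <- unlist(lapply(alleles, function(a) {
    c(paste0(">", a), allele_scaffold_sequence(a))
  }))
  writeLines(lines, path)
  invisible(path)
}
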