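# Anchor-restrained peptide loop modelling.
#
# The pipeline grafts the target onto the selected template (MHC backbone
# copied, peptide backbone copied column-by-column from the anchor-driven
# alignment), then produces n_models peptide models by randomizing the
# non-anchor loop atoms by +/- 5 A and running a short two-phase restrained
# energy minimization. Models are ranked by the final minimization
# objective E (the package's surrogate for an engine-internal score such
# as molpdf: lower is better, and the identical-case shortcut model is
# assigned the minimum generated score minus one).

#' Construct a modelling target
#'
#' @param peptide_seq 1-letter peptide sequence (7-15 residues).
#' @param allele MHC allele name (G-domain style, e.g. `"HLA-A*02:01"`).
#' @param anchors anchor positions; default the canonical `{2, length}`.
#' @param mhc_seq optional user-provided MHC protein sequence (takes
#'   priority over reference-sequence lookup).
#' @param ss_restraints optional secondary-structure restraint spec: a list
#'   of `list(start, end, kind)` with kind `"helix"` or `"strand-pair"`.
#' @param n_models number of models to generate (default 20).
#' @param seed integer seed; model `i` uses stream `seed + i`.
#' @param preset refinement preset: `"fast"`, `"default"` or `"thorough"`
#'   (scales minimization iteration counts by 0.5 / 1 / 4).
#' @return a `modelling_target`.
#' @export
modelling_target <- function(peptide_seq, allele, anchors = NULL,
                             mhc_seq = NULL, ss_restraints = NULL,
                             n_models = 20, seed = 1,
                             preset = c("default", "fast", "thorough")) {
  preset <- match.arg(preset)
  len <- nchar(peptide_seq)
  if (len < 7 || len > 15) stop("peptide length must be 7-15")
  aa1to3(strsplit(peptide_seq, "")[[1]])  # validates letters
  if (is.null(anchors)) anchors <- c(2L, len)
  anchors <- sort(unique(as.integer(anchors)))
  if (length(anchors) < 2 || any(anchors < 1 | anchors > len)) {
    stop("anchors must be >= 2 positions within the peptide")
  }
  if (n_models < 1) stop("n_models must be >= 1")
  structure(list(peptide_seq = peptide_seq, allele = allele,
                 anchors = anchors, mhc_seq = mhc_seq,
                 ss_restraints = ss_restraints,
                 n_models = as.integer(n_models), seed = as.integer(seed),
                 preset = preset),
            class = "modelling_target")
}

#' Default restraint weights and geometry parameters
#'
#' Weights are in 1/A^2 units on squared-deviation terms; `d_min` is the
#' minimum tolerated non-bonded distance.
#' @return named list: `w_bond`, `w_clash`, `w_anchor`, `w_ss`, `d_min`.
#' @export
default_restraint_weights <- function() {
  list(w_bond = 10, w_clash = 5, w_anchor = 100, w_ss = 10, d_min = 2.8)
}

preset_iterations <- function(preset) {
  base <- c(phase1 = 200L, phase2 = 300L)
  mult <- switch(preset, fast = 0.5, default = 1, thorough = 4)
  stats::setNames(as.integer(round(base * mult)), names(base))
}

.blosum_cache <- new.env(parent = emptyenv())

blosum62 <- function() {
  if (is.null(.blosum_cache$m)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    .blosum_cache$m <- e$BLOSUM62
  }
  .blosum_cache$m
}

#' Global pairwise alignment of MHC sequences
#'
#' Needleman-Wunsch global alignment with affine gap penalties and
#' BLOSUM62 scoring, used to map template MHC residues onto the target
#' MHC sequence.
#'
#' @param target_seq,template_seq MHC protein sequences.
#' @param gap_opening,gap_extension affine gap costs (positive).
#' @return list with `target_row`, `template_row` (gapped, equal length)
#'   and `score`.
#' @export
align_mhc <- function(target_seq, template_seq,
                      gap_opening = 10, gap_extension = 4) {
  for (s in c(target_seq, template_seq)) {
    if (!nzchar(s)) stop("empty MHC sequence")
    if (!all(strsplit(s, "")[[1]] %in% AA1)) {
      stop("non-amino-acid character in MHC sequence")
    }
  }
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(target_seq), Biostrings::AAString(template_seq),
    type = "global", substitutionMatrix = blosum62(),
    gapOpening = gap_opening, gapExtension = gap_extension)
  list(target_row = as.character(Biostrings::pattern(pa)),
       template_row = as.character(Biostrings::subject(pa)),
       score = Biostrings::score(pa))
}

# ideal CB from backbone atoms of one residue
ideal_cb <- function(N, CA, C) {
  g <- IDEAL_GEOM
  place_atom(N, C, CA, g$b_ca_cb, g$a_c_ca_cb, g$t_n_c_ca_cb)
}

residue_atoms_row <- function(chain, resno, resid, names, xyz) {
  data.frame(record = "ATOM", chain = chain, resno = resno, ins = "",
             resid = resid, atom = names,
             x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], occ = 1,
             elem = substr(names, 1, 1), line = NA_integer_,
             stringsAsFactors = FALSE)
}

# copy one residue's backbone (+CB policy) from a template residue table
graft_residue <- function(tmpl_res, new_resno, target_aa3, chain) {
  bb <- tmpl_res[tmpl_res$atom %in% c("N", "CA", "C", "O"), ]
  out <- bb
  out$chain <- chain
  out$resno <- new_resno
  out$resid <- target_aa3
  out$record <- "ATOM"
  if (target_aa3 != "GLY") {
    cb <- tmpl_res[tmpl_res$atom == "CB", ]
    if (nrow(cb) == 1 && tmpl_res$resid[1] != "GLY") {
      cb$chain <- chain; cb$resno <- new_resno; cb$resid <- target_aa3
      cb$record <- "ATOM"
      out <- rbind(out, cb)
    } else {
      gx <- function(a) as.numeric(bb[bb$atom == a, c("x", "y", "z")])
      cbx <- ideal_cb(gx("N"), gx("CA"), gx("C"))
      out <- rbind(out, residue_atoms_row(chain, new_resno, target_aa3,
                                          "CB", matrix(cbx, 1)))
    }
  }
  out
}

#' Build the initial (grafted) model
#'
#' MHC chain: template backbone copied column-by-column from the MHC
#' alignment; residues whose identity differs from the target are renamed
#' and truncated to C-beta at ideal geometry (glycine gets no C-beta).
#' Peptide chain: backbone copied from the template at aligned columns;
#' template-row gaps (target insertions) are built by linear interpolation
#' of flanking backbone positions; target-row gaps are skipped. Anchor
#' residues land exactly on the template anchor coordinates.
#'
#' @param entry selected `template_entry`.
#' @param pep_alignment scored `peptide_alignment` from selection.
#' @param mhc_alignment output of [align_mhc()].
#' @param target the `modelling_target`.
#' @return a `pmhc_structure` (the unrandomized initial model).
#' @export
build_initial_model <- function(entry, pep_alignment, mhc_alignment, target) {
  tmpl <- entry$structure$atoms
  if (gsub("-", "", pep_alignment$target_row) != target$peptide_seq ||
      gsub("-", "", pep_alignment$template_row) != entry$peptide_seq) {
    stop("peptide alignment is inconsistent with the sequences")
  }
  # --- M chain ---
  trow <- strsplit(mhc_alignment$target_row, "")[[1]]
  prow <- strsplit(mhc_alignment$template_row, "")[[1]]
  m_atoms <- list()
  ti <- 0L; pi_ <- 0L; new_no <- 0L
  for (k in seq_along(trow)) {
    if (trow[k] != "-") ti <- ti + 1L
    if (prow[k] != "-") pi_ <- pi_ + 1L
    if (trow[k] == "-" || prow[k] == "-") next
    new_no <- new_no + 1L
    res <- tmpl[tmpl$chain == "M" & tmpl$resno == pi_, ]
    m_atoms[[new_no]] <- graft_residue(res, new_no, aa1to3(trow[k]), "M")
  }
  # --- P chain ---
  arow <- strsplit(pep_alignment$target_row, "")[[1]]
  brow <- strsplit(pep_alignment$template_row, "")[[1]]
  n_cols <- length(arow)
  tpos <- cumsum(arow != "-")          # target residue index per column
  ppos <- cumsum(brow != "-")          # template residue index per column
  backed <- arow != "-" & brow != "-"  # columns with template support
  p_atoms <- vector("list", nchar(target$peptide_seq))
  tgt3 <- aa1to3(strsplit(target$peptide_seq, "")[[1]])
  bb_names <- c("N", "CA", "C", "O")
  get_bb <- function(template_resno) {
    res <- tmpl[tmpl$chain == "P" & tmpl$resno == template_resno, ]
    t(vapply(bb_names, function(a)
      as.numeric(res[res$atom == a, c("x", "y", "z")]), numeric(3)))
  }
  for (k in seq_len(n_cols)) {
    if (arow[k] == "-") next
    r <- tpos[k]
    if (backed[k]) {
      res <- tmpl[tmpl$chain == "P" & tmpl$resno == ppos[k], ]
      p_atoms[[r]] <- graft_residue(res, r, tgt3[r], "P")
    } else {
      # target insertion: interpolate between flanking backed columns
      prev <- which(backed & seq_len(n_cols) < k)
      nxt <- which(backed & seq_len(n_cols) > k)
      if (length(prev) > 0 && length(nxt) > 0) {
        kp <- max(prev); kn <- min(nxt)
        frac <- (k - kp) / (kn - kp)
        xyz <- get_bb(ppos[kp]) + frac * (get_bb(ppos[kn]) - get_bb(ppos[kp]))
      } else if (length(prev) > 0) {
        kp <- max(prev)
        anchor_bb <- get_bb(ppos[kp])
        ref <- if (ppos[kp] > 1) get_bb(ppos[kp] - 1) else anchor_bb - 3.8
        xyz <- anchor_bb + (k - kp) * (anchor_bb - ref)
      } else {
        kn <- min(nxt)
        anchor_bb <- get_bb(ppos[kn])
        ref <- if (ppos[kn] < max(ppos)) get_bb(ppos[kn] + 1) else
          anchor_bb + 3.8
        xyz <- anchor_bb + (kn - k) * (anchor_bb - ref)
      }
      rows <- residue_atoms_row("P", r, tgt3[r], bb_names, xyz)
      if (tgt3[r] != "GLY") {
        cbx <- ideal_cb(xyz[1, ], xyz[2, ], xyz[3, ])
        rows <- rbind(rows, residue_atoms_row("P", r, tgt3[r], "CB",
                                              matrix(cbx, 1)))
      }
      p_atoms[[r]] <- rows
    }
  }
  atoms <- rbind(do.call(rbind, m_atoms), do.call(rbind, p_atoms))
  rownames(atoms) <- NULL
  pmhc_structure(atoms, paste0("model:", entry$source_id))
}

#' Randomize the peptide loop
#'
#' Displaces every atom of the loop residues (peptide positions not in the
#' anchor set) by an independent uniform offset in
#' `[-amplitude, +amplitude]` per coordinate. Anchor-residue atoms and all
#' MHC atoms are untouched. Deterministic given the RNG state.
#'
#' @param model a `pmhc_structure`.
#' @param loop_positions peptide positions to perturb.
#' @param amplitude maximum per-coordinate displacement (A, default 5.0);
#'   0 is a valid degenerate value (no perturbation), negative errors.
#' @return the perturbed `pmhc_structure`.
#' @export
randomize_loop <- function(model, loop_positions, amplitude = 5.0) {
  if (amplitude < 0) stop("amplitude must be >= 0")
  sel <- model$atoms$chain == "P" & model$atoms$resno %in% loop_positions
  n <- sum(sel)
  if (n == 0 || amplitude == 0) return(model)
  model$atoms$x[sel] <- model$atoms$x[sel] + stats::runif(n, -amplitude, amplitude)
  model$atoms$y[sel] <- model$atoms$y[sel] + stats::runif(n, -amplitude, amplitude)
  model$atoms$z[sel] <- model$atoms$z[sel] + stats::runif(n, -amplitude, amplitude)
  model
}

#' Build secondary-structure restraint terms
#'
#' Helix spans give O(i)-N(i+4) distance targets of 3.0 A for
#' `i in [start, end - 4]`; strand pairs give CA(i)-CA(j) targets of 4.8 A
#' for the antiparallel pairing `(start + k, end - k)`.
#'
#' @param spec list of `list(start, end, kind)` entries (kind `"helix"` or
#'   `"strand-pair"`); `NULL`/empty gives an empty term set.
#' @param peptide_length the peptide length (positions validated against it).
#' @return data.frame with columns `resno_i`, `atom_i`, `resno_j`,
#'   `atom_j`, `d0`.
#' @export
build_ss_restraints <- function(spec, peptide_length) {
  empty <- data.frame(resno_i = integer(), atom_i = character(),
                      resno_j = integer(), atom_j = character(),
                      d0 = numeric(), stringsAsFactors = FALSE)
  if (is.null(spec) || length(spec) == 0) return(empty)
  out <- list(empty)
  for (term in spec) {
    start <- term$start; end <- term$end; kind <- term$kind
    if (start < 1 || end > peptide_length || start >= end) {
      stop("invalid secondary-structure span ", start, "-", end)
    }
    if (kind == "helix") {
      if (end - start + 1 < 5) {
        stop("helix span must cover >= 5 residues for O(i)-N(i+4) restraints")
      }
      ii <- start:(end - 4)
      out[[length(out) + 1]] <- data.frame(
        resno_i = ii, atom_i = "O", resno_j = ii + 4, atom_j = "N",
        d0 = 3.0, stringsAsFactors = FALSE)
    } else if (kind == "strand-pair") {
      i <- start; j <- end
      ii <- jj <- integer(0)
      while (i < j - 1) {
        ii <- c(ii, i); jj <- c(jj, j)
        i <- i + 1; j <- j - 1
      }
      if (length(ii) == 0) stop("strand-pair span too short")
      out[[length(out) + 1]] <- data.frame(
        resno_i = ii, atom_i = "CA", resno_j = jj, atom_j = "CA",
        d0 = 4.8, stringsAsFactors = FALSE)
    } else {
      stop("unknown secondary-structure kind: ", kind)
    }
  }
  do.call(rbind, out)
}

# ---- restraint system -----------------------------------------------------

# Assemble the restraint system for a model: peptide coordinate matrix,
# bonded pair list, movable mask, anchor targets, ss pairs and the MHC
# clash neighbour coordinates.
build_restraints <- function(model, anchors, ss_terms = NULL,
                             weights = default_restraint_weights(),
                             clash_cutoff = 14) {
  a <- model$atoms
  pep <- a[a$chain == "P", ]
  n <- nrow(pep)
  idx <- function(resno, atom) {
    i <- which(pep$resno == resno & pep$atom == atom)
    if (length(i) != 1) NA_integer_ else i
  }
  g <- IDEAL_GEOM
  maxres <- max(pep$resno)
  bonds <- list()
  add_bond <- function(i, j, d0) {
    if (!is.na(i) && !is.na(j)) {
      bonds[[length(bonds) + 1]] <<- c(i, j, d0)
    }
  }
  for (r in seq_len(maxres)) {
    add_bond(idx(r, "N"), idx(r, "CA"), g$b_n_ca)
    add_bond(idx(r, "CA"), idx(r, "C"), g$b_ca_c)
    add_bond(idx(r, "C"), idx(r, "O"), g$b_c_o)
    add_bond(idx(r, "CA"), idx(r, "CB"), g$b_ca_cb)
    if (r < maxres) add_bond(idx(r, "C"), idx(r + 1, "N"), g$b_c_n)
  }
  bonds <- do.call(rbind, bonds)
  colnames(bonds) <- c("i", "j", "d0")

  # all peptide atoms are free to move; anchor backbone atoms are held by
  # the strong harmonic position restraints rather than frozen, so bonded
  # strain at the anchor junctions can relax while anchors stay put
  movable <- rep(TRUE, n)
  is_anchor <- pep$resno %in% anchors
  anchor_rows <- which(is_anchor & pep$atom %in% c("N", "CA", "C", "O"))
  anchor_targets <- atom_xyz(pep)[anchor_rows, , drop = FALSE]

  ss <- NULL
  if (!is.null(ss_terms) && nrow(ss_terms) > 0) {
    ii <- mapply(idx, ss_terms$resno_i, ss_terms$atom_i)
    jj <- mapply(idx, ss_terms$resno_j, ss_terms$atom_j)
    keep <- !is.na(ii) & !is.na(jj)
    if (any(keep)) {
      ss <- cbind(i = ii[keep], j = jj[keep], d0 = ss_terms$d0[keep])
    }
  }

  # peptide-peptide clash pairs: residues >= 2 apart
  pres <- pep$resno
  pp <- which(outer(pres, pres, function(x, y) y - x >= 2), arr.ind = TRUE)
  pp_pairs <- cbind(i = pp[, 1], j = pp[, 2])

  # MHC neighbour atoms for peptide-MHC clashes
  m_xyz <- atom_xyz(a[a$chain == "M", ])
  p_xyz <- atom_xyz(pep)
  d2 <- outer(rowSums(m_xyz^2), rowSums(p_xyz^2), "+") -
    2 * m_xyz %*% t(p_xyz)
  near <- sqrt(pmax(apply(d2, 1, min), 0)) <= clash_cutoff
  list(pep = pep, xyz0 = p_xyz, bonds = bonds, movable = movable,
       anchor_rows = anchor_rows, anchor_targets = anchor_targets,
       ss = ss, pp_pairs = pp_pairs, m_xyz = m_xyz[near, , drop = FALSE],
       weights = weights)
}

# Objective and gradient of the restrained energy. Terms:
#   E = w_bond Sum (b-b0)^2 + w_clash Sum max(0, d_min - d)^2
#     + w_anchor Sum |x - x_target|^2 + w_ss Sum (d - d_ss)^2
restraint_energy <- function(x, rs, include_clash = TRUE, include_ss = TRUE,
                             gradient = FALSE) {
  w <- rs$weights
  E <- 0
  G <- if (gradient) matrix(0, nrow(x), 3) else NULL
  pair_harmonic <- function(pairs, weight, E, G) {
    dvec <- x[pairs[, "i"], , drop = FALSE] - x[pairs[, "j"], , drop = FALSE]
    d <- sqrt(rowSums(dvec^2))
    dev <- d - pairs[, "d0"]
    E <- E + weight * sum(dev^2)
    if (gradient) {
      coef <- 2 * weight * dev / pmax(d, 1e-9)
      gv <- dvec * coef
      gi <- rowsum(gv, pairs[, "i"], reorder = FALSE)
      G[as.integer(rownames(gi)), ] <- G[as.integer(rownames(gi)), ] + gi
      gj <- rowsum(-gv, pairs[, "j"], reorder = FALSE)
      G[as.integer(rownames(gj)), ] <- G[as.integer(rownames(gj)), ] + gj
    }
    list(E = E, G = G)
  }
  # bonds
  r <- pair_harmonic(rs$bonds, w$w_bond, E, G)
  E <- r$E; G <- r$G
  # ss targets
  if (include_ss && !is.null(rs$ss)) {
    r <- pair_harmonic(rs$ss, w$w_ss, E, G)
    E <- r$E; G <- r$G
  }
  # anchor harmonic position restraints
  if (length(rs$anchor_rows) > 0) {
    dv <- x[rs$anchor_rows, , drop = FALSE] - rs$anchor_targets
    E <- E + w$w_anchor * sum(dv^2)
    if (gradient) {
      G[rs$anchor_rows, ] <- G[rs$anchor_rows, ] + 2 * w$w_anchor * dv
    }
  }
  if (include_clash) {
    dmin <- w$d_min
    # peptide-peptide
    pp <- rs$pp_pairs
    dvec <- x[pp[, "i"], , drop = FALSE] - x[pp[, "j"], , drop = FALSE]
    d <- sqrt(rowSums(dvec^2))
    viol <- pmax(0, dmin - d)
    hit <- which(viol > 0)
    if (length(hit) > 0) {
      E <- E + w$w_clash * sum(viol[hit]^2)
      if (gradient) {
        coef <- -2 * w$w_clash * viol[hit] / pmax(d[hit], 1e-9)
        gv <- dvec[hit, , drop = FALSE] * coef
        gi <- rowsum(gv, pp[hit, "i"], reorder = FALSE)
        G[as.integer(rownames(gi)), ] <- G[as.integer(rownames(gi)), ] + gi
        gj <- rowsum(-gv, pp[hit, "j"], reorder = FALSE)
        G[as.integer(rownames(gj)), ] <- G[as.integer(rownames(gj)), ] + gj
      }
    }
    # peptide-MHC
    if (nrow(rs$m_xyz) > 0) {
      d2 <- outer(rowSums(x^2), rowSums(rs$m_xyz^2), "+") -
        2 * x %*% t(rs$m_xyz)
      d2[d2 < 0] <- 0
      dm <- sqrt(d2)
      violm <- dmin - dm
      hit <- which(violm > 0, arr.ind = TRUE)
      if (nrow(hit) > 0) {
        v <- violm[hit]
        E <- E + w$w_clash * sum(v^2)
        if (gradient) {
          dvec <- x[hit[, 1], , drop = FALSE] -
            rs$m_xyz[hit[, 2], , drop = FALSE]
          coef <- -2 * w$w_clash * v / pmax(dm[hit], 1e-9)
          gv <- dvec * coef
          gi <- rowsum(gv, hit[, 1], reorder = FALSE)
          G[as.integer(rownames(gi)), ] <- G[as.integer(rownames(gi)), ] + gi
        }
      }
    }
  }
  list(E = E, G = G)
}

#' Two-phase restrained energy minimization
#'
#' Gradient descent with step halving on objective increase. Phase 1
#' minimizes the bonded and anchor terms only (restoring chain geometry
#' after randomization); phase 2 adds the clash and secondary-structure
#' terms. Only loop-residue atoms move; the accepted-step objective
#' sequence is non-increasing.
#'
#' @param model a `pmhc_structure` (typically randomized).
#' @param restraints restraint system from `build_restraints()` (internal;
#'   built automatically by [model_case()]).
#' @param preset iteration preset (see [modelling_target()]).
#' @return list with `model` (minimized), `score` (final full objective),
#'   and `diagnostics` (`trace` of accepted objective values per phase,
#'   `anchor_max_displacement`, `iterations`, term breakdown).
#' @export
minimize_model <- function(model, restraints,
                           preset = c("default", "fast", "thorough")) {
  preset <- match.arg(preset)
  iters <- preset_iterations(preset)
  rs <- restraints
  pep_rows <- which(model$atoms$chain == "P")
  x <- atom_xyz(model$atoms[pep_rows, ])
  movable <- rs$movable

  # first-order descent: conjugate-gradient (Polak-Ribiere+) directions
  # with a backtracking (step-halving) line search; the accepted-step
  # objective sequence is non-increasing by construction
  run_phase <- function(x, n_iter, include_clash, include_ss) {
    eg <- restraint_energy(x, rs, include_clash, include_ss, gradient = TRUE)
    E <- eg$E
    g <- eg$G
    g[!movable, ] <- 0
    d <- -g
    step <- 1e-3
    trace <- E
    used <- 0L
    for (it in seq_len(n_iter)) {
      if (!is.finite(E)) stop("non-finite objective during minimization")
      gn2 <- sum(g^2)
      if (gn2 < 1e-16) break
      accepted <- FALSE
      for (h in 1:40) {
        xt <- x + step * d
        Et <- restraint_energy(xt, rs, include_clash, include_ss)$E
        if (is.finite(Et) && Et <= E) {
          x <- xt; E <- Et
          step <- step * 1.5
          accepted <- TRUE
          break
        }
        step <- step / 2
      }
      used <- it
      if (!accepted) {  # restart along steepest descent once, then give up
        if (all(d == -g)) break
        d <- -g
        step <- 1e-3
        next
      }
      trace <- c(trace, E)
      eg <- restraint_energy(x, rs, include_clash, include_ss, gradient = TRUE)
      gn <- eg$G
      gn[!movable, ] <- 0
      beta <- max(0, sum(gn * (gn - g)) / gn2)
      d <- -gn + beta * d
      g <- gn
      if (sum(d * g) > 0) d <- -g  # ensure descent direction
    }
    list(x = x, E = E, trace = trace, iterations = used)
  }

  # user-supplied secondary-structure restraints act in both phases (as a
  # modelling engine would apply user restraints throughout optimization);
  # phase 1 otherwise covers only the bonded + anchor terms
  p1 <- run_phase(x, iters["phase1"], include_clash = FALSE,
                  include_ss = TRUE)
  p2 <- run_phase(p1$x, iters["phase2"], include_clash = TRUE,
                  include_ss = TRUE)
  x <- p2$x
  final <- restraint_energy(x, rs, TRUE, TRUE)
  anchor_disp <- if (length(rs$anchor_rows) > 0) {
    max(sqrt(rowSums((x[rs$anchor_rows, , drop = FALSE] -
                        rs$anchor_targets)^2)))
  } else 0
  model$atoms$x[pep_rows] <- x[, 1]
  model$atoms$y[pep_rows] <- x[, 2]
  model$atoms$z[pep_rows] <- x[, 3]
  list(model = model, score = final$E,
       diagnostics = list(trace_phase1 = p1$trace, trace_phase2 = p2$trace,
                          anchor_max_displacement = anchor_disp,
                          iterations = c(phase1 = p1$iterations,
                                         phase2 = p2$iterations)))
}

#' Model one pMHC-I case end to end
#'
#' Runs the full pipeline: template selection, MHC and peptide alignment,
#' initial model grafting, then `n_models` rounds of seeded loop
#' randomization (stream `seed + i` for model `i`) and two-phase
#' minimization. Results are sorted by ascending surrogate score. If the
#' target peptide sequence and allele both match the template exactly, the
#' unrandomized initial model is appended as rank 1 with score equal to
#' the minimum generated score minus one, and the identity is noted in the
#' run log.
#'
#' @param target a `modelling_target`.
#' @param db a `template_db`.
#' @param weights restraint weights (see [default_restraint_weights()]).
#' @param amplitude loop randomization amplitude in A (default 5.0).
#' @return a `model_run`: list with `results` (list of `model_result`),
#'   `target`, `template`, `tier`, `alignment`, `mhc_alignment`,
#'   `identical_case`, `log`.
#' @export
model_case <- function(target, db, weights = default_restraint_weights(),
                       amplitude = 5.0) {
  sel <- select_template(db, target)
  entry <- sel$entry
  tgt_mhc <- resolve_mhc_sequence(db, target)
  mal <- align_mhc(tgt_mhc, mhc_sequence(entry$structure))
  init <- build_initial_model(entry, sel$alignment, mal, target)
  ss_terms <- build_ss_restraints(target$ss_restraints,
                                  nchar(target$peptide_seq))
  rs <- build_restraints(init, target$anchors, ss_terms, weights,
                         clash_cutoff = 2 * amplitude + 4)
  loop_pos <- setdiff(seq_len(nchar(target$peptide_seq)), target$anchors)
  results <- vector("list", target$n_models)
  for (i in seq_len(target$n_models)) {
    seed_i <- target$seed + i
    set.seed(seed_i)
    pert <- randomize_loop(init, loop_pos, amplitude)
    fit <- minimize_model(pert, rs, preset = target$preset)
    results[[i]] <- structure(
      list(structure = fit$model, score = fit$score, rank = NA_integer_,
           diagnostics = fit$diagnostics, seed_used = seed_i),
      class = "model_result")
  }
  ord <- order(vapply(results, function(r) r$score, numeric(1)))
  results <- results[ord]
  identical_case <- target$peptide_seq == entry$peptide_seq &&
    target$allele %in% entry$alleles
  log <- list(template = entry$source_id, tier = sel$tier,
              candidates = sel$candidates)
  if (identical_case) {
    min_score <- results[[1]]$score
    shortcut <- structure(
      list(structure = init, score = min_score - 1, rank = NA_integer_,
           diagnostics = list(shortcut = TRUE,
                              anchor_max_displacement = 0),
           seed_used = NA_integer_),
      class = "model_result")
    results <- c(list(shortcut), results)
    log$identity_notice <- paste0(
      "target peptide and allele identical to template ", entry$source_id,
      "; returning the unrandomized initial model as rank 1")
  }
  for (i in seq_along(results)) results[[i]]$rank <- i
  structure(list(results = results, target = target, template = entry,
                 tier = sel$tier, alignment = sel$alignment,
                 mhc_alignment = mal, identical_case = identical_case,
                 initial_model = init, log = log),
            class = "model_run")
}

#' @export
print.model_run <- function(x, ...) {
  cat("model_run:", length(x$results), "models; template",
      x$template$source_id, "(tier", x$tier, ")",
      if (x$identical_case) "[identical-case shortcut]" else "", "\n")
  print(utils::head(run_manifest(x), 5))
  invisible(x)
}

#' Run manifest of a model run
#'
#' @param run a `model_run`.
#' @return data.frame: `rank`, `score`, `seed`, `anchor_max_displacement`,
#'   `shortcut`.
#' @export
run_manifest <- function(run) {
  data.frame(
    rank = vapply(run$results, function(r) r$rank, integer(1)),
    score = vapply(run$results, function(r) r$score, numeric(1)),
    seed = vapply(run$results, function(r)
      as.integer(r$seed_used %||% NA), integer(1)),
    anchor_max_displacement = vapply(run$results, function(r)
      r$diagnostics$anchor_max_displacement %||% NA_real_, numeric(1)),
    shortcut = vapply(run$results, function(r)
      isTRUE(r$diagnostics$shortcut), logical(1)),
    stringsAsFactors = FALSE)
}
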