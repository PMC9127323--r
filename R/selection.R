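# Template selection: allele hierarchy (allele -> group -> gene), the
# anchor-position-driven peptide alignment, and PAM30 ranking.

.pam30_cache <- new.env(parent = emptyenv())

#' Load the PAM30 substitution matrix
#'
#' Reads the NCBI-layout plain-text PAM30 matrix shipped with the package
#' (20 standard amino acids, symmetric integers).
#'
#' @param path matrix file; default the shipped copy.
#' @return 20x20 integer matrix with amino-acid dimnames.
#' @export
load_pam30 <- function(path = system.file("extdata", "PAM30.txt",
                                          package = "anchormod")) {
  if (!is.null(.pam30_cache[[path]])) return(.pam30_cache[[path]])
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  header <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  rows <- lapply(lines[-1], function(ln) strsplit(trimws(ln), "\\s+")[[1]])
  m <- t(vapply(rows, function(r) as.integer(r[-1]), integer(length(header))))
  dimnames(m) <- list(vapply(rows, `[[`, character(1), 1), header)
  .pam30_cache[[path]] <- m
  m
}

#' Candidate templates for a target allele
#'
#' Searches the database hierarchy: tier 1 are entries annotated with the
#' exact allele (protein level, e.g. HLA-A*02:01); if none, tier 2 are
#' entries from the same allele group (e.g. HLA-A*02); if none, tier 3 are
#' entries from the same gene (e.g. HLA-A). Returns the first non-empty
#' tier. Allele comparison is case-exact.
#'
#' @param db a `template_db`.
#' @param target_allele allele name string.
#' @return list with `entries` (possibly empty, ordered by `source_id`)
#'   and `tier` (1, 2, 3 or `NA` when empty at all tiers).
#' @export
candidate_templates <- function(db, target_allele) {
  if (length(db$entries) == 0) stop("template database is empty")
  tgt <- parse_allele(target_allele)
  levels <- lapply(db$entries, function(e) lapply(e$alleles, parse_allele))
  match_tier <- function(e_alleles, level) {
    any(vapply(e_alleles, function(a) {
      switch(level,
        protein = identical(a$raw, tgt$raw) ||
          (!is.na(a$protein) && !is.na(tgt$protein) &&
             a$protein == tgt$protein),
        group = !is.na(a$group) && !is.na(tgt$group) && a$group == tgt$group,
        gene = !is.na(a$gene) && !is.na(tgt$gene) && a$gene == tgt$gene)
    }, logical(1)))
  }
  for (tier in c("protein", "group", "gene")) {
    hit <- vapply(levels, match_tier, logical(1), level = tier)
    if (any(hit)) {
      ents <- db$entries[hit]
      ents <- ents[order(vapply(ents, function(e) e$source_id, character(1)))]
      return(list(entries = unname(ents),
                  tier = match(tier, c("protein", "group", "gene"))))
    }
  }
  list(entries = list(), tier = NA_integer_)
}

#' Anchor-position-driven peptide alignment
#'
#' Aligns two peptides by forcing paired anchor positions (sorted
#' ascending, paired in order) into shared columns. Length mismatches in
#' the segments between consecutive anchors (the binding core) are
#' resolved by inserting a gap block in the shorter row at the centre of
#' that segment (odd surplus: the block sits immediately left of centre);
#' flank-length mismatches are resolved by terminal gaps on the shorter
#' flank. No optimisation is performed: the construction is prescriptive.
#'
#' @param target_seq,template_seq 1-letter peptide sequences.
#' @param target_anchors,template_anchors equal-cardinality anchor sets
#'   (>= 2 positions each).
#' @return a `peptide_alignment`: `target_row`, `template_row` (equal
#'   length, over amino acids and `'-'`), `anchor_columns`, `score`
#'   (`NA` until scored).
#' @export
anchor_align <- function(target_seq, target_anchors,
                         template_seq, template_anchors) {
  ta <- sort(unique(as.integer(target_anchors)))
  pa <- sort(unique(as.integer(template_anchors)))
  if (length(ta) != length(pa)) {
    stop("anchor sets must have equal cardinality")
  }
  if (length(ta) < 2) stop("at least two anchors are required")
  nt <- nchar(target_seq); np <- nchar(template_seq)
  if (any(ta < 1 | ta > nt) || any(pa < 1 | pa > np)) {
    stop("anchor position out of peptide range")
  }
  tgt <- strsplit(target_seq, "")[[1]]
  tpl <- strsplit(template_seq, "")[[1]]

  # centre-gap pairing of an inter-anchor (core) segment
  pair_core <- function(a, b) {  # a, b: character vectors of the two rows
    la <- length(a); lb <- length(b)
    if (la == lb) return(list(a = a, b = b))
    if (la < lb) {
      k <- lb - la
      left <- floor(la / 2)
      list(a = c(a[seq_len(left)], rep("-", k),
                 if (la > left) a[(left + 1):la]),
           b = b)
    } else {
      sw <- pair_core(b, a)
      list(a = sw$b, b = sw$a)
    }
  }
  pad_flank <- function(a, b, side) {
    la <- length(a); lb <- length(b)
    if (la == lb) return(list(a = a, b = b))
    k <- abs(la - lb)
    pad <- rep("-", k)
    if (la < lb) {
      a <- if (side == "left") c(pad, a) else c(a, pad)
    } else {
      b <- if (side == "left") c(pad, b) else c(b, pad)
    }
    list(a = a, b = b)
  }
  seg <- function(x, from, to) if (from > to) character(0) else x[from:to]

  rowA <- character(0); rowB <- character(0); anchor_cols <- integer(0)
  fl <- pad_flank(seg(tgt, 1, ta[1] - 1), seg(tpl, 1, pa[1] - 1), "left")
  rowA <- fl$a; rowB <- fl$b
  for (k in seq_along(ta)) {
    rowA <- c(rowA, tgt[ta[k]]); rowB <- c(rowB, tpl[pa[k]])
    anchor_cols <- c(anchor_cols, length(rowA))
    if (k < length(ta)) {
      core <- pair_core(seg(tgt, ta[k] + 1, ta[k + 1] - 1),
                        seg(tpl, pa[k] + 1, pa[k + 1] - 1))
      rowA <- c(rowA, core$a); rowB <- c(rowB, core$b)
    }
  }
  fr <- pad_flank(seg(tgt, ta[length(ta)] + 1, nt),
                  seg(tpl, pa[length(pa)] + 1, np), "right")
  rowA <- c(rowA, fr$a); rowB <- c(rowB, fr$b)

  structure(list(target_row = paste(rowA, collapse = ""),
                 template_row = paste(rowB, collapse = ""),
                 anchor_columns = anchor_cols,
                 target_anchors = ta, template_anchors = pa,
                 score = NA_real_),
            class = "peptide_alignment")
}

#' Score a peptide alignment with a substitution matrix
#'
#' Sum of substitution scores over residue-residue columns plus affine gap
#' penalties: `gap_open` for the first column of each gap run and
#' `gap_extend` for each additional column.
#'
#' @param alignment a `peptide_alignment`.
#' @param matrix substitution matrix (default shipped PAM30).
#' @param gap_open,gap_extend gap penalties (negative integers; defaults
#'   -9 / -1).
#' @return integer score.
#' @export
score_alignment <- function(alignment, matrix = load_pam30(),
                            gap_open = -9, gap_extend = -1) {
  a <- strsplit(alignment$target_row, "")[[1]]
  b <- strsplit(alignment$template_row, "")[[1]]
  stopifnot(length(a) == length(b))
  ok <- c(rownames(matrix), "-")
  if (!all(a %in% ok) || !all(b %in% ok)) {
    stop("alignment contains characters outside the matrix alphabet")
  }
  score <- 0
  in_gap_a <- in_gap_b <- FALSE
  for (i in seq_along(a)) {
    if (a[i] == "-" || b[i] == "-") {
      if (a[i] == "-") {
        score <- score + if (in_gap_a) gap_extend else gap_open
        in_gap_a <- TRUE
      } else in_gap_a <- FALSE
      if (b[i] == "-") {
        score <- score + if (in_gap_b) gap_extend else gap_open
        in_gap_b <- TRUE
      } else in_gap_b <- FALSE
    } else {
      score <- score + matrix[a[i], b[i]]
      in_gap_a <- in_gap_b <- FALSE
    }
  }
  score
}

#' Select the best template for a target
#'
#' Compiles the candidate tier via [candidate_templates()], builds the
#' anchor-driven alignment against every candidate, ranks by PAM30 score
#' and returns the maximum; ties are broken by better (lower) resolution,
#' then lexicographically smallest `source_id`.
#'
#' @param db a `template_db`.
#' @param target a `modelling_target`.
#' @param matrix,gap_open,gap_extend scoring parameters
#'   (see [score_alignment()]).
#' @return list with `entry` (the chosen `template_entry`), `alignment`
#'   (scored `peptide_alignment`), `tier`, and `candidates` (data.frame
#'   log: source_id, score, resolution).
#' @export
select_template <- function(db, target, matrix = load_pam30(),
                            gap_open = -9, gap_extend = -1) {
  cand <- candidate_templates(db, target$allele)
  if (length(cand$entries) == 0) {
    stop("no template for gene of allele '", target$allele,
         "' in the database")
  }
  aligns <- lapply(cand$entries, function(e) {
    al <- anchor_align(target$peptide_seq, target$anchors,
                       e$peptide_seq, e$anchors)
    al$score <- score_alignment(al, matrix, gap_open, gap_extend)
    al
  })
  scores <- vapply(aligns, function(a) a$score, numeric(1))
  res <- vapply(cand$entries, function(e)
    ifelse(is.na(e$resolution), Inf, e$resolution), numeric(1))
  ids <- vapply(cand$entries, function(e) e$source_id, character(1))
  best <- order(-scores, res, ids)[1]
  list(entry = cand$entries[[best]], alignment = aligns[[best]],
       tier = cand$tier,
       candidates = data.frame(source_id = ids, score = scores,
                               resolution = vapply(cand$entries, function(e)
                                 e$resolution, numeric(1)),
                               tier = cand$tier,
                               stringsAsFactors = FALSE))
}
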