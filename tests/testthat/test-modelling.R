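# Grafting, loop randomization, restrained minimization, ranking, and the
# comparative-modelling input files.

make_case <- function(seed = 2, n_models = 2, ...) {
  ch <- make_benchmark_cohort(1, seed = seed, n_models = n_models,
                              preset = "fast", ...)
  list(cohort = ch, case = ch$cases[[1]], target = ch$cases[[1]]$target,
       db = ch$db)
}

test_that("identical peptide and allele graft is a pure copy", {
  mc <- make_case(seed = 3, n_mutations = 0, coord_noise = 0)
  sel <- select_template(mc$db, mc$target)
  mal <- align_mhc(resolve_mhc_sequence(mc$db, mc$target),
                   mhc_sequence(sel$entry$structure))
  init <- build_initial_model(sel$entry, sel$alignment, mal, mc$target)
  tp <- sel$entry$structure$atoms
  ip <- init$atoms
  expect_equal(ip[ip$chain == "P", c("x", "y", "z")],
               tp[tp$chain == "P", c("x", "y", "z")], ignore_attr = TRUE)
  expect_equal(ip[ip$chain == "M", "x"], tp[tp$chain == "M", "x"])
})

test_that("a central point mutation only renames and truncates to C-beta", {
  mc <- make_case(seed = 4, n_mutations = 0, coord_noise = 0)
  pep <- mc$target$peptide_seq
  mid <- 5L
  letters1 <- strsplit(pep, "")[[1]]
  letters1[mid] <- if (letters1[mid] == "W") "F" else "W"
  mut <- modelling_target(paste(letters1, collapse = ""), mc$target$allele,
                          anchors = mc$target$anchors, seed = 1)
  sel <- select_template(mc$db, mut)
  mal <- align_mhc(resolve_mhc_sequence(mc$db, mut),
                   mhc_sequence(sel$entry$structure))
  init <- build_initial_model(sel$entry, sel$alignment, mal, mut)
  tp <- sel$entry$structure$atoms
  ip <- init$atoms
  bb <- function(a) a[a$chain == "P" & a$atom %in% c("N", "CA", "C", "O"), ]
  expect_equal(bb(ip)[, c("x", "y", "z")], bb(tp)[, c("x", "y", "z")],
               ignore_attr = TRUE)
  mut_res <- ip[ip$chain == "P" & ip$resno == mid, ]
  expect_setequal(mut_res$atom, c("N", "CA", "C", "O", "CB"))
  expect_equal(unique(mut_res$resid), anchormod:::aa1to3(letters1[mid]))
})

test_that("a shorter target on a longer template lands on the anchor coordinates", {
  tmpl_s <- anchormod:::fixture_structure("ACDEFGHIKL", c(2, 10),
                                          "HLA-A*02:01", "T10", seed = 6)
  db <- template_db(list(template_entry(tmpl_s, "ACDEFGHIKL", "HLA-A*02:01",
                                        anchors = c(2, 10), source_id = "T10")),
                    ref_sequences = stats::setNames(
                      anchormod:::allele_scaffold_sequence("HLA-A*02:01"),
                      "HLA-A*02:01"))
  tgt <- modelling_target("ACDEFGHIK", "HLA-A*02:01", anchors = c(2, 9))
  sel <- select_template(db, tgt)
  mal <- align_mhc(resolve_mhc_sequence(db, tgt), mhc_sequence(tmpl_s))
  init <- build_initial_model(sel$entry, sel$alignment, mal, tgt)
  expect_equal(anchormod:::chain_length(init, "P"), 9)
  # anchor residues sit exactly on the template anchor positions
  for (pair in list(c(2, 2), c(9, 10))) {
    got <- init$atoms[init$atoms$chain == "P" & init$atoms$resno == pair[1] &
                        init$atoms$atom == "CA", c("x", "y", "z")]
    want <- tmpl_s$atoms[tmpl_s$atoms$chain == "P" &
                           tmpl_s$atoms$resno == pair[2] &
                           tmpl_s$atoms$atom == "CA", c("x", "y", "z")]
    expect_equal(got, want, ignore_attr = TRUE)
  }
})

test_that("loop randomization is bounded, seeded and anchor-preserving", {
  mc <- make_case(seed = 7)
  sel <- select_template(mc$db, mc$target)
  mal <- align_mhc(resolve_mhc_sequence(mc$db, mc$target),
                   mhc_sequence(sel$entry$structure))
  init <- build_initial_model(sel$entry, sel$alignment, mal, mc$target)
  loop <- setdiff(seq_len(nchar(mc$target$peptide_seq)), mc$target$anchors)

  set.seed(11)
  p1 <- randomize_loop(init, loop, 5)
  set.seed(11)
  p2 <- randomize_loop(init, loop, 5)
  expect_identical(p1$atoms, p2$atoms)  # determinism under a fixed seed

  d <- abs(anchormod:::atom_xyz(p1$atoms) - anchormod:::atom_xyz(init$atoms))
  expect_lte(max(d), 5.0)
  anchor_sel <- p1$atoms$chain == "P" & p1$atoms$resno %in% mc$target$anchors
  expect_equal(max(d[anchor_sel | p1$atoms$chain == "M", ]), 0)

  expect_identical(randomize_loop(init, loop, 0)$atoms, init$atoms)
  expect_error(randomize_loop(init, loop, -1), "amplitude")
})

test_that("minimization descends monotonically and matches a numeric gradient", {
  mc <- make_case(seed = 8)
  sel <- select_template(mc$db, mc$target)
  mal <- align_mhc(resolve_mhc_sequence(mc$db, mc$target),
                   mhc_sequence(sel$entry$structure))
  init <- build_initial_model(sel$entry, sel$alignment, mal, mc$target)
  rs <- anchormod:::build_restraints(init, mc$target$anchors)
  loop <- setdiff(seq_len(nchar(mc$target$peptide_seq)), mc$target$anchors)

  set.seed(21)
  pert <- randomize_loop(init, loop, 5)
  fit <- minimize_model(pert, rs, "fast")
  expect_lt(fit$score, anchormod:::restraint_energy(
    anchormod:::atom_xyz(pert$atoms[pert$atoms$chain == "P", ]), rs)$E)
  expect_true(all(diff(fit$diagnostics$trace_phase1) <= 0))
  expect_true(all(diff(fit$diagnostics$trace_phase2) <= 0))
  # only peptide atoms moved
  expect_equal(fit$model$atoms[fit$model$atoms$chain == "M", "x"],
               init$atoms[init$atoms$chain == "M", "x"])

  # near-minimum start: objective does not deteriorate
  fit0 <- minimize_model(init, rs, "fast")
  E0 <- anchormod:::restraint_energy(
    anchormod:::atom_xyz(init$atoms[init$atoms$chain == "P", ]), rs)$E
  expect_lte(fit0$score, E0 + 1e-6)

  # analytic gradient equals central differences (independent oracle)
  x <- anchormod:::atom_xyz(pert$atoms[pert$atoms$chain == "P", ])
  eg <- anchormod:::restraint_energy(x, rs, TRUE, TRUE, gradient = TRUE)
  set.seed(5)
  idx <- cbind(sample(nrow(x), 12, TRUE), sample(3, 12, TRUE))
  h <- 1e-5
  for (k in seq_len(nrow(idx))) {
    xp <- x; xp[idx[k, 1], idx[k, 2]] <- xp[idx[k, 1], idx[k, 2]] + h
    xm <- x; xm[idx[k, 1], idx[k, 2]] <- xm[idx[k, 1], idx[k, 2]] - h
    num <- (anchormod:::restraint_energy(xp, rs)$E -
              anchormod:::restraint_energy(xm, rs)$E) / (2 * h)
    expect_lt(abs(num - eg$G[idx[k, 1], idx[k, 2]]) / max(1, abs(num)), 1e-4)
  }
})

test_that("secondary-structure restraint terms are counted exactly", {
  helix <- build_ss_restraints(list(list(start = 4, end = 10, kind = "helix")),
                               12)
  expect_equal(nrow(helix), 3)  # i = 4, 5, 6
  expect_equal(helix$resno_i, 4:6)
  expect_equal(helix$resno_j, 8:10)
  expect_true(all(helix$d0 == 3.0))
  expect_error(build_ss_restraints(list(list(start = 4, end = 7,
                                             kind = "helix")), 12),
               ">= 5")
  strand <- build_ss_restraints(list(list(start = 2, end = 9,
                                          kind = "strand-pair")), 12)
  expect_equal(strand$resno_i, 2:4)
  expect_equal(strand$resno_j, 9:7)
  expect_true(all(strand$d0 == 4.8))
  expect_equal(nrow(build_ss_restraints(NULL, 9)), 0)
  expect_error(build_ss_restraints(list(list(start = 1, end = 20,
                                             kind = "helix")), 12), "span")
})

test_that("global MHC alignment matches an exhaustive DP oracle", {
  s <- anchormod:::allele_scaffold_sequence("HLA-A*02:01")
  self <- align_mhc(s, s)
  expect_false(grepl("-", self$target_row))
  expect_equal(self$target_row, self$template_row)

  # one deleted residue: a single gap column
  del <- align_mhc(s, paste0(substr(s, 1, 89), substr(s, 91, 180)))
  expect_equal(lengths(regmatches(del$template_row,
                                  gregexpr("-", del$template_row))), 1)

  # score equals the brute-force affine DP oracle on short sequences
  b62 <- biostrings_blosum62()
  set.seed(31)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  for (rep in 1:10) {
    a <- paste(sample(aa, sample(6:12, 1), TRUE), collapse = "")
    b <- paste(sample(aa, sample(6:12, 1), TRUE), collapse = "")
    expect_equal(align_mhc(a, b)$score, nw_affine_score(a, b, b62),
                 tolerance = 1e-9, label = paste(a, b))
  }
  expect_error(align_mhc("ACDX1", s), "non-amino-acid")
  expect_error(align_mhc("", s), "empty")
})

test_that("model_case ranks ascending, is seeded-deterministic, and applies the identity shortcut", {
  mc <- make_case(seed = 9, n_models = 3)
  run <- model_case(mc$target, mc$db)
  man <- run_manifest(run)
  expect_equal(man$rank, seq_len(nrow(man)))
  expect_true(all(diff(man$score) >= 0))
  expect_true(all(man$anchor_max_displacement <= 0.25))

  run2 <- model_case(mc$target, mc$db)
  expect_identical(run_manifest(run2), man)
  expect_identical(run2$results[[2]]$structure$atoms,
                   run$results[[2]]$structure$atoms)

  # n_models = 1 gives exactly one model (no shortcut here: mutated peptide)
  t1 <- modelling_target(mc$target$peptide_seq, mc$target$allele,
                         anchors = mc$target$anchors, n_models = 1,
                         seed = 5, preset = "fast")
  expect_length(model_case(t1, mc$db)$results, 1)

  # identical-case: template peptide == target peptide and same allele
  mc0 <- make_case(seed = 10, n_models = 2, n_mutations = 0, coord_noise = 0)
  run0 <- model_case(mc0$target, mc0$db)
  expect_true(run0$identical_case)
  man0 <- run_manifest(run0)
  expect_length(run0$results, 3)  # 2 generated + shortcut
  expect_true(man0$shortcut[1])
  expect_equal(man0$score[1], min(man0$score[-1]) - 1)
  # the shortcut model is the untouched graft: L-RMSD 0 to its template
  expect_equal(lrmsd(run0$results[[1]]$structure,
                     mc0$db$entries[[run0$template$source_id]]$structure),
               0, tolerance = 1e-9)
})

test_that("emitted PIR files round-trip and reference the template", {
  mc <- make_case(seed = 12)
  run <- model_case(mc$target, mc$db)
  outdir <- file.path(tempdir(), "modeller_out")
  files <- emit_modeller_inputs(mc$target, run$template, run$alignment,
                                run$mhc_alignment, outdir)
  expect_true(all(file.exists(files)))

  pir <- read_pir(files[["alignment"]])
  expect_length(pir, 2)
  expect_equal(pir[[1]]$name, run$template$source_id)
  expect_match(pir[[1]]$description, "^structureX:")
  expect_match(pir[[2]]$description, "^sequence:")
  expect_equal(nchar(pir[[1]]$sequence), nchar(pir[[2]]$sequence))
  # rows recovered verbatim (gaps and chain break included)
  expect_equal(pir[[1]]$sequence,
               paste0(run$mhc_alignment$template_row, "/",
                      run$alignment$template_row))
  expect_equal(pir[[2]]$sequence,
               paste0(run$mhc_alignment$target_row, "/",
                      run$alignment$target_row))
  raw <- readLines(files[["alignment"]])
  expect_true(any(grepl("\\*$", raw)))

  # template PDB parses back to the stored template
  tmpl <- parse_pmhc(readLines(files[["template"]]),
                     source_id = run$template$source_id)
  expect_equal(peptide_sequence(tmpl), run$template$peptide_seq)
  # restraint file lists the 1-based anchors
  restr <- readLines(files[["restraints"]])
  expect_equal(sum(grepl("^anchor", restr)), length(mc$target$anchors))
})

test_that("gap columns survive the PIR round-trip", {
  al <- anchor_align("ACDEFGHIK", c(2, 9), "ACDEFGHIKL", c(2, 10))
  mc <- make_case(seed = 13)
  run <- model_case(mc$target, mc$db)
  outdir <- file.path(tempdir(), "modeller_gap")
  files <- emit_modeller_inputs(mc$target, run$template, al,
                                run$mhc_alignment, outdir)
  pir <- read_pir(files[["alignment"]])
  expect_match(pir[[2]]$sequence, "-")
})
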