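# Template database: allele parsing, curation filters, persistence,
# reference-sequence resolution.

test_that("allele names parse into gene/group/protein with graceful degradation", {
  a <- parse_allele("HLA-A*02:01")
  expect_equal(a$gene, "HLA-A")
  expect_equal(a$group, "HLA-A*02")
  expect_equal(a$protein, "HLA-A*02:01")
  expect_equal(a$raw, "HLA-A*02:01")

  b <- parse_allele("HLA-B*07")
  expect_equal(b$group, "HLA-B*07")
  expect_true(is.na(b$protein))

  h <- parse_allele("H2-Kb")
  expect_equal(h$gene, "H2-Kb")
  expect_true(is.na(h$group))
  expect_true(is.na(h$protein))

  # extra fields beyond the protein level are dropped from `protein`
  expect_equal(parse_allele("HLA-A*02:01:05")$protein, "HLA-A*02:01")
  expect_error(parse_allele(""), "non-empty")
})

test_that("each curation defect maps to its reason code", {
  cases <- list(
    list(defect = "noncanonical_residue", reason = "NONCANONICAL"),
    list(defect = "groove_ligand", reason = "GROOVE_LIGAND"),
    list(defect = "corrupt_record", reason = "UNPARSEABLE"),
    list(defect = "missing_allele", reason = "NO_ALLELE"))
  for (cs in cases) {
    fx <- make_toy_pmhc("ACDEFGHIK", defects = cs$defect, seed = 10)
    res <- apply_filters(fx$pdb_text, fx$alleles, cs$defect)
    expect_equal(res$status, "rejected")
    expect_equal(res$reason, cs$reason)
  }
  fx <- make_toy_pmhc("ACDEFG", defects = "short_peptide", seed = 10)
  expect_equal(apply_filters(fx$pdb_text, fx$alleles, "short")$reason,
               "BAD_LENGTH")
  clean <- make_toy_pmhc("ACDEFGHIK", seed = 10)
  res <- apply_filters(clean$pdb_text, clean$alleles, "clean",
                       resolution = clean$resolution)
  expect_equal(res$status, "accepted")
  expect_s3_class(res$entry, "template_entry")
  expect_equal(res$entry$peptide_seq, "ACDEFGHIK")
  expect_equal(res$entry$anchors, c(2L, 9L))  # canonical default
})

test_that("the groove-ligand geometry test is specific to the groove", {
  fx <- make_toy_pmhc("ACDEFGHIK", seed = 11)
  raw <- parse_pdb(fx$pdb_text)
  pep <- raw$atoms[raw$atoms$chain == "C", ]
  # a molecule far from the peptide (surface additive) is not flagged
  far <- data.frame(record = "HETATM", chain = "X", resno = 1, ins = "",
                    resid = "LIG", atom = "C1", x = 60, y = 60, z = 60,
                    occ = 1, elem = "C", line = NA_integer_,
                    stringsAsFactors = FALSE)
  expect_false(anchormod:::groove_ligand_present(far, pep))
  # water near the peptide is excluded from the test entirely
  wat <- pep[pep$atom == "CA", ][5, ]
  wat$record <- "HETATM"; wat$resid <- "HOH"; wat$atom <- "O"
  wat$chain <- "X"; wat$z <- wat$z + 2
  expect_equal(nrow(anchormod:::ligand_atoms(rbind(wat))), 0)
})

test_that("database build partitions inputs into accepted plus reasons", {
  set <- make_defect_set()
  db <- build_database(set$structures, set$annotations)
  expect_s3_class(db, "template_db")
  expect_length(db$entries, 8)
  counts <- db$build_metadata$counts
  expect_equal(counts$accepted, 8L)
  expect_equal(counts$NONCANONICAL, 1L)
  expect_equal(counts$GROOVE_LIGAND, 1L)
  expect_equal(counts$UNPARSEABLE, 1L)
  expect_equal(counts$NO_ALLELE, 1L)
  expect_equal(Reduce(`+`, counts), length(set$structures))
  # rebuild determinism
  db2 <- build_database(set$structures, set$annotations)
  expect_equal(names(db$entries), names(db2$entries))
  expect_equal(db$entries[[1]]$structure$atoms, db2$entries[[1]]$structure$atoms)
})

test_that("widening the peptide length bounds never loses accepted entries", {
  set <- make_defect_set()
  narrow <- build_database(set$structures, set$annotations,
                           settings = list(peptide_bounds = c(9, 9)))
  wide <- build_database(set$structures, set$annotations,
                         settings = list(peptide_bounds = c(7, 15)))
  expect_true(all(names(narrow$entries) %in% names(wide$entries)))
  expect_gte(length(wide$entries), length(narrow$entries))
})

test_that("single clean structure yields a database of one; none errors", {
  fx <- make_toy_pmhc("ACDEFGHIK", source_id = "ONE", seed = 12)
  ann <- data.frame(source_id = "ONE", alleles = "HLA-A*02:01",
                    stringsAsFactors = FALSE)
  db <- build_database(list(ONE = fx$pdb_text), ann)
  expect_length(db$entries, 1)
  bad <- make_toy_pmhc("ACDEFGHIK", source_id = "BAD", seed = 12,
                       defects = "missing_allele")
  ann2 <- data.frame(source_id = "BAD", alleles = "", stringsAsFactors = FALSE)
  expect_error(build_database(list(BAD = bad$pdb_text), ann2), "empty database")
})

test_that("database persistence round-trips losslessly and deterministically", {
  set <- make_defect_set()
  db <- build_database(set$structures, set$annotations)
  p1 <- file.path(tempdir(), "db1.json")
  p2 <- file.path(tempdir(), "db2.json")
  save_database(db, p1)
  save_database(db, p2)
  expect_identical(readLines(p1), readLines(p2))  # byte-identical saves
  back <- load_database(p1)
  expect_equal(names(back$entries), names(db$entries))
  for (id in names(db$entries)) {
    expect_equal(back$entries[[id]]$peptide_seq, db$entries[[id]]$peptide_seq)
    expect_equal(back$entries[[id]]$alleles, db$entries[[id]]$alleles)
    expect_equal(back$entries[[id]]$anchors, db$entries[[id]]$anchors)
    a0 <- db$entries[[id]]$structure$atoms
    a1 <- back$entries[[id]]$structure$atoms
    expect_equal(a1$x, round(a0$x, 3))
    expect_equal(a1$resid, a0$resid)
  }
  # truncated file -> explicit incompatibility error
  lines <- readLines(p1)
  writeLines(substr(paste(lines, collapse = ""), 1, 500),
             file.path(tempdir(), "trunc.json"))
  expect_error(load_database(file.path(tempdir(), "trunc.json")),
               "incompatible|corrupt")
  # wrong version header
  writeLines(jsonlite::toJSON(list(format = "other-format-9"),
                              auto_unbox = TRUE),
             file.path(tempdir(), "vers.json"))
  expect_error(load_database(file.path(tempdir(), "vers.json")),
               "incompatible")
})

test_that("MHC sequence resolution honours user > exact allele > group", {
  db <- make_hierarchy_db()
  tgt_user <- modelling_target("ILKEPVHGV", "HLA-A*02:01",
                               mhc_seq = strrep("A", 180))
  expect_equal(resolve_mhc_sequence(db, tgt_user), strrep("A", 180))

  tgt_exact <- modelling_target("ILKEPVHGV", "HLA-A*02:01")
  expect_equal(resolve_mhc_sequence(db, tgt_exact),
               unname(db$ref_sequences[["HLA-A*02:01"]]))

  tgt_group <- modelling_target("ILKEPVHGV", "HLA-A*02:05")
  expect_warning(seq_g <- resolve_mhc_sequence(db, tgt_group),
                 "group representative")
  expect_equal(seq_g, unname(db$ref_sequences[["HLA-A*02:01"]]))

  tgt_none <- modelling_target("ILKEPVHGV", "HLA-C*05:01")
  expect_error(resolve_mhc_sequence(db, tgt_none), "available alleles")
})

test_that("reference sequences load from FASTA during build", {
  fx <- make_toy_pmhc("ACDEFGHIK", source_id = "F1", seed = 13)
  ann <- data.frame(source_id = "F1", alleles = "HLA-A*02:01",
                    stringsAsFactors = FALSE)
  fasta <- file.path(tempdir(), "refs.fasta")
  write_fixture_ref_fasta(c("HLA-A*02:01", "HLA-B*07:02"), fasta)
  db <- build_database(list(F1 = fx$pdb_text), ann, ref_fasta = fasta)
  expect_length(db$ref_sequences, 2)
  expect_equal(nchar(db$ref_sequences[["HLA-A*02:01"]]), 180)
})

test_that("contact heuristic recovers the designed anchor positions", {
  for (seed in 1:3) {
    fx <- make_toy_pmhc("ACDEFGHIK", anchors = c(2, 9), seed = seed)
    e <- apply_filters(fx$pdb_text, fx$alleles, "h")$entry
    expect_equal(anchors_from_contacts(e$structure), c(2L, 9L))
  }
  # non-canonical anchors within the windows are recovered too
  fx <- make_toy_pmhc("ACDEFGHIK", anchors = c(1, 8), seed = 4)
  e <- apply_filters(fx$pdb_text, fx$alleles, "h2")$entry
  expect_equal(anchors_from_contacts(e$structure), c(1L, 8L))
})

test_that("entry invariants are enforced", {
  fx <- make_toy_pmhc("ACDEFGHIK", seed = 14)
  e <- apply_filters(fx$pdb_text, fx$alleles, "inv")$entry
  expect_error(template_entry(e$structure, "SHORT", "HLA-A*02:01",
                              source_id = "x"), "length")
  expect_error(template_entry(e$structure, e$peptide_seq, character(0),
                              source_id = "x"), "alleles")
  expect_error(template_entry(e$structure, e$peptide_seq, "HLA-A*02:01",
                              anchors = c(2, 99), source_id = "x"), "anchors")
  expect_error(template_db(list(e, e)), "duplicate")
})
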