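# Shared fixture builders (all generated in code at test time).

# The 12-structure curation set: 8 clean + 1 of each designed defect.
make_defect_set <- function(seed = 42) {
  peps <- c("ACDEFGHIK", "LMNPQRSTV", "WYACDEFGH", "IKLMNPQRS",
            "TVWYACDEF", "GHIKLMNPQ", "RSTVWYACD", "EFGHIKLMN")
  structures <- list()
  ann <- list()
  add <- function(id, fx) {
    structures[[id]] <<- fx$pdb_text
    ann[[id]] <<- data.frame(
      source_id = id, alleles = paste(fx$alleles, collapse = ";"),
      anchors = "", resolution = fx$resolution, stringsAsFactors = FALSE)
  }
  for (i in seq_along(peps)) {
    id <- sprintf("CLEAN%02d", i)
    add(id, make_toy_pmhc(peps[i], alleles = sprintf("HLA-A*%02d:01", i),
                          source_id = id, seed = seed + i))
  }
  add("DEF_NC", make_toy_pmhc("ACDEFGHIK", alleles = "HLA-B*07:02",
                              source_id = "DEF_NC", seed = seed + 20,
                              defects = "noncanonical_residue"))
  add("DEF_GL", make_toy_pmhc("ACDEFGHIK", alleles = "HLA-B*07:02",
                              source_id = "DEF_GL", seed = seed + 21,
                              defects = "groove_ligand"))
  add("DEF_UP", make_toy_pmhc("ACDEFGHIK", alleles = "HLA-B*07:02",
                              source_id = "DEF_UP", seed = seed + 22,
                              defects = "corrupt_record"))
  add("DEF_NA", make_toy_pmhc("ACDEFGHIK", alleles = "HLA-B*07:02",
                              source_id = "DEF_NA", seed = seed + 23,
                              defects = "missing_allele"))
  list(structures = structures, annotations = do.call(rbind, ann))
}

# small clean db with three HLA alleles for hierarchy tests
make_hierarchy_db <- function(seed = 7) {
  specs <- list(
    list(id = "TA0201", pep = "ILKEPVHGV", allele = "HLA-A*02:01"),
    list(id = "TA1101", pep = "KLTPLCVTL", allele = "HLA-A*11:01"),
    list(id = "TB0702", pep = "APRTLVYLL", allele = "HLA-B*07:02"))
  entries <- lapply(seq_along(specs), function(i) {
    sp <- specs[[i]]
    template_entry(
      structure = anchormod:::fixture_structure(
        sp$pep, c(2, nchar(sp$pep)), sp$allele, sp$id, seed = seed + i),
      peptide_seq = sp$pep, alleles = sp$allele,
      anchors = c(2, nchar(sp$pep)), resolution = 1.5 + 0.3 * i,
      source_id = sp$id)
  })
  refs <- vapply(specs, function(sp)
    anchormod:::allele_scaffold_sequence(sp$allele), character(1))
  names(refs) <- vapply(specs, function(sp) sp$allele, character(1))
  template_db(entries, ref_sequences = refs)
}

# raw author-style PDB text with two alpha copies and two peptides
# (asymmetric-unit style); alpha chain D is truncated by 3 residues.
make_two_copy_pdb <- function(seed = 5) {
  s1 <- anchormod:::fixture_structure("ACDEFGHIK", c(2, 9), "HLA-A*02:01",
                                      "COPY", seed = seed)
  a <- s1$atoms
  alpha1 <- a[a$chain == "M", ]; alpha1$chain <- "A"
  pep1 <- a[a$chain == "P", ]; pep1$chain <- "C"
  # second copy shifted far away; alpha truncated by 3 residues
  shift <- function(df, dx) {
    df$x <- df$x + dx
    df
  }
  alpha2 <- shift(alpha1, 100); alpha2$chain <- "D"
  alpha2 <- alpha2[alpha2$resno <= 177, ]
  pep2 <- shift(pep1, 100); pep2$chain <- "E"
  anchormod:::write_raw_pdb(rbind(alpha1, alpha2, pep1, pep2))
}
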