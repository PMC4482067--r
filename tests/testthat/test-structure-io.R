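test_that("a minimal hand-written PDB record parses to one residue", {
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  P     G A   1       1.000   2.000   3.000  1.00 10.00           P",
    "ATOM      2  C1'   G A   1       2.500   3.500   4.500  1.00 10.00           C",
    "END"), path)
  m <- read_structure(path)
  expect_s3_class(m, "structure_model")
  expect_equal(nrow(m$atom), 2)
  rt <- residue_table(m)
  expect_equal(nrow(rt), 1)
  expect_equal(rt$chain, "A")
  expect_equal(rt$base, "G")
  expect_equal(coords(m)[1, ], c(x = 1, y = 2, z = 3))
})

test_that("write/read round-trips preserve topology and coordinates", {
  m <- make_aform_duplex(8, seed = 11)
  for (spec in list(list(ext = ".pdb", tol = 1e-3),
                    list(ext = ".cif", tol = 1e-4))) {
    path <- withr::local_tempfile(fileext = spec$ext)
    write_structure(m, path)
    back <- read_structure(path)
    expect_equal(nrow(back$atom), nrow(m$atom))
    expect_equal(nrow(residue_table(back)), nrow(residue_table(m)))
    expect_equal(back$atom$elety, m$atom$elety)
    expect_equal(back$atom$resno, m$atom$resno)
    expect_lt(max(abs(coords(back) - coords(m))), spec$tol)
  }
})

test_that("unparsable and missing files raise format errors", {
  expect_error(read_structure(tempfile()), "not found")
  bad <- withr::local_tempfile(fileext = ".pdb")
  writeLines("REMARK nothing here", bad)
  expect_error(read_structure(bad))
})

test_that("alt-locs resolve to the highest-occupancy location, ties to 'A'", {
  path <- altloc_fixture_path()
  expect_true(file.exists(path))
  # brute-force census of the text file: every ATOM record minus the
  # alt-B duplicates should survive parsing
  lines <- grep("^ATOM ", readLines(path), value = TRUE)
  alt_field <- vapply(strsplit(lines, " "), `[`, "", 5)
  expected <- length(lines) - sum(alt_field == "B")
  m <- read_structure(path)
  expect_equal(nrow(m$atom), expected)
  kept <- m$atom[m$atom$alt != "", ]
  expect_equal(nrow(kept), 2)          # residues 3 (0.6 > 0.4) and 5 (tie)
  expect_true(all(kept$alt == "A"))
  expect_equal(nrow(residue_table(m)), 20)
})

test_that("zero-occupancy atoms are dropped on read", {
  m <- make_aform_duplex(4, seed = 2, loop_len = 3)
  path <- withr::local_tempfile(fileext = ".pdb")
  m$atom$o[5] <- 0
  write_structure(m, path)
  back <- read_structure(path)
  expect_equal(nrow(back$atom), nrow(m$atom) - 1)
})

test_that("auto rRNA selection applies the length and composition census", {
  n <- c(A = 1500, B = 120, C = 76)
  big <- structure_model(data.frame(
    elety = "P", resid = "G",
    chain = rep(names(n), n),
    resno = unlist(lapply(n, seq_len)),
    x = seq_len(sum(n)), y = 0, z = 0))
  sel <- select_rrna(big, "auto", min_len = 100)
  expect_setequal(unique(sel$atom$chain), c("A", "B"))
  # idempotent
  sel2 <- select_rrna(sel, "auto", min_len = 100)
  expect_identical(sel2$atom, sel$atom)
  # protein chains fail the ribonucleotide census
  prot <- structure_model(data.frame(
    elety = "CA", resid = "ALA", chain = "P", resno = 1:150,
    x = 1:150, y = 0, z = 0))
  both <- combine_models(big, prot)
  expect_setequal(unique(select_rrna(both, "auto")$atom$chain), c("A", "B"))
  # explicit selector naming an absent chain
  expect_error(select_rrna(big, "Z"), "empty selection")
})

test_that("numbering maps relabel without touching coordinates", {
  m <- chain_model(c("A", "C", "G", "U", "A"))
  ident <- numbering_map(data.frame(chain = "A", author_number = 1:5,
                                    reference_number = 1:5))
  mi <- apply_numbering(m, ident)
  expect_equal(residue_table(mi)$refno, 1:5)
  off <- numbering_map(data.frame(chain = "A", author_number = 1:5,
                                  reference_number = 11:15))
  mo <- apply_numbering(m, off)
  expect_equal(residue_table(mo)$refno, 11:15)
  expect_identical(coords(mo), coords(m))
  expect_equal(nrow(mo$atom), nrow(m$atom))
  # omitting residue 3 flags it unmapped but keeps it
  holey <- numbering_map(data.frame(chain = "A",
                                    author_number = c(1, 2, 4, 5),
                                    reference_number = c(1, 2, 4, 5)))
  mh <- apply_numbering(m, holey)
  rt <- residue_table(mh)
  expect_equal(rt$unmapped, c(FALSE, FALSE, TRUE, FALSE, FALSE))
  expect_equal(sum(!is.na(rt$refno)), 4)
  # absent chain in the map
  bad <- numbering_map(data.frame(chain = "Q", author_number = 1,
                                  reference_number = 1))
  expect_error(apply_numbering(m, bad), "absent chain")
  # non-injective map refused
  expect_error(numbering_map(data.frame(chain = "A",
                                        author_number = c(1, 1),
                                        reference_number = c(2, 3))),
               "injective")
})

test_that("numbering-map TSV files round-trip", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("chain\tauthor_number\treference_number",
               "A\t1\t101", "A\t2\t102"), path)
  nm <- read_numbering_map(path)
  expect_equal(nm$reference_number, c(101, 102))
  m <- chain_model(c("G", "C"))
  expect_equal(residue_table(apply_numbering(m, nm))$refno, c(101, 102))
})
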