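test_that("a hand-written PDB parses to per-residue effective atoms", {
  f <- tempfile(fileext = ".pdb")
  fix <- write_tiny_pdb(f)
  rec <- read_structure(f)
  expect_equal(nrow(rec), 3L)
  expect_equal(rec$resno, 1:3)
  expect_equal(rec$aa3, c("GLY", "ALA", "LEU"))
  # effective atom = mean of heavy atoms; waters (HETATM) excluded
  expect_equal(c(rec$x[1], rec$y[1], rec$z[1]), c(1, 0, 0))
  expect_equal(c(rec$x[2], rec$y[2], rec$z[2]), c(5, 1, 1))
  expect_equal(c(rec$x[3], rec$y[3], rec$z[3]), unname(fix$leu_mean),
               tolerance = 1e-6)
  expect_equal(rec$h, unname(hydro_scale()$values[rec$aa3]))
})

test_that("HETATM-only files raise an empty-structure error", {
  f <- tempfile(fileext = ".pdb")
  writeLines(c(
    "HETATM    1 CU    CU A 800      10.000  10.000  10.000  1.00  0.00          CU",
    "HETATM    2  O   HOH A 801      12.000  10.000  10.000  1.00  0.00           O",
    "END"), f)
  expect_error(read_structure(f), "no standard amino-acid residues")
})

test_that("alternate locations resolve to the highest-occupancy conformer", {
  f <- tempfile(fileext = ".pdb")
  writeLines(c(
    pdb_atom_line(1, " CA ", "ALA", "A", 1, 0, 0, 0, occ = 0.4, alt = "A"),
    pdb_atom_line(2, " CA ", "ALA", "A", 1, 9, 9, 9, occ = 0.6, alt = "B"),
    pdb_atom_line(3, " CA ", "GLY", "A", 2, 1, 1, 1),
    "END"), f)
  rec <- read_structure(f)
  expect_equal(nrow(rec), 2L)
  expect_equal(c(rec$x[1], rec$y[1], rec$z[1]), c(9, 9, 9))
})

test_that("modified residues map to their parent under the alias rule", {
  f <- tempfile(fileext = ".pdb")
  writeLines(c(
    pdb_atom_line(1, " CA ", "MSE", "A", 1, 0, 0, 0),
    pdb_atom_line(2, " CA ", "ALA", "A", 2, 3, 0, 0),
    "END"), f)
  rec <- read_structure(f)
  expect_equal(rec$aa3[1], "MET")
  expect_equal(rec$h[1], unname(hydro_scale()$values["MET"]))
})

test_that("effective_atom averages heavy atoms and is equivariant", {
  expect_equal(effective_atom(rbind(c(0, 0, 0), c(2, 0, 0))), c(1, 0, 0))
  expect_equal(effective_atom(c(1, 1, 1)), c(1, 1, 1))
  expect_error(effective_atom(matrix(numeric(0), ncol = 3)), "degenerate")
  set.seed(42)
  atoms <- matrix(rnorm(24), ncol = 3L)
  rot <- random_rotation()
  shift <- c(3, -2, 7)
  moved <- atoms %*% t(rot) + matrix(shift, nrow(atoms), 3L, byrow = TRUE)
  expect_equal(effective_atom(moved),
               as.numeric(rot %*% effective_atom(atoms)) + shift,
               tolerance = 1e-12)
})

test_that("hydrophobicity scales are complete, normalized and assignable", {
  for (nm in c("aggregate", "kd", "fauchere", "eisenberg")) {
    sc <- hydro_scale(nm)
    expect_setequal(names(sc$values), oildrop:::.AA3)
    expect_true(all(sc$values >= 0 & sc$values <= 1))
    expect_equal(unname(range(sc$values)), c(0, 1))
  }
  sc <- hydro_scale()
  poly <- data.frame(chain = "A", resno = 1:20, icode = "",
                     aa3 = names(sc$values), x = 0, y = 0, z = 0,
                     h = NA_real_)
  out <- assign_hydrophobicity(poly, sc)
  expect_equal(out$h, unname(sc$values))
  expect_equal(out$aa3, poly$aa3)   # order preserved
  bad <- poly; bad$aa3[5] <- "XYZ"
  expect_error(assign_hydrophobicity(bad, sc), "XYZ")
})

test_that("user TSV scales load and validate", {
  sc <- hydro_scale()
  f <- tempfile(fileext = ".tsv")
  write.table(data.frame(aa3 = names(sc$values), value = sc$values), f,
              sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  sc2 <- read_hydro_scale(f)
  expect_equal(sc2$values, sc$values)
  write.table(data.frame(aa3 = "ALA", value = 1), f, sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  expect_error(read_hydro_scale(f), "missing standard residues")
})

test_that("selection reports round-trip through TSV", {
  rec <- generate_structure(synthetic_spec(seed = 5))
  f <- tempfile(fileext = ".tsv")
  write_residue_tsv(rec, f)
  back <- read_residue_tsv(f)
  attr(rec, "truth") <- NULL
  expect_equal(as.data.frame(back), as.data.frame(rec), tolerance = 1e-12)
})

test_that("selections resolve order-stable, duplicate-free and checked", {
  rec <- rbind(random_records(10),
               transform(random_records(10), chain = "B"))
  rec <- oildrop:::.as_fod_residues(rec)
  # chain plus overlapping range must not duplicate rows
  idx <- resolve_selection(rec, unit_selection(chains = "A",
                                               ranges = "A:3-7"))
  expect_equal(idx, 1:10)
  idx <- resolve_selection(rec, unit_selection(ranges = c("A:3-5", "B:1-2")))
  expect_equal(rec$chain[idx], c(rep("A", 3), rep("B", 2)))
  expect_false(is.unsorted(idx))
  # exclusions must lie inside the resolved selection
  expect_error(resolve_selection(rec, unit_selection(chains = "A",
                                                     excluded = "B:1")),
               "not in selection")
  expect_error(resolve_selection(rec, unit_selection(ranges = "A:900-999")),
               "empty")
})

test_that("residue identifiers parse with insertion codes", {
  ids <- parse_residue_ids("A:48, A:52B,C:-3")
  expect_equal(ids$chain, c("A", "A", "C"))
  expect_equal(ids$resno, c(48L, 52L, -3L))
  expect_equal(ids$icode, c("", "B", ""))
  expect_error(parse_residue_ids("48"), "cannot parse")
})

test_that("generated PDB record count matches an independent ATOM scan", {
  f <- tempfile(fileext = ".pdb")
  rec <- generate_structure(synthetic_spec(n_residues = 40, seed = 11),
                            pdb_path = f)
  lines <- readLines(f)
  atom_res <- unique(substr(grep("^ATOM", lines, value = TRUE), 18, 27))
  expect_equal(nrow(read_structure(f)), length(atom_res))
  expect_equal(length(atom_res), 40L)
})
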