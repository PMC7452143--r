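test_that("a minimal PDB parses to the stated atom and malformed input errors", {
  f <- write_pdb_fixture(pdb_atom_line(1, "CA", "ALA", "A", 1, 1.5, -2.25, 3.125))
  s <- read_structure(f)
  expect_equal(nrow(s$atoms), 1L)
  expect_equal(unlist(s$atoms[1, c("x", "y", "z")], use.names = FALSE),
               c(1.5, -2.25, 3.125))
  expect_equal(s$atoms$name, "CA")
  expect_equal(s$atoms$chain, "A")

  empty <- tempfile(fileext = ".pdb"); file.create(empty)
  expect_error(read_structure(empty), "empty|no ATOM")

  bad <- write_pdb_fixture(c(pdb_atom_line(1, "CA", "ALA", "A", 1, 0, 0, 0),
                             "ATOM      2  CA  ALA A   2      bad"))
  expect_error(read_structure(bad), "line 2")
})

test_that("alternate locations resolve by occupancy with deterministic ties", {
  f <- write_pdb_fixture(c(
    pdb_atom_line(1, "CA", "ALA", "A", 1, 0, 0, 0),
    pdb_atom_line(2, "CA", "ALA", "A", 2, 1, 0, 0, occ = 0.4, altloc = "A"),
    pdb_atom_line(3, "CA", "ALA", "A", 2, 1.2, 0, 0, occ = 0.6, altloc = "B")))
  s <- read_structure(f)                      # highest occupancy
  expect_equal(nrow(s$atoms), 2L)
  expect_equal(s$atoms$x[2], 1.2)
  s1 <- read_structure(f, altloc_policy = "first")
  expect_equal(s1$atoms$x[2], 1.0)
  s2 <- read_structure(f, altloc_policy = "all")
  expect_equal(nrow(s2$atoms), 3L)

  # occupancy tie: altloc identifier order decides
  g <- write_pdb_fixture(c(
    pdb_atom_line(1, "CA", "ALA", "A", 1, 5, 0, 0, occ = 0.5, altloc = "B"),
    pdb_atom_line(2, "CA", "ALA", "A", 1, 7, 0, 0, occ = 0.5, altloc = "A")))
  expect_equal(read_structure(g)$atoms$x, 7)
})

test_that("header resolution and multi-model selection are honoured", {
  f <- write_pdb_fixture(c(
    "REMARK   2 RESOLUTION.    2.10 ANGSTROMS.",
    "MODEL        1",
    pdb_atom_line(1, "CA", "ALA", "A", 1, 0, 0, 0),
    "ENDMDL",
    "MODEL        2",
    pdb_atom_line(1, "CA", "ALA", "A", 1, 9, 9, 9),
    "ENDMDL"))
  s <- read_structure(f)
  expect_equal(s$resolution, 2.1)
  expect_equal(s$atoms$x, 0)                  # first model by default
  s2 <- read_structure(f, model = 2)
  expect_equal(unlist(s2$atoms[1, c("x", "y", "z")], use.names = FALSE), c(9, 9, 9))
  expect_error(read_structure(f, model = 3), "out of range")
})

test_that("serialize then parse preserves identities and coordinates", {
  toy <- make_toy_complex(62, c(1, -2), planted_contacts = list(
    list(type = "HB", target = "peptide", tcr_chain = "alpha", distance = 2.9)))
  tf <- tempfile(fileext = ".pdb")
  write_structure(toy$structure, tf)
  back <- read_structure(tf)
  a0 <- toy$structure$atoms; a1 <- back$atoms
  expect_equal(nrow(a1), nrow(a0))
  expect_equal(a1$chain, a0$chain)
  expect_equal(a1$resno, a0$resno)
  expect_equal(a1$name, a0$name)
  expect_equal(a1$resname, a0$resname)
  expect_equal(round(a1$x, 3), round(a0$x, 3))
  expect_equal(round(a1$y, 3), round(a0$y, 3))
  expect_equal(round(a1$z, 3), round(a0$z, 3))
})

test_that("role assignment uses the length heuristic, config wins, few chains error", {
  toy <- make_toy_complex(45)                 # chain lengths 275/99/9/200/240
  ann <- annotate_complex(toy$structure)
  expect_equal(unname(ann$roles[c("HLA_heavy", "beta2m", "peptide",
                                  "TCR_alpha", "TCR_beta")]),
               c("A", "B", "C", "D", "E"))
  expect_true(all(c("CDR3a", "CDR3b") %in% names(ann$loops)))

  # explicit config overrides the heuristic (swap the TCR chains)
  cfg <- list(roles = list(TCR_alpha = "E", TCR_beta = "D", HLA_heavy = "A",
                           beta2m = "B", peptide = "C"))
  ann2 <- annotate_complex(toy$structure, config = cfg)
  expect_equal(unname(ann2$roles[["TCR_alpha"]]), "E")

  three <- mk_complex(
    mk_structure("CA", "ALA", "A", 1:20, (1:20) * 3.8, 0, 0),
    mk_structure("CA", "ALA", "B", 1:20, (1:20) * 3.8, 5, 0),
    mk_structure("CA", "ALA", "C", 1:9, (1:9) * 3.8, 10, 0))
  expect_error(annotate_complex(three), "chains")
  expect_error(annotate_complex(toy$structure,
                                config = list(roles = list(peptide = "C"))),
               "missing roles")
})

test_that("sequence diff labels loops, is antisymmetric and guards identity", {
  wt <- make_toy_complex(45)
  va <- wt
  va$structure <- mutate_residue(va$structure, "D", 26, "TYR")   # CDR1a
  va$structure <- mutate_residue(va$structure, "E", 98, "TRP")   # CDR3b
  d <- diff_sequences(wt$structure, wt$annotation, va$structure, va$annotation)
  expect_equal(nrow(d), 2L)
  expect_equal(d$region[d$chain_role == "TCR_alpha"], "CDR1a")
  expect_equal(d$region[d$chain_role == "TCR_beta"], "CDR3b")
  expect_equal(d$wt[d$position == 26], "A")
  expect_equal(d$variant[d$position == 26], "Y")

  # identical sequences: empty
  d0 <- diff_sequences(wt$structure, wt$annotation, wt$structure, wt$annotation)
  expect_equal(nrow(d0), 0L)

  # antisymmetry: wt and variant residues swap
  dr <- diff_sequences(va$structure, va$annotation, wt$structure, wt$annotation)
  expect_equal(dr$position, d$position)
  expect_equal(dr$wt, d$variant)
  expect_equal(dr$variant, d$wt)

  # unrelated sequences fall below the identity floor
  scram <- wt
  set.seed(4)
  sel <- scram$structure$atoms$chain == "D"
  scram$structure$atoms$resname[sel] <-
    sample(c("TRP", "PHE", "MET", "HIS", "GLU"), sum(sel), replace = TRUE)
  expect_error(diff_sequences(wt$structure, wt$annotation,
                              scram$structure, scram$annotation),
               "identity")
})
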