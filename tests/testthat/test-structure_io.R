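test_that("a minimal single-model PDB parses into one model with its atoms", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    pdb_line(1, "N", "ALA", "A", 1, 11.104, 6.134, -6.504),
    pdb_line(2, "CA", "ALA", "A", 1, 12.560, 6.351, -6.510),
    pdb_line(3, "C", "ALA", "A", 1, 13.061, 6.567, -5.084),
    "END"), f)
  st <- read_structure(f)
  expect_equal(n_models(st), 1L)
  expect_equal(n_atoms(st), 3L)
  expect_equal(model_coords(st)[2, ], c(12.560, 6.351, -6.510))
  expect_equal(st$atoms$elety, c("N", "CA", "C"))
})

test_that("MODEL blocks delimit models and rosters must agree", {
  a <- c(pdb_line(1, "CA", "GLY", "A", 1, 0, 0, 0),
         pdb_line(2, "CA", "GLY", "A", 2, 3.8, 0, 0))
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c("MODEL     1", a, "ENDMDL",
               "MODEL     2", sub("0\\.000", "1.000", a[1]), a[2], "ENDMDL",
               "END"), f)
  st <- read_structure(f)
  expect_equal(n_models(st), 2L)

  f2 <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c("MODEL     1", a, "ENDMDL",
               "MODEL     2", a[1], "ENDMDL", "END"), f2)
  expect_error(read_structure(f2), "roster.*missing.*A\\|2\\|\\|CA")
})

test_that("altlocs resolve to highest occupancy, ties to first in file", {
  f <- withr::local_tempfile(fileext = ".pdb")
  l1 <- pdb_line(1, "CA", "SER", "A", 1, 1, 0, 0, occ = 0.4)
  l2 <- pdb_line(2, "CA", "SER", "A", 1, 2, 0, 0, occ = 0.6)
  substr(l1, 17, 17) <- "A"; substr(l2, 17, 17) <- "B"
  writeLines(c(l1, l2, "END"), f)
  st <- read_structure(f)
  expect_equal(n_atoms(st), 1L)
  expect_equal(model_coords(st)[1, 1], 2)   # the 0.6-occupancy copy

  f2 <- withr::local_tempfile(fileext = ".pdb")
  l3 <- pdb_line(1, "CA", "SER", "A", 1, 1, 0, 0, occ = 0.5)
  l4 <- pdb_line(2, "CA", "SER", "A", 1, 2, 0, 0, occ = 0.5)
  substr(l3, 17, 17) <- "A"; substr(l4, 17, 17) <- "B"
  writeLines(c(l3, l4, "END"), f2)
  expect_equal(model_coords(read_structure(f2))[1, 1], 1)  # tie: first wins
})

test_that("waters and hetero atoms are excluded by default, kept on request", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(pdb_line(1, "CA", "ALA", "A", 1, 0, 0, 0),
               pdb_line(2, "O", "HOH", "A", 90, 5, 5, 5, type = "HETATM"),
               pdb_line(3, "ZN", "ZN", "A", 91, 6, 6, 6, type = "HETATM",
                        element = "ZN"),
               "END"), f)
  expect_equal(n_atoms(read_structure(f)), 1L)
  expect_equal(n_atoms(read_structure(f, keep_hetero = TRUE)), 2L)
  expect_equal(n_atoms(read_structure(f, keep_hetero = TRUE, keep_waters = TRUE)), 3L)
})

test_that("parse failures name the offending line", {
  f <- withr::local_tempfile(fileext = ".pdb")
  bad <- pdb_line(1, "CA", "ALA", "A", 1, 0, 0, 0)
  substr(bad, 31, 38) <- "  xx.xxx"
  writeLines(c(bad, "END"), f)
  expect_error(read_structure(f), "parse failure.*line 1")
})

test_that("write -> read round-trip preserves coordinates to PDB precision and all residue ids", {
  toy <- make_toy_fab(toy_fab_spec(n_frames = 3, seed = 7, jitter_sigma = 0.2))
  st <- toy$structure
  f <- withr::local_tempfile(fileext = ".pdb")
  write_structure(st, f)
  st2 <- read_structure(f)
  expect_equal(n_models(st2), n_models(st))
  expect_equal(n_atoms(st2), n_atoms(st))
  expect_lt(max(abs(st2$xyz - st$xyz)), 5.1e-4)
  expect_identical(st2$atoms[c("chain", "resno", "insert", "elety")],
                   st$atoms[c("chain", "resno", "insert", "elety")])
  # read -> write -> read is a fixed point (byte level)
  f2 <- withr::local_tempfile(fileext = ".pdb")
  write_structure(st2, f2)
  f3 <- withr::local_tempfile(fileext = ".pdb")
  write_structure(read_structure(f2), f3)
  expect_identical(readBin(f2, "raw", file.size(f2)),
                   readBin(f3, "raw", file.size(f3)))
})

test_that("insertion-coded residues order after their parent number and fall in its range", {
  rows <- rbind(atom_row("CA", "ALA", "L", 100), atom_row("CA", "GLY", "L", 103),
                atom_row("CA", "SER", "L", 103, insert = "a"),
                atom_row("CA", "VAL", "L", 103, insert = "b"),
                atom_row("CA", "LEU", "L", 104))
  extra <- do.call(rbind, lapply(85:99, function(i) atom_row("CA", "ALA", "L", i)))
  h <- ca_chain("H", 1:25)
  atoms <- rbind(h$atoms, extra, rows)
  atoms$eleno <- seq_len(nrow(atoms))
  coords <- rbind(h$coords, matrix(rnorm(3 * (nrow(extra) + nrow(rows))), ncol = 3))
  st <- fab_structure(atoms, coords)
  map <- domain_map(VH = list(chain = "H", range = c(1, 25)),
                    VL = list(chain = "L", range = c(85, 107)))
  fab <- apply_domain_map(st, map)
  s <- extract_sequence(fab, "VL", with_positions = TRUE)
  expect_equal(substr(s$sequence, 16, 20), "AGSVL")        # 100,103,103a,103b,104
  expect_equal(s$positions[17:19], c("103", "103a", "103b"))
})

test_that("a range ending at the parent number still includes its insertions", {
  # kappa FWR4 convention: a chain carrying 107a is captured by range 1-107
  ch <- ca_chain("L", 88:107)
  ins <- atom_row("CA", "GLY", "L", 107, insert = "a")
  h <- ca_chain("H", 1:25)
  atoms <- rbind(h$atoms, ch$atoms, ins)
  atoms$eleno <- seq_len(nrow(atoms))
  st <- fab_structure(atoms, rbind(h$coords, ch$coords, c(0, 9, 9)))
  fab <- apply_domain_map(st, domain_map(VH = list(chain = "H", range = c(1, 25)),
                                         VL = list(chain = "L", range = c(1, 107))))
  ca <- domain_calphas(fab, "VL")
  expect_equal(sum(ca$positions == 107), 2L)
  expect_true("a" %in% ca$insert)
})

test_that("sequence extraction maps standard residues and falls back to X", {
  p <- ca_chain("H", 1:20)
  tail3 <- rbind(atom_row("CA", "ALA", "H", 21), atom_row("CA", "GLY", "H", 22),
                 atom_row("CA", "SER", "H", 23), atom_row("CA", "MSE", "H", 24))
  atoms <- rbind(p$atoms, tail3)
  atoms$eleno <- seq_len(nrow(atoms))
  l <- ca_chain("L", 1:20, origin = c(0, 20, 0))
  atoms2 <- rbind(atoms, l$atoms)
  atoms2$eleno <- seq_len(nrow(atoms2))
  st <- fab_structure(atoms2, rbind(p$coords, matrix(rnorm(12), ncol = 3), l$coords))
  fab <- apply_domain_map(st, domain_map(VH = list(chain = "H", range = c(1, 24)),
                                         VL = list(chain = "L", range = c(1, 20))))
  expect_equal(substr(extract_sequence(fab, "VH"), 21, 24), "AGSX")
})

test_that("domain-map violations raise informative errors", {
  toy <- make_toy_fab(toy_fab_spec(seed = 1))
  st <- toy$structure
  expect_error(apply_domain_map(st, domain_map(VH = list(chain = "Z", range = c(1, 60)),
                                               VL = list(chain = "L", range = c(1, 60)))),
               "chain 'Z' not present")
  expect_error(apply_domain_map(st, domain_map(VH = list(chain = "H", range = c(1, 10)),
                                               VL = list(chain = "L", range = c(1, 60)))),
               "only 10 C-alpha")
  expect_error(domain_map(VH = list(chain = "H", range = c(1, 60)),
                          VL = list(chain = "L", range = c(1, 60)),
                          CH1 = list(chain = "H", range = c(50, 120))),
               "overlapping")
})

test_that("domain maps round-trip through YAML", {
  toy <- make_toy_fab(toy_fab_spec(seed = 1))
  f <- withr::local_tempfile(fileext = ".yaml")
  write_domain_map(toy$map, f)
  m2 <- read_domain_map(f)
  expect_equal(m2$light_isotype, toy$map$light_isotype)
  expect_equal(lapply(m2$domains, `[[`, "range"),
               lapply(toy$map$domains, function(d) as.integer(d$range)))
})
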