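test_that("single-sphere ASA matches the closed form within quadrature error", {
  a <- shrake_rupley(matrix(c(0, 0, 0), 1), radii = 1.6, probe_radius = 1.4)
  expect_equal(a$total, 4 * pi * 3^2, tolerance = 0.01)
  # per-atom ASA can never exceed the full expanded sphere
  expect_lte(a$total, 4 * pi * 3^2 + 1e-9)
})

test_that("well-separated atoms contribute independent areas", {
  sep <- shrake_rupley(rbind(c(0, 0, 0), c(100, 0, 0)), radii = c(1.6, 1.7))
  iso <- shrake_rupley(matrix(c(0, 0, 0), 1), radii = 1.6)$total +
         shrake_rupley(matrix(c(0, 0, 0), 1), radii = 1.7)$total
  expect_equal(sep$total, iso, tolerance = 1e-12)
})

test_that("two intersecting equal spheres match the spherical-cap closed form", {
  # expanded radius R = 3.0, centres 2.0 apart: per-sphere exposed area
  # 2 pi R (R + d/2) = 24 pi
  a <- shrake_rupley(rbind(c(0, 0, 0), c(2, 0, 0)), radii = c(1.6, 1.6))
  expect_equal(a$atom_asa[1], 24 * pi, tolerance = 0.01)
  expect_equal(a$atom_asa[2], 24 * pi, tolerance = 0.01)
})

test_that("quadrature converges: 960 versus 4000 points differ by under 1%", {
  set.seed(21)
  for (i in 1:3) {
    coords <- matrix(rnorm(150, sd = 4), ncol = 3)
    radii <- stats::runif(50, 1.4, 1.9)
    a1 <- shrake_rupley(coords, radii = radii, n_points = 960)$total
    a2 <- shrake_rupley(coords, radii = radii, n_points = 4000)$total
    expect_lt(abs(a1 - a2) / a2, 0.01)
  }
})

test_that("native quadrature agrees with an independent grid oracle within 2%", {
  set.seed(22)
  for (i in 1:3) {
    n <- sample(5:20, 1)
    coords <- matrix(rnorm(3 * n, sd = 3), ncol = 3)
    radii <- stats::runif(n, 1.4, 1.9)
    mine <- shrake_rupley(coords, radii = radii)$total
    oracle <- grid_sasa(coords, radii)$total
    expect_lt(abs(mine - oracle) / oracle, 0.02)
  }
})

test_that("buried ASA follows the two-sphere closed form and basic identities", {
  # one sphere per side, the contact system from the cap-formula check
  atoms <- rbind(atom_row("O", "SER", "A", 1, elesy = "O"),
                 atom_row("O", "SER", "B", 1, elesy = "O"))
  atoms$eleno <- 1:2
  atoms$radius <- 1.6
  mkfab <- function(d) {
    st <- fab_structure(atoms, rbind(c(0, 0, 0), c(d, 0, 0)))
    st$atoms$radius <- c(1.6, 1.6)
    apply_domain_map(st, domain_map(VH = list(chain = "A", range = c(1, 1)),
                                    VL = list(chain = "B", range = c(1, 1))),
                     min_calpha = 0L)
  }
  spec <- interface_spec("VH-VL")
  b <- buried_asa(mkfab(2), spec)
  expect_equal(as.numeric(b), 2 * 4 * pi * 9 - 2 * 24 * pi, tolerance = 0.01)
  expect_equal(attr(b, "interface_area"), as.numeric(b) / 2)
  # separated sides bury nothing
  expect_equal(as.numeric(buried_asa(mkfab(100), spec)), 0, tolerance = 1e-9)
  # symmetric in side order
  spec_rev <- interface_spec("custom", side_a = "VL", side_b = "VH")
  expect_equal(as.numeric(buried_asa(mkfab(2), spec_rev)), as.numeric(b),
               tolerance = 1e-9)
})

test_that("buried ASA is non-negative on random jittered Fabs", {
  toy <- make_toy_fab(toy_fab_spec(seed = 23, n_frames = 3, jitter_sigma = 0.3))
  fab <- apply_domain_map(toy$structure, toy$map)
  for (m in 1:3) {
    expect_gte(as.numeric(buried_asa(fab, interface_spec("VH-VL"), m)), 0)
    expect_gte(as.numeric(buried_asa(fab, interface_spec("elbow"), m)), 0)
  }
})

test_that("interface residues are those losing more than the ASA threshold", {
  fx <- make_contact_fixture("saltbridge", 3.0)
  ir <- interface_residues(fx$fab, fx$spec)
  expect_equal(nrow(ir$side_a), 1L)
  expect_equal(nrow(ir$side_b), 1L)
  # an absurdly high threshold excludes everything
  ir2 <- interface_residues(fx$fab, fx$spec, min_delta = 1e6)
  expect_equal(nrow(ir2$side_a), 0L)
  # distant sides share no interface
  toy <- make_toy_fab(toy_fab_spec(seed = 24))
  st <- toy$structure
  cm <- model_coords(st, 1)
  idx <- which(st$atoms$chain == "L" & st$atoms$resno <= 60)
  cm[idx, 1] <- cm[idx, 1] + 500
  far <- apply_domain_map(set_model_coords(st, 1, cm), toy$map)
  irf <- interface_residues(far, interface_spec("VH-VL"))
  expect_equal(nrow(irf$side_a) + nrow(irf$side_b), 0L)
})

test_that("hydrogen bonds require donor typing, distance, and angle", {
  ok <- make_contact_fixture("hbond", 2.9, 160)
  expect_equal(nrow(detect_hbonds(ok$fab, ok$spec)), 1L)
  too_far <- make_contact_fixture("hbond", 3.6, 160)
  expect_equal(nrow(detect_hbonds(too_far$fab, too_far$spec)), 0L)
  bad_angle <- make_contact_fixture("hbond", 2.9, 100)
  expect_equal(nrow(detect_hbonds(bad_angle$fab, bad_angle$spec)), 0L)
  carbon <- make_contact_fixture("none", 2.9)
  expect_equal(nrow(detect_hbonds(carbon$fab, carbon$spec)), 0L)
})

test_that("without hydrogens detection falls back to heavy-atom mode and flags it", {
  fx <- make_contact_fixture("hbond", 2.9, 160)
  st <- fx$fab$structure
  keep <- which(st$atoms$elesy != "H")
  st2 <- fab_structure(st$atoms[keep, ], model_coords(st, 1)[keep, ])
  fab2 <- apply_domain_map(st2, domain_map(VH = list(chain = "A", range = c(1, 1)),
                                           VL = list(chain = "B", range = c(1, 1))),
                           min_calpha = 1L)
  hb <- detect_hbonds(fab2, fx$spec)
  expect_equal(nrow(hb), 1L)
  expect_true(attr(hb, "heavy_only"))
  expect_true(is.na(hb$angle[1]))
})

test_that("salt bridges need opposite charges within the cutoff", {
  ok <- make_contact_fixture("saltbridge", 3.2)
  expect_equal(nrow(detect_saltbridges(ok$fab, ok$spec)), 1L)
  far <- make_contact_fixture("saltbridge", 4.5)
  expect_equal(nrow(detect_saltbridges(far$fab, far$spec)), 0L)
  # same-sign pair: Glu OE1 against Asp OD1
  a <- atom_row("OE1", "GLU", "A", 1, elesy = "O")
  b <- atom_row("OD1", "ASP", "B", 1, elesy = "O")
  ca1 <- atom_row("CA", "GLU", "A", 1); ca2 <- atom_row("CA", "ASP", "B", 1)
  atoms <- rbind(a, ca1, b, ca2); atoms$eleno <- 1:4
  st <- fab_structure(atoms, rbind(c(0, 0, 0), c(0, 0, 50), c(3.2, 0, 0), c(3, 0, 50)))
  fab <- apply_domain_map(st, domain_map(VH = list(chain = "A", range = c(1, 1)),
                                         VL = list(chain = "B", range = c(1, 1))),
                          min_calpha = 1L)
  expect_equal(nrow(detect_saltbridges(fab, interface_spec("VH-VL"))), 0L)
})

test_that("contact occupancy counts the fraction of snapshots satisfying the criteria", {
  fx <- make_contact_fixture("saltbridge", 3.2)
  st1 <- fx$fab$structure
  # 10 models: in the last 5, pull the negative-charge atom out of range
  xyz <- st1$xyz[rep(1, 10), , drop = FALSE]
  acc <- which(st1$atoms$elety == "OE1")
  for (m in 6:10) xyz[m, 3 * (acc - 1) + 1] <- xyz[m, 3 * (acc - 1) + 1] - 10
  st10 <- fab_structure(st1$atoms, xyz)
  fab10 <- apply_domain_map(st10, domain_map(VH = list(chain = "A", range = c(1, 1)),
                                             VL = list(chain = "B", range = c(1, 1))),
                            min_calpha = 1L)
  occ <- contact_occupancy(fab10, fx$spec, kinds = "saltbridge")
  expect_equal(nrow(occ), 1L)
  expect_equal(occ$occupancy, 0.5)
  expect_equal(occ$n_models, 10L)
  # always present -> 1.0
  stc <- fab_structure(st1$atoms, st1$xyz[rep(1, 4), , drop = FALSE])
  fabc <- apply_domain_map(stc, domain_map(VH = list(chain = "A", range = c(1, 1)),
                                           VL = list(chain = "B", range = c(1, 1))),
                           min_calpha = 1L)
  expect_equal(contact_occupancy(fabc, fx$spec, kinds = "saltbridge")$occupancy, 1.0)
  # never-present pairs are absent, not rows of zero occupancy
  expect_true(all(occ$occupancy > 0))
  rl <- attr(occ, "residue_level")
  expect_equal(rl$occupancy, 0.5)
})

test_that("spatial-hash contact search equals the exhaustive nested-loop oracle", {
  mism <- 0
  for (s in 1:60) {
    fab <- random_contact_fab(seed = 3000 + s)
    spec <- interface_spec("VH-VL")
    got <- c()
    hb <- detect_hbonds(fab, spec)
    sb <- detect_saltbridges(fab, spec)
    atoms <- fab$structure$atoms
    lab <- paste0(atoms$chain, ":", atoms$resid, atoms$resno, atoms$insert, ":",
                  atoms$elety)
    to_idx <- function(v) match(v, lab)
    got <- as.character(sort(unique(c(
      if (nrow(hb)) paste("hbond", to_idx(hb$donor), to_idx(hb$acceptor)),
      if (nrow(sb)) paste("saltbridge", to_idx(sb$donor), to_idx(sb$acceptor))))))
    want <- oracle_contacts(atoms, model_coords(fab$structure, 1),
                            fab$domains$VH, fab$domains$VL)
    if (!identical(got, want)) mism <- mism + 1
  }
  expect_equal(mism, 0)
})
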