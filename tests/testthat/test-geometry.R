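test_that("Kabsch superposition recovers identity and pure rotations", {
  set.seed(11)
  pts <- matrix(rnorm(30), ncol = 3)
  tf <- kabsch_superpose(pts, pts)
  expect_equal(tf$rotation, diag(3), tolerance = 1e-12)
  expect_equal(tf$translation, c(0, 0, 0), tolerance = 1e-12)
  expect_equal(tf$rmsd, 0, tolerance = 1e-12)

  R90 <- rotation_matrix(c(0, 0, 1), 90)
  tf2 <- kabsch_superpose(pts, pts %*% t(R90))
  expect_equal(sum(diag(tf2$rotation)), 1, tolerance = 1e-9)  # 1 + 2 cos 90
  expect_equal(tf2$rmsd, 0, tolerance = 1e-9)
})

test_that("the reflection branch is corrected: best proper fit of a mirror image matches brute force", {
  set.seed(12)
  pts <- matrix(rnorm(12), ncol = 3)       # 4-point non-planar set
  mirror <- pts %*% diag(c(-1, 1, 1))
  tf <- kabsch_superpose(pts, mirror)
  expect_equal(det(tf$rotation), 1, tolerance = 1e-9)
  expect_gt(tf$rmsd, 0)
  expect_equal(tf$rmsd, brute_force_rmsd(pts, mirror), tolerance = 1e-5)
})

test_that("Kabsch agrees with an independent quaternion oracle on 1000 random instances", {
  set.seed(13)
  worst <- 0
  for (i in 1:1000) {
    n <- sample(4:30, 1)
    a <- matrix(rnorm(3 * n, sd = 5), ncol = 3)
    b <- matrix(rnorm(3 * n, sd = 5), ncol = 3)
    worst <- max(worst, abs(kabsch_superpose(a, b)$rmsd - quaternion_superpose(a, b)$rmsd))
  }
  expect_lt(worst, 1e-9)
})

test_that("degenerate point sets are rejected", {
  line <- cbind(1:5, 0, 0)
  expect_error(kabsch_superpose(line, line + 1), "degenerate")
  expect_error(kabsch_superpose(matrix(0, 2, 3), matrix(0, 2, 3)), "at least 3")
})

test_that("frame registration is exact on the reference and equivariant under rigid motion", {
  ref <- reference_domain("V")
  fr <- fit_domain_frame(list(positions = ref$positions, coords = ref$coords), ref)
  expect_equal(fr$origin, c(0, 0, 0), tolerance = 1e-12)
  expect_equal(fr$v1, c(1, 0, 0), tolerance = 1e-12)
  expect_equal(fr$rmsd, 0, tolerance = 1e-12)

  set.seed(14)
  for (i in 1:5) {
    tf <- random_rigid_transform()
    moved <- apply_transform(ref$coords, tf)
    fr2 <- fit_domain_frame(list(positions = ref$positions, coords = moved), ref)
    expect_equal(fr2$origin, as.numeric(apply_transform(rbind(c(0, 0, 0)), tf)),
                 tolerance = 1e-9)
    expect_equal(fr2$v1, as.numeric(tf$rotation %*% c(1, 0, 0)), tolerance = 1e-9)
    expect_equal(fr2$v2, as.numeric(tf$rotation %*% c(0, 1, 0)), tolerance = 1e-9)
  }
})

test_that("frame registration tolerates missing coreset residues down to the 80% floor", {
  ref <- reference_domain("V")
  keep <- 1:50   # 83% of 60
  fr <- fit_domain_frame(list(positions = keep, coords = ref$coords[keep, ]), ref)
  expect_equal(fr$n_used, 50L)
  expect_error(fit_domain_frame(list(positions = 1:40, coords = ref$coords[1:40, ]), ref),
               "coverage.*67%.*missing")
})

test_that("frame origin stays within the jitter scale over 100 noisy registrations", {
  ref <- reference_domain("V")
  set.seed(15)
  worst <- 0
  for (i in 1:100) {
    noisy <- ref$coords + matrix(rnorm(length(ref$coords), sd = 0.2), ncol = 3)
    fr <- fit_domain_frame(list(positions = ref$positions, coords = noisy), ref)
    worst <- max(worst, sqrt(sum(fr$origin^2)))
  }
  expect_lt(worst, 0.2)
})

test_that("orientation parameters are invariant under global rigid transforms", {
  toy <- make_toy_fab(toy_fab_spec(seed = 5, hl = list(mode = "constant", value = 12),
                                   dc = list(mode = "constant", value = 2)))
  fab <- apply_domain_map(toy$structure, toy$map)
  o <- unclass(vhvl_orientation(fab))
  set.seed(16)
  for (i in 1:5) {
    st2 <- transform_structure(toy$structure, random_rigid_transform())
    o2 <- unclass(vhvl_orientation(apply_domain_map(st2, toy$map)))
    expect_equal(o2, o, tolerance = 1e-9)
  }
})

test_that("a torsion twist moves only HL, a distance shift only dc", {
  base <- make_toy_fab(toy_fab_spec(seed = 6))
  fab0 <- apply_domain_map(base$structure, base$map)
  o0 <- unclass(vhvl_orientation(fab0))

  tw <- make_toy_fab(toy_fab_spec(seed = 6, n_frames = 2,
                                  hl = list(mode = "ramp", from = 0, to = 10)))
  fabt <- apply_domain_map(tw$structure, tw$map)
  ot <- unclass(vhvl_orientation(fabt, 2))
  expect_equal(ot[["HL"]] - o0[["HL"]], 10, tolerance = 1e-9)
  expect_equal(ot[c("HC1", "HC2", "LC1", "LC2", "dc")],
               o0[c("HC1", "HC2", "LC1", "LC2", "dc")], tolerance = 1e-9)

  sh <- make_toy_fab(toy_fab_spec(seed = 6, n_frames = 2,
                                  dc = list(mode = "ramp", from = 0, to = 5)))
  fabs <- apply_domain_map(sh$structure, sh$map)
  os <- unclass(vhvl_orientation(fabs, 2))
  expect_equal(os[["dc"]] - o0[["dc"]], 5, tolerance = 1e-9)
  expect_equal(os[c("HL", "HC1", "HC2", "LC1", "LC2")],
               o0[c("HL", "HC1", "HC2", "LC1", "LC2")], tolerance = 1e-9)
})

test_that("HL responds antisymmetrically to twisting VH versus VL", {
  toy <- make_toy_fab(toy_fab_spec(seed = 8))
  fab <- apply_domain_map(toy$structure, toy$map)
  fh <- fit_domain_frame(domain_calphas(fab, "VH"), reference_domain("V"))
  fl <- fit_domain_frame(domain_calphas(fab, "VL"), reference_domain("V"))
  axis <- fl$origin - fh$origin
  rot_domain <- function(st, idx, angle) {
    cm <- model_coords(st, 1)
    R <- rotation_matrix(axis, angle)
    cm[idx, ] <- sweep(sweep(cm[idx, , drop = FALSE], 2, fh$origin) %*% t(R),
                       2, -fh$origin)
    set_model_coords(st, 1, cm)
  }
  o0 <- vhvl_orientation(fab)[["HL"]]
  st_h <- rot_domain(toy$structure, fab$domains$VH, +7)
  st_l <- rot_domain(toy$structure, fab$domains$VL, -7)
  hl_h <- vhvl_orientation(apply_domain_map(st_h, toy$map))[["HL"]]
  hl_l <- vhvl_orientation(apply_domain_map(st_l, toy$map))[["HL"]]
  expect_equal(hl_h - o0, hl_l - o0, tolerance = 1e-9)
})

test_that("pseudo-dyad recovers a constructed twofold axis", {
  ref <- reference_domain("V")
  a <- list(positions = ref$positions, coords = ref$coords)
  b <- list(positions = ref$positions,
            coords = apply_transform(ref$coords,
                                     list(rotation = rotation_matrix(c(0, 0, 1), 180),
                                          translation = c(0, 0, 0))))
  d <- pseudo_dyad(a, b)
  # acos conditioning near trace = -1 limits precision to ~1e-6 deg
  expect_equal(d$angle_deg, 180, tolerance = 1e-7)
  expect_equal(abs(d$axis[3]), 1, tolerance = 1e-6)

  set.seed(17)
  bj <- b
  bj$coords <- bj$coords + matrix(rnorm(length(b$coords), sd = 0.1), ncol = 3)
  dj <- pseudo_dyad(a, bj)
  expect_lt(abs(dj$angle_deg - 180), 1)
  expect_lt(vec_angle(dj$axis * sign(dj$axis[3]), c(0, 0, 1)), 1)

  expect_warning(di <- pseudo_dyad(a, a), "magnitude")
  expect_true(di$low_angle)
  expect_lt(di$angle_deg, 1)
})

test_that("elbow angle reads 180 for the parallel-dyad assembly and tracks applied rotations", {
  toy <- make_toy_fab(toy_fab_spec(seed = 9))
  fab <- apply_domain_map(toy$structure, toy$map)
  expect_equal(as.numeric(elbow_angle(fab)), 180, tolerance = 1e-9)

  for (delta in c(25, -40, 60)) {
    t2 <- make_toy_fab(toy_fab_spec(seed = 9, n_frames = 2,
                                    elbow = list(mode = "ramp", from = 0, to = delta)))
    f2 <- apply_domain_map(t2$structure, t2$map)
    expect_equal(as.numeric(elbow_angle(f2, 2)) - as.numeric(elbow_angle(f2, 1)),
                 delta, tolerance = 1e-6)
    expect_equal(as.numeric(elbow_angle(f2, 2)), 180 + delta, tolerance = 1e-6)
  }

  set.seed(18)
  st2 <- transform_structure(toy$structure, random_rigid_transform())
  expect_equal(as.numeric(elbow_angle(apply_domain_map(st2, toy$map))), 180,
               tolerance = 1e-9)
})

test_that("axis-angle extraction is stable near 180 degrees", {
  for (ax in list(c(1, 0, 0), c(1, 2, 3), c(0, 1, -1))) {
    aa <- rotation_axis_angle(rotation_matrix(ax, 180))
    expect_equal(aa$angle_deg, 180, tolerance = 1e-6)
    expect_lt(min(vec_angle(aa$axis, ax), vec_angle(-aa$axis, ax)), 1e-4)
  }
})
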