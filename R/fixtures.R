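# Deterministic generator of idealized Fab-like assemblies and rigid-body
# "trajectories" with known ground-truth geometry.  The toy domains are
# geometric idealizations (two-layer beta-sandwich C-alpha lattices with
# backbone stubs), NOT physical proteins: every operation in this toolkit is
# purely geometric or statistical, so a rigid body with known applied
# rotations is the appropriate test double for MD output and PDB depositions.
# Do not mistake these fixtures for structural models.

#' Idealized reference domain
#'
#' Builds a two-layer antiparallel beta-sandwich C-alpha lattice with a small
#' deterministic jitter (to break lattice symmetry), centred on the origin,
#' with an embedded orthonormal frame (`v1 = x`, `v2 = y`).  Deterministic
#' per seed; the frame origin is exactly the coreset centroid.
#'
#' @param size number of residues, `>= 20`.
#' @param seed integer seed fixing the lattice jitter.
#' @return list with `positions` (1:size), `coords` (`size x 3`, centred),
#'   `origin` (zero vector), `v1`, `v2`, `seed`.
#' @export
make_reference_domain <- function(size = 60L, seed = 1L) {
  size <- as.integer(size)
  if (size < 20L) stop("size must be >= 20")
  i <- seq_len(size) - 1L
  strand <- i %/% 10L
  pos <- i %% 10L
  layer <- strand %% 2L
  x <- ifelse(strand %% 2L == 0L, 3.4 * pos, 3.4 * (9L - pos))
  y <- 4.8 * (strand %/% 2L)
  z <- ifelse(layer == 0L, -2.4, 2.4)
  coords <- cbind(x, y, z)
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old))
  set.seed(seed)
  coords <- coords + matrix(rnorm(3L * size, sd = 0.15), ncol = 3L)
  coords <- sweep(coords, 2L, colMeans(coords))
  rownames(coords) <- seq_len(size)
  list(positions = seq_len(size), coords = coords, origin = c(0, 0, 0),
       v1 = c(1, 0, 0), v2 = c(0, 1, 0), seed = seed)
}

.Random.seed_get <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_set <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Specification for a synthetic Fab trajectory
#'
#' Describes the rigid perturbation program of [make_toy_fab()].  Each of the
#' three perturbation channels (`hl` torsion twist in degrees, `dc` distance
#' offset in Angstrom, `elbow` rotation in degrees) is one of
#' `list(mode = "constant", value =)`, `list(mode = "ramp", from =, to =)`,
#' or `list(mode = "gaussian", mean =, sd =)`.  Frame 1 is the unperturbed
#' assembly for programs that start at zero (constant 0, ramp from 0); the
#' Gaussian program draws frames 2..n and leaves frame 1 unperturbed.
#'
#' @param n_res residues per domain (the packaged geometry references use 60;
#'   coverage below 80% of the reference coreset is rejected downstream).
#' @param n_frames number of trajectory frames (models), `>= 1`.
#' @param seed integer seed; fixes all randomness.  Perturbation draws and
#'   per-frame jitter use separate derived streams, so adding frames does not
#'   change earlier frames.
#' @param hl,dc,elbow perturbation programs (see above).
#' @param jitter_sigma per-atom isotropic Gaussian jitter SD in Angstrom
#'   (per coordinate), applied after the rigid perturbations.
#' @param atoms `"backbone"` (N, CA, C, O stubs per residue) or `"calpha"`.
#' @param include_constant build CH1/CL (full Fab) or only the Fv module.
#' @return object of class `toy_fab_spec`.
#' @export
toy_fab_spec <- function(n_res = 60L, n_frames = 1L, seed = 1L,
                         hl = list(mode = "constant", value = 0),
                         dc = list(mode = "constant", value = 0),
                         elbow = list(mode = "constant", value = 0),
                         jitter_sigma = 0, atoms = c("backbone", "calpha"),
                         include_constant = TRUE) {
  atoms <- match.arg(atoms)
  if (n_frames < 1L) stop("n_frames must be >= 1")
  if (jitter_sigma < 0) stop("jitter_sigma must be >= 0")
  for (p in list(hl, dc, elbow)) {
    if (!p$mode %in% c("constant", "ramp", "gaussian")) stop("unknown mode: ", p$mode)
    if (p$mode == "gaussian" && p$sd < 0) stop("gaussian sd must be >= 0")
  }
  structure(list(n_res = as.integer(n_res), n_frames = as.integer(n_frames),
                 seed = as.integer(seed), hl = hl, dc = dc, elbow = elbow,
                 jitter_sigma = jitter_sigma, atoms = atoms,
                 include_constant = include_constant),
            class = "toy_fab_spec")
}

program_values <- function(p, n_frames, subseed) {
  switch(p$mode,
    constant = rep(p$value, n_frames),
    ramp = if (n_frames == 1L) p$from else seq(p$from, p$to, length.out = n_frames),
    gaussian = {
      old <- .Random.seed_get(); on.exit(.Random.seed_set(old))
      set.seed(subseed)
      c(0, if (n_frames > 1L) rnorm(n_frames - 1L, p$mean, p$sd))
    })
}

# backbone stub offsets (Angstrom) relative to the C-alpha, in the domain
# local frame; non-planar so small point sets stay full-rank
BACKBONE_OFFSETS <- list(
  N  = c(-1.20, 0.45, 0.30),
  CA = c(0, 0, 0),
  C  = c(1.20, 0.50, 0.20),
  O  = c(1.80, 1.30, -0.40)
)

AA20 <- names(AA_321)

toy_domain_atoms <- function(ref, chain, resno_offset, atoms, seq_seed) {
  n <- length(ref$positions)
  old <- .Random.seed_get(); on.exit(.Random.seed_set(old))
  set.seed(seq_seed)
  resnames <- sample(AA20, n, replace = TRUE)
  anames <- if (atoms == "backbone") names(BACKBONE_OFFSETS) else "CA"
  k <- length(anames)
  df <- data.frame(
    type = "ATOM", eleno = 0L,
    elety = rep(anames, times = n),
    resid = rep(resnames, each = k),
    chain = chain,
    resno = rep(ref$positions + resno_offset, each = k),
    insert = "", o = 1.0, b = 0.0,
    elesy = rep(vapply(anames, function(a) substr(a, 1L, 1L), character(1)), times = n),
    stringsAsFactors = FALSE
  )
  offs <- do.call(rbind, BACKBONE_OFFSETS[anames])
  coords <- ref$coords[rep(seq_len(n), each = k), , drop = FALSE] +
    offs[rep(seq_len(k), times = n), , drop = FALSE]
  list(atoms = df, coords = coords)
}

rot_about <- function(coords, axis, angle_deg, point) {
  R <- rotation_matrix(axis, angle_deg)
  sweep(sweep(coords, 2L, point) %*% t(R), 2L, -point)
}

#' Generate a synthetic Fab assembly / trajectory
#'
#' Builds an idealized four-domain (or Fv-only) assembly from the packaged
#' reference domains and applies the rigid perturbation program of a
#' [toy_fab_spec()] frame by frame: a VH-VL torsion twist about the axis
#' through the two variable-domain frame origins, a distance offset along
#' that axis, a rotation of the whole constant module about the V-to-C
#' direction (the elbow channel), then optional isotropic Gaussian jitter.
#' The unperturbed assembly has `HL = 0`, `dc = 14` A, `elbow = 180` deg
#' under the packaged conventions; `GroundTruth` records the exact per-frame
#' values (`elbow` ground truth assumes no concurrent HL twist, since
#' twisting VL genuinely moves the V-module dyad axis).
#'
#' @param spec a [toy_fab_spec()].
#' @return list with `structure` (multi-model [fab_structure()]), `map`
#'   ([domain_map()]), and `ground_truth` (data.frame `frame`, `hl`, `dc`,
#'   `elbow`).
#' @export
make_toy_fab <- function(spec) {
  stopifnot(inherits(spec, "toy_fab_spec"))
  n <- spec$n_res
  ref_v <- reference_domain("V", n)
  ref_c <- reference_domain("C", n)
  seed <- spec$seed

  a_v <- c(0, 0, 8)     # V-module dyad point
  a_c <- c(0, 0, 0)     # C-module dyad point
  half_sep <- 7         # half inter-origin distance => dc = 14

  place <- function(ref, shift) sweep(ref$coords, 2L, -shift)
  vh0 <- place(ref_v, a_v + c(0, -half_sep, 0))
  k <- if (spec$atoms == "backbone") length(BACKBONE_OFFSETS) else 1L
  rep_res <- rep(seq_len(n), each = k)
  # each domain is built in the reference local frame, then carried onto its
  # placement by the same rigid motion applied to every stub atom
  shift_part <- function(part, base0, ref) {
    part$coords <- part$coords - ref$coords[rep_res, , drop = FALSE] +
      base0[rep_res, , drop = FALSE]
    part
  }
  parts <- list(
    VH = toy_domain_atoms(ref_v, "H", 0L, spec$atoms, seq_seed = seed * 131L + 1L),
    VL = toy_domain_atoms(ref_v, "L", 0L, spec$atoms, seq_seed = seed * 131L + 2L)
  )
  parts$VH <- shift_part(parts$VH, vh0, ref_v)
  # VL: VH placement followed by the 180-degree dyad rotation about x
  # through a_v
  parts$VL <- shift_part(parts$VL, vh0, ref_v)
  parts$VL$coords <- rot_about(parts$VL$coords, c(1, 0, 0), 180, a_v)

  if (spec$include_constant) {
    ch0 <- place(ref_c, a_c + c(0, -half_sep, 0))
    parts$CH1 <- toy_domain_atoms(ref_c, "H", 120L, spec$atoms, seq_seed = seed * 131L + 3L)
    parts$CL <- toy_domain_atoms(ref_c, "L", 110L, spec$atoms, seq_seed = seed * 131L + 4L)
    parts$CH1 <- shift_part(parts$CH1, ch0, ref_c)
    parts$CL <- shift_part(parts$CL, ch0, ref_c)
    parts$CL$coords <- rot_about(parts$CL$coords, c(1, 0, 0), 180, a_c)
  }

  atoms <- do.call(rbind, lapply(parts, `[[`, "atoms"))
  base <- do.call(rbind, lapply(parts, `[[`, "coords"))
  rownames(atoms) <- NULL
  atoms$eleno <- seq_len(nrow(atoms))
  is_vl <- atoms$chain == "L" & atoms$resno <= n
  is_cmod <- atoms$resno > 100L

  hl_vals <- program_values(spec$hl, spec$n_frames, seed * 7919L + 11L)
  dc_vals <- program_values(spec$dc, spec$n_frames, seed * 7919L + 12L)
  el_vals <- program_values(spec$elbow, spec$n_frames, seed * 7919L + 13L)

  u_elbow <- c(0, 0, -1)             # V-module to C-module direction
  # through both variable-domain origins; sign chosen so a positive program
  # value reads back as a positive HL under the packaged dihedral convention
  twist_axis <- c(0, -1, 0)
  twist_point <- a_v

  nmod <- spec$n_frames
  xyz <- matrix(NA_real_, nrow = nmod, ncol = 3L * nrow(atoms))
  for (f in seq_len(nmod)) {
    cf <- base
    if (hl_vals[f] != 0) {
      cf[is_vl, ] <- rot_about(cf[is_vl, , drop = FALSE], twist_axis, hl_vals[f], twist_point)
    }
    if (dc_vals[f] != 0) {
      cf[is_vl, ] <- sweep(cf[is_vl, , drop = FALSE], 2L, -dc_vals[f] * c(0, 1, 0))
    }
    if (spec$include_constant && el_vals[f] != 0) {
      cf[is_cmod, ] <- rot_about(cf[is_cmod, , drop = FALSE], u_elbow, el_vals[f], a_c)
    }
    if (spec$jitter_sigma > 0) {
      old <- .Random.seed_get()
      set.seed((seed %% 100000L) * 10007L + 3000000L + f)
      cf <- cf + matrix(rnorm(length(cf), sd = spec$jitter_sigma), ncol = 3L)
      .Random.seed_set(old)
    }
    xyz[f, ] <- as.numeric(t(cf))
  }

  st <- fab_structure(atoms, xyz, source = "make_toy_fab", format = "pdb")
  map <- if (spec$include_constant) {
    domain_map(VH = list(chain = "H", range = c(1, n)),
               VL = list(chain = "L", range = c(1, n)),
               CH1 = list(chain = "H", range = c(121, 120 + n)),
               CL = list(chain = "L", range = c(111, 110 + n)),
               light_isotype = "kappa")
  } else {
    domain_map(VH = list(chain = "H", range = c(1, n)),
               VL = list(chain = "L", range = c(1, n)),
               light_isotype = "kappa")
  }
  hl_wrapped <- ((hl_vals + 180) %% 360) - 180
  hl_wrapped[hl_wrapped == -180] <- 180    # HL lives in (-180, 180]
  gt <- data.frame(frame = seq_len(nmod),
                   hl = hl_wrapped,
                   dc = 2 * half_sep + dc_vals,
                   elbow = if (spec$include_constant) 180 + el_vals else NA_real_)
  list(structure = st, map = map, ground_truth = gt)
}

#' Minimal two-residue contact fixture
#'
#' Builds a two-chain system realizing exactly one putative contact with the
#' requested geometry, for exercising the hydrogen-bond and salt-bridge
#' detectors.  `kind = "hbond"` places a backbone N-H donor on chain A and a
#' backbone O acceptor on chain B at the given heavy-atom distance and
#' D-H...A angle; `"saltbridge"` places Glu OE1 against Lys NZ; `"none"`
#' places a carbon pair (no donor) at the given distance.
#'
#' @param kind `"hbond"`, `"saltbridge"`, or `"none"`.
#' @param distance heavy-atom (or charged-atom) distance in Angstrom.
#' @param angle D-H...A angle in degrees (hbond only).
#' @return list with `fab` (a `fab_model` with chain A as VH, chain B as VL)
#'   and `spec` (the VH-VL [interface_spec()]).
#' @export
make_contact_fixture <- function(kind = c("hbond", "saltbridge", "none"),
                                 distance = 2.9, angle = 160) {
  kind <- match.arg(kind)
  mk <- function(chain, resno, resid, elety, elesy, coords) {
    data.frame(type = "ATOM", eleno = 0L, elety = elety, resid = resid,
               chain = chain, resno = resno, insert = "", o = 1, b = 0,
               elesy = elesy, stringsAsFactors = FALSE)[rep(1, length(elety)), ] ->
      df
    df$elety <- elety; df$elesy <- elesy
    list(atoms = df, coords = coords)
  }
  far <- c(0, 0, 50)  # CA stubs well away from the contact
  if (kind == "hbond") {
    # donor N at origin, acceptor O on +x at `distance`; H placed on the unit
    # circle so the angle at H between H->N and H->O equals `angle`
    f <- function(beta) {
      H <- c(cos(beta), sin(beta), 0)
      vec_angle(-H, c(distance, 0, 0) - H) - angle
    }
    beta <- uniroot(f, c(1e-6, pi - 1e-6), tol = 1e-12)$root
    a <- mk("A", 1L, "GLY", c("N", "H", "CA"), c("N", "H", "C"),
            rbind(c(0, 0, 0), c(cos(beta), sin(beta), 0), far))
    b <- mk("B", 1L, "GLY", c("O", "CA"), c("O", "C"),
            rbind(c(distance, 0, 0), far + c(3, 0, 0)))
  } else if (kind == "saltbridge") {
    a <- mk("A", 1L, "GLU", c("OE1", "CA"), c("O", "C"),
            rbind(c(0, 0, 0), far))
    b <- mk("B", 1L, "LYS", c("NZ", "CA"), c("N", "C"),
            rbind(c(distance, 0, 0), far + c(3, 0, 0)))
  } else {
    a <- mk("A", 1L, "GLY", c("CA", "CB"), c("C", "C"),
            rbind(far, c(0, 0, 0)))
    b <- mk("B", 1L, "GLY", c("O", "CA"), c("O", "C"),
            rbind(c(distance, 0, 0), far + c(3, 0, 0)))
  }
  atoms <- rbind(a$atoms, b$atoms)
  coords <- rbind(a$coords, b$coords)
  rownames(atoms) <- NULL
  atoms$eleno <- seq_len(nrow(atoms))
  st <- fab_structure(atoms, coords, source = "make_contact_fixture")
  map <- domain_map(VH = list(chain = "A", range = c(1, 1)),
                    VL = list(chain = "B", range = c(1, 1)))
  fab <- apply_domain_map(st, map, min_calpha = 1L)
  list(fab = fab, spec = interface_spec("VH-VL"))
}
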