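# Rigid-body geometry: Kabsch superposition, domain-frame registration, the
# six-parameter VH-VL orientation, and the elbow angle from pseudo-twofold
# axes.
#
# Conventions.  Rotations act on row-vector coordinates as x %*% t(R) + t.
# All angles are degrees; the VH-VL torsion HL lies in (-180, 180], the four
# tilts in [0, 180], the elbow angle in (0, 360).

DEG <- 180 / pi

unit <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-12) stop("zero-length vector")
  v / n
}

clamp1 <- function(x) pmin(1, pmax(-1, x))

#' Angle between two vectors (degrees)
#' @param a,b numeric 3-vectors.
#' @return angle in `[0, 180]`.
#' @export
vec_angle <- function(a, b) acos(clamp1(sum(unit(a) * unit(b)))) * DEG

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Signed dihedral angle of four points (degrees)
#'
#' Standard atan2 formulation; the sign follows the right-hand rule about the
#' p2->p3 axis.  Result in `(-180, 180]`.
#'
#' @param p1,p2,p3,p4 numeric 3-vectors.
#' @return signed angle in degrees.
#' @export
signed_dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- cross3(b1, b2); n2 <- cross3(b2, b3)
  m <- cross3(n1, unit(b2))
  ang <- atan2(sum(m * n2), sum(n1 * n2)) * DEG
  if (ang <= -180) ang + 360 else ang
}

#' Rotation matrix from axis and angle
#'
#' @param axis 3-vector (normalized internally).
#' @param angle_deg rotation angle in degrees (right-hand rule).
#' @return 3x3 proper orthogonal matrix.
#' @export
rotation_matrix <- function(axis, angle_deg) {
  a <- unit(axis)
  th <- angle_deg / DEG
  K <- matrix(c(0, -a[3], a[2], a[3], 0, -a[1], -a[2], a[1], 0),
              nrow = 3, byrow = TRUE)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

#' Axis and angle of a rotation matrix
#'
#' @param R 3x3 proper rotation matrix.
#' @return list with `axis` (unit 3-vector, +1 eigenvector) and `angle_deg`
#'   in `[0, 180]`.  The axis sign is arbitrary for callers that do not fix
#'   it themselves.
#' @export
rotation_axis_angle <- function(R) {
  ang <- acos(clamp1((sum(diag(R)) - 1) / 2)) * DEG
  if (ang < 1e-4) return(list(axis = c(0, 0, 1), angle_deg = ang))
  if (ang < 179.99) {
    ax <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2])
    return(list(axis = unit(ax), angle_deg = ang))
  }
  # near 180 degrees the skew part vanishes; use the +1 eigenvector
  e <- eigen(R)
  i <- which.min(abs(e$values - 1))
  list(axis = unit(Re(e$vectors[, i])), angle_deg = ang)
}

#' Least-squares rigid superposition (Kabsch)
#'
#' Finds the proper rotation `R` and translation `t` minimising the
#' (optionally weighted) RMSD of `mobile %*% t(R) + t` against `target`.
#' The reflection branch is corrected so `det(R) = +1`.
#'
#' @param mobile,target `N x 3` coordinate matrices with matched rows, N >= 3.
#' @param weights optional non-negative N-vector.
#' @return list of class `rigid_transform` with `rotation`, `translation`,
#'   and `rmsd` (post-fit, in Angstrom).
#' @export
kabsch_superpose <- function(mobile, target, weights = NULL) {
  mobile <- as.matrix(mobile); target <- as.matrix(target)
  stopifnot(ncol(mobile) == 3L, ncol(target) == 3L, nrow(mobile) == nrow(target))
  n <- nrow(mobile)
  if (n < 3L) stop("need at least 3 points")
  if (is.null(weights)) weights <- rep(1, n)
  if (any(weights < 0) || sum(weights) <= 0) stop("invalid weights")
  w <- weights / sum(weights)
  cm <- colSums(mobile * w); ct <- colSums(target * w)
  P <- sweep(mobile, 2L, cm); Q <- sweep(target, 2L, ct)
  C <- t(P * w) %*% Q
  s <- svd(C)
  # degenerate (collinear or coincident) input leaves the rotation
  # under-determined
  pe <- svd(t(P * sqrt(w)) %*% (P * sqrt(w)))$d
  if (pe[2] < 1e-10 * max(pe[1], 1e-12)) stop("degenerate point set: rank < 2")
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  fitted <- P %*% t(R)
  rmsd <- sqrt(sum(w * rowSums((fitted - Q)^2)))
  structure(list(rotation = R, translation = as.numeric(ct - R %*% cm),
                 rmsd = rmsd), class = "rigid_transform")
}

#' Apply a rigid transform to coordinates
#' @param coords `N x 3` matrix.
#' @param tf a `rigid_transform` (or `list(rotation=, translation=)`).
#' @return transformed `N x 3` matrix.
#' @export
apply_transform <- function(coords, tf) {
  sweep(as.matrix(coords) %*% t(tf$rotation), 2L, -tf$translation)
}

#' Random rigid transform
#'
#' Uniform random rotation (quaternion method) plus a uniform translation,
#' for invariance testing.
#'
#' @param translation_scale half-width of the uniform translation (Angstrom).
#' @return a `rigid_transform` with `rmsd = NA`.
#' @export
random_rigid_transform <- function(translation_scale = 50) {
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  R <- matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
                2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
                2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
              nrow = 3, byrow = TRUE)
  structure(list(rotation = R,
                 translation = stats::runif(3, -translation_scale, translation_scale),
                 rmsd = NA_real_), class = "rigid_transform")
}

# ---------------------------------------------------------------------------
# Domain reference frames

.reference_cache <- new.env(parent = emptyenv())

#' Packaged reference domain for frame registration
#'
#' The convention-defining coordinate set used to attach an orthonormal frame
#' to a variable (`"V"`) or constant (`"C"`) domain.  Generated
#' deterministically by [make_reference_domain()] (fixed seeds 101 and 202)
#' and cached; absolute orientation-angle values are therefore a fixed,
#' documented convention of this toolkit -- differences between variants are
#' the meaningful output.
#'
#' @param type `"V"` or `"C"`.
#' @param size number of reference residues (coreset positions `1:size`).
#' @return list with `positions`, `coords` (centred `size x 3`), `origin`,
#'   `v1`, `v2`.
#' @export
reference_domain <- function(type = c("V", "C"), size = 60L) {
  type <- match.arg(type)
  key <- paste0(type, "_", size)
  if (!is.null(.reference_cache[[key]])) return(.reference_cache[[key]])
  ref <- make_reference_domain(size, seed = if (type == "V") 101L else 202L)
  .reference_cache[[key]] <- ref
  ref
}

#' Fit a reference frame to an observed domain
#'
#' Superposes the packaged reference coreset onto the observed C-alpha
#' positions (matched by Chothia number; missing positions are dropped
#' pairwise) and returns the rigidly transformed reference frame.
#'
#' @param calphas list with `positions` and `coords` as returned by
#'   [domain_calphas()], or a matrix with rownames giving positions.
#' @param reference a [reference_domain()]-style list.
#' @param coreset positions to use (default: all reference positions).
#' @param min_coverage hard floor on the fraction of coreset positions that
#'   must be observed (default 0.8).
#' @return list of class `domain_frame`: `origin`, `v1`, `v2`, `rmsd`,
#'   `n_used`.
#' @export
fit_domain_frame <- function(calphas, reference = reference_domain("V"),
                             coreset = NULL, min_coverage = 0.8) {
  if (is.matrix(calphas)) {
    calphas <- list(positions = as.integer(rownames(calphas)), coords = calphas)
  }
  if (is.null(coreset)) coreset <- reference$positions
  obs_pos <- calphas$positions
  use <- intersect(coreset, obs_pos)
  cov <- length(use) / length(coreset)
  if (cov < min_coverage) {
    stop("coreset coverage ", sprintf("%.0f%%", 100 * cov), " below ",
         sprintf("%.0f%%", 100 * min_coverage), "; missing positions: ",
         paste(setdiff(coreset, obs_pos), collapse = ", "))
  }
  ri <- match(use, reference$positions)
  oi <- match(use, obs_pos)
  tf <- kabsch_superpose(reference$coords[ri, , drop = FALSE],
                         calphas$coords[oi, , drop = FALSE])
  structure(list(
    origin = as.numeric(apply_transform(rbind(reference$origin), tf)),
    v1 = as.numeric(tf$rotation %*% reference$v1),
    v2 = as.numeric(tf$rotation %*% reference$v2),
    rmsd = tf$rmsd, n_used = length(use)), class = "domain_frame")
}

#' Six-parameter VH-VL pairing orientation
#'
#' Registers the packaged reference frame onto the VH and VL domains and
#' reports the torsion angle `HL`, the four tilt angles `HC1`, `HC2`, `LC1`,
#' `LC2`, and the inter-domain distance `dc`.  With `C = origin_L - origin_H`:
#' `dc = |C|`; `HL` is the signed dihedral of
#' `(origin_H + H1, origin_H, origin_L, origin_L + L1)`;
#' `HC1 = angle(H1, C)`, `HC2 = angle(H2, C)`, `LC1 = angle(L1, -C)`,
#' `LC2 = angle(L2, -C)`, where `H1`, `H2` (`L1`, `L2`) are the fitted VH
#' (VL) frame vectors.  All six values are invariant under global rigid
#' transforms of the Fab.
#'
#' @param fab a `fab_model`.
#' @param model model (snapshot) index.
#' @param reference_v reference domain used for both variable-domain frames.
#' @param coreset optional coreset positions (default: all reference
#'   positions).
#' @return named numeric of class `orientation_angles`:
#'   `HL, HC1, HC2, LC1, LC2` (degrees) and `dc` (Angstrom).
#' @export
vhvl_orientation <- function(fab, model = 1L, reference_v = reference_domain("V"),
                             coreset = NULL) {
  fh <- fit_domain_frame(domain_calphas(fab, "VH", model), reference_v, coreset)
  fl <- fit_domain_frame(domain_calphas(fab, "VL", model), reference_v, coreset)
  orientation_from_frames(fh, fl)
}

orientation_from_frames <- function(fh, fl) {
  C <- fl$origin - fh$origin
  out <- c(
    HL  = signed_dihedral(fh$origin + fh$v1, fh$origin, fl$origin, fl$origin + fl$v1),
    HC1 = vec_angle(fh$v1, C),
    HC2 = vec_angle(fh$v2, C),
    LC1 = vec_angle(fl$v1, -C),
    LC2 = vec_angle(fl$v2, -C),
    dc  = sqrt(sum(C^2))
  )
  class(out) <- "orientation_angles"
  out
}

#' @export
print.orientation_angles <- function(x, ...) {
  v <- unclass(x)
  cat(sprintf("VH-VL orientation: HL=%.2f HC1=%.2f HC2=%.2f LC1=%.2f LC2=%.2f deg, dc=%.2f A\n",
              v["HL"], v["HC1"], v["HC2"], v["LC1"], v["LC2"], v["dc"]))
  invisible(x)
}

#' Pseudo-twofold (dyad) axis relating two domains
#'
#' Superposes domain A onto domain B using position-paired C-alpha atoms and
#' returns the rotation axis and magnitude.  For a true pseudo-twofold the
#' magnitude is close to 180 degrees; a magnitude below 90 degrees sets a
#' warning flag (the pairing is likely wrong).
#'
#' @param a,b C-alpha lists as from [domain_calphas()].
#' @param pairing two-column matrix/data.frame of paired positions
#'   (A position, B position); default pairs equal position numbers.
#' @return list: `axis` (unit 3-vector, sign arbitrary), `angle_deg`,
#'   `rmsd`, `low_angle` (logical warning flag), `n_pairs`.
#' @export
pseudo_dyad <- function(a, b, pairing = NULL) {
  if (is.null(pairing)) {
    common <- intersect(a$positions, b$positions)
    pairing <- cbind(common, common)
  }
  pairing <- as.matrix(pairing)
  ia <- match(pairing[, 1], a$positions)
  ib <- match(pairing[, 2], b$positions)
  ok <- !is.na(ia) & !is.na(ib)
  if (sum(ok) < 10L) stop("need at least 10 paired C-alpha positions, got ", sum(ok))
  tf <- kabsch_superpose(a$coords[ia[ok], , drop = FALSE],
                         b$coords[ib[ok], , drop = FALSE])
  aa <- rotation_axis_angle(tf$rotation)
  low <- aa$angle_deg < 90
  if (low) {
    warning("pseudo-dyad rotation magnitude ", sprintf("%.1f", aa$angle_deg),
            " deg < 90 deg; pairing may be wrong", call. = FALSE)
  }
  list(axis = aa$axis, angle_deg = aa$angle_deg, rmsd = tf$rmsd,
       low_angle = low, n_pairs = sum(ok))
}

#' Elbow angle between the variable and constant modules
#'
#' Computes the pseudo-twofold axis `v` relating VH to VL and `c` relating
#' CH1 to CL, sign-fixes both axes against the fitted domain frames (`v`
#' toward the VH frame's first axis, `c` away from the CH1 frame's first
#' axis), and reports `theta = acos(v . c)` or its reflex `360 - theta`
#' depending on the sign of `(v x c) . u`, where `u` points from the
#' V-module C-alpha centroid to the C-module centroid.  The value lies in
#' `(0, 360)` so elbow conformations beyond 180 degrees are representable,
#' and is invariant under global rigid transforms.
#'
#' @inheritParams vhvl_orientation
#' @param reference_c reference domain for the constant-domain frames.
#' @return numeric elbow angle in degrees with attribute `low_angle` if a
#'   dyad magnitude fell below 90 degrees.
#' @export
elbow_angle <- function(fab, model = 1L, reference_v = reference_domain("V"),
                        reference_c = reference_domain("C"), coreset = NULL) {
  need <- c("VH", "VL", "CH1", "CL")
  miss <- setdiff(need, names(fab$domains))
  if (length(miss)) stop("elbow angle needs all four domains; missing: ",
                         paste(miss, collapse = ", "))
  vh <- domain_calphas(fab, "VH", model); vl <- domain_calphas(fab, "VL", model)
  ch <- domain_calphas(fab, "CH1", model); cl <- domain_calphas(fab, "CL", model)
  # constant domains carry arbitrary numbering offsets (CH1 vs CL live in
  # different ranges); shift each to a domain-relative scale, preserving gaps
  norm_pos <- function(ca) { ca$positions <- ca$positions - min(ca$positions) + 1L; ca }
  ch <- norm_pos(ch); cl <- norm_pos(cl)
  dv <- pseudo_dyad(vh, vl)
  dcst <- pseudo_dyad(ch, cl)
  fh <- fit_domain_frame(vh, reference_v, coreset)
  fc <- fit_domain_frame(ch, reference_c, coreset)
  v <- dv$axis; cc <- dcst$axis
  if (sum(v * fh$v1) < 0) v <- -v
  if (sum(cc * fc$v1) > 0) cc <- -cc
  u <- unit(colMeans(rbind(ch$coords, cl$coords)) -
            colMeans(rbind(vh$coords, vl$coords)))
  theta <- acos(clamp1(sum(v * cc))) * DEG
  trip <- sum(cross3(v, cc) * u)
  val <- if (trip >= 0) theta else 360 - theta
  attr(val, "low_angle") <- dv$low_angle || dcst$low_angle
  val
}
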