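# Independent oracle implementations and small fixture builders shared by the
# test files.  These deliberately re-derive results through different
# algorithms than the package (quaternion superposition, latitude-band SASA
# quadrature, nested-loop contact search, recursive KS enumeration).

# ---- quaternion (Horn) absolute-orientation oracle -------------------------
quaternion_superpose <- function(mobile, target) {
  cm <- colMeans(mobile); ct <- colMeans(target)
  P <- sweep(mobile, 2, cm); Q <- sweep(target, 2, ct)
  M <- t(P) %*% Q
  Sxx <- M[1,1]; Sxy <- M[1,2]; Sxz <- M[1,3]
  Syx <- M[2,1]; Syy <- M[2,2]; Syz <- M[2,3]
  Szx <- M[3,1]; Szy <- M[3,2]; Szz <- M[3,3]
  N <- matrix(c(
    Sxx+Syy+Szz, Syz-Szy,     Szx-Sxz,     Sxy-Syx,
    Syz-Szy,     Sxx-Syy-Szz, Sxy+Syx,     Szx+Sxz,
    Szx-Sxz,     Sxy+Syx,     -Sxx+Syy-Szz, Syz+Szy,
    Sxy-Syx,     Szx+Sxz,     Syz+Szy,     -Sxx-Syy+Szz), 4, 4, byrow = TRUE)
  e <- eigen(N, symmetric = TRUE)
  q <- e$vectors[, 1]
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  R <- matrix(c(1-2*(y^2+z^2), 2*(x*y-w*z), 2*(x*z+w*y),
                2*(x*y+w*z), 1-2*(x^2+z^2), 2*(y*z-w*x),
                2*(x*z-w*y), 2*(y*z+w*x), 1-2*(x^2+y^2)), 3, 3, byrow = TRUE)
  fitted <- P %*% t(R)
  list(rotation = R, rmsd = sqrt(mean(rowSums((fitted - Q)^2))))
}

# brute-force best proper rotation by multi-start numerical search over the
# rotation group (axis-angle parameterization)
brute_force_rmsd <- function(mobile, target, n_starts = 40) {
  cm <- colMeans(mobile); ct <- colMeans(target)
  P <- sweep(mobile, 2, cm); Q <- sweep(target, 2, ct)
  obj <- function(par) {
    th <- sqrt(sum(par^2))
    R <- if (th < 1e-12) diag(3) else fabkit::rotation_matrix(par, th * 180 / pi)
    sqrt(mean(rowSums((P %*% t(R) - Q)^2)))
  }
  best <- Inf
  for (s in seq_len(n_starts)) {
    p0 <- stats::runif(3, -pi, pi)
    o <- stats::optim(p0, obj, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-14))
    best <- min(best, o$value)
  }
  best
}

# ---- latitude-band numeric SASA oracle -------------------------------------
grid_sasa <- function(coords, radii, probe = 1.4, n_theta = 80, n_phi = 160) {
  r <- radii + probe
  n <- nrow(coords)
  th <- (seq_len(n_theta) - 0.5) * pi / n_theta
  ph <- (seq_len(n_phi) - 0.5) * 2 * pi / n_phi
  grid <- expand.grid(th = th, ph = ph)
  dirs <- cbind(sin(grid$th) * cos(grid$ph), sin(grid$th) * sin(grid$ph),
                cos(grid$th))
  w <- sin(grid$th) * (pi / n_theta) * (2 * pi / n_phi)   # solid-angle weights
  total <- 0
  per_atom <- numeric(n)
  for (i in seq_len(n)) {
    pts <- sweep(dirs * r[i], 2, -coords[i, ])
    exposed <- rep(TRUE, nrow(pts))
    for (j in seq_len(n)) {
      if (j == i) next
      d2 <- (pts[, 1] - coords[j, 1])^2 + (pts[, 2] - coords[j, 2])^2 +
            (pts[, 3] - coords[j, 3])^2
      exposed <- exposed & d2 >= r[j]^2
      if (!any(exposed)) break
    }
    per_atom[i] <- sum(w[exposed]) * r[i]^2
  }
  list(atom_asa = per_atom, total = sum(per_atom))
}

# ---- exhaustive nested-loop contact oracle (heavy-atom fixtures) ----------
ORACLE_DONORS <- c("GLY|N", "ALA|N", "SER|N", "SER|OG", "LYS|N", "LYS|NZ",
                   "ARG|N", "ARG|NE", "ARG|NH1", "ARG|NH2", "GLU|N", "ASP|N",
                   "HIS|N", "HIS|ND1", "HIS|NE2", "TYR|N", "TYR|OH",
                   "GLN|N", "GLN|NE2", "ASN|N", "ASN|ND2", "THR|N", "THR|OG1",
                   "TRP|N", "TRP|NE1")
ORACLE_ACCEPTORS <- c("GLY|O", "ALA|O", "SER|O", "SER|OG", "LYS|O", "ARG|O",
                      "GLU|O", "GLU|OE1", "GLU|OE2", "ASP|O", "ASP|OD1",
                      "ASP|OD2", "HIS|O", "HIS|ND1", "HIS|NE2", "TYR|O",
                      "TYR|OH", "GLN|O", "GLN|OE1", "ASN|O", "ASN|OD1",
                      "THR|O", "THR|OG1", "TRP|O", "CYS|SG", "MET|SD")
ORACLE_POS <- c("LYS|NZ", "ARG|NE", "ARG|NH1", "ARG|NH2", "HIS|ND1", "HIS|NE2")
ORACLE_NEG <- c("ASP|OD1", "ASP|OD2", "GLU|OE1", "GLU|OE2")

oracle_contacts <- function(atoms, coords, side_a, side_b,
                            d_hb = 3.5, d_sb = 4.0) {
  key <- paste(atoms$resid, atoms$elety, sep = "|")
  out <- character(0)
  for (i in side_a) {
    for (j in side_b) {
      d <- sqrt(sum((coords[i, ] - coords[j, ])^2))
      if ((key[i] %in% ORACLE_DONORS && key[j] %in% ORACLE_ACCEPTORS && d <= d_hb) ||
          (key[j] %in% ORACLE_DONORS && key[i] %in% ORACLE_ACCEPTORS && d <= d_hb)) {
        don <- if (key[i] %in% ORACLE_DONORS && key[j] %in% ORACLE_ACCEPTORS) i else j
        acc <- if (don == i) j else i
        out <- c(out, paste("hbond", don, acc))
        # both directions may qualify (e.g. hydroxyl vs hydroxyl)
        if (key[j] %in% ORACLE_DONORS && key[i] %in% ORACLE_ACCEPTORS &&
            key[i] %in% ORACLE_DONORS && key[j] %in% ORACLE_ACCEPTORS) {
          out <- c(out, paste("hbond", acc, don))
        }
      }
      if (d <= d_sb &&
          ((key[i] %in% ORACLE_POS && key[j] %in% ORACLE_NEG) ||
           (key[j] %in% ORACLE_POS && key[i] %in% ORACLE_NEG))) {
        pos <- if (key[i] %in% ORACLE_POS) i else j
        neg <- if (pos == i) j else i
        out <- c(out, paste("saltbridge", pos, neg))
      }
    }
  }
  sort(unique(out))
}

# random two-sided residue cluster for contact-detection equivalence checks
RESIDUE_TEMPLATES <- list(
  GLY = c("N", "CA", "C", "O"),
  ALA = c("N", "CA", "C", "O"),
  SER = c("N", "CA", "C", "O", "OG"),
  GLU = c("N", "CA", "C", "O", "OE1", "OE2"),
  ASP = c("N", "CA", "C", "O", "OD1", "OD2"),
  LYS = c("N", "CA", "C", "O", "NZ"),
  ARG = c("N", "CA", "C", "O", "NE", "NH1", "NH2"),
  HIS = c("N", "CA", "C", "O", "ND1", "NE2"),
  TYR = c("N", "CA", "C", "O", "OH"),
  GLN = c("N", "CA", "C", "O", "NE2", "OE1")
)

random_contact_fab <- function(seed, n_res_per_side = 4) {
  set.seed(seed)
  rows <- list(); coords <- list(); k <- 0
  for (side in 1:2) {
    chain <- c("A", "B")[side]
    centre <- if (side == 1) c(0, 0, 0) else c(stats::runif(1, 2, 7), 0, 0)
    for (r in seq_len(n_res_per_side)) {
      resid <- sample(names(RESIDUE_TEMPLATES), 1)
      ats <- RESIDUE_TEMPLATES[[resid]]
      k <- k + 1
      rows[[k]] <- data.frame(type = "ATOM", eleno = 0L, elety = ats,
                              resid = resid, chain = chain, resno = r,
                              insert = "", o = 1, b = 0,
                              elesy = substr(ats, 1, 1),
                              stringsAsFactors = FALSE)
      coords[[k]] <- matrix(rep(centre, each = length(ats)), ncol = 3) +
        matrix(stats::runif(3 * length(ats), -4, 4), ncol = 3)
    }
  }
  atoms <- do.call(rbind, rows)
  atoms$eleno <- seq_len(nrow(atoms))
  st <- fab_structure(atoms, do.call(rbind, coords), source = "random_contact")
  map <- domain_map(VH = list(chain = "A", range = c(1, n_res_per_side)),
                    VL = list(chain = "B", range = c(1, n_res_per_side)))
  apply_domain_map(st, map, min_calpha = 1L)
}

# ---- recursive KS enumeration oracle ---------------------------------------
oracle_ks_D <- function(x, y) {
  pool <- sort(unique(c(x, y)))
  dmax <- 0
  for (t in pool) {
    fx <- sum(x <= t) / length(x)
    fy <- sum(y <= t) / length(y)
    dmax <- max(dmax, abs(fx - fy))
  }
  dmax
}

oracle_ks_exact_p <- function(x, y) {
  v <- c(x, y)
  n <- length(x); nm <- length(v)
  d_obs <- oracle_ks_D(x, y)
  count <- 0L; total <- 0L
  # recursive enumeration of all size-n index subsets
  recurse <- function(start, chosen) {
    if (length(chosen) == n) {
      total <<- total + 1L
      if (oracle_ks_D(v[chosen], v[-chosen]) >= d_obs - 1e-12) count <<- count + 1L
      return(invisible())
    }
    if (start > nm) return(invisible())
    for (i in start:nm) recurse(i + 1L, c(chosen, i))
  }
  recurse(1L, integer(0))
  count / total
}

# ---- misc ------------------------------------------------------------------
transform_structure <- function(st, tf) {
  for (m in seq_len(n_models(st))) {
    st <- set_model_coords(st, m, apply_transform(model_coords(st, m), tf))
  }
  st
}

xyz_cols <- function(idx) as.numeric(vapply(idx, function(i) (3 * (i - 1)) + 1:3,
                                            numeric(3)))
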