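# Hydrogen-bond and salt-bridge detection across named interfaces, with
# per-snapshot occupancy.
#
# Criteria (conventional values, configurable): H-bond donor-acceptor
# heavy-atom distance <= 3.5 A and, when hydrogens are present, a D-H...A
# angle >= 120 deg at some hydrogen attached to the donor; salt bridge =
# opposite-charge atom pair within 4.0 A.  Candidate pairs come from a
# spatial hash (cell list); results are identical to exhaustive all-pairs
# search by construction and verified against it in the test suite.

# donor/acceptor typing: backbone N (except proline) donates, backbone O and
# OXT accept; side-chain roles by (residue, atom) pairs
SIDECHAIN_DONORS <- c(
  "SER|OG", "THR|OG1", "TYR|OH", "ASN|ND2", "GLN|NE2", "LYS|NZ",
  "ARG|NE", "ARG|NH1", "ARG|NH2", "HIS|ND1", "HIS|NE2", "TRP|NE1"
)
SIDECHAIN_ACCEPTORS <- c(
  "ASP|OD1", "ASP|OD2", "GLU|OE1", "GLU|OE2", "ASN|OD1", "GLN|OE1",
  "SER|OG", "THR|OG1", "TYR|OH", "HIS|ND1", "HIS|NE2", "MET|SD", "CYS|SG"
)
# charged groups for salt bridges
POSITIVE_ATOMS <- c("LYS|NZ", "ARG|NE", "ARG|NH1", "ARG|NH2", "HIS|ND1", "HIS|NE2")
NEGATIVE_ATOMS <- c("ASP|OD1", "ASP|OD2", "GLU|OE1", "GLU|OE2")

atom_role_key <- function(atoms) paste(atoms$resid, atoms$elety, sep = "|")

is_donor <- function(atoms) {
  (atoms$elety == "N" & atoms$resid != "PRO" & atoms$elesy == "N") |
    atom_role_key(atoms) %in% SIDECHAIN_DONORS
}

is_acceptor <- function(atoms) {
  (atoms$elety %in% c("O", "OXT") & atoms$elesy == "O") |
    atom_role_key(atoms) %in% SIDECHAIN_ACCEPTORS
}

# spatial hash: integer cell coordinates at `cutoff` resolution; candidate
# pairs are those within the 27-cell neighbourhood
hash_candidate_pairs <- function(coords_a, coords_b, cutoff) {
  if (!nrow(coords_a) || !nrow(coords_b)) {
    return(matrix(integer(0), ncol = 2L))
  }
  cell <- function(m) floor(m / cutoff)
  ca <- cell(coords_a); cb <- cell(coords_b)
  keyb <- paste(cb[, 1], cb[, 2], cb[, 3], sep = ",")
  lookup <- split(seq_len(nrow(coords_b)), keyb)
  out <- vector("list", nrow(coords_a))
  shifts <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  for (i in seq_len(nrow(coords_a))) {
    neigh <- sweep(shifts, 2L, -ca[i, ])
    keys <- paste(neigh[, 1], neigh[, 2], neigh[, 3], sep = ",")
    js <- unlist(lookup[keys], use.names = FALSE)
    if (length(js)) {
      d2 <- (coords_b[js, 1] - coords_a[i, 1])^2 +
            (coords_b[js, 2] - coords_a[i, 2])^2 +
            (coords_b[js, 3] - coords_a[i, 3])^2
      js <- js[d2 <= cutoff^2]
      if (length(js)) out[[i]] <- cbind(i, js)
    }
  }
  res <- do.call(rbind, out)
  if (is.null(res)) matrix(integer(0), ncol = 2L) else res
}

atom_label <- function(atoms, idx) {
  paste0(atoms$chain[idx], ":", atoms$resid[idx], atoms$resno[idx],
         atoms$insert[idx], ":", atoms$elety[idx])
}

res_label <- function(atoms, idx) {
  paste0(atoms$chain[idx], ":", atoms$resid[idx], atoms$resno[idx], atoms$insert[idx])
}

empty_contacts <- function() {
  data.frame(kind = character(0), donor = character(0), acceptor = character(0),
             donor_res = character(0), acceptor_res = character(0),
             distance = numeric(0), angle = numeric(0),
             stringsAsFactors = FALSE)
}

structure_has_hydrogens <- function(st) any(st$atoms$elesy == "H")

# hydrogens attached to a donor: H atoms of the same residue within 1.3 A
donor_hydrogens <- function(atoms, coords, donor_idx) {
  h_idx <- which(atoms$elesy == "H")
  if (!length(h_idx)) return(list())
  rk <- res_keys(atoms)
  out <- vector("list", length(donor_idx))
  for (i in seq_along(donor_idx)) {
    d <- donor_idx[i]
    cand <- h_idx[rk[h_idx] == rk[d]]
    if (length(cand)) {
      dd <- sqrt(rowSums((coords[cand, , drop = FALSE] -
                          matrix(coords[d, ], length(cand), 3, byrow = TRUE))^2))
      cand <- cand[dd <= 1.3]
    }
    out[[i]] <- cand
  }
  out
}

detect_directed_hbonds <- function(atoms, coords, don_idx, acc_idx,
                                   d_heavy_max, dha_min, use_h) {
  if (!length(don_idx) || !length(acc_idx)) return(empty_contacts())
  pairs <- hash_candidate_pairs(coords[don_idx, , drop = FALSE],
                                coords[acc_idx, , drop = FALSE], d_heavy_max)
  if (!nrow(pairs)) return(empty_contacts())
  di <- don_idx[pairs[, 1]]; ai <- acc_idx[pairs[, 2]]
  dist <- sqrt(rowSums((coords[di, , drop = FALSE] - coords[ai, , drop = FALSE])^2))
  ang <- rep(NA_real_, length(di))
  keep <- rep(TRUE, length(di))
  if (use_h) {
    hs <- donor_hydrogens(atoms, coords, di)
    for (i in seq_along(di)) {
      hi <- hs[[i]]
      if (!length(hi)) { keep[i] <- FALSE; next }
      angs <- vapply(hi, function(h) {
        vec_angle(coords[di[i], ] - coords[h, ], coords[ai[i], ] - coords[h, ])
      }, numeric(1))
      ang[i] <- max(angs)
      keep[i] <- ang[i] >= dha_min
    }
  }
  out <- data.frame(kind = "hbond",
                    donor = atom_label(atoms, di), acceptor = atom_label(atoms, ai),
                    donor_res = res_label(atoms, di), acceptor_res = res_label(atoms, ai),
                    distance = dist, angle = ang, stringsAsFactors = FALSE)
  out[keep, , drop = FALSE]
}

#' Detect hydrogen bonds across an interface
#'
#' Donor-acceptor pairs spanning the two sides of `spec` with heavy-atom
#' distance below `d_heavy_max`; when the structure carries hydrogens, a
#' D-H...A angle of at least `dha_min` at some donor hydrogen is also
#' required.  Structures without hydrogens (most crystal structures) are
#' evaluated in heavy-atom-only mode, flagged via attribute `heavy_only`.
#'
#' @param fab a `fab_model`.
#' @param spec an [interface_spec()].
#' @param model model index.
#' @param d_heavy_max donor-acceptor heavy-atom cutoff (A).
#' @param dha_min minimum D-H...A angle (degrees), used only with hydrogens.
#' @return data.frame of contacts (`kind`, `donor`, `acceptor`, `donor_res`,
#'   `acceptor_res`, `distance`, `angle`).
#' @export
detect_hbonds <- function(fab, spec, model = 1L, d_heavy_max = 3.5, dha_min = 120) {
  s <- interface_sides(fab, spec)
  st <- fab$structure
  atoms <- st$atoms
  coords <- model_coords(st, model)
  use_h <- structure_has_hydrogens(st)
  don <- which(is_donor(atoms)); acc <- which(is_acceptor(atoms))
  ab <- detect_directed_hbonds(atoms, coords, intersect(don, s$a),
                               intersect(acc, s$b), d_heavy_max, dha_min, use_h)
  ba <- detect_directed_hbonds(atoms, coords, intersect(don, s$b),
                               intersect(acc, s$a), d_heavy_max, dha_min, use_h)
  out <- rbind(ab, ba)
  out <- out[order(out$donor, out$acceptor), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "heavy_only") <- !use_h
  out
}

#' Detect salt bridges across an interface
#'
#' Opposite-charge atom pairs (Asp/Glu carboxylate oxygens against Lys NZ,
#' Arg guanidinium nitrogens, His imidazole nitrogens) spanning the interface
#' within `d_max`.
#'
#' @inheritParams detect_hbonds
#' @param d_max distance cutoff in Angstrom (default 4.0).
#' @return data.frame of contacts; `donor` holds the positive atom,
#'   `acceptor` the negative one.
#' @export
detect_saltbridges <- function(fab, spec, model = 1L, d_max = 4.0) {
  s <- interface_sides(fab, spec)
  st <- fab$structure
  atoms <- st$atoms
  coords <- model_coords(st, model)
  rk <- atom_role_key(atoms)
  pos <- which(rk %in% POSITIVE_ATOMS)
  neg <- which(rk %in% NEGATIVE_ATOMS)
  one <- function(pi, ni) {
    if (!length(pi) || !length(ni)) return(empty_contacts())
    pr <- hash_candidate_pairs(coords[pi, , drop = FALSE],
                               coords[ni, , drop = FALSE], d_max)
    if (!nrow(pr)) return(empty_contacts())
    p <- pi[pr[, 1]]; q <- ni[pr[, 2]]
    dist <- sqrt(rowSums((coords[p, , drop = FALSE] - coords[q, , drop = FALSE])^2))
    data.frame(kind = "saltbridge",
               donor = atom_label(atoms, p), acceptor = atom_label(atoms, q),
               donor_res = res_label(atoms, p), acceptor_res = res_label(atoms, q),
               distance = dist, angle = NA_real_, stringsAsFactors = FALSE)
  }
  out <- rbind(one(intersect(pos, s$a), intersect(neg, s$b)),
               one(intersect(pos, s$b), intersect(neg, s$a)))
  out <- out[order(out$donor, out$acceptor), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Contact occupancy over a trajectory
#'
#' Runs hydrogen-bond and/or salt-bridge detection on every model in the
#' analysis window and reports, per contact, the fraction of snapshots in
#' which it satisfies its criteria.  Contacts are keyed by atom-pair
#' identity; a residue-pair summary (fraction of snapshots with at least one
#' atom contact between the residues) is attached as attribute
#' `residue_level`.  Pairs never observed are absent from the report.
#'
#' @inheritParams detect_hbonds
#' @param kinds subset of `c("hbond", "saltbridge")`.
#' @param criteria list overriding `d_heavy_max`, `dha_min`, `d_salt_max`.
#' @param window `(start_fraction, end_fraction)` of models analysed,
#'   default the full trajectory.
#' @return data.frame (`kind`, `donor`, `acceptor`, `donor_res`,
#'   `acceptor_res`, `mean_distance`, `occupancy`, `n_models`).
#' @export
contact_occupancy <- function(fab, spec, kinds = c("hbond", "saltbridge"),
                              criteria = list(), window = c(0, 1)) {
  crit <- utils::modifyList(list(d_heavy_max = 3.5, dha_min = 120,
                                 d_salt_max = 4.0), criteria)
  idx <- window_models(n_models(fab$structure), window, min_models = 1L)
  per_model <- lapply(idx, function(m) {
    parts <- list()
    if ("hbond" %in% kinds) {
      parts$h <- detect_hbonds(fab, spec, m, crit$d_heavy_max, crit$dha_min)
    }
    if ("saltbridge" %in% kinds) {
      parts$s <- detect_saltbridges(fab, spec, m, crit$d_salt_max)
    }
    d <- do.call(rbind, parts)
    if (nrow(d)) d$model <- m
    d
  })
  all <- do.call(rbind, per_model)
  nm <- length(idx)
  if (is.null(all) || !nrow(all)) {
    out <- cbind(empty_contacts()[, c("kind", "donor", "acceptor",
                                      "donor_res", "acceptor_res")],
                 mean_distance = numeric(0), occupancy = numeric(0),
                 n_models = integer(0))
    attr(out, "residue_level") <- out
    return(out)
  }
  key <- paste(all$kind, all$donor, all$acceptor, sep = " ~ ")
  first <- !duplicated(key)
  out <- data.frame(kind = all$kind[first], donor = all$donor[first],
                    acceptor = all$acceptor[first],
                    donor_res = all$donor_res[first],
                    acceptor_res = all$acceptor_res[first],
                    mean_distance = as.numeric(rowsum(all$distance, key, reorder = FALSE)) /
                      as.numeric(rowsum(rep(1, nrow(all)), key, reorder = FALSE)),
                    occupancy = as.numeric(rowsum(rep(1, nrow(all)), key, reorder = FALSE)) / nm,
                    n_models = nm, stringsAsFactors = FALSE)
  out <- out[order(-out$occupancy, out$donor), , drop = FALSE]
  rownames(out) <- NULL
  # residue-pair granularity: a residue pair is "present" in a model when any
  # atom pair between the two residues satisfies the criteria
  rkey <- paste(all$kind, all$donor_res, all$acceptor_res, sep = " ~ ")
  mkey <- paste(rkey, all$model)
  keep <- !duplicated(mkey)
  rfirst <- !duplicated(rkey[keep])
  rl <- data.frame(kind = all$kind[keep][rfirst],
                   donor_res = all$donor_res[keep][rfirst],
                   acceptor_res = all$acceptor_res[keep][rfirst],
                   occupancy = as.numeric(rowsum(rep(1, sum(keep)), rkey[keep],
                                                 reorder = FALSE)) / nm,
                   n_models = nm, stringsAsFactors = FALSE)
  rl <- rl[order(-rl$occupancy, rl$donor_res), , drop = FALSE]
  rownames(rl) <- NULL
  attr(out, "residue_level") <- rl
  out
}
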