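# Multi-model structure container.
#
# A `fab_structure` holds one atom roster shared by all models plus an
# n_models x 3N coordinate matrix (columns x1,y1,z1,x2,... as in trajectory
# packages), so trajectory snapshots and single crystal structures share one
# representation.

#' Construct a multi-model structure object
#'
#' Low-level constructor used by the readers and the synthetic-fixture
#' generator.  All models share the atom roster in `atoms`; coordinates for
#' model `i` live in row `i` of `xyz`.
#'
#' @param atoms data.frame with columns `type`, `eleno`, `elety` (atom name),
#'   `resid` (residue name), `chain`, `resno`, `insert` (insertion code, ""
#'   when absent), `o` (occupancy), `b`, `elesy` (element symbol).  A `radius`
#'   column is added from the packaged vdW table if missing.
#' @param xyz numeric matrix `n_models x (3 * nrow(atoms))`, or a single
#'   `N x 3` coordinate matrix, or a list of such matrices (one per model).
#' @param source,format free-form provenance metadata.
#' @return object of class `fab_structure`.
#' @export
fab_structure <- function(atoms, xyz, source = NA_character_, format = "pdb") {
  stopifnot(is.data.frame(atoms))
  needed <- c("type", "eleno", "elety", "resid", "chain", "resno", "insert",
              "o", "b", "elesy")
  miss <- setdiff(needed, names(atoms))
  if (length(miss)) stop("atoms is missing column(s): ", paste(miss, collapse = ", "))
  atoms$insert[is.na(atoms$insert)] <- ""
  if (is.null(atoms$radius)) atoms$radius <- vdw_radius(atoms$elesy)
  if (is.list(xyz) && !is.matrix(xyz)) {
    xyz <- do.call(rbind, lapply(xyz, function(m) as.numeric(t(m))))
  } else if (is.matrix(xyz) && ncol(xyz) == 3L && nrow(xyz) == nrow(atoms)) {
    xyz <- matrix(as.numeric(t(xyz)), nrow = 1L)
  }
  xyz <- as.matrix(xyz)
  if (ncol(xyz) != 3L * nrow(atoms)) {
    stop("xyz has ", ncol(xyz), " columns; expected ", 3L * nrow(atoms))
  }
  if (!all(is.finite(xyz))) stop("non-finite coordinates")
  rownames(atoms) <- NULL
  structure(list(atoms = atoms, xyz = xyz, source = source, format = format),
            class = "fab_structure")
}

#' @export
print.fab_structure <- function(x, ...) {
  cat("<fab_structure> ", n_models(x), " model(s), ", n_atoms(x), " atoms, chains: ",
      paste(sort(unique(x$atoms$chain)), collapse = " "), "\n", sep = "")
  invisible(x)
}

#' Number of models / atoms in a structure
#' @param x a `fab_structure`.
#' @return integer count.
#' @export
n_models <- function(x) nrow(x$xyz)

#' @rdname n_models
#' @export
n_atoms <- function(x) nrow(x$atoms)

#' Coordinates of one model
#'
#' @param x a `fab_structure`.
#' @param model 1-based model index.
#' @return `N x 3` numeric matrix.
#' @export
model_coords <- function(x, model = 1L) {
  if (model < 1L || model > n_models(x)) stop("model index out of range: ", model)
  matrix(x$xyz[model, ], ncol = 3L, byrow = TRUE)
}

#' Replace coordinates of one model
#' @inheritParams model_coords
#' @param coords `N x 3` matrix.
#' @return the modified structure.
#' @export
set_model_coords <- function(x, model, coords) {
  stopifnot(nrow(coords) == n_atoms(x), ncol(coords) == 3L)
  x$xyz[model, ] <- as.numeric(t(coords))
  x
}

atom_keys <- function(atoms) {
  paste(atoms$chain, atoms$resno, atoms$insert, atoms$elety, sep = "|")
}

res_keys <- function(atoms) {
  paste(atoms$chain, atoms$resno, atoms$insert, sep = "|")
}

# residue ordering: by chain, then number, then insertion code alphabetically
residue_order <- function(atoms) {
  order(atoms$chain, atoms$resno, atoms$insert, atoms$eleno)
}

parse_num <- function(s, what, lines_no) {
  v <- suppressWarnings(as.numeric(s))
  bad <- which(!is.finite(v))
  if (length(bad)) {
    stop("PDB parse failure: bad ", what, " field at line ", lines_no[bad[1]],
         call. = FALSE)
  }
  v
}

element_from_name <- function(elety) {
  e <- sub("^[0-9']+", "", elety)
  e <- substr(e, 1L, 1L)
  toupper(e)
}

#' Read a structure file
#'
#' Reads single- or multi-model PDB (MODEL/ENDMDL delimited) or, read-only,
#' mmCIF.  Alternate locations are resolved to the highest-occupancy record
#' (ties: first in file).  Water and hetero atoms are excluded unless
#' requested.  All models must share an identical atom roster; a mismatch
#' raises an error listing the offending atoms.
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"pdb"`, or `"mmcif"`.
#' @param keep_hetero keep HETATM records (waters still controlled by
#'   `keep_waters`).
#' @param keep_waters keep water residues (HOH/WAT/DOD).
#' @return a [fab_structure()].
#' @export
read_structure <- function(path, format = c("auto", "pdb", "mmcif"),
                           keep_hetero = FALSE, keep_waters = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.(cif|mmcif)$", path, ignore.case = TRUE)) "mmcif" else "pdb"
  }
  if (format == "mmcif") {
    return(read_structure_cif(path, keep_hetero = keep_hetero, keep_waters = keep_waters))
  }
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1L, 6L)
  is_atom <- rec %in% c("ATOM  ", "HETATM")
  model_id <- cumsum(startsWith(lines, "MODEL"))
  if (max(model_id) == 0L) model_id <- model_id + 1L
  # atoms after the last ENDMDL of a MODEL file would be orphaned; treat any
  # atom line with model_id 0 (before first MODEL) as a parse error
  if (any(is_atom & model_id == 0L)) {
    stop("PDB parse failure: ATOM record before first MODEL at line ",
         which(is_atom & model_id == 0L)[1], call. = FALSE)
  }
  idx <- which(is_atom)
  if (!length(idx)) stop("PDB parse failure: no ATOM/HETATM records in ", path, call. = FALSE)
  al <- lines[idx]
  at <- data.frame(
    type   = trimws(substr(al, 1L, 6L)),
    eleno  = suppressWarnings(as.integer(substr(al, 7L, 11L))),
    elety  = trimws(substr(al, 13L, 16L)),
    alt    = trimws(substr(al, 17L, 17L)),
    resid  = trimws(substr(al, 18L, 20L)),
    chain  = trimws(substr(al, 22L, 22L)),
    resno  = NA_integer_,
    insert = trimws(substr(al, 27L, 27L)),
    o      = 1.0, b = 0.0,
    elesy  = trimws(substr(al, 77L, 78L)),
    stringsAsFactors = FALSE
  )
  at$resno <- as.integer(parse_num(substr(al, 23L, 26L), "residue number", idx))
  x <- parse_num(substr(al, 31L, 38L), "x coordinate", idx)
  y <- parse_num(substr(al, 39L, 46L), "y coordinate", idx)
  z <- parse_num(substr(al, 47L, 54L), "z coordinate", idx)
  occ <- trimws(substr(al, 55L, 60L))
  at$o <- ifelse(nzchar(occ), suppressWarnings(as.numeric(occ)), 1.0)
  at$o[!is.finite(at$o)] <- 1.0
  bf <- trimws(substr(al, 61L, 66L))
  at$b <- ifelse(nzchar(bf), suppressWarnings(as.numeric(bf)), 0.0)
  at$b[!is.finite(at$b)] <- 0.0
  no_el <- !nzchar(at$elesy)
  at$elesy[no_el] <- element_from_name(at$elety[no_el])
  at$model <- model_id[idx]

  keep <- rep(TRUE, nrow(at))
  if (!keep_waters) keep <- keep & !(at$resid %in% c("HOH", "WAT", "DOD"))
  if (!keep_hetero) keep <- keep & at$type == "ATOM"
  at <- at[keep, , drop = FALSE]
  x <- x[keep]; y <- y[keep]; z <- z[keep]
  if (!nrow(at)) stop("no atoms retained from ", path)

  # altloc resolution: per (model, atom key) keep highest occupancy, ties by
  # file order
  key <- paste(at$model, atom_keys(at), sep = "@")
  ord <- order(-at$o, seq_len(nrow(at)))       # best candidates first
  first_best <- ord[!duplicated(key[ord])]
  sel <- sort(first_best)
  at <- at[sel, , drop = FALSE]
  x <- x[sel]; y <- y[sel]; z <- z[sel]
  at$alt <- NULL

  models <- sort(unique(at$model))
  m1 <- at$model == models[1]
  roster <- atom_keys(at[m1, , drop = FALSE])
  coords <- matrix(NA_real_, nrow = length(models), ncol = 3L * length(roster))
  for (mi in seq_along(models)) {
    im <- which(at$model == models[mi])
    k <- atom_keys(at[im, , drop = FALSE])
    extra <- setdiff(k, roster)
    missing <- setdiff(roster, k)
    if (length(extra) || length(missing) || length(k) != length(roster)) {
      stop("inconsistent atom roster in model ", mi,
           if (length(missing)) paste0("; missing: ", paste(missing, collapse = ", ")),
           if (length(extra)) paste0("; extra: ", paste(extra, collapse = ", ")),
           call. = FALSE)
    }
    pos <- match(roster, k)
    xm <- x[im][pos]; ym <- y[im][pos]; zm <- z[im][pos]
    coords[mi, ] <- as.numeric(rbind(xm, ym, zm))
  }
  atoms <- at[m1, , drop = FALSE]
  atoms$model <- NULL
  fab_structure(atoms, coords, source = path, format = "pdb")
}

read_structure_cif <- function(path, keep_hetero = FALSE, keep_waters = FALSE) {
  cif <- bio3d::read.cif(path)
  at <- cif$atom
  keep <- rep(TRUE, nrow(at))
  if (!keep_waters) keep <- keep & !(at$resid %in% c("HOH", "WAT", "DOD"))
  if (!keep_hetero) keep <- keep & at$type == "ATOM"
  at <- at[keep, , drop = FALSE]
  if (!nrow(at)) stop("no atoms retained from ", path)
  atoms <- data.frame(
    type = at$type, eleno = at$eleno, elety = at$elety,
    resid = at$resid, chain = at$chain, resno = at$resno,
    insert = ifelse(is.na(at$insert), "", at$insert),
    o = ifelse(is.finite(at$o), at$o, 1.0),
    b = ifelse(is.finite(at$b), at$b, 0.0),
    elesy = ifelse(nzchar(at$elesy) & !is.na(at$elesy), at$elesy,
                   element_from_name(at$elety)),
    stringsAsFactors = FALSE
  )
  coords <- cbind(at$x, at$y, at$z)
  fab_structure(atoms, coords, source = path, format = "mmcif")
}

fmt_atom_name <- function(elety, elesy) {
  # names of 1-3 characters start in column 14 when the element symbol is a
  # single character (standard PDB convention)
  ifelse(nchar(elety) >= 4L | nchar(elesy) > 1L,
         formatC(elety, width = -4L),
         formatC(paste0(" ", elety), width = -4L))
}

#' Write a structure as (multi-model) PDB
#'
#' Models are wrapped in MODEL/ENDMDL records when there is more than one.
#' Output is deterministic: identical structures yield byte-identical files.
#'
#' @param x a `fab_structure`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(x, path) {
  stopifnot(inherits(x, "fab_structure"))
  a <- x$atoms
  nm <- n_models(x)
  name4 <- fmt_atom_name(a$elety, a$elesy)
  con <- file(path, open = "wb")   # binary mode: fixed "\n", byte-reproducible
  on.exit(close(con))
  for (mi in seq_len(nm)) {
    if (nm > 1L) writeLines(sprintf("MODEL     %4d", mi), con, sep = "\n")
    cm <- model_coords(x, mi)
    lines <- sprintf("%-6s%5d %s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                     a$type, a$eleno %% 100000L, name4, "", a$resid, a$chain,
                     a$resno, a$insert, cm[, 1], cm[, 2], cm[, 3], a$o, a$b,
                     formatC(a$elesy, width = 2L))
    writeLines(lines, con, sep = "\n")
    if (nm > 1L) writeLines("ENDMDL", con, sep = "\n")
  }
  writeLines("END", con, sep = "\n")
  invisible(path)
}
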