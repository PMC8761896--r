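# quick builders for hand-crafted structures and PDB text

pdb_line <- function(serial, name, resid, chain, resno, x, y, z,
                     occ = 1, b = 0, icode = "", element = NULL,
                     type = "ATOM") {
  if (is.null(element)) element <- substr(gsub("[0-9]", "", name), 1, 1)
  name4 <- if (nchar(name) >= 4) sprintf("%-4s", name) else sprintf(" %-3s", name)
  sprintf("%-6s%5d %s %-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          type, serial, name4, resid, chain, resno, icode, x, y, z, occ, b,
          sprintf("%2s", element))
}

# data.frame row(s) for hand-built fab_structure objects
atom_row <- function(elety, resid, chain, resno, insert = "", elesy = NULL) {
  if (is.null(elesy)) elesy <- substr(gsub("[0-9]", "", elety), 1, 1)
  data.frame(type = "ATOM", eleno = 0L, elety = elety, resid = resid,
             chain = chain, resno = resno, insert = insert, o = 1, b = 0,
             elesy = elesy, stringsAsFactors = FALSE)
}

# a chain of n CA-only residues along x (plus slight y/z so sets are 3D)
ca_chain <- function(chain, resnos, resids = NULL, origin = c(0, 0, 0)) {
  n <- length(resnos)
  if (is.null(resids)) resids <- rep("ALA", n)
  atoms <- do.call(rbind, Map(function(e, r, no) atom_row("CA", r, chain, no),
                              seq_len(n), resids, resnos))
  coords <- cbind(origin[1] + 3.8 * seq_len(n),
                  origin[2] + 0.3 * (seq_len(n) %% 3),
                  origin[3] + 0.5 * (seq_len(n) %% 2))
  list(atoms = atoms, coords = coords)
}

build_structure <- function(...) {
  parts <- list(...)
  atoms <- do.call(rbind, lapply(parts, `[[`, "atoms"))
  atoms$eleno <- seq_len(nrow(atoms))
  rownames(atoms) <- NULL
  fab_structure(atoms, do.call(rbind, lapply(parts, `[[`, "coords")))
}
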