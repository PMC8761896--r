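# Domain maps assign chains and inclusive Chothia residue ranges to the four
# Fab domains.  Insertion-coded residues (e.g. 103a) belong to the range that
# contains their parent number, i.e. a range ending at 103 includes 103a.

#' Create a domain map
#'
#' @param VH,VL,CH1,CL each a `list(chain = , range = c(lo, hi))` with an
#'   inclusive Chothia residue range.  `VH` and `VL` are required; `CH1`/`CL`
#'   are needed only for elbow-angle and elbow-interface computations.
#' @param light_isotype `"kappa"`, `"lambda"`, or `"unspecified"`.
#' @return object of class `domain_map`.
#' @export
domain_map <- function(VH, VL, CH1 = NULL, CL = NULL,
                       light_isotype = c("unspecified", "kappa", "lambda")) {
  light_isotype <- match.arg(light_isotype)
  doms <- list(VH = VH, VL = VL, CH1 = CH1, CL = CL)
  doms <- doms[!vapply(doms, is.null, logical(1))]
  for (nm in names(doms)) {
    d <- doms[[nm]]
    if (is.null(d$chain) || is.null(d$range) || length(d$range) != 2L) {
      stop("domain ", nm, " must be list(chain=, range=c(lo, hi))")
    }
    if (d$range[1] > d$range[2]) stop("domain ", nm, ": range lo > hi")
  }
  # ranges must not overlap within a chain
  by_chain <- split(doms, vapply(doms, function(d) as.character(d$chain), character(1)))
  for (ds in by_chain) {
    if (length(ds) > 1L) {
      rng <- t(vapply(ds, function(d) as.numeric(d$range), numeric(2)))
      o <- order(rng[, 1])
      rng <- rng[o, , drop = FALSE]
      if (any(rng[-1, 1] <= rng[-nrow(rng), 2])) {
        stop("overlapping domain ranges on chain ", ds[[1]]$chain)
      }
    }
  }
  structure(list(domains = doms, light_isotype = light_isotype),
            class = "domain_map")
}

#' Read / write a domain map as YAML
#'
#' The YAML layout is `domains: {VH: {chain: H, range: [1, 113]}, ...}` with
#' an optional top-level `light_isotype`.
#'
#' @param path file path.
#' @return [domain_map()] for the reader; `path` invisibly for the writer.
#' @export
read_domain_map <- function(path) {
  y <- yaml::read_yaml(path)
  d <- y$domains
  if (is.null(d)) stop("domain map YAML lacks a 'domains' block")
  norm <- function(e) if (is.null(e)) NULL else list(chain = as.character(e$chain),
                                                     range = as.numeric(unlist(e$range)))
  domain_map(VH = norm(d$VH), VL = norm(d$VL), CH1 = norm(d$CH1), CL = norm(d$CL),
             light_isotype = if (is.null(y$light_isotype)) "unspecified" else y$light_isotype)
}

#' @rdname read_domain_map
#' @param map a `domain_map`.
#' @export
write_domain_map <- function(map, path) {
  stopifnot(inherits(map, "domain_map"))
  y <- list(domains = lapply(map$domains, function(d)
              list(chain = d$chain, range = as.integer(d$range))),
            light_isotype = map$light_isotype)
  yaml::write_yaml(y, path)
  invisible(path)
}

#' Partition a structure into Fab domains
#'
#' Resolves each mapped domain to its atom indices.  Residues outside mapped
#' ranges are ignored; insertion-coded residues fall inside the range that
#' contains their number (103a is within a range ending at 103).
#'
#' @param structure a [fab_structure()].
#' @param map a [domain_map()].
#' @param min_calpha minimum number of C-alpha atoms per resolved domain
#'   (default 20, the floor for a credible immunoglobulin domain).
#' @return object of class `fab_model` with elements `structure`, `map`, and
#'   `domains` (named list of atom index vectors).
#' @export
apply_domain_map <- function(structure, map, min_calpha = 20L) {
  stopifnot(inherits(structure, "fab_structure"), inherits(map, "domain_map"))
  a <- structure$atoms
  chains <- unique(a$chain)
  domains <- list()
  for (nm in names(map$domains)) {
    d <- map$domains[[nm]]
    if (!(d$chain %in% chains)) {
      stop("domain ", nm, ": chain '", d$chain, "' not present in structure")
    }
    idx <- which(a$chain == d$chain & a$resno >= d$range[1] & a$resno <= d$range[2])
    nca <- sum(a$elety[idx] == "CA")
    if (nca < min_calpha) {
      stop("domain ", nm, " resolves only ", nca, " C-alpha atoms (need >= ",
           min_calpha, ")")
    }
    ord <- idx[order(a$resno[idx], a$insert[idx], a$eleno[idx])]
    domains[[nm]] <- ord
  }
  structure(list(structure = structure, map = map, domains = domains),
            class = "fab_model")
}

#' @export
print.fab_model <- function(x, ...) {
  cat("<fab_model> domains:",
      paste(sprintf("%s(%d atoms)", names(x$domains),
                    vapply(x$domains, length, integer(1))), collapse = " "),
      "| models:", n_models(x$structure), "\n")
  invisible(x)
}

#' C-alpha coordinates of one domain in one model
#'
#' @param fab a `fab_model`.
#' @param domain one of `"VH"`, `"VL"`, `"CH1"`, `"CL"`.
#' @param model model index.
#' @return list with `positions` (integer Chothia numbers), `insert`
#'   (insertion codes), and `coords` (`n x 3` matrix, residue order).
#' @export
domain_calphas <- function(fab, domain, model = 1L) {
  stopifnot(inherits(fab, "fab_model"))
  idx <- fab$domains[[domain]]
  if (is.null(idx)) stop("domain ", domain, " not resolved in this model")
  a <- fab$structure$atoms
  ca <- idx[a$elety[idx] == "CA"]
  cm <- model_coords(fab$structure, model)
  list(positions = a$resno[ca], insert = a$insert[ca],
       coords = cm[ca, , drop = FALSE])
}

domain_atom_idx <- function(fab, domains) {
  miss <- setdiff(domains, names(fab$domains))
  if (length(miss)) stop("domain(s) not resolved: ", paste(miss, collapse = ", "))
  sort(unique(unlist(fab$domains[domains])))
}

# one-letter amino-acid codes; anything else becomes 'X'
AA_321 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
            GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
            MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
            TYR = "Y", VAL = "V")

#' Extract the amino-acid sequence of a domain
#'
#' One-letter sequence in residue order (number, then insertion code);
#' residues with non-standard names are reported as `X`.
#'
#' @inheritParams domain_calphas
#' @param with_positions also return the Chothia position labels.
#' @return character scalar, or a list with `sequence` and `positions` when
#'   `with_positions = TRUE`.
#' @export
extract_sequence <- function(fab, domain = c("VH", "VL"), with_positions = FALSE) {
  domain <- match.arg(domain)
  ca <- domain_calphas(fab, domain)
  a <- fab$structure$atoms
  idx <- fab$domains[[domain]]
  ca_idx <- idx[a$elety[idx] == "CA"]
  aa <- unname(AA_321[a$resid[ca_idx]])
  aa[is.na(aa)] <- "X"
  seqs <- paste(aa, collapse = "")
  if (!with_positions) return(seqs)
  list(sequence = seqs, positions = paste0(ca$positions, ca$insert))
}

#' Write sequences to FASTA
#'
#' @param sequences named character vector of sequences.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(sequences, path) {
  seqinr::write.fasta(as.list(unname(sequences)), names = names(sequences),
                      file.out = path, nbchar = 60)
  invisible(path)
}
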