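# Non-redundant structure-set construction and interface residue-position
# frequency profiling.

#' Annotate a Fab structure with conformational features
#'
#' Computes the feature set of one structure (model 1): VH/VL sequences with
#' Chothia position labels, the six orientation parameters, the elbow angle
#' (when CH1/CL are mapped -- Fv-only entries get partial records), buried
#' ASA and contact counts at the VH-VL and elbow interfaces, and the
#' interface residue positions per side.  Field-level failures are recorded
#' as `NA` rather than aborting a batch.  Gene origin and SHM level are
#' accepted as pass-through `metadata`, never computed.
#'
#' @param fab a `fab_model`.
#' @param id unique identifier for the record.
#' @param metadata named list of pass-through columns (e.g. `gene_origin`,
#'   `shm_level`).
#' @param probe_radius,n_points forwarded to the SASA engine.
#' @return one-row data.frame (an annotation record).
#' @export
annotate_structure <- function(fab, id = "structure", metadata = list(),
                               probe_radius = 1.4, n_points = 960L) {
  try_na <- function(expr) tryCatch(expr, error = function(e) NA)
  vh <- try_na(extract_sequence(fab, "VH", with_positions = TRUE))
  vl <- try_na(extract_sequence(fab, "VL", with_positions = TRUE))
  ori <- try_na(unclass(vhvl_orientation(fab)))
  has_c <- all(c("CH1", "CL") %in% names(fab$domains))
  elbow <- if (has_c) try_na(as.numeric(elbow_angle(fab))) else NA_real_
  sp_v <- interface_spec("VH-VL")
  basa_v <- try_na(as.numeric(buried_asa(fab, sp_v, probe_radius = probe_radius,
                                         n_points = n_points)))
  basa_e <- if (has_c) {
    try_na(as.numeric(buried_asa(fab, interface_spec("elbow"),
                                 probe_radius = probe_radius, n_points = n_points)))
  } else NA_real_
  nhb <- try_na(nrow(detect_hbonds(fab, sp_v)))
  nsb <- if (has_c) try_na(nrow(detect_saltbridges(fab, interface_spec("elbow")))) else NA_integer_
  ires <- try_na(interface_residues(fab, sp_v, probe_radius = probe_radius,
                                    n_points = n_points))
  pos_str <- function(df) {
    if (!is.data.frame(df) || !nrow(df)) return("")
    paste0(df$resno, df$insert, collapse = ",")
  }
  rec <- data.frame(
    identifier = id,
    vh_seq = if (is.list(vh)) vh$sequence else NA_character_,
    vh_positions = if (is.list(vh)) paste(vh$positions, collapse = ",") else NA_character_,
    vl_seq = if (is.list(vl)) vl$sequence else NA_character_,
    vl_positions = if (is.list(vl)) paste(vl$positions, collapse = ",") else NA_character_,
    light_isotype = fab$map$light_isotype,
    HL = if (is.numeric(ori)) ori[["HL"]] else NA_real_,
    HC1 = if (is.numeric(ori)) ori[["HC1"]] else NA_real_,
    HC2 = if (is.numeric(ori)) ori[["HC2"]] else NA_real_,
    LC1 = if (is.numeric(ori)) ori[["LC1"]] else NA_real_,
    LC2 = if (is.numeric(ori)) ori[["LC2"]] else NA_real_,
    dc = if (is.numeric(ori)) ori[["dc"]] else NA_real_,
    elbow = elbow,
    basa_vhvl = basa_v,
    basa_elbow = basa_e,
    n_hbonds_vhvl = if (length(nhb) == 1 && !is.na(nhb)) as.integer(nhb) else NA_integer_,
    n_saltbridges_elbow = if (length(nsb) == 1 && !is.na(nsb)) as.integer(nsb) else NA_integer_,
    interface_vh = if (is.list(ires)) pos_str(ires$side_a) else NA_character_,
    interface_vl = if (is.list(ires)) pos_str(ires$side_b) else NA_character_,
    stringsAsFactors = FALSE
  )
  for (nm in names(metadata)) rec[[nm]] <- metadata[[nm]]
  rec
}

#' Remove antibodies with identical variable-domain sequences
#'
#' Records are grouped by exact, case-normalised identity of the
#' concatenated VH+VL sequence; one representative per group is kept (first
#' by identifier sort), and the cluster map is retained.  Records with a
#' missing sequence are skipped with a warning.  The operation is idempotent
#' and its output set is independent of input order.
#'
#' @param records data.frame of annotation records (rows from
#'   [annotate_structure()], or any frame with `identifier`, `vh_seq`,
#'   `vl_seq`).
#' @return list with `unique` (representative records, identifier-sorted)
#'   and `clusters` (data.frame `identifier`, `representative`,
#'   `cluster_size`).
#' @export
dedup_by_sequence <- function(records) {
  stopifnot(is.data.frame(records))
  missing <- is.na(records$vh_seq) | is.na(records$vl_seq) |
    !nzchar(records$vh_seq) | !nzchar(records$vl_seq)
  if (any(missing)) {
    warning(sum(missing), " record(s) skipped: missing VH or VL sequence (",
            paste(records$identifier[missing], collapse = ", "), ")",
            call. = FALSE)
    records <- records[!missing, , drop = FALSE]
  }
  if (!nrow(records)) {
    return(list(unique = records,
                clusters = data.frame(identifier = character(0),
                                      representative = character(0),
                                      cluster_size = integer(0))))
  }
  key <- toupper(paste0(records$vh_seq, records$vl_seq))
  reps <- tapply(records$identifier, key, function(ids) sort(ids)[1])
  sizes <- tapply(records$identifier, key, length)
  clusters <- data.frame(identifier = records$identifier,
                         representative = as.character(reps[key]),
                         cluster_size = as.integer(sizes[key]),
                         stringsAsFactors = FALSE)
  clusters <- clusters[order(clusters$representative, clusters$identifier), ,
                       drop = FALSE]
  rownames(clusters) <- NULL
  keep <- records$identifier %in% unname(reps)
  uni <- records[keep, , drop = FALSE]
  uni <- uni[order(uni$identifier), , drop = FALSE]
  rownames(uni) <- NULL
  list(unique = uni, clusters = clusters)
}

parse_positions <- function(s) {
  if (is.na(s) || !nzchar(s)) return(character(0))
  strsplit(s, ",", fixed = TRUE)[[1]]
}

#' Interface residue-position frequency profile
#'
#' Fraction of records in which each Chothia position is an interface
#' residue, over the records carrying interface annotation.  Positions below
#' `min_report` are omitted from the profile but retained in the raw table
#' (the conventional reporting filter drops positions under 1%).
#'
#' @param records annotation records (normally the non-redundant set).
#' @param side `"VH"` or `"VL"`.
#' @param min_report reporting threshold as a fraction (default 0.01).
#' @return list of class `position_profile`: `profile` (filtered data.frame
#'   `position`, `frequency`, `count`), `raw` (unfiltered), `n_records`,
#'   `min_report`.
#' @export
position_frequencies <- function(records, side = c("VH", "VL"), min_report = 0.01) {
  side <- match.arg(side)
  col <- if (side == "VH") "interface_vh" else "interface_vl"
  ann <- records[[col]]
  has <- !is.na(ann)
  if (!any(has)) stop("no records carry interface annotation for ", side)
  n <- sum(has)
  pos <- unlist(lapply(ann[has], parse_positions), use.names = FALSE)
  if (length(pos)) {
    tab <- table(pos)
    num <- as.integer(sub("[a-z]*$", "", names(tab)))
    ic <- sub("^[0-9]*", "", names(tab))
    o <- order(num, ic)
    raw <- data.frame(position = names(tab)[o],
                      frequency = as.numeric(tab[o]) / n,
                      count = as.integer(tab[o]), stringsAsFactors = FALSE,
                      row.names = NULL)
  } else {
    raw <- data.frame(position = character(0), frequency = numeric(0),
                      count = integer(0))
  }
  structure(list(profile = raw[raw$frequency >= min_report, , drop = FALSE],
                 raw = raw, n_records = n, min_report = min_report,
                 side = side),
            class = "position_profile")
}

#' @export
print.position_profile <- function(x, ...) {
  cat(sprintf("<position_profile> %s interface, %d records, %d position(s) >= %g%%\n",
              x$side, x$n_records, nrow(x$profile), 100 * x$min_report))
  invisible(x)
}

lookup_residue <- function(seq, positions, pos) {
  labs <- parse_positions(positions)
  i <- match(as.character(pos), labs)
  if (is.na(i)) NA_character_ else substr(seq, i, i)
}

#' Partition annotation records for stratified comparison
#'
#' `key = "light_isotype"` splits into kappa / lambda / unspecified.
#' `key = "position_pair"` splits into records that carry the stated residue
#' pair (e.g. Gln at heavy 39 and Gln at light 38) and records that do not;
#' records whose sequences cannot be interrogated fall into `unspecified`.
#' The partitions feed [compare_variants()] or [ks_two_sample()] on any
#' numeric field.
#'
#' @param records annotation records.
#' @param key `"light_isotype"` or `"position_pair"`.
#' @param vh_pos,vh_aa,vl_pos,vl_aa the residue pair (position-pair key
#'   only); positions are Chothia labels (insertion codes allowed, e.g.
#'   `"103a"`).
#' @return named list of data.frame partitions.
#' @export
stratify <- function(records, key = c("light_isotype", "position_pair"),
                     vh_pos = 39, vh_aa = "Q", vl_pos = 38, vl_aa = "Q") {
  key <- match.arg(key)
  if (key == "light_isotype") {
    g <- records$light_isotype
    g[is.na(g) | !g %in% c("kappa", "lambda")] <- "unspecified"
  } else {
    g <- vapply(seq_len(nrow(records)), function(i) {
      r <- records[i, ]
      if (is.na(r$vh_seq) || is.na(r$vl_seq) ||
          is.na(r$vh_positions) || is.na(r$vl_positions)) return("unspecified")
      h <- lookup_residue(r$vh_seq, r$vh_positions, vh_pos)
      l <- lookup_residue(r$vl_seq, r$vl_positions, vl_pos)
      if (is.na(h) || is.na(l)) return("without")
      if (h == vh_aa && l == vl_aa) "with" else "without"
    }, character(1))
  }
  sp <- split(records, g)
  lapply(sp, function(d) { rownames(d) <- NULL; d })
}

#' Build sequence-only records from a FASTA file
#'
#' For dedup of sequence collections without structures.  Headers must be
#' `<id>|VH` and `<id>|VL`; entries lacking either mate are dropped with a
#' warning.
#'
#' @param path FASTA file path.
#' @return data.frame with `identifier`, `vh_seq`, `vl_seq`.
#' @export
records_from_fasta <- function(path) {
  fa <- seqinr::read.fasta(path, seqtype = "AA", as.string = TRUE)
  nm <- names(fa)
  parts <- strsplit(nm, "|", fixed = TRUE)
  ok <- lengths(parts) == 2L & vapply(parts, function(p) p[2] %in% c("VH", "VL"), logical(1))
  if (any(!ok)) warning("ignoring ", sum(!ok), " FASTA entries without |VH or |VL suffix")
  ids <- vapply(parts[ok], `[`, character(1), 1)
  dom <- vapply(parts[ok], `[`, character(1), 2)
  seqs <- toupper(vapply(fa[ok], as.character, character(1)))
  uids <- unique(ids)
  vh <- seqs[match(paste0(uids, "VH"), paste0(ids, dom))]
  vl <- seqs[match(paste0(uids, "VL"), paste0(ids, dom))]
  drop <- is.na(vh) | is.na(vl)
  if (any(drop)) warning("dropping ", sum(drop), " id(s) without both VH and VL")
  data.frame(identifier = uids[!drop], vh_seq = unname(vh[!drop]),
             vl_seq = unname(vl[!drop]), stringsAsFactors = FALSE)
}
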