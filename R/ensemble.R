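# Trajectory-level analytics over multi-model structures: alignment, RMSD,
# RMSF, coordinate PCA, and per-snapshot feature series.

# models inside a fractional window (start, end]: for n = 100 and (0.5, 1)
# this is models 51..100
window_models <- function(n, window = c(0.5, 1), min_models = 1L) {
  stopifnot(length(window) == 2L, window[1] >= 0, window[2] <= 1,
            window[1] < window[2])
  idx <- seq.int(floor(window[1] * n) + 1L, floor(window[2] * n))
  if (length(idx) < min_models) {
    stop("analysis window holds ", length(idx), " model(s); need >= ", min_models)
  }
  idx
}

#' Select C-alpha atoms
#'
#' @param x a [fab_structure()] or `fab_model`.
#' @param chains optional chain filter.
#' @param residues optional residue-number filter.
#' @param domains for a `fab_model`, restrict to these domains (e.g.
#'   `c("VH", "VL")`).
#' @return integer atom indices into the structure's atom table.
#' @export
select_calpha <- function(x, chains = NULL, residues = NULL, domains = NULL) {
  if (inherits(x, "fab_model")) {
    pool <- if (is.null(domains)) seq_len(n_atoms(x$structure)) else
      domain_atom_idx(x, domains)
    a <- x$structure$atoms
  } else {
    pool <- seq_len(n_atoms(x))
    a <- x$atoms
    if (!is.null(domains)) stop("domains selection needs a fab_model")
  }
  idx <- pool[a$elety[pool] == "CA"]
  if (!is.null(chains)) idx <- idx[a$chain[idx] %in% chains]
  if (!is.null(residues)) idx <- idx[a$resno[idx] %in% residues]
  idx
}

#' Superpose every model onto a reference model
#'
#' Kabsch superposition on the selected C-alpha atoms (typically the VH+VL
#' C-alphas), applied to all atoms of each model; the post-fit RMSD of the
#' selection gives the convergence series.
#'
#' @param structure a [fab_structure()].
#' @param selection integer atom indices used for fitting (e.g. from
#'   [select_calpha()]); default all C-alpha atoms.
#' @param reference_model model to superpose onto (default 1, the first
#'   snapshot).
#' @return list with `structure` (aligned copy) and `rmsd` (per-model
#'   Angstrom series).
#' @export
align_trajectory <- function(structure, selection = NULL, reference_model = 1L) {
  st <- structure
  if (is.null(selection)) selection <- which(st$atoms$elety == "CA")
  if (!length(selection)) stop("empty selection")
  ref <- model_coords(st, reference_model)[selection, , drop = FALSE]
  rmsd <- numeric(n_models(st))
  for (m in seq_len(n_models(st))) {
    cm <- model_coords(st, m)
    tf <- kabsch_superpose(cm[selection, , drop = FALSE], ref)
    rmsd[m] <- tf$rmsd
    st <- set_model_coords(st, m, apply_transform(cm, tf))
  }
  list(structure = st, rmsd = rmsd)
}

#' RMSD-plateau convergence diagnostic
#'
#' Sliding-window mean drift of an RMSD series: the absolute difference
#' between consecutive window means, in Angstrom.  Convergence screening is
#' a user decision; this diagnostic never drops data.
#'
#' @param rmsd numeric RMSD series.
#' @param n_windows number of equal windows.
#' @return list with `window_means`, `max_drift`, and `converged`
#'   (`max_drift < tol`).
#' @param tol drift tolerance in Angstrom.
#' @export
rmsd_plateau <- function(rmsd, n_windows = 5L, tol = 0.5) {
  cuts <- cut(seq_along(rmsd), breaks = n_windows, labels = FALSE)
  wm <- tapply(rmsd, cuts, mean)
  drift <- max(abs(diff(wm)))
  list(window_means = as.numeric(wm), max_drift = drift, converged = drift < tol)
}

#' Per-residue root-mean-square fluctuation
#'
#' `RMSF_i = sqrt(mean_t |r_i(t) - mean_t r_i|^2)` over the models in the
#' analysis window, computed on C-alpha atoms of an already-aligned
#' trajectory.
#'
#' @param structure an aligned [fab_structure()].
#' @param selection C-alpha atom indices (default: all C-alphas).
#' @param window fractional `(start, end)` of models used; the default
#'   `(0.5, 1)` drops the first half as equilibration.
#' @return data.frame `chain`, `resno`, `insert`, `rmsf` (Angstrom).
#' @export
rmsf <- function(structure, selection = NULL, window = c(0.5, 1)) {
  if (is.null(selection)) selection <- which(structure$atoms$elety == "CA")
  idx <- window_models(n_models(structure), window, min_models = 2L)
  cols <- as.numeric(vapply(selection, function(i) (3 * (i - 1)) + 1:3, numeric(3)))
  X <- structure$xyz[idx, cols, drop = FALSE]
  mu <- colMeans(X)
  dev2 <- sweep(X, 2L, mu)^2
  per_atom_ms <- colMeans(dev2)
  ms <- per_atom_ms[seq(1, length(cols), 3)] + per_atom_ms[seq(2, length(cols), 3)] +
        per_atom_ms[seq(3, length(cols), 3)]
  a <- structure$atoms[selection, , drop = FALSE]
  data.frame(chain = a$chain, resno = a$resno, insert = a$insert,
             rmsf = sqrt(ms), stringsAsFactors = FALSE, row.names = NULL)
}

#' Principal component analysis of C-alpha coordinates
#'
#' Eigendecomposition of the 3N-dimensional C-alpha coordinate covariance
#' over the analysis window, as in coordinate-space essential dynamics.
#'
#' @inheritParams rmsf
#' @return object of class `pca_result`: `eigenvalues` (A^2, descending),
#'   `variance_fraction`, `vectors` (columns = components), `projections`
#'   (models x components), `models` (window indices).
#' @export
pca_trajectory <- function(structure, selection = NULL, window = c(0.5, 1)) {
  if (is.null(selection)) selection <- which(structure$atoms$elety == "CA")
  idx <- window_models(n_models(structure), window, min_models = 3L)
  cols <- as.numeric(vapply(selection, function(i) (3 * (i - 1)) + 1:3, numeric(3)))
  X <- structure$xyz[idx, cols, drop = FALSE]
  pc <- prcomp(X, center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2
  structure(list(eigenvalues = ev,
                 variance_fraction = if (sum(ev) > 0) ev / sum(ev) else ev,
                 vectors = pc$rotation, projections = pc$x, models = idx),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  vf <- x$variance_fraction
  cat(sprintf("<pca_result> %d models, top components: %s\n",
              length(x$models),
              paste(sprintf("%.1f%%", 100 * utils::head(vf, 3)), collapse = " ")))
  invisible(x)
}

FEATURE_NAMES <- c("HL", "HC1", "HC2", "LC1", "LC2", "dc", "elbow")

#' Per-snapshot feature table
#'
#' Computes geometry and interface features for every model in the analysis
#' window.  Orientation parameters are computed once per model and shared
#' among the six columns.  Interface features are requested as
#' `"bASA:VH-VL"` or `"bASA:elbow"`.
#'
#' @param fab a `fab_model`.
#' @param features character vector drawn from
#'   `HL, HC1, HC2, LC1, LC2, dc, elbow, bASA:<interface>`.
#' @param window fractional analysis window; the default `(0.5, 1)` keeps
#'   the second half of the trajectory.
#' @param probe_radius,n_points forwarded to the SASA engine.
#' @return data.frame with `model_index` plus one column per feature.
#' @export
feature_table <- function(fab, features = c("HL", "HC1", "HC2", "LC1", "LC2", "dc"),
                          window = c(0.5, 1), probe_radius = 1.4, n_points = 960L) {
  idx <- window_models(n_models(fab$structure), window, min_models = 1L)
  ori_feats <- intersect(features, c("HL", "HC1", "HC2", "LC1", "LC2", "dc"))
  want_elbow <- "elbow" %in% features
  basa_feats <- grep("^bASA:", features, value = TRUE)
  bad <- setdiff(features, c(ori_feats, "elbow", basa_feats))
  if (length(bad)) stop("unknown feature(s): ", paste(bad, collapse = ", "))
  out <- data.frame(model_index = idx)
  for (f in features) out[[f]] <- NA_real_
  specs <- lapply(basa_feats, function(f) {
    nm <- sub("^bASA:", "", f)
    if (nm %in% c("VH-VL", "elbow")) interface_spec(nm) else
      stop("unknown interface in feature ", f)
  })
  names(specs) <- basa_feats
  for (r in seq_along(idx)) {
    m <- idx[r]
    tryCatch({
      if (length(ori_feats)) {
        o <- vhvl_orientation(fab, m)
        for (f in ori_feats) out[[f]][r] <- unclass(o)[[f]]
      }
      if (want_elbow) out[["elbow"]][r] <- as.numeric(elbow_angle(fab, m))
      for (f in basa_feats) {
        out[[f]][r] <- as.numeric(buried_asa(fab, specs[[f]], m,
                                             probe_radius = probe_radius,
                                             n_points = n_points))
      }
    }, error = function(e) {
      stop("feature computation failed at model ", m, ": ", conditionMessage(e),
           call. = FALSE)
    })
  }
  attr(out, "window") <- window
  out
}

#' One feature as a per-snapshot series
#'
#' @inheritParams feature_table
#' @param feature single feature name.
#' @return object of class `feature_series`: numeric vector with attributes
#'   `feature`, `units`, `window`, `model_index`.
#' @export
feature_series <- function(fab, feature, window = c(0.5, 1), ...) {
  tb <- feature_table(fab, features = feature, window = window, ...)
  v <- tb[[feature]]
  attr(v, "feature") <- feature
  attr(v, "units") <- if (feature == "dc") "Angstrom" else
    if (startsWith(feature, "bASA")) "Angstrom^2" else "degrees"
  attr(v, "window") <- window
  attr(v, "model_index") <- tb$model_index
  class(v) <- "feature_series"
  v
}

#' @export
print.feature_series <- function(x, ...) {
  cat(sprintf("<feature_series> %s [%s], %d models: mean %.3f sd %.3f\n",
              attr(x, "feature"), attr(x, "units"), length(x),
              mean(unclass(x)), sd(unclass(x))))
  invisible(x)
}
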