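# Tabular and JSON writers for the standard outputs.  TSV columns follow the
# documented layouts; JSON carries full precision plus convention metadata.

write_tsv <- function(df, path, digits = NULL) {
  out <- as.data.frame(df)
  if (!is.null(digits)) {
    num <- vapply(out, is.numeric, logical(1))
    out[num] <- lapply(out[num], function(v) round(v, digits))
  }
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

CONVENTION_ID <- "fabkit-frames-1"   # packaged reference-frame convention

#' Write a per-model feature table
#'
#' TSV with `model_index` and one column per feature, angles rounded to two
#' decimals; the JSON variant keeps full precision and adds the frame
#' convention id.
#'
#' @param tab a [feature_table()] data.frame.
#' @param path output path.
#' @param format `"tsv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(tab, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (format == "tsv") return(write_tsv(tab, path, digits = 2))
  jsonlite::write_json(list(convention = CONVENTION_ID,
                            window = attr(tab, "window"),
                            features = as.list(tab)),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write an RMSF profile
#' @param profile data.frame from [rmsf()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_rmsf <- function(profile, path) write_tsv(profile, path)

#' Write PCA results
#'
#' Eigenvalues and variance fractions as JSON; per-model projections as TSV
#' when `projections_path` is given.
#'
#' @param pca a `pca_result`.
#' @param path JSON output path.
#' @param projections_path optional TSV path for the projections.
#' @param n_components how many components to include in the projections.
#' @return `path`, invisibly.
#' @export
write_pca <- function(pca, path, projections_path = NULL, n_components = 5L) {
  jsonlite::write_json(list(eigenvalues = pca$eigenvalues,
                            variance_fraction = pca$variance_fraction),
                       path, auto_unbox = TRUE, digits = NA)
  if (!is.null(projections_path)) {
    k <- min(n_components, ncol(pca$projections))
    df <- data.frame(model_index = pca$models,
                     pca$projections[, seq_len(k), drop = FALSE])
    write_tsv(df, projections_path)
  }
  invisible(path)
}

#' Write a contact/occupancy report
#'
#' TSV rows: kind, donor-side atom, acceptor-side atom, mean distance,
#' occupancy.  JSON additionally carries the residue-level granularity.
#'
#' @param contacts data.frame from [contact_occupancy()].
#' @param path output path.
#' @param format `"tsv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_contact_report <- function(contacts, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (format == "tsv") return(write_tsv(contacts, path))
  jsonlite::write_json(list(atom_level = contacts,
                            residue_level = attr(contacts, "residue_level")),
                       path, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(path)
}

#' Write a variant comparison report
#'
#' TSV columns `feature`, `D`, `p`, `p_adj`, `stars` with the star coding of
#' the figure-legend convention; JSON keeps the full report and the
#' correction metadata.
#'
#' @param report a `comparison_report`.
#' @param path output path.
#' @param format `"tsv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_comparison_report <- function(report, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (format == "tsv") {
    return(write_tsv(report[, c("feature", "D", "p", "p_adj", "stars")], path))
  }
  jsonlite::write_json(list(alpha = attr(report, "alpha"), m = attr(report, "m"),
                            method = attr(report, "method"),
                            results = as.data.frame(report)),
                       path, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(path)
}

#' Write annotation records, cluster maps, or position profiles
#'
#' One record per row, `NA` rendered as empty fields.
#'
#' @param x data.frame (records or cluster map) or a `position_profile`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(x, path) {
  if (inherits(x, "position_profile")) x <- x$profile
  out <- as.data.frame(x)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  invisible(path)
}
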