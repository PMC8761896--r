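# van der Waals radii (Angstrom), Bondi-type values for the elements that
# occur in protein structures.  Unknown elements fall back to a configurable
# default with a warning.
VDW_RADII <- c(
  H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
  F = 1.47, CL = 1.75, BR = 1.85, I = 1.98, SE = 1.90,
  FE = 1.80, ZN = 1.39, MG = 1.73, CA = 1.73, MN = 1.73, `NA` = 2.27, K = 2.75
)

#' Van der Waals radius lookup
#'
#' Maps element symbols to van der Waals radii from the packaged table.
#' Elements absent from the table receive `default` and trigger a single
#' warning naming them.
#'
#' @param element character vector of element symbols (case-insensitive).
#' @param default radius in Angstrom for unknown elements.
#' @return numeric vector of radii, same length as `element`.
#' @export
vdw_radius <- function(element, default = 1.8) {
  el <- toupper(trimws(element))
  r <- unname(VDW_RADII[el])
  unknown <- is.na(r) & !is.na(el) & nzchar(el)
  if (any(unknown)) {
    warning("unknown element(s) ", paste(sort(unique(el[unknown])), collapse = ", "),
            "; using default vdW radius ", default, " A", call. = FALSE)
  }
  r[is.na(r)] <- default
  r
}
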