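# Two-sample Kolmogorov-Smirnov comparison between antibody variants with
# multiple-testing control.
#
# Ties are handled by right-continuous empirical CDFs; the enumeration mode
# is the tie-safe exact route (it conditions on the observed pooled values).
# The note on correction scope: the correction is applied over the number of
# features in one comparison call by default; pass `m` to correct over a
# wider family (e.g. features x variant pairs).

ks_statistic <- function(x, y) {
  s <- sort(unique(c(x, y)))
  max(abs(ecdf(x)(s) - ecdf(y)(s)))
}

# exact conditional p by full enumeration of all C(n+m, n) assignments of the
# pooled values to the two groups
ks_p_enumeration <- function(x, y, d_obs) {
  v <- c(x, y)
  n <- length(x); nm <- length(v)
  cmb <- combn(nm, n)
  hits <- 0L
  for (j in seq_len(ncol(cmb))) {
    xi <- cmb[, j]
    if (ks_statistic(v[xi], v[-xi]) >= d_obs - 1e-12) hits <- hits + 1L
  }
  hits / ncol(cmb)
}

# exact p without ties, by counting monotone lattice paths that stay strictly
# below the observed statistic (psmirnov-equivalent dynamic programme)
ks_p_exact_dp <- function(d_obs, n, m) {
  eps <- 1e-9
  f <- matrix(0, nrow = n + 1L, ncol = m + 1L)
  f[1, 1] <- 1
  for (i in 0:n) {
    for (j in 0:m) {
      if (i == 0 && j == 0) next
      if (abs(i / n - j / m) >= d_obs - eps) next
      acc <- 0
      if (i > 0) acc <- acc + f[i, j + 1L]
      if (j > 0) acc <- acc + f[i + 1L, j]
      f[i + 1L, j + 1L] <- acc
    }
  }
  1 - f[n + 1L, m + 1L] / choose(n + m, n)
}

# asymptotic Kolmogorov tail Q(lambda) = 2 sum (-1)^{k-1} exp(-2 k^2 lambda^2)
ks_p_asymptotic <- function(d_obs, n, m) {
  lambda <- sqrt(n * m / (n + m)) * d_obs
  if (lambda < 1e-12) return(1)
  k <- 1:100
  p <- 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * lambda^2))
  min(1, max(0, p))
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' `D = sup |ECDF_x - ECDF_y|` with right-continuous ECDFs.  The p-value is
#' exact by full enumeration of all `C(n+m, n)` group assignments when that
#' count is within `enum_bound` (the tie-safe route), exact by lattice-path
#' counting for larger tie-free samples when `mode = "exact"`, and otherwise
#' asymptotic (Kolmogorov distribution).  `mode = "auto"` follows
#' enumeration-then-asymptotic.
#'
#' @param x,y numeric samples, each of length >= 2, finite.
#' @param mode `"auto"`, `"enumeration"`, `"exact"`, or `"asymptotic"`.
#' @param enum_bound largest admissible `C(n+m, n)` for enumeration.
#' @return object of class `ks_result`: `D`, `p`, `n`, `m`, `mode`.
#' @export
ks_two_sample <- function(x, y, mode = c("auto", "enumeration", "exact", "asymptotic"),
                          enum_bound = 1e5) {
  mode <- match.arg(mode)
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) < 2L || length(y) < 2L) stop("need n, m >= 2")
  if (!all(is.finite(c(x, y)))) stop("samples must be finite")
  n <- length(x); m <- length(y)
  D <- ks_statistic(x, y)
  has_ties <- anyDuplicated(c(x, y)) > 0L
  n_comb <- choose(n + m, n)
  if (mode == "auto") {
    mode <- if (n_comb <= enum_bound) "enumeration" else "asymptotic"
  }
  if (mode == "enumeration" && n_comb > enum_bound) {
    stop("enumeration infeasible: C(n+m, n) = ", format(n_comb), " > ", enum_bound)
  }
  if (mode == "exact" && has_ties) {
    if (n_comb <= enum_bound) {
      mode <- "enumeration"
    } else {
      warning("exact lattice-path p is not valid with ties and enumeration is ",
              "infeasible; falling back to asymptotic", call. = FALSE)
      mode <- "asymptotic"
    }
  }
  p <- switch(mode,
    enumeration = ks_p_enumeration(x, y, D),
    exact = ks_p_exact_dp(D, n, m),
    asymptotic = ks_p_asymptotic(D, n, m))
  out <- list(D = D, p = p, n = n, m = m,
              mode = if (mode == "enumeration") "exact" else mode,
              method = mode)
  class(out) <- "ks_result"
  out
}

#' @export
print.ks_result <- function(x, ...) {
  cat(sprintf("Two-sample KS: D = %.4f, p = %.4g (%s; n = %d, m = %d)\n",
              x$D, x$p, x$method, x$n, x$m))
  invisible(x)
}

#' Bonferroni correction
#'
#' Family-wise error control at level `alpha` over `m = length(pvalues)`
#' tests: test `i` is flagged when `p_i < alpha / m`.  Adjusted p-values
#' `min(1, m p)` are reported alongside.
#'
#' @param pvalues numeric vector in `[0, 1]`.
#' @param alpha family-wise level (default 0.01).
#' @return data.frame `p`, `p_adj`, `significant`; attributes `threshold`
#'   (`alpha / m`), `m`, `alpha`.
#' @export
bonferroni <- function(pvalues, alpha = 0.01) {
  if (any(!is.finite(pvalues)) || any(pvalues < 0 | pvalues > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  m <- length(pvalues)
  out <- data.frame(p = pvalues, p_adj = pmin(1, m * pvalues),
                    significant = pvalues < alpha / m)
  attr(out, "threshold") <- alpha / m
  attr(out, "m") <- m
  attr(out, "alpha") <- alpha
  out
}

star_code <- function(p_adj) {
  ifelse(p_adj < 0.01, "**", ifelse(p_adj < 0.05, "*", "ns"))
}

#' Compare two antibody variants feature by feature
#'
#' Per-feature two-sample KS test between matching feature series of the two
#' variants, with multiple-testing control over the features compared.
#' Star coding follows the usual figure-legend convention on the corrected
#' p-value: `**` below 0.01, `*` in `[0.01, 0.05)`, `ns` otherwise.  The
#' correction labelled "false discovery rate" in some figure legends is
#' standard Bonferroni (a family-wise error control, not an FDR procedure);
#' a Benjamini-Hochberg mode is available for users who want literal FDR.
#'
#' @param a,b named lists of numeric series (or [feature_table()] data
#'   frames, whose `model_index` column is dropped).  Feature names must
#'   match.
#' @param alpha family level (default 0.01).
#' @param m number of tests to correct over; defaults to the number of
#'   features in this call.
#' @param method `"bonferroni"` (default) or `"BH"`.
#' @param ks_mode forwarded to [ks_two_sample()].
#' @return data.frame of class `comparison_report`: `feature`, `D`, `p`,
#'   `p_adj`, `significant`, `stars`, `median_diff` (b minus a), `n_a`,
#'   `n_b`; attributes `alpha`, `m`, `method`.
#' @export
compare_variants <- function(a, b, alpha = 0.01, m = NULL,
                             method = c("bonferroni", "BH"), ks_mode = "auto") {
  method <- match.arg(method)
  as_list <- function(z) {
    if (is.data.frame(z)) z <- as.list(z[setdiff(names(z), "model_index")])
    z
  }
  a <- as_list(a); b <- as_list(b)
  if (is.null(names(a)) || is.null(names(b)) ||
      !setequal(names(a), names(b))) {
    stop("feature names of the two variants do not match: ",
         paste(symdiff_chr(names(a), names(b)), collapse = ", "))
  }
  feats <- names(a)
  ks <- lapply(feats, function(f) ks_two_sample(a[[f]], b[[f]], mode = ks_mode))
  p <- vapply(ks, `[[`, numeric(1), "p")
  if (is.null(m)) m <- length(feats)
  if (method == "bonferroni") {
    p_adj <- pmin(1, m * p)
    sig <- p < alpha / m
  } else {
    p_adj <- p.adjust(p, method = "BH", n = m)
    sig <- p_adj < alpha
  }
  out <- data.frame(
    feature = feats,
    D = vapply(ks, `[[`, numeric(1), "D"),
    p = p, p_adj = p_adj, significant = sig,
    stars = star_code(p_adj),
    median_diff = vapply(feats, function(f) median(b[[f]]) - median(a[[f]]), numeric(1)),
    n_a = vapply(a, length, integer(1)),
    n_b = vapply(b, length, integer(1)),
    stringsAsFactors = FALSE, row.names = NULL
  )
  attr(out, "alpha") <- alpha
  attr(out, "m") <- m
  attr(out, "method") <- method
  class(out) <- c("comparison_report", "data.frame")
  out
}

symdiff_chr <- function(a, b) union(setdiff(a, b), setdiff(b, a))

#' @export
print.comparison_report <- function(x, ...) {
  cat(sprintf("Variant comparison (%s over m = %d tests, alpha = %g):\n",
              attr(x, "method"), attr(x, "m"), attr(x, "alpha")))
  df <- as.data.frame(x)
  df$D <- round(df$D, 4); df$median_diff <- round(df$median_diff, 3)
  df$p <- signif(df$p, 3); df$p_adj <- signif(df$p_adj, 3)
  print(df, row.names = FALSE)
  invisible(x)
}
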