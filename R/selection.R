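# Likelihood-ratio tests and the two selection screens: "fast-evolving"
# genes from the H0/H1/H2 branch-model ladder, and "positively selected"
# genes from the branch-site Model A null/alternative pair, both under
# Benjamini-Hochberg FDR control.

#' Likelihood-ratio test between nested codon models
#'
#' @param lnL_null,lnL_alt log-likelihoods of the nested and the richer
#'   model.
#' @param df difference in free parameters (> 0).
#' @param tolerance negative statistics no larger than this (optimizer
#'   noise) are clamped to 0.
#' @return p-value from the chi-square upper tail of `2 * (lnL_alt -
#'   lnL_null)`.
#' @export
lrt <- function(lnL_null, lnL_alt, df, tolerance = 1e-4) {
  if (df <= 0) stop("df must be positive")
  stat <- 2 * (lnL_alt - lnL_null)
  if (stat < 0) {
    if (stat < -2 * abs(tolerance) - 1e-8 && stat < -0.02)
      warning("alternative lnL below null by ", format(-stat / 2),
              "; statistic clamped to 0")
    stat <- 0
  }
  stats::pchisq(stat, df = df, lower.tail = FALSE)
}

#' Fast-evolving gene screen from branch-model fits
#'
#' Applies the three-hypothesis decision rule per family: the two-ratio
#' model (H1) must beat the single-ratio model (H0) after FDR correction,
#' the free-ratio model (H2) must NOT beat H1 after correction, and the
#' foreground omega must exceed the background omega.
#'
#' @param fits named list, one element per family, each as returned by
#'   [fit_branch_models()] (elements `H0`, `H1`, `H2`).
#' @param alpha significance cutoff on BH-adjusted p-values (default 0.01).
#' @return data.frame with one row per family: lnL values, omegas, raw and
#'   adjusted p-values, and logical `fast_evolving`. Families with any
#'   unconverged fit are excluded (attribute `"excluded"`).
#' @export
classify_fast_evolving <- function(fits, alpha = 0.01) {
  stopifnot(length(fits) > 0)
  ids <- names(fits) %||% as.character(seq_along(fits))
  conv <- vapply(fits, function(f)
    f$H0$converged && f$H1$converged && f$H2$converged, logical(1))
  excluded <- ids[!conv]
  fits <- fits[conv]; ids <- ids[conv]
  if (!length(fits)) {
    out <- data.frame(family = character(0))
    attr(out, "excluded") <- excluded
    return(out)
  }
  nb <- nrow(fits[[1]]$H1$tree$edge)
  df2 <- max(nb - 2L, 1L)
  rows <- lapply(fits, function(f) {
    data.frame(
      lnL_H0 = f$H0$lnL, lnL_H1 = f$H1$lnL, lnL_H2 = f$H2$lnL,
      omega_foreground = f$H1$omega[["foreground"]],
      omega_background = f$H1$omega[["background"]],
      p_H1_vs_H0 = lrt(f$H0$lnL, f$H1$lnL, df = 1),
      p_H2_vs_H1 = lrt(f$H1$lnL, f$H2$lnL, df = df2))
  })
  out <- do.call(rbind, rows)
  out <- cbind(family = ids, out, row.names = NULL)
  out$q_H1_vs_H0 <- stats::p.adjust(out$p_H1_vs_H0, method = "BH")
  out$q_H2_vs_H1 <- stats::p.adjust(out$p_H2_vs_H1, method = "BH")
  out$fast_evolving <- out$q_H1_vs_H0 < alpha &
    out$q_H2_vs_H1 >= alpha &
    out$omega_foreground > out$omega_background
  attr(out, "excluded") <- excluded
  out
}

#' Positively-selected gene screen from branch-site fits
#'
#' One-degree-of-freedom LRT of branch-site Model A alternative vs null,
#' BH-corrected across families; a family is called when the adjusted
#' p-value is below `alpha` and the selected-class omega estimate exceeds
#' 1.
#'
#' @param fits named list per family as returned by
#'   [fit_branchsite_models()] (elements `null`, `alt`).
#' @param alpha cutoff on BH-adjusted p-values (default 0.01).
#' @return data.frame with lnL values, `omega2`, raw/adjusted p and logical
#'   `positively_selected`; unconverged families excluded (attribute
#'   `"excluded"`).
#' @export
classify_positively_selected <- function(fits, alpha = 0.01) {
  stopifnot(length(fits) > 0)
  ids <- names(fits) %||% as.character(seq_along(fits))
  conv <- vapply(fits, function(f)
    f$null$converged && f$alt$converged, logical(1))
  excluded <- ids[!conv]
  fits <- fits[conv]; ids <- ids[conv]
  if (!length(fits)) {
    out <- data.frame(family = character(0))
    attr(out, "excluded") <- excluded
    return(out)
  }
  rows <- lapply(fits, function(f) {
    data.frame(lnL_bs_null = f$null$lnL, lnL_bs_alt = f$alt$lnL,
               omega2 = f$alt$w2,
               p_bs = lrt(f$null$lnL, f$alt$lnL, df = 1))
  })
  out <- do.call(rbind, rows)
  out <- cbind(family = ids, out, row.names = NULL)
  out$q_bs <- stats::p.adjust(out$p_bs, method = "BH")
  out$positively_selected <- out$q_bs < alpha & out$omega2 > 1
  attr(out, "excluded") <- excluded
  out
}

#' Combine the two screens into per-family calls
#'
#' @param fast data.frame from [classify_fast_evolving()].
#' @param possel data.frame from [classify_positively_selected()].
#' @return data.frame keyed by family with `call` in
#'   `{fast_evolving, positively_selected, both, neither}`.
#' @export
selection_calls <- function(fast, possel) {
  fam <- union(fast$family, possel$family)
  fe <- fam %in% fast$family[fast$fast_evolving]
  ps <- fam %in% possel$family[possel$positively_selected]
  call <- ifelse(fe & ps, "both",
                 ifelse(fe, "fast_evolving",
                        ifelse(ps, "positively_selected", "neither")))
  data.frame(family = fam, fast_evolving = fe, positively_selected = ps,
             call = call)
}
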