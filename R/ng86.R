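# Nei-Gojobori (1986) counting estimator of dN/dS. Kept deliberately
# independent of the likelihood machinery: it serves as the counting-based
# cross-check for the GY94 fits.

# Synonymous site count of one codon: for each position, the fraction of
# the three possible nucleotide changes that are synonymous. Changes to
# stop codons count as nonsynonymous.
.syn_sites_per_codon <- function() {
  tab <- codon_tables()
  n <- tab$n
  s <- numeric(n)
  for (i in seq_len(n)) {
    js <- which(tab$ndiff[i, ] == 1L)
    s[i] <- sum(tab$is_syn[i, js]) / 3
  }
  s
}

# Pathway-averaged synonymous/nonsynonymous difference counts between two
# sense codons. Pathways through stop codons are excluded unless every
# pathway hits a stop.
.pathway_counts <- function(ci, cj) {
  tab <- codon_tables()
  if (ci == cj) return(c(syn = 0, nonsyn = 0))
  a <- tab$split3[ci, ]; b <- tab$split3[cj, ]
  pos <- which(a != b)
  perms <- if (length(pos) == 1L) list(pos) else
    if (length(pos) == 2L) list(pos, rev(pos)) else
      lapply(list(c(1,2,3), c(1,3,2), c(2,1,3), c(2,3,1), c(3,1,2), c(3,2,1)),
             function(o) pos[o])
  paths <- list()
  for (p in perms) {
    cur <- a; sy <- 0; ns <- 0; valid <- TRUE
    for (q in p) {
      nxt <- cur; nxt[q] <- b[q]
      from <- tab$idx64[paste(cur, collapse = "")]
      to <- tab$idx64[paste(nxt, collapse = "")]
      if (is.na(to)) { valid <- FALSE; break }   # stop codon on the path
      if (tab$is_syn[from, to]) sy <- sy + 1 else ns <- ns + 1
      cur <- nxt
    }
    paths[[length(paths) + 1L]] <- list(valid = valid, syn = sy, nonsyn = ns)
  }
  ok <- Filter(function(x) x$valid, paths)
  if (!length(ok)) ok <- paths  # degenerate: average over all, truncated
  c(syn = mean(vapply(ok, `[[`, 0, "syn")),
    nonsyn = mean(vapply(ok, `[[`, 0, "nonsyn")))
}

#' Pairwise dN/dS by Nei-Gojobori (1986) counting
#'
#' Counts synonymous and nonsynonymous sites (averaged over the two
#' sequences) and pathway-averaged differences, applies the Jukes-Cantor
#' correction to both proportions, and reports `omega = dN/dS`.
#'
#' @param cds_a,cds_b equal-length, gap-free, in-frame coding sequences
#'   (strings), with no internal stop codons.
#' @return list with `S`, `N` (site counts), `Sd`, `Nd` (difference
#'   counts), `pS`, `pN`, `dS`, `dN`, `omega` (`NA` with
#'   `omega_defined = FALSE` when `dS` is 0 or saturated).
#' @export
ng86_dnds <- function(cds_a, cds_b) {
  if (nchar(cds_a) != nchar(cds_b)) stop("sequences must be equal length")
  ia <- codon_index(cds_a); ib <- codon_index(cds_b)
  if (anyNA(ia) || anyNA(ib))
    stop("sequences must be gap-free with no internal stop codons")
  ssites <- .syn_sites_per_codon()
  S <- sum((ssites[ia] + ssites[ib]) / 2)
  N <- 3 * length(ia) - S
  Sd <- 0; Nd <- 0
  for (k in which(ia != ib)) {
    cnt <- .pathway_counts(ia[k], ib[k])
    Sd <- Sd + unname(cnt["syn"]); Nd <- Nd + unname(cnt["nonsyn"])
  }
  pS <- Sd / S; pN <- Nd / N
  jc <- function(p) if (p >= 0.75) NA_real_ else -0.75 * log(1 - 4 * p / 3)
  dS <- jc(pS); dN <- jc(pN)
  defined <- !is.na(dS) && !is.na(dN) && dS > 0
  list(S = S, N = N, Sd = unname(Sd), Nd = unname(Nd), pS = pS, pN = pN,
       dS = dS, dN = dN,
       omega = if (defined) dN / dS else NA_real_,
       omega_defined = defined)
}
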