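#' @keywords internal
#' @importFrom stats setNames optimize nlminb pchisq p.adjust runif rbinom
#' @importFrom utils read.table write.table
"_PACKAGE"

# Genetic-code tables shared by the codon substitution model, the simulator,
# NG86 counting and fourfold-degenerate-site extraction. All tables are built
# once at load time from the standard code (Biostrings::GENETIC_CODE) and
# cached in an internal environment.

.codon_env <- new.env(parent = emptyenv())

.build_codon_tables <- function() {
  gc_tab <- Biostrings::GENETIC_CODE
  all64 <- names(gc_tab)
  sense <- all64[gc_tab != "*"]          # 61 sense codons, TTT..GGG order
  n <- length(sense)
  aa <- gc_tab[sense]

  # index of each sense codon; stops map to NA
  idx64 <- stats::setNames(rep(NA_integer_, 64L), all64)
  idx64[sense] <- seq_len(n)

  split3 <- do.call(rbind, strsplit(sense, ""))

  ndiff <- matrix(0L, n, n)
  diffpos <- matrix(0L, n, n)            # position of the single difference
  is_ts <- matrix(FALSE, n, n)           # transition at the single difference
  is_syn <- matrix(FALSE, n, n)
  purines <- c("A", "G")
  for (i in seq_len(n)) {
    di <- sweep(split3, 2, split3[i, ], FUN = "!=")
    nd <- rowSums(di)
    ndiff[i, ] <- as.integer(nd)
    one <- which(nd == 1L)
    for (j in one) {
      p <- which(di[j, ])
      diffpos[i, j] <- p
      a <- split3[i, p]; b <- split3[j, p]
      is_ts[i, j] <- (a %in% purines) == (b %in% purines)
      is_syn[i, j] <- aa[i] == aa[j]
    }
  }

  # fourfold-degenerate prefixes: first two bases fix the amino acid
  pre <- unique(substr(all64, 1, 2))
  four <- pre[vapply(pre, function(p) {
    cods <- paste0(p, c("T", "C", "A", "G"))
    length(unique(gc_tab[cods])) == 1L && all(gc_tab[cods] != "*")
  }, logical(1))]

  list(codons = sense, n = n, aa = aa, idx64 = idx64, split3 = split3,
       ndiff = ndiff, diffpos = diffpos, is_ts = is_ts, is_syn = is_syn,
       stop_codons = all64[gc_tab == "*"], fourfold_prefixes = four)
}

codon_tables <- function() {
  if (is.null(.codon_env$tab)) .codon_env$tab <- .build_codon_tables()
  .codon_env$tab
}

#' Convert codon strings to sense-codon indices
#'
#' @param x character vector of codons (3 letters, ACGT) or a single
#'   nucleotide string whose length is a multiple of three.
#' @return integer vector of indices into the 61 sense codons; `NA` for stop
#'   codons or codons containing non-ACGT characters (treated as missing
#'   data downstream).
#' @keywords internal
codon_index <- function(x) {
  tab <- codon_tables()
  if (length(x) == 1L && nchar(x) > 3L) {
    stopifnot(nchar(x) %% 3L == 0L)
    x <- substring(x, seq(1L, nchar(x), 3L), seq(3L, nchar(x), 3L))
  }
  out <- tab$idx64[toupper(x)]
  unname(out)
}

#' @keywords internal
index_to_codon <- function(i) codon_tables()$codons[i]

#' Split a CDS string into codons
#' @keywords internal
split_codons <- function(seq) {
  seq <- as.character(seq)
  stopifnot(nchar(seq) %% 3L == 0L)
  substring(seq, seq(1L, nchar(seq), 3L), seq(3L, nchar(seq), 3L))
}

#' Check a coding sequence for internal stop codons
#' @keywords internal
has_internal_stop <- function(seq) {
  cods <- split_codons(seq)
  any(cods[-length(cods)] %in% codon_tables()$stop_codons)
}

#' Random in-frame coding sequence
#'
#' Draws sense codons uniformly; used for family ancestors and for
#' variety-specific genes (two independent draws share so little identity
#' that they never cluster).
#'
#' @param n_codons sequence length in codons.
#' @return a single nucleotide string of length `3 * n_codons`.
#' @export
random_cds <- function(n_codons) {
  tab <- codon_tables()
  paste(sample(tab$codons, n_codons, replace = TRUE), collapse = "")
}
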