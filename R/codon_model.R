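# GY94-style codon substitution model: rate matrix construction,
# eigendecomposition-based transition probabilities, and Markov simulation
# along a tree. The matrix is reversible, so it is symmetrised with
# diag(sqrt(pi)) and decomposed with the symmetric eigensolver.

#' Build a GY94 codon rate matrix
#'
#' Constructs the 61x61 instantaneous rate matrix of the Goldman-Yang codon
#' model: single-nucleotide changes only, transitions multiplied by `kappa`,
#' nonsynonymous changes multiplied by `omega`, target-codon frequencies
#' `pi`. The matrix is scaled so that the expected number of substitutions
#' per codon site is 1 at equilibrium.
#'
#' @param kappa transition/transversion rate ratio (> 0).
#' @param omega nonsynonymous/synonymous rate ratio (>= 0).
#' @param codon_freq equilibrium frequencies over the 61 sense codons
#'   (positive, summing to 1). Default uniform.
#' @return a 61x61 rate matrix with zero row sums, attribute `"pi"`.
#' @export
build_codon_matrix <- function(kappa, omega, codon_freq = NULL) {
  tab <- codon_tables()
  n <- tab$n
  if (is.null(codon_freq)) codon_freq <- rep(1 / n, n)
  if (length(codon_freq) != n || any(codon_freq <= 0))
    stop("codon_freq must be ", n, " positive values")
  if (abs(sum(codon_freq) - 1) > 1e-8)
    stop("codon_freq must sum to 1")
  if (kappa <= 0 || omega < 0) stop("kappa > 0 and omega >= 0 required")

  Q <- matrix(0, n, n)
  single <- tab$ndiff == 1L
  Q[single] <- 1
  Q[single & tab$is_ts] <- kappa
  Q[single & !tab$is_syn] <- Q[single & !tab$is_syn] * omega
  Q <- sweep(Q, 2, codon_freq, "*")
  diag(Q) <- -rowSums(Q)
  mu <- -sum(codon_freq * diag(Q))        # expected substitutions/codon
  if (mu > 0) Q <- Q / mu
  attr(Q, "pi") <- codon_freq
  attr(Q, "mean_rate") <- mu   # pre-scaling rate; used for mixture scaling
  Q
}

# Eigendecomposition of a reversible rate matrix via symmetrisation.
# Returns components sufficient to compute P(t) = V exp(D t) Vi cheaply.
decompose_rates <- function(Q, codon_freq = attr(Q, "pi")) {
  sp <- sqrt(codon_freq)
  S <- Q * (sp %o% (1 / sp))              # diag(sp) Q diag(1/sp), symmetric
  S <- (S + t(S)) / 2                     # guard numerical asymmetry
  e <- eigen(S, symmetric = TRUE)
  list(V = e$vectors / sp, Vi = t(e$vectors * sp), values = e$values,
       mu = attr(Q, "mean_rate"))
}

# P(t) from a decomposition; clamps tiny negative entries from roundoff.
prob_matrix <- function(dec, t) {
  P <- (dec$V * rep(exp(dec$values * t), each = nrow(dec$Vi))) %*% dec$Vi
  P[P < 0] <- 0
  P
}

#' Empirical codon frequencies from an alignment
#'
#' `F3x4` multiplies per-position nucleotide frequencies (PAML CodonFreq=2);
#' `F1x4` uses overall nucleotide frequencies; `uniform` gives 1/61.
#' Stop codons are excluded and the result renormalised.
#'
#' @param codon_mat integer matrix of sense-codon indices (taxa x sites),
#'   `NA` allowed for gaps/ambiguities.
#' @param method one of `"F3x4"`, `"F1x4"`, `"uniform"`.
#' @return frequency vector over the 61 sense codons.
#' @export
empirical_codon_freq <- function(codon_mat, method = c("F3x4", "F1x4", "uniform")) {
  method <- match.arg(method)
  tab <- codon_tables()
  if (method == "uniform") return(rep(1 / tab$n, tab$n))
  idx <- codon_mat[!is.na(codon_mat)]
  bases <- c("T", "C", "A", "G")
  letters3 <- tab$split3[idx, , drop = FALSE]
  if (method == "F1x4") {
    f <- table(factor(letters3, levels = bases)) + 1  # +1 pseudocount
    f <- f / sum(f)
    freq <- f[tab$split3[, 1]] * f[tab$split3[, 2]] * f[tab$split3[, 3]]
  } else {
    fp <- lapply(1:3, function(p) {
      f <- table(factor(letters3[, p], levels = bases)) + 1
      f / sum(f)
    })
    freq <- fp[[1]][tab$split3[, 1]] * fp[[2]][tab$split3[, 2]] *
      fp[[3]][tab$split3[, 3]]
  }
  freq <- as.numeric(freq)
  freq / sum(freq)
}

# Sample child states given parent states and a transition matrix.
# States are sense-codon indices; vectorised per originating state.
sample_children <- function(parent_states, P) {
  out <- integer(length(parent_states))
  for (s in unique(parent_states)) {
    sel <- parent_states == s
    out[sel] <- sample.int(ncol(P), sum(sel), replace = TRUE, prob = P[s, ])
  }
  out
}

#' Simulate codon sequences along a tree
#'
#' Evolves an alignment of `n_codons` sites (or a given ancestor) down a
#' rooted tree under the GY94 model, with a possibly branch-specific and
#' site-class-specific omega. No indels: sequences are aligned by
#' construction. Substitutions to stop codons have rate zero by model
#' construction.
#'
#' @param tree an `ape::phylo` tree, rooted, with branch lengths in expected
#'   substitutions per codon site.
#' @param kappa transition/transversion ratio.
#' @param omega either a single value, a vector with one value per edge
#'   (in `tree$edge` order), or a matrix `n_site_classes x n_edges` combined
#'   with `class_props`.
#' @param n_codons number of codon sites (ignored when `ancestor` given).
#' @param ancestor optional ancestor CDS string (length divisible by 3,
#'   no internal stops); the root sequence.
#' @param codon_freq equilibrium codon frequencies (default uniform).
#' @param class_props site-class proportions when `omega` is a matrix.
#' @return list with `states` (integer matrix taxa x sites of codon
#'   indices, rownames = tip labels), `sequences` (named character vector of
#'   CDS strings) and `site_classes` (integer vector, when classes used).
#' @export
sim_codon_alignment <- function(tree, kappa, omega, n_codons = NULL,
                                ancestor = NULL, codon_freq = NULL,
                                class_props = NULL) {
  tab <- codon_tables()
  if (is.null(codon_freq)) codon_freq <- rep(1 / tab$n, tab$n)
  ne <- nrow(tree$edge)
  if (is.matrix(omega)) {
    stopifnot(ncol(omega) == ne, !is.null(class_props),
              abs(sum(class_props) - 1) < 1e-8)
    W <- omega
  } else {
    if (length(omega) == 1L) omega <- rep(omega, ne)
    stopifnot(length(omega) == ne)
    W <- matrix(omega, nrow = 1)
    class_props <- 1
  }

  if (!is.null(ancestor)) {
    root_states <- codon_index(ancestor)
    if (anyNA(root_states)) stop("ancestor contains stop or invalid codons")
    n_codons <- length(root_states)
  } else {
    stopifnot(!is.null(n_codons))
    root_states <- sample.int(tab$n, n_codons, replace = TRUE,
                              prob = codon_freq)
  }
  site_cls <- sample.int(nrow(W), n_codons, replace = TRUE,
                         prob = class_props)

  # cache decompositions per distinct omega value
  decs <- new.env(parent = emptyenv())
  get_dec <- function(w) {
    key <- paste0("w", w)
    if (is.null(decs[[key]]))
      decs[[key]] <- decompose_rates(build_codon_matrix(kappa, w, codon_freq))
    decs[[key]]
  }

  # mixture scaling: common per-edge normalisation over site classes
  # (matches the likelihood convention; see pruning_lnL)
  n_cls <- nrow(W)
  rate_mult <- matrix(1, n_cls, ne)
  if (n_cls > 1) {
    MU <- matrix(vapply(as.numeric(W), function(w) get_dec(w)$mu,
                        numeric(1)), n_cls, ne)
    mu_avg <- as.numeric(class_props %*% MU)
    rate_mult <- sweep(MU, 2, mu_avg, "/")
  }

  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  states <- matrix(NA_integer_, nnode, n_codons)
  root <- ntip + 1L
  states[root, ] <- root_states
  # preorder edge traversal
  ord <- ape::reorder.phylo(tree, "postorder")$edge
  pre <- nrow(ord):1
  for (k in pre) {
    par <- ord[k, 1]; chd <- ord[k, 2]
    eidx <- which(tree$edge[, 1] == par & tree$edge[, 2] == chd)
    t_len <- tree$edge.length[eidx]
    child <- integer(n_codons)
    for (cls in unique(site_cls)) {
      sel <- site_cls == cls
      if (t_len <= 0) {
        child[sel] <- states[par, sel]
      } else {
        P <- prob_matrix(get_dec(W[cls, eidx]),
                         t_len * rate_mult[cls, eidx])
        child[sel] <- sample_children(states[par, sel], P)
      }
    }
    states[chd, ] <- child
  }
  tip_states <- states[seq_len(ntip), , drop = FALSE]
  rownames(tip_states) <- tree$tip.label
  seqs <- apply(tip_states, 1, function(s)
    paste(index_to_codon(s), collapse = ""))
  list(states = tip_states, sequences = seqs,
       site_classes = if (nrow(W) > 1) site_cls else NULL)
}
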