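# Felsenstein pruning over the 61 sense-codon states, with site-pattern
# compression, per-pattern log-space rescaling, and site-class mixtures
# (used by both branch and branch-site models). Gap/ambiguous codons are
# treated as missing data: their conditional likelihood vector is all ones.

#' Compress an alignment into site patterns
#'
#' @param codon_mat integer matrix (taxa x sites) of sense-codon indices,
#'   `NA` = missing.
#' @return list `patterns` (taxa x npat), `weights` (pattern multiplicities).
#' @keywords internal
compress_patterns <- function(codon_mat) {
  key <- apply(codon_mat, 2, paste, collapse = ",")
  u <- !duplicated(key)
  list(patterns = codon_mat[, u, drop = FALSE],
       weights = as.numeric(table(key)[key[u]]))
}

# Postorder edge structure for a rooted phylo tree.
tree_postorder <- function(tree) {
  po <- ape::reorder.phylo(tree, "postorder")
  # map postorder rows back to original edge indices
  eidx <- match(paste(po$edge[, 1], po$edge[, 2]),
                paste(tree$edge[, 1], tree$edge[, 2]))
  list(edge = po$edge, edge_length = tree$edge.length[eidx],
       orig_index = eidx, root = length(tree$tip.label) + 1L,
       ntip = length(tree$tip.label), nnode = tree$Nnode)
}

#' Codon-model log-likelihood by pruning
#'
#' Computes the log-likelihood of a codon alignment on a rooted tree under a
#' GY94 model in which omega may vary across branches and across site
#' classes (a mixture). For each site class `c` the omega on edge `e` is
#' `omega_mat[c, e]`; site likelihoods are `sum_c prop[c] * L_c(site)`.
#'
#' @param codon_mat integer matrix taxa x sites of sense-codon indices
#'   (`NA` = missing); rownames must match tip labels.
#' @param tree rooted `ape::phylo` with branch lengths
#'   (substitutions/codon).
#' @param kappa transition/transversion ratio.
#' @param omega_mat numeric matrix `n_classes x n_edges` (or a single value
#'   / per-edge vector for one class).
#' @param class_props site-class proportions (default a single class).
#' @param codon_freq equilibrium codon frequencies (default uniform).
#' @param patterns optional precompressed pattern list (from
#'   [compress_patterns()]) to avoid recompression across optimizer calls.
#' @param dec_cache optional environment caching rate-matrix
#'   eigendecompositions across calls (keyed by kappa/omega); used by the
#'   optimizer so that branch-length moves do not redo the decomposition.
#' @return the total log-likelihood (numeric scalar).
#' @export
pruning_lnL <- function(codon_mat, tree, kappa, omega_mat,
                        class_props = NULL, codon_freq = NULL,
                        patterns = NULL, dec_cache = NULL) {
  tab <- codon_tables()
  ns <- tab$n
  if (is.null(codon_freq)) codon_freq <- rep(1 / ns, ns)
  ne <- nrow(tree$edge)
  if (!is.matrix(omega_mat)) {
    if (length(omega_mat) == 1L) omega_mat <- rep(omega_mat, ne)
    omega_mat <- matrix(omega_mat, nrow = 1)
  }
  stopifnot(ncol(omega_mat) == ne)
  if (is.null(class_props)) class_props <- rep(1 / nrow(omega_mat),
                                               nrow(omega_mat))
  stopifnot(length(class_props) == nrow(omega_mat))

  if (is.null(patterns)) patterns <- compress_patterns(codon_mat)
  pat <- patterns$patterns
  wts <- patterns$weights
  if (!is.null(tree$tip.label) && !is.null(rownames(pat)))
    pat <- pat[tree$tip.label, , drop = FALSE]
  npat <- ncol(pat)

  po <- tree_postorder(tree)
  ntip <- po$ntip

  if (is.null(dec_cache)) dec_cache <- new.env(parent = emptyenv())
  get_dec <- function(w) {
    key <- paste0("k", kappa, "w", w)
    if (is.null(dec_cache[[key]])) {
      if (length(ls(dec_cache)) > 256L)  # bound the cache
        rm(list = ls(dec_cache), envir = dec_cache)
      dec_cache[[key]] <-
        decompose_rates(build_codon_matrix(kappa, w, codon_freq))
    }
    dec_cache[[key]]
  }

  # mixture scaling: one common normalisation per edge so that branch
  # lengths are expected substitutions per codon AVERAGED over site
  # classes; classes with higher omega then run proportionally faster
  # (the standard convention for site-class codon models)
  n_cls <- length(class_props)
  rate_mult <- matrix(1, n_cls, ne)
  if (n_cls > 1) {
    MU <- matrix(vapply(as.numeric(omega_mat), function(w) get_dec(w)$mu,
                        numeric(1)), n_cls, ne)
    mu_avg <- as.numeric(class_props %*% MU)
    rate_mult <- sweep(MU, 2, mu_avg, "/")
  }

  class_loglik <- matrix(0, n_cls, npat)
  for (cls in seq_along(class_props)) {
    Lnode <- vector("list", ntip + po$nnode)
    scaler <- rep(0, npat)
    for (k in seq_len(nrow(po$edge))) {
      par <- po$edge[k, 1]; chd <- po$edge[k, 2]
      oi <- po$orig_index[k]
      w <- omega_mat[cls, oi]
      P <- prob_matrix(get_dec(w),
                       max(po$edge_length[k], 0) * rate_mult[cls, oi])
      if (chd <= ntip) {
        # tip edge: the child's partials are an indicator, so the
        # contribution is a column selection from P
        obs <- pat[chd, ]
        contrib <- matrix(1, ns, npat)
        seen <- !is.na(obs)
        contrib[, seen] <- P[, obs[seen]]
      } else {
        contrib <- P %*% Lnode[[chd]]
        Lnode[[chd]] <- NA  # free memory
      }
      if (is.null(Lnode[[par]])) Lnode[[par]] <- contrib
      else Lnode[[par]] <- Lnode[[par]] * contrib
    }
    root_part <- Lnode[[po$root]]
    # rescue underflow if present (rare on small trees)
    mn <- min(root_part)
    if (mn < 1e-250) {
      m <- apply(root_part, 2, max)
      pos <- m > 0
      root_part[, pos] <- sweep(root_part[, pos, drop = FALSE], 2,
                                m[pos], "/")
      scaler[pos] <- scaler[pos] + log(m[pos])
    }
    site_lik <- as.numeric(codon_freq %*% root_part)
    class_loglik[cls, ] <- log(pmax(site_lik, 1e-320)) + scaler
  }

  if (length(class_props) == 1L) {
    site_ll <- class_loglik[1, ]
  } else {
    M <- apply(class_loglik, 2, max)
    site_ll <- M + log(colSums(exp(sweep(class_loglik, 2, M)) * class_props))
  }
  sum(site_ll * wts)
}

#' Parse a Newick string with branch tags
#'
#' Reads a Newick tree in which tips or internal nodes may carry PAML-style
#' `#k` foreground tags (e.g. `((A,B)#1,C);`). Tags are stripped from the
#' labels and returned as an edge attribute: the tag on a node marks the
#' edge leading to that node.
#'
#' @param text Newick string.
#' @return an `ape::phylo` tree with an integer vector attribute
#'   `"edge_tag"` (0 = untagged background, k = tag `#k`), aligned with
#'   `tree$edge` rows.
#' @export
read_tagged_tree <- function(text) {
  tree <- ape::read.tree(text = gsub("\\s+", "", text))
  strip <- function(lab) {
    tag <- rep(0L, length(lab))
    hit <- grepl("#\\d+$", lab)
    tag[hit] <- as.integer(sub(".*#(\\d+)$", "\\1", lab[hit]))
    list(lab = sub("#\\d+$", "", lab), tag = tag)
  }
  tt <- strip(tree$tip.label)
  tree$tip.label <- tt$lab
  node_tag <- integer(tree$Nnode)
  if (!is.null(tree$node.label)) {
    nt <- strip(tree$node.label)
    tree$node.label <- nt$lab
    node_tag <- nt$tag
  }
  ntip <- length(tree$tip.label)
  all_tags <- c(tt$tag, node_tag)
  edge_tag <- all_tags[tree$edge[, 2]]
  attr(tree, "edge_tag") <- edge_tag
  tree
}

#' Edge indices of the foreground branches
#'
#' @param tree tree from [read_tagged_tree()] (or any `phylo` carrying an
#'   `edge_tag` attribute).
#' @param tag which tag class counts as foreground (default 1).
#' @return integer vector of rows of `tree$edge`.
#' @export
foreground_edges <- function(tree, tag = 1L) {
  et <- attr(tree, "edge_tag")
  if (is.null(et)) stop("tree carries no edge tags; use read_tagged_tree()")
  which(et == tag)
}
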