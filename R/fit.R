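# Maximum-likelihood fitting of GY94 codon models: M0 (one omega),
# two-ratio branch model (foreground vs background), free-ratio branch
# model (one omega per branch), and branch-site Model A (null with the
# selected-class omega fixed at 1, and the alternative with it free).
# Optimisation is bounded quasi-Newton (nlminb) over kappa, omegas,
# mixture proportions and all branch lengths.

.om_lo <- 1e-4; .om_hi <- 99
.len_lo <- 1e-6; .len_hi <- 9
.kap_lo <- 0.05; .kap_hi <- 100

# Unroot a binary-rooted tree while preserving edge tags. Tags are matched
# by the tip set below the tagged edge's child (or its complement when the
# edge orientation flips at the old root).
unroot_tagged <- function(tree) {
  et <- attr(tree, "edge_tag")
  if (!ape::is.rooted(tree)) return(tree)
  ntip <- length(tree$tip.label)
  clades <- function(tr) {
    po <- ape::reorder.phylo(tr, "postorder")
    sets <- vector("list", length(tr$tip.label) + tr$Nnode)
    for (i in seq_along(tr$tip.label)) sets[[i]] <- tr$tip.label[i]
    for (k in seq_len(nrow(po$edge))) {
      par <- po$edge[k, 1]; chd <- po$edge[k, 2]
      sets[[par]] <- c(sets[[par]], sets[[chd]])
    }
    sets
  }
  tagged <- list()
  if (!is.null(et) && any(et > 0)) {
    s <- clades(tree)
    for (k in which(et > 0))
      tagged[[length(tagged) + 1L]] <-
        list(set = sort(s[[tree$edge[k, 2]]]), tag = et[k])
  }
  ut <- ape::unroot(tree)
  new_et <- integer(nrow(ut$edge))
  if (length(tagged)) {
    s <- clades(ut)
    all_tips <- sort(ut$tip.label)
    for (k in seq_len(nrow(ut$edge))) {
      below <- sort(s[[ut$edge[k, 2]]])
      comp <- setdiff(all_tips, below)
      for (tg in tagged)
        if (identical(below, tg$set) || identical(comp, tg$set))
          new_et[k] <- tg$tag
    }
  }
  attr(ut, "edge_tag") <- new_et
  ut
}

# Model A site-class structure: returns omega matrix (classes x edges) and
# class proportions, given p0, p1, w0, w2 and foreground edge indices.
modelA_classes <- function(p0, p1, w0, w2, ne, fg) {
  p2 <- max(1 - p0 - p1, 0)
  props <- c(p0, p1, p2 * p0 / (p0 + p1), p2 * p1 / (p0 + p1))
  W <- matrix(0, 4, ne)
  W[1, ] <- w0; W[2, ] <- 1
  W[3, ] <- w0; W[4, ] <- 1
  W[3, fg] <- w2; W[4, fg] <- w2
  list(W = W, props = props)
}

#' Fit a codon model by maximum likelihood
#'
#' Fits one of five GY94 model variants to a codon alignment on a fixed
#' topology, re-estimating all branch lengths, `kappa` and the model's
#' omega parameters. Initialisation follows common practice for these
#' models: `kappa = 2.5`, `omega = 0.2`, and for the branch-site
#' alternative the selected-class omega starts at 1.5.
#'
#' @param codon_mat integer codon-index matrix (taxa x sites, rownames =
#'   taxa) as produced by [cds_to_codon_matrix()] or
#'   [sim_codon_alignment()]`$states`.
#' @param tree `ape::phylo`; for branch and branch-site models the
#'   foreground must be tagged (see [read_tagged_tree()]). Rooted trees are
#'   unrooted internally (the model is reversible).
#' @param model one of `"M0"`, `"branch_2ratio"`, `"branch_free"`,
#'   `"branchsite_null"`, `"branchsite_alt"`.
#' @param codon_freq `"F3x4"`, `"F1x4"`, `"uniform"`, or a numeric
#'   61-vector.
#' @param init optional list of starting values: `kappa`, `omega`
#'   (scalar or per-edge), `edge_length`, `p0`, `p1`, `w0`, `w2`.
#' @param control passed to [stats::optim()] (`method = "L-BFGS-B"`).
#' @return an object of class `"codon_fit"`: list with `model`, `lnL`,
#'   `kappa`, `omega` (named per role), `codon_freq`, `tree` (fitted branch
#'   lengths), `converged`, `n_params`, and for branch-site models `p0`,
#'   `p1`, `w0`, `w2`.
#' @export
fit_model <- function(codon_mat, tree, model = c("M0", "branch_2ratio",
                                                 "branch_free",
                                                 "branchsite_null",
                                                 "branchsite_alt"),
                      codon_freq = "F3x4", init = list(),
                      control = list(factr = 1e8, maxit = 500)) {
  model <- match.arg(model)
  tree <- unroot_tagged(tree)
  ne <- nrow(tree$edge)
  if (is.character(codon_freq))
    codon_freq <- empirical_codon_freq(codon_mat, codon_freq)
  pats <- compress_patterns(codon_mat)

  fg <- integer(0)
  if (model %in% c("branch_2ratio", "branchsite_null", "branchsite_alt")) {
    fg <- foreground_edges(tree)
    if (!length(fg)) stop("model '", model, "' needs a tagged foreground branch")
  }

  len0 <- init$edge_length %||%
    (if (!is.null(tree$edge.length)) pmax(tree$edge.length, .len_lo)
     else rep(0.1, ne))
  kap0 <- init$kappa %||% 2.5
  om0 <- init$omega %||% 0.2

  lens_idx <- seq_len(ne)
  if (model == "M0") {
    theta0 <- c(kap0, om0[1], len0)
    lower <- c(.kap_lo, .om_lo, rep(.len_lo, ne))
    upper <- c(.kap_hi, .om_hi, rep(.len_hi, ne))
    make_W <- function(th) list(W = matrix(th[2], 1, ne), props = 1)
    n_free <- 2 + ne
  } else if (model == "branch_2ratio") {
    om0 <- rep(om0, length.out = 2)
    theta0 <- c(kap0, om0[1], om0[2], len0)
    lower <- c(.kap_lo, .om_lo, .om_lo, rep(.len_lo, ne))
    upper <- c(.kap_hi, .om_hi, .om_hi, rep(.len_hi, ne))
    make_W <- function(th) {
      w <- rep(th[3], ne); w[fg] <- th[2]
      list(W = matrix(w, 1, ne), props = 1)
    }
    n_free <- 3 + ne
  } else if (model == "branch_free") {
    om0 <- rep(om0, length.out = ne)
    theta0 <- c(kap0, om0, len0)
    lower <- c(.kap_lo, rep(.om_lo, ne), rep(.len_lo, ne))
    upper <- c(.kap_hi, rep(.om_hi, ne), rep(.len_hi, ne))
    make_W <- function(th) list(W = matrix(th[1 + seq_len(ne)], 1, ne),
                                props = 1)
    n_free <- 1 + 2 * ne
  } else { # branch-site Model A
    p00 <- init$p0 %||% 0.7; p10 <- init$p1 %||% 0.2
    w00 <- init$w0 %||% 0.2
    w20 <- init$w2 %||% 1.5
    fixed_w2 <- model == "branchsite_null"
    # proportions via softmax over (a, b, 0)
    a0 <- log(p00 / max(1 - p00 - p10, 1e-3))
    b0 <- log(p10 / max(1 - p00 - p10, 1e-3))
    theta0 <- c(kap0, a0, b0, w00, if (!fixed_w2) w20, len0)
    lower <- c(.kap_lo, -12, -12, .om_lo, if (!fixed_w2) 1, rep(.len_lo, ne))
    upper <- c(.kap_hi, 12, 12, 1, if (!fixed_w2) .om_hi, rep(.len_hi, ne))
    nfix <- if (fixed_w2) 4L else 5L
    lens_idx <- seq_len(ne)
    make_W <- function(th) {
      z <- exp(c(th[2], th[3], 0)); z <- z / sum(z)
      w2 <- if (fixed_w2) 1 else th[5]
      modelA_classes(z[1], z[2], th[4], w2, ne, fg)
    }
    n_free <- nfix + ne
    attr(make_W, "nfix") <- nfix
  }
  nfix <- n_free - ne

  dec_cache <- new.env(parent = emptyenv())
  negll <- function(th) {
    tr <- tree
    tr$edge.length <- th[nfix + lens_idx]
    mw <- make_W(th)
    ll <- tryCatch(
      pruning_lnL(codon_mat, tr, kappa = th[1], omega_mat = mw$W,
                  class_props = mw$props, codon_freq = codon_freq,
                  patterns = pats, dec_cache = dec_cache),
      error = function(e) -Inf)
    if (!is.finite(ll)) return(1e10)
    -ll
  }

  opt <- stats::optim(theta0, negll, method = "L-BFGS-B",
                      lower = lower, upper = upper, control = control)
  th <- opt$par
  tree$edge.length <- th[nfix + lens_idx]
  mw <- make_W(th)

  omega <- switch(model,
    M0 = c(omega = th[2]),
    branch_2ratio = c(foreground = th[2], background = th[3]),
    branch_free = stats::setNames(th[1 + seq_len(ne)],
                                  paste0("edge", seq_len(ne))),
    {
      z <- exp(c(th[2], th[3], 0)); z <- z / sum(z)
      c(w0 = th[4], w1 = 1,
        w2 = if (model == "branchsite_null") 1 else th[5])
    })

  res <- list(model = model, lnL = -opt$value, kappa = th[1],
              omega = omega, codon_freq = codon_freq, tree = tree,
              converged = opt$convergence == 0, n_params = n_free,
              message = opt$message, foreground_edges = fg)
  if (startsWith(model, "branchsite")) {
    z <- exp(c(th[2], th[3], 0)); z <- z / sum(z)
    res$p0 <- z[1]; res$p1 <- z[2]; res$w0 <- th[4]
    res$w2 <- if (model == "branchsite_null") 1 else th[5]
    res$class_props <- mw$props
  }
  class(res) <- "codon_fit"
  res
}

#' @exportS3Method base::print
print.codon_fit <- function(x, ...) {
  cat("GY94 codon model fit [", x$model, "]\n", sep = "")
  cat("  lnL =", format(x$lnL, digits = 10),
      " kappa =", round(x$kappa, 3), "\n")
  cat("  omega:", paste(names(x$omega), round(x$omega, 4),
                        sep = "=", collapse = "  "), "\n")
  cat("  converged:", x$converged, " (", x$n_params, "free parameters )\n")
  invisible(x)
}

#' Fit the branch-model hypothesis ladder H0/H1/H2
#'
#' Fits M0 (H0: one omega on every branch), the two-ratio model (H1:
#' foreground branch has its own omega) and, optionally, the free-ratio
#' model (H2: every branch has its own omega) to one family, warm-starting
#' each model from the previous fit.
#'
#' @inheritParams fit_model
#' @param fit_H2 fit the free-ratio model too (needed for the
#'   fast-evolving screen).
#' @return list with elements `H0`, `H1`, and optionally `H2`
#'   (`codon_fit` objects).
#' @export
fit_branch_models <- function(codon_mat, tree, codon_freq = "F3x4",
                              init = list(), fit_H2 = TRUE) {
  h0 <- fit_model(codon_mat, tree, "M0", codon_freq, init)
  i1 <- list(kappa = h0$kappa, omega = rep(h0$omega[[1]], 2),
             edge_length = h0$tree$edge.length)
  h1 <- fit_model(codon_mat, tree, "branch_2ratio", codon_freq, i1)
  out <- list(H0 = h0, H1 = h1)
  if (fit_H2) {
    ne <- nrow(h1$tree$edge)
    om <- rep(h1$omega[["background"]], ne)
    om[h1$foreground_edges] <- h1$omega[["foreground"]]
    i2 <- list(kappa = h1$kappa, omega = om,
               edge_length = h1$tree$edge.length)
    out$H2 <- fit_model(codon_mat, tree, "branch_free", codon_freq, i2)
  }
  out
}

#' Fit the branch-site null and alternative models
#'
#' Model A on a tagged foreground branch: the null fixes the selected-class
#' omega at 1; the alternative frees it (initialised at 1.5). The
#' alternative is warm-started from the null fit.
#'
#' @inheritParams fit_model
#' @param w2_starts initial values tried for the selected-class omega of
#'   the alternative model; the surface is multimodal (the selected-class
#'   proportion and omega2 trade off), so several starts are fitted and
#'   the best kept. The first start reuses the null's mixture weights;
#'   later ones shrink the selected class.
#' @return list with `null` and `alt` (`codon_fit` objects).
#' @export
fit_branchsite_models <- function(codon_mat, tree, codon_freq = "F3x4",
                                  init = list(),
                                  w2_starts = c(1.5, 4, 8)) {
  h0 <- fit_model(codon_mat, tree, "branchsite_null", codon_freq, init)
  starts <- lapply(seq_along(w2_starts), function(i) {
    if (i == 1)
      list(kappa = h0$kappa, p0 = h0$p0, p1 = h0$p1, w0 = h0$w0,
           w2 = w2_starts[1], edge_length = h0$tree$edge.length)
    else
      list(kappa = h0$kappa, p0 = 0.75, p1 = 0.05, w0 = h0$w0,
           w2 = w2_starts[i], edge_length = h0$tree$edge.length)
  })
  h1 <- NULL
  for (st in starts) {
    cand <- fit_model(codon_mat, tree, "branchsite_alt", codon_freq, st)
    if (is.null(h1) || cand$lnL > h1$lnL) h1 <- cand
  }
  if (h1$lnL < h0$lnL) {  # numerical: the MLE sits on the w2 = 1 boundary
    h1$lnL <- h0$lnL
    h1$w2 <- 1
    h1$omega["w2"] <- 1
  }
  list(null = h0, alt = h1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Codon-index matrix from CDS strings
#'
#' @param cds named character vector (or `Biostrings::DNAStringSet`) of
#'   equal-length, in-frame coding sequences; `-`/`N` codons become `NA`
#'   (missing data).
#' @return integer matrix taxa x codon-sites.
#' @export
cds_to_codon_matrix <- function(cds) {
  if (methods::is(cds, "DNAStringSet")) cds <- as.character(cds)
  lens <- nchar(cds)
  if (length(unique(lens)) != 1L) stop("sequences must be aligned (equal length)")
  mat <- do.call(rbind, lapply(cds, function(s) codon_index(s)))
  rownames(mat) <- names(cds)
  mat
}
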