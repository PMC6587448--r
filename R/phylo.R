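# Single-copy-family phylogenetics: codon-aware family alignment,
# column filtering, GTR distances, neighbor-joining, fourfold-degenerate
# site extraction, and strict-clock least-squares dating with calibration
# intervals.

#' Codon-aware alignment of one gene family
#'
#' Center-star progressive alignment: each protein is globally aligned
#' (Needleman-Wunsch, BLOSUM62, affine gaps) to the longest sequence and
#' the pairwise gap patterns are merged into one multiple alignment,
#' which is back-translated to codons (gaps in whole-codon units).
#'
#' @param cds_by_taxon named character vector of in-frame CDS.
#' @return named character vector of aligned CDS (equal lengths); errors
#'   when a sequence has an internal stop codon.
#' @export
align_family <- function(cds_by_taxon) {
  stopifnot(length(cds_by_taxon) >= 2)
  bad <- vapply(cds_by_taxon, has_internal_stop, logical(1))
  if (any(bad))
    stop("internal stop codon in: ", paste(names(bad)[bad], collapse = ", "))
  if (length(unique(nchar(cds_by_taxon))) == 1L) {
    # equal-length in-frame input is treated as already codon-aligned
    # (the simulator's families are gap-free and aligned by construction)
    return(cds_by_taxon)
  }
  prots <- vapply(cds_by_taxon, function(s) {
    p <- as.character(Biostrings::translate(Biostrings::DNAString(s)))
    sub("\\*$", "", p)
  }, character(1))
  center <- names(prots)[which.max(nchar(prots))]
  others <- setdiff(names(prots), center)

  # per-sequence alignment to the center; record insertion columns
  aligned_pairs <- lapply(others, function(nm) {
    aln <- Biostrings::pairwiseAlignment(
      prots[[nm]], prots[[center]], type = "global",
      substitutionMatrix = "BLOSUM62", gapOpening = 11, gapExtension = 1)
    list(q = strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]],
         s = strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]])
  })
  names(aligned_pairs) <- others

  # merge: count max insertions after each center position
  clen <- nchar(prots[[center]])
  ins_after <- rep(0L, clen + 1L)   # index 1 = before first residue
  for (ap in aligned_pairs) {
    pos <- 0L; run <- 0L
    ins <- rep(0L, clen + 1L)
    for (k in seq_along(ap$s)) {
      if (ap$s[k] == "-") run <- run + 1L
      else { ins[pos + 1L] <- run; run <- 0L; pos <- pos + 1L }
    }
    ins[pos + 1L] <- max(ins[pos + 1L], run)
    ins_after <- pmax(ins_after, ins)
  }

  # expand each row into the merged coordinate system (protein level)
  expand <- function(qchars, schars) {
    outc <- character(0)
    pos <- 0L; buf <- character(0)
    flush <- function(buf, slot) c(buf, rep("-", ins_after[slot] - length(buf)))
    for (k in seq_along(schars)) {
      if (schars[k] == "-") buf <- c(buf, qchars[k])
      else {
        outc <- c(outc, flush(buf, pos + 1L), qchars[k])
        buf <- character(0); pos <- pos + 1L
      }
    }
    c(outc, flush(buf, pos + 1L))
  }
  rows <- list()
  cc <- strsplit(prots[[center]], "")[[1]]
  rows[[center]] <- expand(cc, cc)
  for (nm in others)
    rows[[nm]] <- expand(aligned_pairs[[nm]]$q, aligned_pairs[[nm]]$s)

  # back-translate to codons
  out <- vapply(names(cds_by_taxon), function(nm) {
    chars <- rows[[nm]]
    cods <- split_codons(substr(cds_by_taxon[[nm]], 1,
                                3 * sum(chars != "-")))
    ci <- 0L
    paste(vapply(chars, function(ch) {
      if (ch == "-") "---" else { ci <<- ci + 1L; cods[ci] }
    }, character(1)), collapse = "")
  }, character(1))
  out
}

#' Filter alignment columns by gap and conservation rules
#'
#' Drops columns with gap fraction above `max_gap_fraction` (default:
#' any gap) and columns whose majority character frequency (among
#' non-gaps) is below `min_conservation`.
#'
#' @param mat character matrix (taxa x columns) or named equal-length
#'   string vector.
#' @param max_gap_fraction maximum tolerated gap fraction per column.
#' @param min_conservation minimum majority-character frequency.
#' @return list `matrix` (filtered, same input form), `kept` (original
#'   column indices).
#' @export
filter_columns <- function(mat, max_gap_fraction = 0,
                           min_conservation = 0.5) {
  strings <- is.character(mat) && !is.matrix(mat)
  if (strings) {
    m <- do.call(rbind, strsplit(mat, ""))
    rownames(m) <- names(mat)
  } else m <- mat
  stopifnot(ncol(m) > 0)
  gapfrac <- colMeans(m == "-" | m == "N" | m == "?")
  cons <- apply(m, 2, function(col) {
    col <- col[!(col %in% c("-", "N", "?"))]
    if (!length(col)) return(0)
    max(table(col)) / length(col)
  })
  keep <- which(gapfrac <= max_gap_fraction & cons >= min_conservation)
  if (!length(keep)) stop("all columns removed by filtering")
  mf <- m[, keep, drop = FALSE]
  out <- if (strings) apply(mf, 1, paste, collapse = "") else mf
  list(matrix = out, kept = keep)
}

# symmetrized divergence matrix of one sequence pair
.pair_divergence <- function(x, y) {
  bases <- c("A", "C", "G", "T")
  ok <- x %in% bases & y %in% bases
  F <- unclass(table(factor(x[ok], levels = bases),
                     factor(y[ok], levels = bases)))
  storage.mode(F) <- "double"
  (F + t(F)) / (2 * sum(F))
}

#' Pairwise GTR distances
#'
#' General time-reversible distances via the closed-form estimator
#' `d = -tr(Pi log(Pi^{-1} F))` on the symmetrized divergence matrix
#' (the maximum-likelihood distance under GTR when base frequencies are
#' taken from the data). Pairs for which the matrix logarithm is
#' undefined (saturation) fall back to the Tamura-Nei distance, or to
#' `cap` when that is undefined too.
#'
#' @param seqs named character vector of aligned nucleotide sequences
#'   (or a character matrix taxa x sites).
#' @param cap distance assigned to saturated pairs (default 5).
#' @return symmetric distance matrix with zero diagonal.
#' @export
gtr_distances <- function(seqs, cap = 5) {
  if (is.matrix(seqs)) {
    m <- seqs
  } else {
    m <- do.call(rbind, strsplit(seqs, ""))
    rownames(m) <- names(seqs)
  }
  n <- nrow(m)
  stopifnot(n >= 2)
  D <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    F <- .pair_divergence(m[i, ], m[j, ])
    pi_f <- rowSums(F)
    d <- NA_real_
    if (all(pi_f > 0)) {
      A <- solve(diag(pi_f), F)
      ev <- eigen(A)
      if (all(Mod(ev$values) > 0) && all(abs(Im(ev$values)) < 1e-8) &&
          all(Re(ev$values) > 0)) {
        logA <- ev$vectors %*% diag(log(Re(ev$values))) %*%
          solve(ev$vectors)
        d <- -sum(diag(diag(pi_f) %*% logA))
        d <- Re(d)
      }
    }
    if (!is.finite(d) || d < 0) {
      # Tamura-Nei fallback
      db <- ape::dist.dna(ape::as.DNAbin(tolower(m[c(i, j), ])),
                          model = "TN93", pairwise.deletion = TRUE)
      d <- as.numeric(db)
      if (!is.finite(d)) d <- cap
    }
    D[i, j] <- D[j, i] <- min(d, cap)
  }
  D
}

#' Neighbor-joining tree, optionally rooted on an outgroup
#'
#' Standard NJ (via ape) with negative branch lengths clamped to zero
#' and the deficit moved to the sibling edge. When an outgroup is
#' given, the tree is rooted on the outgroup's stem edge and the root
#' is placed along that edge at the point balancing the mean
#' root-to-tip depth of the two sides (distance data cannot locate the
#' root within the stem; the balanced point is the natural choice for
#' downstream clock dating).
#'
#' @param D symmetric distance matrix.
#' @param outgroup optional tip label (or vector of labels whose clade)
#'   to root on.
#' @return `ape::phylo` tree.
#' @export
nj_tree <- function(D, outgroup = NULL) {
  if (max(abs(D - t(D))) > 1e-8) stop("distance matrix must be symmetric")
  tr <- ape::nj(as.dist(D))
  # clamp negatives, compensating on the sibling edge
  neg <- which(tr$edge.length < 0)
  for (k in neg) {
    deficit <- tr$edge.length[k]
    tr$edge.length[k] <- 0
    par <- tr$edge[k, 1]
    sib <- which(tr$edge[, 1] == par & seq_len(nrow(tr$edge)) != k)
    if (length(sib)) {
      s <- sib[1]
      tr$edge.length[s] <- max(tr$edge.length[s] + deficit, 0)
    }
  }
  if (!is.null(outgroup)) {
    tr <- ape::root(tr, outgroup = outgroup, resolve.root = TRUE)
    # rebalance the two root edges: keep their sum, split so the mean
    # root-to-tip depths of the two sides match as closely as possible
    root <- length(tr$tip.label) + 1L
    ke <- which(tr$edge[, 1] == root)
    if (length(ke) == 2) {
      depth_below <- function(node) {
        if (node <= length(tr$tip.label)) return(0)
        tips <- ape::extract.clade(tr, node)$tip.label
        sub <- ape::keep.tip(tr, tips)
        mean(ape::node.depth.edgelength(sub)[seq_along(tips)])
      }
      dA <- depth_below(tr$edge[ke[1], 2])
      dB <- depth_below(tr$edge[ke[2], 2])
      L <- sum(tr$edge.length[ke])
      xA <- min(max((L + dB - dA) / 2, 0), L)
      tr$edge.length[ke[1]] <- xA
      tr$edge.length[ke[2]] <- L - xA
    }
  }
  tr
}

#' Extract fourfold-degenerate third positions
#'
#' Returns third-codon-position columns at codon sites where every taxon
#' has identical first two positions and those two positions define a
#' fourfold-degenerate codon family in the standard genetic code.
#'
#' @param aligned_cds named character vector of aligned CDS (equal
#'   length, multiples of 3; gap codons disqualify a site).
#' @return character matrix (taxa x extracted sites); attribute
#'   `"codon_sites"` gives the source codon indices.
#' @export
fourfold_sites <- function(aligned_cds) {
  tab <- codon_tables()
  m <- do.call(rbind, strsplit(aligned_cds, ""))
  rownames(m) <- names(aligned_cds)
  nc <- ncol(m) %/% 3L
  m1 <- m[, 3 * seq_len(nc) - 2, drop = FALSE]
  m2 <- m[, 3 * seq_len(nc) - 1, drop = FALSE]
  m3 <- m[, 3 * seq_len(nc), drop = FALSE]
  no_gap <- colSums(m1 == "-" | m2 == "-" | m3 == "-") == 0
  uni1 <- colSums(m1 != m1[rep(1, nrow(m1)), , drop = FALSE]) == 0
  uni2 <- colSums(m2 != m2[rep(1, nrow(m2)), , drop = FALSE]) == 0
  prefix <- paste0(m1[1, ], m2[1, ])
  keep <- which(no_gap & uni1 & uni2 & prefix %in% tab$fourfold_prefixes)
  out <- m3[, keep, drop = FALSE]
  attr(out, "codon_sites") <- keep
  out
}

#' Strict-clock dating by constrained least squares
#'
#' Given a rooted tree with branch lengths (substitutions/site) and hard
#' calibration intervals on internal nodes, estimates node ages and a
#' single substitution rate minimizing the squared difference between
#' expected (`rate * (age_root - age_node)`) and observed root-to-node
#' path lengths, subject to parent-older-than-child ordering and the
#' calibration boxes. Solved by coordinate descent on ages nested in a
#' golden-section search over the rate; deterministic.
#'
#' @param tree rooted binary `ape::phylo` with branch lengths.
#' @param calibrations list: either tip-set-keyed, i.e.
#'   `list(list(tips = c(...), min =, max =), ...)` where `tips` picks
#'   the MRCA, or node-number-keyed `list(list(node =, min =, max =))`.
#' @return list of class `"dated_tree"`: `tree` (ultrametric, branch
#'   lengths in MY), `ages` (per node, MYA), `rate`
#'   (substitutions/site/MY), `calibrations`.
#' @export
strict_clock_dating <- function(tree, calibrations) {
  stopifnot(ape::is.rooted(tree), length(calibrations) >= 1)
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  root <- ntip + 1L

  # observed root-to-node distances
  po <- ape::reorder.phylo(tree, "postorder")
  depth <- numeric(nnode)
  pre <- rev(seq_len(nrow(po$edge)))
  for (k in pre)
    depth[po$edge[k, 2]] <- depth[po$edge[k, 1]] + po$edge.length[k]

  parent <- rep(NA_integer_, nnode)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  children <- split(tree$edge[, 2], tree$edge[, 1])

  lo <- rep(0, nnode); hi <- rep(Inf, nnode)
  lo[seq_len(ntip)] <- hi[seq_len(ntip)] <- 0
  for (cal in calibrations) {
    node <- if (!is.null(cal$node)) cal$node else
      ape::getMRCA(tree, cal$tips)
    stopifnot(node > ntip)
    lo[node] <- max(lo[node], cal$min)
    hi[node] <- min(hi[node], cal$max)
    if (lo[node] > hi[node]) stop("infeasible calibration on node ", node)
  }

  internal <- (ntip + 1L):nnode
  # propagate calibration boxes through the order constraints:
  # a node's effective minimum is the max over its subtree's minima,
  # its effective maximum the min over its ancestors' maxima
  for (k in seq_len(nrow(po$edge))) {            # postorder: children first
    par <- po$edge[k, 1]; chd <- po$edge[k, 2]
    lo[par] <- max(lo[par], lo[chd])
  }
  for (k in rev(seq_len(nrow(po$edge)))) {       # preorder: parents first
    par <- po$edge[k, 1]; chd <- po$edge[k, 2]
    if (chd > ntip) hi[chd] <- min(hi[chd], hi[par])
  }
  if (any(lo[internal] > hi[internal]))
    stop("infeasible calibrations after order-constraint propagation")
  ord <- internal[order(-depth[internal])]  # deepest first

  init_ages <- function(r) {
    a <- pmax((depth[root] - depth) / r, 0)
    a[seq_len(ntip)] <- 0
    # project into boxes respecting order (children first, then push up)
    for (v in rev(ord)) {  # shallow -> deep? ensure child < parent
      a[v] <- min(max(a[v], lo[v]), ifelse(is.finite(hi[v]), hi[v], a[v]))
    }
    a
  }

  sse_for_rate <- function(r, n_sweeps = 60) {
    a <- init_ages(r)
    for (s in seq_len(n_sweeps)) {
      for (v in ord) {
        kids <- children[[as.character(v)]]
        # terms involving a[v]: for each non-root node u, residual
        # r*(a[root]-a[u]) - depth[u]. a[v] appears in its own term (if
        # not root) and in a[root]'s presence in all terms (if v is root)
        if (v == root) {
          # optimal root age given others: all terms involve a[root]
          others <- setdiff(seq_len(nnode), root)
          t_opt <- mean(depth[others] / r + a[others])
          lb <- max(c(lo[v], a[kids]))
          ub <- hi[v]
          a[v] <- min(max(t_opt, lb), ub)
        } else {
          t_opt <- a[root] - depth[v] / r
          lb <- max(c(lo[v], a[children[[as.character(v)]]], 0))
          ub <- min(hi[v], a[parent[v]])
          a[v] <- min(max(t_opt, lb), ub)
        }
      }
    }
    others <- setdiff(seq_len(nnode), root)
    resid <- r * (a[root] - a[others]) - depth[others]
    list(sse = sum(resid^2), ages = a)
  }

  # bracket the rate from each calibrated node: the mean root-to-tip
  # depth below it divided by its age bounds
  cal_nodes <- which(lo > 0 | (is.finite(hi) & hi > 0))
  cal_nodes <- cal_nodes[cal_nodes > ntip]
  tipset <- function(v) {
    if (v <= ntip) return(v)
    out <- integer(0); stack <- v
    while (length(stack)) {
      x <- stack[1]; stack <- stack[-1]
      kids <- children[[as.character(x)]]
      for (k in kids) if (k <= ntip) out <- c(out, k) else
        stack <- c(stack, k)
    }
    out
  }
  r_guesses <- unlist(lapply(cal_nodes, function(v) {
    below <- mean(depth[tipset(v)] - depth[v])
    c(below / pmax(lo[v], 1e-9), below / hi[v])
  }))
  r_guesses <- r_guesses[is.finite(r_guesses) & r_guesses > 0]
  if (!length(r_guesses))
    r_guesses <- max(depth) / max(c(lo[cal_nodes], 1))
  r_lo <- min(r_guesses) / 10; r_hi <- max(r_guesses) * 10
  opt <- stats::optimize(function(r) sse_for_rate(r)$sse,
                         interval = c(r_lo, r_hi), tol = 1e-10)
  rate <- opt$minimum
  fit <- sse_for_rate(rate, n_sweeps = 200)
  ages <- fit$ages

  dated <- tree
  dated$edge.length <- ages[tree$edge[, 1]] - ages[tree$edge[, 2]]
  structure(list(tree = dated, ages = ages, rate = rate,
                 calibrations = calibrations, sse = fit$sse),
            class = "dated_tree")
}

#' @exportS3Method base::print
print.dated_tree <- function(x, ...) {
  ntip <- length(x$tree$tip.label)
  cat("Strict-clock dated tree:", ntip, "tips, rate =",
      signif(x$rate, 4), "subst/site/MY\n")
  ages <- x$ages[(ntip + 1):length(x$ages)]
  cat("  node ages (MYA):", paste(signif(ages, 4), collapse = ", "), "\n")
  invisible(x)
}
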