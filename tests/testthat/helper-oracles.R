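# Independent brute-force oracles used to cross-check the package's
# implementations. These deliberately re-derive everything from first
# principles (genetic code, quadratic DP, exhaustive enumeration) rather
# than calling the code paths they verify.

# --- Smith-Waterman local alignment score, quadratic DP ----------------
sw_score_oracle <- function(a, b, open = 11, ext = 1) {
  data("BLOSUM62", package = "Biostrings", envir = environment())
  S <- BLOSUM62
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  H <- matrix(0, n + 1, m + 1)   # best ending in match
  E <- matrix(-Inf, n + 1, m + 1) # gap in b (deletion)
  F <- matrix(-Inf, n + 1, m + 1)
  best <- 0
  for (i in 2:(n + 1)) for (j in 2:(m + 1)) {
    E[i, j] <- max(H[i, j - 1] - open - ext, E[i, j - 1] - ext)
    F[i, j] <- max(H[i - 1, j] - open - ext, F[i - 1, j] - ext)
    H[i, j] <- max(0, H[i - 1, j - 1] + S[av[i - 1], bv[j - 1]],
                   E[i, j], F[i, j])
    best <- max(best, H[i, j])
  }
  best
}

# --- exhaustive best chain of collinear anchors ------------------------
chain_enumerate <- function(anchors, max_gap = 1) {
  n <- nrow(anchors)
  if (!n) return(integer(0))
  best <- integer(0)
  extend <- function(chain) {
    last <- chain[length(chain)]
    cand <- which(anchors$pos_a > anchors$pos_a[last] &
                    anchors$pos_a - anchors$pos_a[last] - 1 <= max_gap &
                    anchors$pos_b > anchors$pos_b[last] &
                    anchors$pos_b - anchors$pos_b[last] - 1 <= max_gap)
    if (!length(cand)) {
      if (length(chain) > length(best)) best <<- chain
      return(invisible())
    }
    for (nx in cand) extend(c(chain, nx))
  }
  for (s in seq_len(n)) extend(s)
  best
}

# --- GY94 rate matrix built independently from the genetic code --------
oracle_codon_Q <- function(kappa, omega, freq = NULL) {
  gc_tab <- Biostrings::GENETIC_CODE
  sense <- names(gc_tab)[gc_tab != "*"]
  n <- length(sense)
  if (is.null(freq)) freq <- rep(1 / n, n)
  sp <- do.call(rbind, strsplit(sense, ""))
  Q <- matrix(0, n, n, dimnames = list(sense, sense))
  purine <- c("A", "G")
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    d <- which(sp[i, ] != sp[j, ])
    if (length(d) != 1) next
    r <- freq[j]
    if ((sp[i, d] %in% purine) == (sp[j, d] %in% purine)) r <- r * kappa
    if (gc_tab[sense[i]] != gc_tab[sense[j]]) r <- r * omega
    Q[i, j] <- r
  }
  diag(Q) <- -rowSums(Q)
  mu <- -sum(freq * diag(Q))
  Q / mu
}

# --- likelihood by explicit marginalisation over internal states -------
brute_force_lnL <- function(states, tree, kappa, omega, freq = NULL) {
  n <- 61
  if (is.null(freq)) freq <- rep(1 / n, n)
  Q <- oracle_codon_Q(kappa, omega, freq)
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  P <- lapply(seq_len(nrow(tree$edge)), function(k)
    as.matrix(Matrix::expm(Q * tree$edge.length[k])))
  internal <- (ntip + 1):nnode
  states <- states[tree$tip.label, , drop = FALSE]
  total <- 0
  for (site in seq_len(ncol(states))) {
    obs <- states[, site]
    lik <- 0
    grid <- do.call(expand.grid, rep(list(seq_len(n)), length(internal)))
    for (g in seq_len(nrow(grid))) {
      assign_state <- function(v)
        if (v <= ntip) obs[v] else grid[g, match(v, internal)]
      p <- freq[assign_state(ntip + 1)]
      for (k in seq_len(nrow(tree$edge))) {
        a <- assign_state(tree$edge[k, 1])
        b <- assign_state(tree$edge[k, 2])
        p <- p * P[[k]][as.integer(a), as.integer(b)]
      }
      lik <- lik + p
    }
    total <- total + log(lik)
  }
  total
}

# --- NG86 pathway enumeration via explicit permutations ----------------
ng86_pair_oracle <- function(cod_a, cod_b) {
  gc_tab <- Biostrings::GENETIC_CODE
  a <- strsplit(cod_a, "")[[1]]; b <- strsplit(cod_b, "")[[1]]
  pos <- which(a != b)
  if (!length(pos)) return(c(syn = 0, nonsyn = 0))
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (rest in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
    out
  }
  res <- list()
  for (p in perms(pos)) {
    cur <- a; sy <- 0; ns <- 0; ok <- TRUE
    for (q in p) {
      nxt <- cur; nxt[q] <- b[q]
      aa1 <- gc_tab[paste(cur, collapse = "")]
      aa2 <- gc_tab[paste(nxt, collapse = "")]
      if (aa2 == "*") { ok <- FALSE; break }
      if (aa1 == aa2) sy <- sy + 1 else ns <- ns + 1
      cur <- nxt
    }
    res[[length(res) + 1]] <- list(ok = ok, sy = sy, ns = ns)
  }
  valid <- Filter(function(x) x$ok, res)
  if (!length(valid)) valid <- res
  c(syn = mean(sapply(valid, `[[`, "sy")),
    nonsyn = mean(sapply(valid, `[[`, "ns")))
}

# --- N50 by direct cumulative scan -------------------------------------
n50_oracle <- function(lengths) {
  s <- sort(lengths, decreasing = TRUE)
  half <- sum(s) / 2
  acc <- 0
  for (l in s) { acc <- acc + l; if (acc >= half) return(l) }
}

# --- reciprocal best hits by O(n^2) scan -------------------------------
rbh_oracle <- function(score, a_names, b_names) {
  # score: matrix |A| x |B|, NA = no edge
  out <- list()
  for (i in seq_along(a_names)) {
    if (all(is.na(score[i, ]))) next
    jbest <- which(score[i, ] == max(score[i, ], na.rm = TRUE))
    jbest <- jbest[order(b_names[jbest])][1]
    ibest <- which(score[, jbest] == max(score[, jbest], na.rm = TRUE))
    ibest <- ibest[order(a_names[ibest])][1]
    if (ibest == i)
      out[[length(out) + 1]] <- data.frame(gene_a = a_names[i],
                                           gene_b = b_names[jbest])
  }
  if (!length(out)) return(data.frame(gene_a = character(0),
                                      gene_b = character(0)))
  do.call(rbind, out)
}

# --- per-column filter rule evaluation ---------------------------------
column_filter_oracle <- function(m, max_gap_fraction, min_conservation) {
  keep <- logical(ncol(m))
  for (j in seq_len(ncol(m))) {
    col <- m[, j]
    gf <- mean(col %in% c("-", "N", "?"))
    res <- col[!col %in% c("-", "N", "?")]
    cons <- if (length(res)) max(table(res)) / length(res) else 0
    keep[j] <- gf <= max_gap_fraction && cons >= min_conservation
  }
  which(keep)
}

# --- fourfold-degeneracy check straight from the code table ------------
is_fourfold_codon <- function(codon) {
  gc_tab <- Biostrings::GENETIC_CODE
  pre <- substr(codon, 1, 2)
  aas <- gc_tab[paste0(pre, c("T", "C", "A", "G"))]
  length(unique(aas)) == 1 && all(aas != "*")
}
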