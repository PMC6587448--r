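# Ortholog-family construction: all-vs-all protein similarity edges,
# Markov clustering (MCL) of the similarity graph, reciprocal best hits,
# and single-copy family extraction.

# Karlin-Altschul parameters for gapped BLOSUM62, gap open 11 / extend 1
.ka_lambda <- 0.267
.ka_K <- 0.041

#' All-vs-all protein similarity edges
#'
#' Smith-Waterman local alignment (BLOSUM62, affine gaps open 11 extend
#' 1) of every cross pair, with bitscores and e-values from
#' Karlin-Altschul statistics using the standard gapped BLOSUM62
#' constants. Edges with e-value above the cutoff are discarded.
#' A precomputed outfmt-6 table can be used instead via
#' [read_outfmt6()] + [hits_to_edges()].
#'
#' @param proteins_a,proteins_b named character vectors (or
#'   `AAStringSet`s) of protein sequences; use the same set twice for a
#'   self-comparison (self-pairs are skipped).
#' @param evalue_cutoff maximum e-value (default 1e-5).
#' @return data.frame gene_a, gene_b, score (raw SW), bitscore, evalue.
#' @export
pairwise_similarity <- function(proteins_a, proteins_b,
                                evalue_cutoff = 1e-5) {
  if (!methods::is(proteins_a, "AAStringSet"))
    proteins_a <- Biostrings::AAStringSet(proteins_a)
  if (!methods::is(proteins_b, "AAStringSet"))
    proteins_b <- Biostrings::AAStringSet(proteins_b)
  if (!length(proteins_a) || !length(proteins_b))
    stop("empty protein set")
  db_len <- sum(Biostrings::width(proteins_b))
  rows <- list()
  for (i in seq_along(proteins_a)) {
    qa <- proteins_a[[i]]
    qname <- names(proteins_a)[i]
    for (j in seq_along(proteins_b)) {
      sname <- names(proteins_b)[j]
      if (qname == sname) next
      aln <- Biostrings::pairwiseAlignment(
        qa, proteins_b[[j]], type = "local",
        substitutionMatrix = "BLOSUM62",
        gapOpening = 11, gapExtension = 1, scoreOnly = TRUE)
      bits <- (.ka_lambda * aln - log(.ka_K)) / log(2)
      ev <- length(qa) * db_len * 2^(-bits)
      if (ev <= evalue_cutoff)
        rows[[length(rows) + 1L]] <- data.frame(
          gene_a = qname, gene_b = sname, score = aln,
          bitscore = bits, evalue = ev, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(gene_a = character(0), gene_b = character(0),
                      score = numeric(0), bitscore = numeric(0),
                      evalue = numeric(0)))
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Convert an outfmt-6 table to similarity edges
#' @param hits outfmt-6 data.frame.
#' @param evalue_cutoff maximum e-value retained.
#' @return edge data.frame (gene_a, gene_b, bitscore, evalue).
#' @export
hits_to_edges <- function(hits, evalue_cutoff = 1e-5) {
  keep <- hits$evalue <= evalue_cutoff & hits$qseqid != hits$sseqid
  data.frame(gene_a = hits$qseqid[keep], gene_b = hits$sseqid[keep],
             bitscore = hits$bitscore[keep], evalue = hits$evalue[keep],
             stringsAsFactors = FALSE)
}

#' Build a symmetric similarity graph
#'
#' Symmetrizes directed edges (averaging weights of reciprocal pairs),
#' removes self-edges, and attaches `-log10(evalue)` weights capped at
#' `cap`.
#'
#' @param edges data.frame gene_a, gene_b, evalue (and optionally
#'   bitscore).
#' @param genes optional full gene universe (isolated genes are carried
#'   as graph nodes).
#' @param gene_species optional named vector gene -> species/variety.
#' @param cap weight cap corresponding to evalue 0 (default 300).
#' @return list of class `"similarity_graph"`: `nodes`, `edges`
#'   (gene_a, gene_b, weight, bitscore), `species`.
#' @export
similarity_graph <- function(edges, genes = NULL, gene_species = NULL,
                             cap = 300) {
  e <- edges[edges$gene_a != edges$gene_b, , drop = FALSE]
  w <- pmin(-log10(pmax(e$evalue, 1e-300)), cap)
  a <- pmin(e$gene_a, e$gene_b)
  b <- pmax(e$gene_a, e$gene_b)
  key <- paste(a, b, sep = "\r")
  bs <- if ("bitscore" %in% names(e)) e$bitscore else w
  agg_w <- tapply(w, key, mean)
  agg_b <- tapply(bs, key, max)
  ks <- strsplit(names(agg_w), "\r", fixed = TRUE)
  out <- data.frame(gene_a = vapply(ks, `[[`, "", 1),
                    gene_b = vapply(ks, `[[`, "", 2),
                    weight = as.numeric(agg_w),
                    bitscore = as.numeric(agg_b),
                    stringsAsFactors = FALSE)
  nodes <- unique(c(out$gene_a, out$gene_b, genes))
  structure(list(nodes = nodes, edges = out, species = gene_species),
            class = "similarity_graph")
}

#' Markov clustering of a similarity graph
#'
#' MCL on the column-stochastic weighted adjacency matrix: expansion
#' (matrix squaring), inflation (entrywise power + renormalisation),
#' pruning of entries below `prune`, iterated until the matrix is
#' idempotent within `tol` or `max_iter` iterations. Self-loops are added
#' with each node's maximum incident weight to stabilise the process.
#' Attractor connected components define clusters; singletons are
#' returned as unclustered genes.
#'
#' @param graph a [similarity_graph()].
#' @param inflation inflation exponent (default 1.5).
#' @param prune column entries below this are zeroed (default 1e-6).
#' @param tol idempotence tolerance on max absolute change (default 1e-8).
#' @param max_iter iteration cap.
#' @return list `clusters` (named list of member vectors, sizes >= 2),
#'   `unclustered` (character vector), `iterations`, `converged`.
#' @export
mcl_cluster <- function(graph, inflation = 1.5, prune = 1e-6,
                        tol = 1e-8, max_iter = 200) {
  nodes <- sort(graph$nodes)
  n <- length(nodes)
  e <- graph$edges
  ia <- match(e$gene_a, nodes); ib <- match(e$gene_b, nodes)
  M <- Matrix::sparseMatrix(i = c(ia, ib), j = c(ib, ia),
                            x = rep(pmax(e$weight, 1e-12), 2),
                            dims = c(n, n))
  loop <- apply_max_loop(M, n)
  M <- M + Matrix::Diagonal(n, loop)
  normalize <- function(A) {
    cs <- Matrix::colSums(A)
    cs[cs == 0] <- 1
    A %*% Matrix::Diagonal(n, 1 / cs)
  }
  M <- normalize(M)
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    M2 <- M %*% M                        # expansion
    M2@x <- M2@x^inflation               # inflation
    M2 <- Matrix::drop0(M2, tol = 0)
    M2@x[M2@x < prune] <- 0
    M2 <- Matrix::drop0(M2)
    M2 <- normalize(M2)
    delta <- max(abs(M2 - M))
    M <- M2
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning("MCL did not converge within ", max_iter, " iterations")
  # clusters = connected components of the non-zero structure
  Msym <- M + Matrix::t(M)
  g <- igraph::graph_from_adjacency_matrix(Msym > 0, mode = "undirected",
                                           diag = FALSE)
  comp <- igraph::components(g)$membership
  cl <- split(nodes, comp)
  sizes <- lengths(cl)
  clusters <- cl[sizes >= 2]
  clusters <- clusters[order(-lengths(clusters),
                             vapply(clusters, `[[`, "", 1))]
  names(clusters) <- sprintf("cl%05d", seq_along(clusters))
  list(clusters = clusters,
       unclustered = sort(unlist(unname(cl[sizes == 1]))),
       iterations = it, converged = converged)
}

# self-loop weight: max incident edge weight per node (1 for isolated)
apply_max_loop <- function(M, n) {
  A <- methods::as(M, "CsparseMatrix")
  mx <- rep(1, n)
  if (length(A@x)) {
    cols <- rep(seq_len(n), diff(A@p))
    got <- tapply(A@x, factor(cols, levels = seq_len(n)), max)
    ok <- !is.na(got) & got > 0
    mx[ok] <- got[ok]
  }
  mx
}

#' Reciprocal best hits between two species
#'
#' @param graph a [similarity_graph()] whose `species` map covers all
#'   genes involved.
#' @param species_a,species_b species/variety labels.
#' @return data.frame gene_a, gene_b of mutual best (highest-bitscore)
#'   hits; ties broken by lexicographic gene id.
#' @export
reciprocal_best_hits <- function(graph, species_a, species_b) {
  sp <- graph$species
  if (is.null(sp)) stop("graph has no species annotation")
  if (!any(sp == species_a) || !any(sp == species_b))
    stop("species absent from graph")
  e <- graph$edges
  # directed view both ways
  d <- rbind(
    data.frame(from = e$gene_a, to = e$gene_b, bitscore = e$bitscore),
    data.frame(from = e$gene_b, to = e$gene_a, bitscore = e$bitscore))
  d <- d[sp[d$from] == species_a & sp[d$to] == species_b, , drop = FALSE]
  if (!nrow(d)) return(data.frame(gene_a = character(0),
                                  gene_b = character(0)))
  best_of <- function(df, keycol, valcol) {
    df <- df[order(df[[keycol]], -df$bitscore, df[[valcol]]), ]
    df[!duplicated(df[[keycol]]), ]
  }
  best_a <- best_of(d, "from", "to")      # best hit in B for each A gene
  best_b <- best_of(d, "to", "from")      # best hit in A for each B gene
  bb <- stats::setNames(best_b$from, best_b$to)
  keep <- bb[best_a$to] == best_a$from
  keep[is.na(keep)] <- FALSE
  out <- data.frame(gene_a = best_a$from[keep], gene_b = best_a$to[keep],
                    stringsAsFactors = FALSE)
  out[order(out$gene_a), , drop = FALSE]
}

#' Single-copy families across required taxa
#'
#' @param clusters named list of member gene vectors.
#' @param gene_species named vector gene -> taxon.
#' @param required_taxa taxa that must each contribute exactly one gene;
#'   clusters containing any other gene are excluded.
#' @return the qualifying subset of `clusters`.
#' @export
single_copy_families <- function(clusters, gene_species, required_taxa) {
  keep <- vapply(clusters, function(m) {
    tx <- gene_species[m]
    !anyNA(tx) && setequal(tx, required_taxa) &&
      !anyDuplicated(tx) && length(m) == length(required_taxa)
  }, logical(1))
  clusters[keep]
}
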