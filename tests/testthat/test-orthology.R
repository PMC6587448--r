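# Similarity edges, Markov clustering, reciprocal best hits,
# single-copy families.

test_that("Smith-Waterman scoring matches a quadratic DP oracle", {
  a <- "HEAGAWGHEE"; b <- "PAWHEAE"
  got <- Biostrings::pairwiseAlignment(
    a, b, type = "local", substitutionMatrix = "BLOSUM62",
    gapOpening = 11, gapExtension = 1, scoreOnly = TRUE)
  expect_equal(got, sw_score_oracle(a, b))
  set.seed(41)
  aas <- c("A","R","N","D","C","Q","E","G","H","I","L","K","M","F","P",
           "S","T","W","Y","V")
  for (rep in 1:5) {
    x <- paste(sample(aas, 30, TRUE), collapse = "")
    y <- paste(sample(aas, 25, TRUE), collapse = "")
    got <- Biostrings::pairwiseAlignment(
      x, y, type = "local", substitutionMatrix = "BLOSUM62",
      gapOpening = 11, gapExtension = 1, scoreOnly = TRUE)
    expect_equal(got, sw_score_oracle(x, y))
  }
})

test_that("identical proteins pass the e-value cutoff, random ones do not", {
  set.seed(42)
  aas <- c("A","R","N","D","C","Q","E","G","H","I","L","K","M","F","P",
           "S","T","W","Y","V")
  p1 <- paste(sample(aas, 200, TRUE), collapse = "")
  ed <- pairwise_similarity(c(x = p1, y = p1), c(x = p1, y = p1))
  expect_true(nrow(ed) >= 1)
  expect_lt(min(ed$evalue), 1e-5)
  # unrelated random pairs: no edge at 1e-5 (checked over several pairs)
  hits <- 0
  for (rep in 1:5) {
    q <- paste(sample(aas, 100, TRUE), collapse = "")
    s <- paste(sample(aas, 100, TRUE), collapse = "")
    hits <- hits + nrow(pairwise_similarity(c(q = q), c(s = s)))
  }
  expect_equal(hits, 0)
})

test_that("MCL separates disjoint cliques and leaves singletons out", {
  clique <- function(ids) {
    p <- t(combn(ids, 2))
    data.frame(gene_a = p[, 1], gene_b = p[, 2], evalue = 1e-50,
               bitscore = 100, stringsAsFactors = FALSE)
  }
  edges <- rbind(clique(c("a1", "a2", "a3")), clique(c("b1", "b2", "b3")))
  g <- similarity_graph(edges, genes = "lone")
  res <- mcl_cluster(g)
  expect_length(res$clusters, 2)
  expect_true(all(lengths(res$clusters) == 3))
  expect_equal(res$unclustered, "lone")
  expect_true(res$converged)
  # clique components equal connected components for any inflation >= 1.2
  for (infl in c(1.2, 1.5, 2, 4)) {
    r2 <- mcl_cluster(g, inflation = infl)
    expect_length(r2$clusters, 2)
    sets <- lapply(r2$clusters, sort)
    expect_true(list(c("a1", "a2", "a3")) %in% sets ||
                  any(vapply(sets, identical, TRUE,
                             y = c("a1", "a2", "a3"))))
  }
})

test_that("MCL is invariant to node input order and partitions the genes", {
  set.seed(43)
  clique <- function(ids, w) {
    p <- t(combn(ids, 2))
    data.frame(gene_a = p[, 1], gene_b = p[, 2],
               evalue = 10^(-w), bitscore = w, stringsAsFactors = FALSE)
  }
  edges <- rbind(clique(paste0("x", 1:4), 60), clique(paste0("y", 1:5), 40))
  g1 <- similarity_graph(edges)
  g2 <- similarity_graph(edges[sample(nrow(edges)), ])
  r1 <- mcl_cluster(g1); r2 <- mcl_cluster(g2)
  expect_equal(lapply(r1$clusters, sort), lapply(r2$clusters, sort))
  all_genes <- c(unlist(r1$clusters), r1$unclustered)
  expect_setequal(all_genes, g1$nodes)
  expect_equal(anyDuplicated(all_genes), 0L)
})

test_that("MCL recovers planted partitions from noisy weighted graphs", {
  recover_rate <- function(seed) {
    set.seed(seed)
    blocks <- split(sprintf("g%03d", 1:60), rep(1:4, each = 15))
    rows <- list()
    for (b in blocks) {
      p <- t(combn(b, 2))
      keep <- runif(nrow(p)) < 0.8   # dense within-block
      rows[[length(rows) + 1]] <- data.frame(
        gene_a = p[keep, 1], gene_b = p[keep, 2],
        evalue = 10^-runif(sum(keep), 30, 80))
    }
    # sparse cross-block noise, weak weights
    for (k in 1:25) {
      b2 <- sample(4, 2)
      rows[[length(rows) + 1]] <- data.frame(
        gene_a = sample(blocks[[b2[1]]], 1),
        gene_b = sample(blocks[[b2[2]]], 1),
        evalue = 10^-runif(1, 5, 8))
    }
    edges <- do.call(rbind, rows)
    g <- similarity_graph(edges, genes = unlist(blocks))
    res <- mcl_cluster(g, inflation = 1.5)
    truth <- rep(1:4, each = 15)
    names(truth) <- unlist(blocks)
    # fraction of genes whose cluster is the majority-matched block
    ok <- 0
    for (cl in res$clusters) {
      maj <- names(which.max(table(truth[cl])))
      ok <- ok + sum(truth[cl] == as.integer(maj))
    }
    ok / length(truth)
  }
  rates <- vapply(1:20, recover_rate, numeric(1))
  expect_gte(mean(rates), 0.95)
})

test_that("reciprocal best hits match the exhaustive scan", {
  set.seed(44)
  for (rep in 1:10) {
    na <- sample(3:7, 1); nb <- sample(3:7, 1)
    a_names <- paste0("a", seq_len(na)); b_names <- paste0("b", seq_len(nb))
    S <- matrix(sample(c(NA, 30:90), na * nb, TRUE), na, nb)
    rows <- which(!is.na(S), arr.ind = TRUE)
    if (!nrow(rows)) next
    edges <- data.frame(gene_a = a_names[rows[, 1]],
                        gene_b = b_names[rows[, 2]],
                        evalue = 1e-30, bitscore = S[rows])
    sp <- setNames(c(rep("A", na), rep("B", nb)), c(a_names, b_names))
    g <- similarity_graph(edges, gene_species = sp)
    got <- reciprocal_best_hits(g, "A", "B")
    want <- rbh_oracle(S, a_names, b_names)
    got <- got[order(got$gene_a), ]; want <- want[order(want$gene_a), ]
    expect_equal(got$gene_a, want$gene_a)
    expect_equal(got$gene_b, want$gene_b)
  }
})

test_that("asymmetric best hits are excluded", {
  edges <- data.frame(gene_a = c("a1", "a2"), gene_b = c("b1", "b1"),
                      evalue = 1e-30, bitscore = c(50, 80))
  sp <- c(a1 = "A", a2 = "A", b1 = "B")
  g <- similarity_graph(edges, gene_species = sp)
  out <- reciprocal_best_hits(g, "A", "B")
  expect_equal(out$gene_a, "a2")   # b1's best is a2, so a1 gets nothing
})

test_that("single-copy families require exactly one gene per taxon", {
  sp <- c(a1 = "A", a2 = "A", b1 = "B", c1 = "C", b2 = "B")
  cl <- list(ok = c("a1", "b1", "c1"),
             paralog = c("a1", "a2", "b1", "c1"),
             missing = c("a1", "b1"))
  out <- single_copy_families(cl, sp, c("A", "B", "C"))
  expect_equal(names(out), "ok")
})
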