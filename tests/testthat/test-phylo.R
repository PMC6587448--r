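# Family alignment, column filtering, GTR distances, NJ, fourfold sites
# and strict-clock dating.

test_that("family alignment handles identity, indels and simulator input", {
  a <- random_cds(40)
  expect_equal(unname(align_family(c(A = a, B = a))), c(a, a))
  # one extra codon -> one 3-column gap
  longer <- paste0(substr(a, 1, 60), "GCT", substr(a, 61, nchar(a)))
  out <- align_family(c(A = longer, B = a))
  expect_equal(nchar(out[["A"]]), nchar(longer))
  expect_equal(nchar(out[["B"]]), nchar(longer))
  expect_true(grepl("---", out[["B"]], fixed = TRUE))
  expect_equal(gsub("-", "", out[["B"]]), a)
  # internal stop rejected
  bad <- paste0("TAA", random_cds(20))
  expect_error(align_family(c(A = bad, B = paste0(random_cds(21)))),
               "stop")
})

test_that("column filter applies gap and conservation rules per column", {
  m <- rbind(A = c("A", "C", "G", "T", "A"),
             B = c("A", "C", "-", "T", "C"),
             C = c("A", "G", "G", "T", "G"))
  out <- filter_columns(m)
  expect_equal(out$kept, column_filter_oracle(m, 0, 0.5))
  expect_false(3 %in% out$kept)        # gap column dropped
  # fully conserved gap-free matrix unchanged
  m2 <- matrix("A", 3, 4)
  expect_equal(filter_columns(m2)$kept, 1:4)
  # idempotence
  again <- filter_columns(out$matrix)
  expect_equal(ncol(again$matrix), ncol(out$matrix))
  # randomized agreement with the per-column oracle
  set.seed(71)
  for (rep in 1:10) {
    mr <- matrix(sample(c("A", "C", "G", "T", "-"), 60, TRUE,
                        prob = c(rep(0.22, 4), 0.12)), 5, 12)
    gf <- runif(1, 0, 0.5); mc <- runif(1, 0.3, 0.9)
    want <- column_filter_oracle(mr, gf, mc)
    if (!length(want)) {
      expect_error(filter_columns(mr, gf, mc))
    } else {
      expect_equal(filter_columns(mr, gf, mc)$kept, want)
    }
  }
})

test_that("GTR distances: zero for identical, symmetric, recovers truth", {
  s <- paste(sample(c("A", "C", "G", "T"), 2000, TRUE), collapse = "")
  D <- gtr_distances(c(A = s, B = s))
  expect_equal(D[1, 2], 0, tolerance = 1e-9)
  set.seed(72)
  tr <- ape::read.tree(text = "(A:0.1,B:0.1);")   # true distance 0.2
  ests <- replicate(8, {
    sim <- sim_codon_alignment(tr, kappa = 2.5, omega = 1,
                               n_codons = 12000)
    m <- do.call(rbind, strsplit(sim$sequences, ""))
    rownames(m) <- names(sim$sequences)
    gtr_distances(m)[1, 2]
  })
  se <- sd(ests) / sqrt(length(ests))
  expect_lt(abs(mean(ests) - 0.2 / 3), 3 * se + 0.004)
  # (codon branch lengths are per codon; nucleotide distance is ~1/3)
  D2 <- gtr_distances(c(X = "ACGTACGTAA", Y = "ACGTACGAAA"))
  expect_equal(D2[1, 2], D2[2, 1])
  expect_equal(diag(D2), c(X = 0, Y = 0))
})

test_that("NJ recovers additive and ultrametric topologies", {
  # additive 4-taxon matrix from a known tree
  tr <- ape::read.tree(text = "((A:2,B:3):1,(C:2,D:4):2);")
  D <- ape::cophenetic.phylo(tr)
  njt <- nj_tree(D)
  expect_equal(ape::dist.topo(ape::unroot(njt), ape::unroot(tr)), 0,
               ignore_attr = TRUE)
  expect_true(all(njt$edge.length >= 0))
  # 3-taxon ultrametric: closest pair are siblings
  D3 <- matrix(c(0, 1, 4, 1, 0, 4, 4, 4, 0), 3,
               dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  t3 <- nj_tree(D3, outgroup = "c")
  sib <- ape::extract.clade(t3, ape::getMRCA(t3, c("a", "b")))$tip.label
  expect_setequal(sib, c("a", "b"))
  expect_error(nj_tree(matrix(c(0, 1, 2, 0), 2)), "symmetric")
})

test_that("fourfold site extraction matches the genetic code", {
  # alanine box: all GC* codons -> third position extracted
  aln <- c(A = "GCTAAA", B = "GCCAAA", C = "GCGAAA")
  out <- fourfold_sites(aln)
  expect_equal(ncol(out), 1)
  expect_equal(unname(out[, 1]), c("T", "C", "G"))
  # AAA/AAG (Lys, twofold) not extracted even though prefix matches
  expect_false(2 %in% attr(out, "codon_sites"))
  # random-codon agreement with a direct code-table check
  set.seed(73)
  for (rep in 1:10) {
    cods <- sample(panforge:::codon_tables()$codons, 30, TRUE)
    aln <- c(X = paste(cods, collapse = ""),
             Y = paste(cods, collapse = ""))
    out <- fourfold_sites(aln)
    want <- which(vapply(cods, is_fourfold_codon, logical(1)))
    expect_equal(attr(out, "codon_sites"), unname(want))
  }
})

test_that("strict-clock dating is exact on clean input and respects boxes", {
  tt <- ape::read.tree(text = "((A:1,B:1):2,(C:2,D:2):1);")
  d <- strict_clock_dating(tt, list(list(tips = c("C", "D"),
                                         min = 2, max = 2)))
  expect_equal(unname(d$ages[5:7]), c(3, 1, 2), tolerance = 1e-4)
  expect_equal(d$rate, 1, tolerance = 1e-4)
  # ultrametric output
  depths <- ape::node.depth.edgelength(d$tree)
  expect_lt(diff(range(depths[1:4])), 1e-8)
  # child ages below parent ages
  expect_true(all(d$ages[d$tree$edge[, 2]] <
                    d$ages[d$tree$edge[, 1]] + 1e-9))
  # scale invariance: lengths x c -> rate x c, ages unchanged
  t2 <- tt; t2$edge.length <- tt$edge.length * 2.5
  d2 <- strict_clock_dating(t2, list(list(tips = c("C", "D"),
                                          min = 2, max = 2)))
  expect_equal(d2$ages, d$ages, tolerance = 1e-3)
  expect_equal(d2$rate, 2.5 * d$rate, tolerance = 1e-3)
  # interval calibration is honoured
  d3 <- strict_clock_dating(tt, list(list(tips = c("C", "D"),
                                          min = 1.5, max = 1.8)))
  cd <- ape::getMRCA(tt, c("C", "D"))
  expect_gte(d3$ages[cd], 1.5 - 1e-9)
  expect_lte(d3$ages[cd], 1.8 + 1e-9)
  # infeasible calibrations error out
  expect_error(strict_clock_dating(
    tt, list(list(tips = c("C", "D"), min = 5, max = 6),
             list(node = 5, min = 1, max = 2))), "infeasible")
})
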