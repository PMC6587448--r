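# Tandem arrays, collinear chaining, duplication-origin labels and the
# class summary table.

test_that("consecutive homologs form one array, distant ones none", {
  go <- data.frame(gene_id = sprintf("g%02d", 1:50), chromosome = "chr1",
                   order = 1:50)
  prs <- data.frame(gene_a = c("g05", "g05", "g06"),
                    gene_b = c("g06", "g07", "g07"))
  ta <- detect_tandem_arrays(prs, go)
  expect_equal(nrow(ta), 3)
  expect_length(unique(ta$array_id), 1)
  far <- data.frame(gene_a = "g05", gene_b = "g40")
  expect_equal(nrow(detect_tandem_arrays(far, go)), 0)
  expect_error(detect_tandem_arrays(
    data.frame(gene_a = "zz", gene_b = "g01"), go), "zz")
  # arrays are disjoint
  prs2 <- rbind(prs, data.frame(gene_a = "g20", gene_b = "g21"))
  ta2 <- detect_tandem_arrays(prs2, go)
  expect_equal(anyDuplicated(ta2$gene_id), 0L)
  expect_length(unique(ta2$array_id), 2)
})

test_that("widening max_gap never loses tandem genes", {
  set.seed(61)
  go <- data.frame(gene_id = sprintf("g%02d", 1:40), chromosome = "chr1",
                   order = 1:40)
  idx <- sort(sample(1:40, 12))
  prs <- data.frame(gene_a = go$gene_id[idx[-length(idx)]],
                    gene_b = go$gene_id[idx[-1]])
  counts <- vapply(1:4, function(g)
    nrow(detect_tandem_arrays(prs, go, max_gap = g)), numeric(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("perfect anchor runs chain into one block; short runs do not", {
  anc <- data.frame(gene_a = sprintf("q%02d", 1:20),
                    gene_b = sprintf("s%02d", 1:20),
                    pos_a = 1:20, pos_b = 1:20)
  cb <- collinear_blocks(anc, min_block = 15)
  expect_equal(nrow(cb), 20)
  expect_length(unique(cb$block_id), 1)
  expect_equal(nrow(collinear_blocks(anc[1:14, ], min_block = 15)), 0)
  # inverted block
  inv <- data.frame(gene_a = sprintf("q%02d", 1:16),
                    gene_b = sprintf("s%02d", 16:1),
                    pos_a = 1:16, pos_b = 16:1)
  cbi <- collinear_blocks(inv, min_block = 15)
  expect_equal(nrow(cbi), 16)
  expect_equal(unique(cbi$orientation), "-")
})

test_that("chaining matches the exhaustive enumerator on small instances", {
  set.seed(62)
  for (rep in 1:15) {
    n <- sample(5:12, 1)
    anc <- data.frame(gene_a = paste0("q", 1:n), gene_b = paste0("s", 1:n),
                      pos_a = sample(1:20, n), pos_b = sample(1:20, n))
    got <- panforge:::.best_chain(anc, max_gap = 1)
    want <- chain_enumerate(anc, max_gap = 1)
    expect_equal(length(got), length(want))
    if (length(got)) {
      # both must be valid chains of the same maximal length
      g <- anc[got, ]
      expect_true(all(diff(g$pos_a) >= 1 & diff(g$pos_a) <= 2))
      expect_true(all(diff(g$pos_b) >= 1 & diff(g$pos_b) <= 2))
    }
  }
})

test_that("raising min_block never increases the block count", {
  set.seed(63)
  anc <- data.frame(gene_a = paste0("q", 1:60), gene_b = paste0("s", 1:60),
                    pos_a = 1:60,
                    pos_b = c(1:20, 41:60, 21:40))
  nb <- vapply(c(5, 10, 15, 20, 25),
               function(mb) length(unique(
                 collinear_blocks(anc, min_block = mb)$block_id)),
               numeric(1))
  expect_true(all(diff(nb) <= 0))
  # anchors belong to at most one block
  cb <- collinear_blocks(anc, min_block = 5)
  expect_equal(anyDuplicated(cb$gene_a), 0L)
})

test_that("origin labels follow block/array membership with TD precedence", {
  arrays <- data.frame(array_id = "ta0001", chromosome = "c",
                       gene_id = c("g1", "g2"), position = 1:2)
  blocks <- data.frame(block_id = "cb0001", orientation = "+",
                       gene_a = c("g2", "g3"), gene_b = c("o1", "o2"),
                       pos_a = 1:2, pos_b = 1:2)
  lab <- classify_duplication_origin(paste0("g", 1:4), arrays, blocks)
  expect_equal(unname(lab),
               c("TD", "TD", "WGD", "other"))  # g2: TD wins over WGD
})

test_that("class summary reproduces printed core-gene percentages", {
  n_core <- 23372
  origin <- setNames(rep("other", n_core), sprintf("g%05d", 1:n_core))
  origin[1:10932] <- "WGD"
  origin[10933:(10932 + 2076)] <- "TD"
  cat_v <- setNames(rep("core", n_core), names(origin))
  var_v <- setNames(rep("zz13", n_core), names(origin))
  tab <- summarize_by_class(origin, cat_v, var_v)
  core_row <- tab[tab$category == "core", ]
  expect_equal(core_row$wgd_pct, 46.77)
  expect_equal(core_row$td_pct, 8.88)
  expect_lte(core_row$wgd_pct + core_row$td_pct, 100)
  # empty class gives 0.00
  tab0 <- summarize_by_class(setNames("other", "g1"),
                             setNames("core", "g1"),
                             setNames("v", "g1"))
  expect_equal(tab0$wgd_pct[tab0$category == "core"], 0)
})

test_that("self-homolog pairs are symmetric and cutoff-filtered", {
  hits <- data.frame(qseqid = c("a", "b", "a", "c"),
                     sseqid = c("b", "a", "a", "d"),
                     pident = 90, length = 100, mismatch = 10,
                     gapopen = 0, qstart = 1, qend = 100, sstart = 1,
                     send = 100,
                     evalue = c(1e-30, 1e-30, 0, 1e-10), bitscore = 200)
  p <- self_homolog_pairs(hits, evalue_cutoff = 1e-20)
  expect_equal(nrow(p), 1)           # a-b deduplicated, self and weak gone
  expect_equal(p$gene_a, "a"); expect_equal(p$gene_b, "b")
})
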