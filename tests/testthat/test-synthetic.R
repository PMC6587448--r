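# The synthetic pan-genome generator and its ground truth.

small_cfg <- function(seed = 1, ...) {
  sim_config(n_core_families = 12, n_dispensable_families = 6,
             n_specific_genes = 3, cds_len = 60, n_chromosomes = 3,
             seed = seed, ...)
}

test_that("generation is byte-identical under a fixed seed", {
  cfg <- small_cfg(td_arrays = list(list(variety = "zz13", array_size = 3,
                                         chromosome = 1)),
                   wgd_blocks = list(list(variety = "yz11",
                                          block_anchor_count = 4)))
  d1 <- simulate_pangenome(cfg)
  d2 <- simulate_pangenome(cfg)
  expect_identical(d1$genes, d2$genes)
  expect_identical(d1$cds, d2$cds)
  expect_identical(d1$hits, d2$hits)
  dir1 <- withr::local_tempdir(); dir2 <- withr::local_tempdir()
  m1 <- write_dataset(d1, dir1); m2 <- write_dataset(d2, dir2)
  expect_identical(m1$md5, m2$md5)   # byte-identical files
  # different seed changes content (checksum property)
  d3 <- simulate_pangenome(small_cfg(seed = 2))
  dir3 <- withr::local_tempdir()
  m3 <- write_dataset(d3, dir3)
  expect_false(identical(m1$md5, m3$md5))
})

test_that("family structure honours the configuration", {
  cfg <- small_cfg()
  ds <- simulate_pangenome(cfg)
  tr <- ds$truth
  expect_equal(sum(tr$family_labels == "core"), 12)
  expect_equal(sum(tr$family_labels == "dispensable"), 6)
  # each core family has one gene in every variety
  for (f in names(tr$family_labels)[tr$family_labels == "core"]) {
    vs <- ds$genes$variety[!is.na(ds$genes$family) & ds$genes$family == f]
    expect_setequal(unique(vs), cfg$varieties)
  }
  # dispensable families appear exactly in their presence subset
  for (f in names(tr$family_labels)[tr$family_labels == "dispensable"]) {
    vs <- unique(ds$genes$variety[!is.na(ds$genes$family) &
                                    ds$genes$family == f])
    expect_setequal(vs, tr$presence[[f]])
    expect_lt(length(vs), length(cfg$varieties))
    expect_gte(length(vs), 1)
  }
  # truth covers every gene exactly once per axis
  expect_setequal(names(tr$gene_family), ds$genes$gene_id)
  expect_setequal(names(tr$gene_origin), ds$genes$gene_id)
  expect_equal(sum(is.na(ds$genes$family)),
               length(tr$specific_genes))
  # zero dispensable families -> all families core
  ds0 <- simulate_pangenome(sim_config(n_core_families = 5,
                                       n_dispensable_families = 0,
                                       n_specific_genes = 0,
                                       cds_len = 30, seed = 3))
  expect_true(all(ds0$truth$family_labels == "core"))
})

test_that("specific genes stay below any clustering threshold", {
  ds <- simulate_pangenome(small_cfg())
  spec <- ds$truth$specific_genes
  expect_false(any(spec %in% c(ds$hits$qseqid, ds$hits$sseqid)))
  # direct identity check of one specific gene against family genes
  s <- strsplit(ds$cds[[spec[1]]], "")[[1]]
  fam_gene <- ds$genes$gene_id[!is.na(ds$genes$family)][1]
  f <- strsplit(ds$cds[[fam_gene]], "")[[1]]
  expect_lt(mean(s == f), 0.45)   # random codon background identity
})

test_that("planted duplications are recorded and placed correctly", {
  cfg <- small_cfg(td_arrays = list(list(variety = "zz13", array_size = 3,
                                         chromosome = 2)),
                   wgd_blocks = list(list(variety = "bzm",
                                          block_anchor_count = 4)))
  ds <- simulate_pangenome(cfg)
  td_genes <- names(ds$truth$gene_origin)[ds$truth$gene_origin == "TD"]
  expect_length(td_genes, 3)
  g <- ds$genes[ds$genes$gene_id %in% td_genes, ]
  expect_length(unique(g$chromosome), 1)
  expect_equal(max(g$order) - min(g$order) + 1, 3)   # consecutive
  wgd_genes <- names(ds$truth$gene_origin)[ds$truth$gene_origin == "WGD"]
  expect_length(wgd_genes, 8)                        # run + copy
  gw <- ds$genes[ds$genes$gene_id %in% wgd_genes, ]
  expect_length(unique(gw$chromosome), 2)            # two chromosomes
  # empty specs leave the genome unchanged
  ds0 <- simulate_pangenome(small_cfg())
  expect_true(all(ds0$truth$gene_origin == "other"))
})

test_that("contradictory configurations raise errors", {
  expect_error(sim_config(n_dispensable_families = 2,
                          dispensable_presence = list("zz13")),
               "one subset per")
  expect_error(sim_config(
    n_dispensable_families = 1,
    dispensable_presence = list(c("zz13", "yz11", "bzm", "mszm",
                                  "swetha"))), "proper")
  cfg_bad <- small_cfg(td_arrays = list(list(variety = "zz13",
                                             array_size = 50,
                                             chromosome = 1)))
  expect_error(simulate_pangenome(cfg_bad), "capacity")
})

test_that("written dataset round-trips coordinates and validates as GFF3", {
  ds <- simulate_pangenome(small_cfg())
  dir <- withr::local_tempdir()
  write_dataset(ds, dir)
  for (v in c("zz13", "swetha")) {
    got <- read_gff3_genes(file.path(dir, paste0(v, ".gff3")))
    want <- ds$genes[ds$genes$variety == v, ]
    want <- want[order(want$chromosome, want$start), ]
    expect_equal(got$gene_id, want$gene_id)
    expect_equal(got$start, want$start)
    expect_equal(got$end, want$end)
    # raw GFF3: 1-based inclusive, at most one Parent per CDS row
    lines <- readLines(file.path(dir, paste0(v, ".gff3")))
    body <- lines[!startsWith(lines, "#")]
    fields <- strsplit(body, "\t")
    cds_rows <- Filter(function(f) f[3] == "CDS", fields)
    for (f in cds_rows) {
      expect_lte(as.integer(f[4]), as.integer(f[5]))
      expect_equal(lengths(regmatches(f[9],
                                      gregexpr("Parent=", f[9]))), 1L)
    }
    # CDS sequences round-trip through the genome FASTA
    genome <- Biostrings::readDNAStringSet(file.path(dir,
                                                     paste0(v, ".fa")))
    names(genome) <- sub(" .*", "", names(genome))
    i <- which(want$gene_id == want$gene_id[1])
    sub <- Biostrings::subseq(genome[[want$chromosome[i]]],
                              want$start[i] + 1, want$end[i])
    expect_equal(as.character(sub), ds$cds[[want$gene_id[i]]])
  }
})

test_that("similarity hits link exactly the within-family gene pairs", {
  ds <- simulate_pangenome(small_cfg())
  fam <- ds$truth$gene_family
  same_family <- fam[ds$hits$qseqid] == fam[ds$hits$sseqid]
  expect_true(all(same_family))
  expect_true(all(ds$hits$evalue <= 1e-5))
  # every multi-member family is connected in the hit graph
  for (f in unique(stats::na.omit(fam))) {
    members <- names(fam)[!is.na(fam) & fam == f]
    if (length(members) < 2) next
    hit_members <- unique(c(
      ds$hits$qseqid[fam[ds$hits$qseqid] == f],
      ds$hits$sseqid[fam[ds$hits$sseqid] == f]))
    expect_setequal(stats::na.omit(hit_members), members)
  }
})
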