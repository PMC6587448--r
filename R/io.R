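# File-format plumbing: BLAST outfmt-6 tables, GFF3 gene models (via
# rtracklayer), FASTA (via Biostrings), OrthoMCL-style cluster text, and
# the synthetic-dataset writer with its checksum manifest.

.outfmt6_cols <- c("qseqid", "sseqid", "pident", "length", "mismatch",
                   "gapopen", "qstart", "qend", "sstart", "send",
                   "evalue", "bitscore")

#' Read a BLAST outfmt-6 table
#'
#' @param path TSV file with the 12 standard columns (no header).
#' @return data.frame with standard column names; coordinates are left in
#'   BLAST's 1-based inclusive convention.
#' @export
read_outfmt6 <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE, comment.char = "#",
                          col.names = .outfmt6_cols)
  df
}

#' Write a BLAST outfmt-6 table
#' @param hits data.frame with the 12 standard columns.
#' @param path output TSV path.
#' @export
write_outfmt6 <- function(hits, path) {
  stopifnot(all(.outfmt6_cols %in% names(hits)))
  utils::write.table(format(hits[.outfmt6_cols], scientific = TRUE,
                            trim = TRUE),
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# GRanges for a gene table (internal 0-based half-open -> 1-based inclusive)
.genes_to_gff_granges <- function(gene_df) {
  mk <- function(type, ids, parents = NA_character_) {
    gr <- GenomicRanges::GRanges(
      seqnames = gene_df$chromosome,
      ranges = IRanges::IRanges(start = gene_df$start + 1L,
                                end = gene_df$end),
      strand = gene_df$strand)
    S4Vectors::mcols(gr)$type <- type
    S4Vectors::mcols(gr)$ID <- ids
    S4Vectors::mcols(gr)$Parent <- parents
    S4Vectors::mcols(gr)$phase <- if (type == "CDS") 0L else NA_integer_
    gr
  }
  g <- mk("gene", gene_df$gene_id)
  m <- mk("mRNA", paste0(gene_df$gene_id, ".t1"), gene_df$gene_id)
  cchar <- mk("CDS", paste0(gene_df$gene_id, ".cds"),
              paste0(gene_df$gene_id, ".t1"))
  out <- c(g, m, cchar)
  out[order(as.character(GenomicRanges::seqnames(out)),
            GenomicRanges::start(out))]
}

#' Write gene models to GFF3
#'
#' Emits gene/mRNA/CDS rows (single-exon models), converting the internal
#' 0-based half-open coordinates to GFF3's 1-based inclusive convention.
#'
#' @param gene_df gene table with `gene_id`, `chromosome`, `start`, `end`,
#'   `strand`.
#' @param path output file.
#' @export
write_gff3 <- function(gene_df, path) {
  rtracklayer::export(.genes_to_gff_granges(gene_df), path, format = "gff3")
  invisible(path)
}

#' Read gene models from GFF3
#'
#' Inverse of [write_gff3()]: returns one row per gene feature with
#' internal 0-based half-open coordinates.
#'
#' @param path GFF3 file.
#' @return data.frame gene_id, chromosome, start, end, strand.
#' @export
read_gff3_genes <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[S4Vectors::mcols(gr)$type == "gene"]
  df <- data.frame(
    gene_id = as.character(S4Vectors::mcols(gr)$ID),
    chromosome = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    stringsAsFactors = FALSE)
  df[order(df$chromosome, df$start), ]
}

#' Write ortholog clusters as OrthoMCL-style text
#' @param clusters list of character vectors (members) named by cluster id.
#' @param path output file; lines look like `cl0001: geneA geneB`.
#' @export
write_clusters <- function(clusters, path) {
  lines <- vapply(names(clusters), function(id)
    paste0(id, ": ", paste(clusters[[id]], collapse = " ")), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read OrthoMCL-style cluster text
#' @param path file written by [write_clusters()].
#' @return named list of member vectors.
#' @export
read_clusters <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, ":\\s*")
  stats::setNames(lapply(parts, function(p) strsplit(p[2], "\\s+")[[1]]),
                  vapply(parts, `[[`, "", 1))
}

# chromosome sequences for one variety: intergenic spacer (deterministic
# from the dataset seed stream) + CDS in order
.build_chromosomes <- function(gene_df, cds, intergenic) {
  spacers <- function(n) paste(sample(c("A", "C", "G", "T"),
                                      n, replace = TRUE), collapse = "")
  out <- list()
  for (ch in unique(gene_df$chromosome)) {
    sel <- gene_df[gene_df$chromosome == ch, , drop = FALSE]
    pieces <- character(2 * nrow(sel))
    for (i in seq_len(nrow(sel))) {
      pieces[2 * i - 1] <- spacers(intergenic)
      pieces[2 * i] <- cds[[sel$gene_id[i]]]
    }
    out[[ch]] <- paste(pieces, collapse = "")
  }
  Biostrings::DNAStringSet(unlist(out))
}

#' Write a simulated dataset to disk
#'
#' Writes, per variety: genome FASTA, CDS FASTA, protein FASTA, and GFF3;
#' plus similarity hits (outfmt-6 TSV), the outgroup gene order, truth
#' tables (TSV), a YAML echo of the configuration, and a manifest with md5
#' checksums of every file.
#'
#' @param dataset,truth as returned by [simulate_pangenome()] (`truth` is
#'   `dataset$truth` when omitted).
#' @param dir output directory (created if needed).
#' @return data.frame manifest (file, md5), invisibly; also written as
#'   `manifest.tsv`.
#' @export
write_dataset <- function(dataset, dir, truth = dataset$truth) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  written <- character(0)
  add <- function(p) { written <<- c(written, p); p }

  genes <- dataset$genes
  set.seed(dataset$config$seed + 10007L)  # spacer stream
  for (v in unique(genes$variety)) {
    gv <- genes[genes$variety == v, , drop = FALSE]
    chrom <- .build_chromosomes(gv, dataset$cds, dataset$config$intergenic)
    Biostrings::writeXStringSet(chrom, add(file.path(dir, paste0(v, ".fa"))))
    Biostrings::writeXStringSet(
      Biostrings::DNAStringSet(dataset$cds[gv$gene_id]),
      add(file.path(dir, paste0(v, ".cds.fa"))))
    Biostrings::writeXStringSet(
      Biostrings::AAStringSet(dataset$proteins[gv$gene_id]),
      add(file.path(dir, paste0(v, ".faa"))))
    write_gff3(gv, add(file.path(dir, paste0(v, ".gff3"))))
  }
  write_outfmt6(dataset$hits, add(file.path(dir, "hits.tsv")))
  utils::write.table(dataset$outgroup, add(file.path(dir, "outgroup.tsv")),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  tt <- data.frame(gene_id = names(truth$gene_family),
                   family = truth$gene_family,
                   origin = truth$gene_origin[names(truth$gene_family)])
  utils::write.table(tt, add(file.path(dir, "truth_genes.tsv")),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  fl <- data.frame(family = names(truth$family_labels),
                   label = truth$family_labels)
  utils::write.table(fl, add(file.path(dir, "truth_families.tsv")),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  cfg <- dataset$config
  cfg_list <- cfg[setdiff(names(cfg), "phy")]
  yaml::write_yaml(cfg_list, add(file.path(dir, "config.yaml")))

  manifest <- data.frame(file = basename(written),
                         md5 = unname(tools::md5sum(written)),
                         stringsAsFactors = FALSE)
  utils::write.table(manifest, file.path(dir, "manifest.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(manifest)
}
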