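# Duplication-origin labelling: tandem arrays from homology + adjacency,
# collinear block detection by dynamic-programming chaining of anchor
# pairs, and the WGD/TD/other classification with its summary table.

#' Self-homolog pairs from an outfmt-6 table
#'
#' @param hits outfmt-6 data.frame of a within-proteome self-comparison.
#' @param evalue_cutoff maximum e-value (default 1e-20).
#' @return data.frame gene_a, gene_b (symmetric closure, self-pairs
#'   removed, deduplicated).
#' @export
self_homolog_pairs <- function(hits, evalue_cutoff = 1e-20) {
  keep <- hits$evalue <= evalue_cutoff & hits$qseqid != hits$sseqid
  a <- pmin(hits$qseqid[keep], hits$sseqid[keep])
  b <- pmax(hits$qseqid[keep], hits$sseqid[keep])
  u <- !duplicated(paste(a, b, sep = "\r"))
  data.frame(gene_a = a[u], gene_b = b[u], stringsAsFactors = FALSE)
}

#' Detect tandem arrays
#'
#' Maximal single-linkage groups of homologous genes on one chromosome in
#' which consecutive members are separated by fewer than `max_gap`
#' intervening genes (`max_gap = 1`: strictly adjacent).
#'
#' @param pairs homolog pair data.frame (gene_a, gene_b), e.g. from
#'   [self_homolog_pairs()].
#' @param gene_order data.frame gene_id, chromosome, order (1-based gene
#'   rank within its chromosome) covering every gene in `pairs`.
#' @param max_gap allowed intervening-gene count is `< max_gap`.
#' @return data.frame array_id, chromosome, gene_id, position (members in
#'   chromosomal order).
#' @export
detect_tandem_arrays <- function(pairs, gene_order, max_gap = 1) {
  missing <- setdiff(unique(c(pairs$gene_a, pairs$gene_b)),
                     gene_order$gene_id)
  if (length(missing))
    stop("genes absent from gene_order: ",
         paste(utils::head(missing, 5), collapse = ", "))
  ord <- stats::setNames(gene_order$order, gene_order$gene_id)
  chr <- stats::setNames(gene_order$chromosome, gene_order$gene_id)
  same_chr <- chr[pairs$gene_a] == chr[pairs$gene_b]
  gap_ok <- abs(ord[pairs$gene_a] - ord[pairs$gene_b]) - 1 < max_gap
  keep <- same_chr & gap_ok
  if (!any(keep))
    return(data.frame(array_id = character(0), chromosome = character(0),
                      gene_id = character(0), position = integer(0)))
  g <- igraph::graph_from_data_frame(
    pairs[keep, c("gene_a", "gene_b")], directed = FALSE)
  comp <- igraph::components(g)$membership
  members <- split(names(comp), comp)
  members <- members[lengths(members) >= 2]
  rows <- list()
  for (k in seq_along(members)) {
    m <- members[[k]]
    m <- m[order(ord[m])]
    rows[[k]] <- data.frame(array_id = sprintf("ta%04d", k),
                            chromosome = unname(chr[m[1]]), gene_id = m,
                            position = unname(ord[m]),
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  # stable array ids by first position
  firsts <- tapply(out$position, out$array_id, min)
  chr1 <- tapply(out$chromosome, out$array_id, `[[`, 1)
  remap <- stats::setNames(
    sprintf("ta%04d", order(order(chr1, firsts))), names(firsts))
  out$array_id <- unname(remap[out$array_id])
  out[order(out$array_id, out$position), , drop = FALSE]
}

#' Detect collinear blocks by chaining anchors
#'
#' Dynamic-programming chaining of anchor pairs between two genomes: a
#' chain extends when the query index increases and the subject index
#' increases (forward blocks) or decreases (inverted blocks), with
#' per-step gaps of at most `max_gap` skipped genes on both genomes.
#' Maximal chains of at least `min_block` anchors are reported; each
#' anchor joins at most one block (longest chain first).
#'
#' @param anchors data.frame gene_a, gene_b, pos_a, pos_b (gene-order
#'   indices on the two genomes; one chromosome pair at a time, or
#'   include columns chr_a/chr_b to chain within chromosome pairs).
#' @param min_block minimum anchors per block (default 15).
#' @param max_gap maximum skipped genes per step (default 1).
#' @return data.frame block_id, orientation, gene_a, gene_b, pos_a,
#'   pos_b.
#' @export
collinear_blocks <- function(anchors, min_block = 15, max_gap = 1) {
  if (!all(c("chr_a", "chr_b") %in% names(anchors))) {
    anchors$chr_a <- "a"; anchors$chr_b <- "b"
  }
  rownames(anchors) <- NULL
  out <- list()
  bi <- 0L
  for (key in unique(paste(anchors$chr_a, anchors$chr_b, sep = "\r"))) {
    sub <- anchors[paste(anchors$chr_a, anchors$chr_b, sep = "\r") == key, ,
                   drop = FALSE]
    for (orient in c("+", "-")) {
      sub2 <- sub
      if (orient == "-") sub2$pos_b <- -sub2$pos_b
      repeat {
        chain <- .best_chain(sub2, max_gap)
        if (length(chain) < min_block) break
        bi <- bi + 1L
        blk <- sub[match(rownames(sub2)[chain], rownames(sub)), ,
                   drop = FALSE]
        blk$block_id <- sprintf("cb%04d", bi)
        blk$orientation <- orient
        out[[bi]] <- blk
        sub2 <- sub2[-chain, , drop = FALSE]
        sub <- sub[match(rownames(sub2), rownames(sub)), , drop = FALSE]
      }
    }
  }
  if (!length(out))
    return(data.frame(block_id = character(0), orientation = character(0),
                      gene_a = character(0), gene_b = character(0),
                      pos_a = integer(0), pos_b = integer(0)))
  res <- do.call(rbind, c(out, list(make.row.names = FALSE)))
  res[, c("block_id", "orientation", "gene_a", "gene_b", "pos_a",
          "pos_b")]
}

# longest chain under the gap constraint (anchor count score);
# returns row indices of the chain, in order. Predecessors are found by
# binary search on the sorted query positions (the gap bound keeps the
# candidate window small).
.best_chain <- function(a, max_gap) {
  n <- nrow(a)
  if (!n) return(integer(0))
  o <- order(a$pos_a, a$pos_b)
  pa <- a$pos_a[o]; pb <- a$pos_b[o]
  score <- rep(1L, n)
  back <- rep(0L, n)
  for (j in seq_len(n)) {
    lo <- pa[j] - max_gap - 1L
    i1 <- findInterval(lo - 0.5, pa) + 1L
    i2 <- findInterval(pa[j] - 0.5, pa)     # strictly smaller pos_a
    if (i2 >= i1) for (i in i1:i2) {
      if (pb[j] > pb[i] && pb[j] - pb[i] - 1 <= max_gap &&
          score[i] + 1L > score[j]) {
        score[j] <- score[i] + 1L
        back[j] <- i
      }
    }
  }
  end <- which.max(score)
  chain <- integer(0)
  while (end != 0L) { chain <- c(end, chain); end <- back[end] }
  o[chain]
}

#' Classify gene duplication origin
#'
#' A gene is `WGD` when it participates in at least one anchor of a
#' collinear block against the outgroup, `TD` when it belongs to a
#' tandem array; `TD` takes precedence for genes qualifying for both;
#' everything else is `other`.
#'
#' @param genes character vector of gene ids (the classification
#'   universe).
#' @param arrays tandem-array table from [detect_tandem_arrays()].
#' @param blocks collinear-block table from [collinear_blocks()] (query
#'   genes in `gene_a`).
#' @return named character vector over `genes` with values
#'   `"WGD"`/`"TD"`/`"other"`.
#' @export
classify_duplication_origin <- function(genes, arrays, blocks) {
  lab <- stats::setNames(rep("other", length(genes)), genes)
  lab[genes %in% blocks$gene_a] <- "WGD"
  lab[genes %in% arrays$gene_id] <- "TD"
  lab
}

#' Summarise duplication classes within core/dispensable gene sets
#'
#' @param origin named `"WGD"`/`"TD"`/`"other"` vector
#'   ([classify_duplication_origin()]).
#' @param gene_category named `"core"`/`"dispensable"` vector over the
#'   same genes.
#' @param gene_variety named variety vector over the same genes.
#' @return data.frame with one row per (variety, category): total, wgd_n,
#'   wgd_pct, td_n, td_pct (percentages to 2 dp).
#' @export
summarize_by_class <- function(origin, gene_category, gene_variety) {
  genes <- names(origin)
  stopifnot(!is.null(genes), all(genes %in% names(gene_category)),
            all(genes %in% names(gene_variety)))
  df <- data.frame(gene = genes, origin = unname(origin),
                   category = unname(gene_category[genes]),
                   variety = unname(gene_variety[genes]))
  rows <- list()
  for (v in sort(unique(df$variety))) for (cat in c("core", "dispensable")) {
    sub <- df[df$variety == v & df$category == cat, , drop = FALSE]
    tot <- nrow(sub)
    wgd <- sum(sub$origin == "WGD"); td <- sum(sub$origin == "TD")
    rows[[length(rows) + 1L]] <- data.frame(
      variety = v, category = cat, total = tot,
      wgd_n = wgd, wgd_pct = if (tot) round(100 * wgd / tot, 2) else 0,
      td_n = td, td_pct = if (tot) round(100 * td / tot, 2) else 0,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
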