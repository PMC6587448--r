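# Core/dispensable partitioning of gene families and genome regions, and
# the composition summaries (cluster percentages, pan-genome sizes,
# group-unique family sets).

#' Membership matrix from clusters
#'
#' @param clusters named list of member gene vectors.
#' @param gene_variety named vector gene -> variety.
#' @param panel variety panel (columns); defaults to the observed set.
#' @return integer matrix clusters x varieties of member gene counts.
#' @export
membership_matrix <- function(clusters, gene_variety, panel = NULL) {
  if (is.null(panel)) panel <- sort(unique(gene_variety))
  m <- t(vapply(clusters, function(g)
    table(factor(gene_variety[g], levels = panel)), integer(length(panel))))
  colnames(m) <- panel
  m
}

#' Classify clusters as core or dispensable
#'
#' A cluster is core iff it has at least one member gene in every panel
#' variety; anything else (including single-variety clusters) is
#' dispensable.
#'
#' @param matrix membership matrix (clusters x varieties).
#' @param panel variety subset to classify against (default all columns).
#' @return named character vector `"core"`/`"dispensable"` per cluster.
#' @export
classify_clusters <- function(matrix, panel = colnames(matrix)) {
  if (!length(panel)) stop("empty panel")
  stopifnot(all(panel %in% colnames(matrix)))
  core <- rowSums(matrix[, panel, drop = FALSE] > 0) == length(panel)
  stats::setNames(ifelse(core, "core", "dispensable"), rownames(matrix))
}

#' Pan-genome composition summary
#'
#' Percentages are computed over clusters only; variety-specific
#' (unclustered) genes are reported separately and added to each
#' variety's dispensable gene count.
#'
#' @param labels named `"core"`/`"dispensable"` vector from
#'   [classify_clusters()].
#' @param matrix membership matrix (same clusters).
#' @param unclustered_by_variety named integer vector: count of
#'   unclustered genes per variety.
#' @return list of class `"pangenome_summary"`: n_clusters_total, n_core,
#'   n_dispensable_clusters, n_variety_specific_genes, pct_core,
#'   pct_dispensable, per_variety (data.frame core_genes,
#'   dispensable_genes).
#' @export
pangenome_composition <- function(labels, matrix = NULL,
                                  unclustered_by_variety = NULL) {
  n_total <- length(labels)
  n_core <- sum(labels == "core")
  n_disp <- n_total - n_core
  out <- list(n_clusters_total = n_total, n_core = n_core,
              n_dispensable_clusters = n_disp,
              n_variety_specific_genes =
                sum(unclustered_by_variety %||% 0),
              pct_core = round(100 * n_core / n_total, 2),
              pct_dispensable = round(100 * n_disp / n_total, 2))
  if (!is.null(matrix)) {
    stopifnot(setequal(rownames(matrix), names(labels)))
    lab <- labels[rownames(matrix)]
    core_genes <- colSums(matrix[lab == "core", , drop = FALSE])
    disp_genes <- colSums(matrix[lab == "dispensable", , drop = FALSE])
    if (!is.null(unclustered_by_variety)) {
      extra <- unclustered_by_variety[colnames(matrix)]
      extra[is.na(extra)] <- 0
      disp_genes <- disp_genes + extra
    }
    out$per_variety <- data.frame(variety = colnames(matrix),
                                  core_genes = as.integer(core_genes),
                                  dispensable_genes = as.integer(disp_genes),
                                  row.names = NULL)
  }
  class(out) <- "pangenome_summary"
  out
}

#' @exportS3Method base::print
print.pangenome_summary <- function(x, ...) {
  cat("Pan-genome composition\n")
  cat(sprintf("  clusters: %d total; %d core (%.2f%%), %d dispensable (%.2f%%)\n",
              x$n_clusters_total, x$n_core, x$pct_core,
              x$n_dispensable_clusters, x$pct_dispensable))
  cat(sprintf("  variety-specific genes: %d\n",
              x$n_variety_specific_genes))
  if (!is.null(x$per_variety)) {
    cat("  per-variety gene counts:\n")
    print(x$per_variety, row.names = FALSE)
  }
  invisible(x)
}

#' Partition genome regions into core/dispensable/pan sizes
#'
#' Blocks present in every panel variety contribute their representative
#' span (longest member span, counted once) to the core genome; blocks in
#' a proper subset contribute to the dispensable genome, as does each
#' variety's unaligned sequence (genome length minus its aligned bp,
#' after merging overlapping spans).
#'
#' @param blocks data.frame block_id, variety, chromosome, start, end
#'   (0-based half-open; one row per variety a block is present in).
#' @param genome_lengths named vector of total genome length per variety.
#' @param panel variety panel.
#' @return list core_bp, dispensable_bp, pan_bp, aligned_bp (per
#'   variety).
#' @export
partition_genome_regions <- function(blocks, genome_lengths,
                                     panel = names(genome_lengths)) {
  stopifnot(all(blocks$start < blocks$end))
  stopifnot(all(blocks$variety %in% names(genome_lengths)))
  # merged aligned length per variety
  aligned <- stats::setNames(numeric(length(panel)), panel)
  for (v in panel) {
    bv <- blocks[blocks$variety == v, , drop = FALSE]
    if (!nrow(bv)) next
    if (any(bv$end > genome_lengths[[v]]))
      stop("block span exceeds genome length for ", v)
    ir <- IRanges::reduce(IRanges::IRanges(start = bv$start + 1L,
                                           end = bv$end))
    aligned[v] <- sum(IRanges::width(ir))
  }
  span_len <- blocks$end - blocks$start
  rep_len_by_block <- tapply(span_len, blocks$block_id, max)
  present <- tapply(blocks$variety, blocks$block_id,
                    function(v) length(unique(v)))
  is_core <- present == length(panel)
  core_bp <- sum(rep_len_by_block[is_core])
  disp_blocks_bp <- sum(rep_len_by_block[!is_core])
  unaligned_bp <- sum(genome_lengths[panel] - aligned[panel])
  dispensable_bp <- disp_blocks_bp + unaligned_bp
  list(core_bp = unname(core_bp),
       dispensable_bp = unname(dispensable_bp),
       pan_bp = unname(core_bp + dispensable_bp),
       aligned_bp = aligned)
}

#' Families and specific genes unique to variety groups
#'
#' @param matrix membership matrix.
#' @param unclustered_by_variety named counts of unclustered genes.
#' @param group_a,group_b disjoint variety sets (subsets of the panel).
#' @return list families_unique_a, specific_genes_a, families_unique_b,
#'   specific_genes_b (family id vectors / gene counts).
#' @export
group_unique_sets <- function(matrix, unclustered_by_variety,
                              group_a, group_b) {
  if (length(intersect(group_a, group_b)))
    stop("groups must be disjoint")
  stopifnot(all(c(group_a, group_b) %in% colnames(matrix)))
  in_a <- rowSums(matrix[, group_a, drop = FALSE] > 0) > 0
  in_b <- rowSums(matrix[, group_b, drop = FALSE] > 0) > 0
  list(
    families_unique_a = rownames(matrix)[in_a & !in_b],
    specific_genes_a = sum(unclustered_by_variety[group_a], na.rm = TRUE),
    families_unique_b = rownames(matrix)[in_b & !in_a],
    specific_genes_b = sum(unclustered_by_variety[group_b], na.rm = TRUE))
}

#' Synthetic alignment blocks with planted core/dispensable structure
#'
#' Generates region blocks over a variety panel: `n_core` blocks present
#' in every variety and `n_disp` blocks present in random proper
#' subsets, with block lengths drawn uniformly from `len_range`; each
#' variety's genome length is the sum of its block spans plus
#' `unaligned_per_variety` unique sequence.
#'
#' @param panel variety names.
#' @param n_core,n_disp block counts.
#' @param len_range block length range (bp).
#' @param unaligned_per_variety extra unaligned bp per variety.
#' @param seed integer seed.
#' @return list `blocks` (data.frame), `genome_lengths`, and `truth`
#'   (core_bp, dispensable_bp, pan_bp).
#' @export
sim_region_blocks <- function(panel, n_core = 50, n_disp = 30,
                              len_range = c(1000, 10000),
                              unaligned_per_variety = 20000, seed = 1) {
  set.seed(seed)
  nb <- n_core + n_disp
  lens <- sample(seq(len_range[1], len_range[2]), nb, replace = TRUE)
  ids <- sprintf("blk%04d", seq_len(nb))
  present <- c(replicate(n_core, panel, simplify = FALSE),
               replicate(n_disp,
                         sort(sample(panel,
                                     sample(length(panel) - 1L, 1))),
                         simplify = FALSE))
  rows <- list()
  offset <- stats::setNames(rep(0L, length(panel)), panel)
  for (k in seq_len(nb)) {
    for (v in present[[k]]) {
      rows[[length(rows) + 1L]] <- data.frame(
        block_id = ids[k], variety = v, chromosome = "chr01",
        start = offset[[v]], end = offset[[v]] + lens[k],
        stringsAsFactors = FALSE)
      offset[v] <- offset[v] + lens[k]
    }
  }
  blocks <- do.call(rbind, rows)
  genome_lengths <- offset + unaligned_per_variety
  core_bp <- sum(lens[seq_len(n_core)])
  disp_bp <- sum(lens[n_core + seq_len(n_disp)]) +
    length(panel) * unaligned_per_variety
  list(blocks = blocks, genome_lengths = genome_lengths,
       truth = list(core_bp = core_bp, dispensable_bp = disp_bp,
                    pan_bp = core_bp + disp_bp))
}
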