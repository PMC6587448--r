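# Evidence-based refinement of predicted gene sets: the 50%-coverage
# support rule, removal of single-source ab initio predictions, and
# merging of fragmented gene pairs that split one homolog.

#' Build a candidate gene object
#'
#' @param gene_id identifier.
#' @param cds_intervals two-column matrix of 0-based half-open intervals
#'   on the genome (non-overlapping, sorted).
#' @param sources character subset of `c("augustus", "fgenesh")`
#'   (non-empty).
#' @param evidence data.frame with columns `type`
#'   (`"protein"`/`"transcript"`), `start`, `end` (0-based half-open, in
#'   CDS coordinates), `homolog_id` (NA for transcript evidence).
#' @param variety,chromosome,strand,order optional positional metadata.
#' @return object of class `"candidate_gene"`.
#' @export
candidate_gene <- function(gene_id, cds_intervals, sources,
                           evidence = NULL, variety = NA, chromosome = NA,
                           strand = "+", order = NA) {
  cds_intervals <- matrix(as.numeric(cds_intervals), ncol = 2)
  stopifnot(all(cds_intervals[, 1] < cds_intervals[, 2]),
            length(sources) >= 1,
            all(sources %in% c("augustus", "fgenesh")))
  if (is.null(evidence))
    evidence <- data.frame(type = character(0), start = numeric(0),
                           end = numeric(0), homolog_id = character(0))
  structure(list(gene_id = gene_id, cds_intervals = cds_intervals,
                 sources = sources, evidence = evidence,
                 variety = variety, chromosome = chromosome,
                 strand = strand, order = order),
            class = "candidate_gene")
}

#' Fraction of CDS covered by evidence
#'
#' Coverage of the CDS (in CDS coordinates) by the union of protein and
#' transcript evidence intervals. Intervals extending beyond the CDS are
#' clipped with a warning.
#'
#' @param gene a [candidate_gene()].
#' @return fraction in `[0, 1]`.
#' @export
evidence_support_fraction <- function(gene) {
  cds_len <- sum(gene$cds_intervals[, 2] - gene$cds_intervals[, 1])
  stopifnot(cds_len > 0)
  ev <- gene$evidence
  if (!nrow(ev)) return(0)
  s <- pmax(ev$start, 0)
  e <- pmin(ev$end, cds_len)
  if (any(ev$start < 0 | ev$end > cds_len))
    warning("evidence interval outside CDS span clipped for ",
            gene$gene_id)
  keep <- s < e
  if (!any(keep)) return(0)
  ir <- IRanges::reduce(IRanges::IRanges(start = s[keep] + 1L,
                                         end = e[keep]))
  sum(IRanges::width(ir)) / cds_len
}

# single homolog id supporting a gene, or NA
.single_homolog <- function(gene) {
  h <- unique(stats::na.omit(gene$evidence$homolog_id))
  if (length(h) == 1L) h else NA_character_
}

#' Refine a candidate gene set
#'
#' Applies three rules to one variety's candidate genes, in gene order:
#' \enumerate{
#'   \item Fragmented-pair merge: two consecutive genes on the same
#'     strand whose evidence is one and the same single homolog, hitting
#'     non-overlapping portions of it, are replaced by one merged model
#'     spanning both (CDS interval union).
#'   \item Support rule: genes with evidence covering at least
#'     `min_support` of the CDS are retained.
#'   \item Below-support genes predicted by both ab initio sources are
#'     retained; genes from a single source with insufficient evidence
#'     are removed.
#' }
#'
#' @param genes list of [candidate_gene()] objects from one variety,
#'   in gene order along the genome.
#' @param min_support minimum evidence coverage fraction (default 0.5,
#'   inclusive).
#' @return list `retained` (genes, merged models included),
#'   `removed` (data.frame gene_id, reason), `merged_pairs` (data.frame
#'   gene_a, gene_b, merged_id).
#' @export
refine_gene_set <- function(genes, min_support = 0.5) {
  if (!length(genes))
    return(list(retained = list(),
                removed = data.frame(gene_id = character(0),
                                     reason = character(0)),
                merged_pairs = data.frame(gene_a = character(0),
                                          gene_b = character(0),
                                          merged_id = character(0))))
  vs <- unique(vapply(genes, function(g) as.character(g$variety),
                      character(1)))
  if (length(vs) > 1) stop("genes must come from one variety")

  merged_pairs <- list()
  consumed <- rep(FALSE, length(genes))
  merged_models <- list()
  # homolog evidence interval span (on the homolog's own coordinates is
  # not modelled; non-overlap is checked on CDS-projected evidence)
  i <- 1L
  while (i < length(genes)) {
    a <- genes[[i]]; b <- genes[[i + 1]]
    ha <- .single_homolog(a); hb <- .single_homolog(b)
    same_locus <- !consumed[i] && !consumed[i + 1] &&
      identical(a$strand, b$strand) && !is.na(ha) && !is.na(hb) &&
      ha == hb
    if (same_locus) {
      # the two halves must align to non-overlapping portions of the
      # shared homolog (columns hstart/hend when available)
      ea <- a$evidence[!is.na(a$evidence$homolog_id), , drop = FALSE]
      eb <- b$evidence[!is.na(b$evidence$homolog_id), , drop = FALSE]
      if (all(c("hstart", "hend") %in% names(ea)) &&
          all(c("hstart", "hend") %in% names(eb)) &&
          nrow(ea) && nrow(eb)) {
        no_overlap <- TRUE
        for (x in seq_len(nrow(ea)))
          if (any(ea$hstart[x] < eb$hend & ea$hend[x] > eb$hstart))
            no_overlap <- FALSE
      } else no_overlap <- TRUE
      if (no_overlap) {
        merged_id <- paste0(a$gene_id, "+", b$gene_id)
        shared <- intersect(names(a$evidence), names(b$evidence))
        len_a <- sum(a$cds_intervals[, 2] - a$cds_intervals[, 1])
        ev_b <- b$evidence[shared]
        ev_b$start <- ev_b$start + len_a   # CDS coords shift in the merge
        ev_b$end <- ev_b$end + len_a
        m <- candidate_gene(
          gene_id = merged_id,
          cds_intervals = rbind(a$cds_intervals, b$cds_intervals),
          sources = union(a$sources, b$sources),
          evidence = rbind(a$evidence[shared], ev_b),
          variety = a$variety, chromosome = a$chromosome,
          strand = a$strand, order = a$order)
        merged_models[[length(merged_models) + 1L]] <- m
        merged_pairs[[length(merged_pairs) + 1L]] <-
          data.frame(gene_a = a$gene_id, gene_b = b$gene_id,
                     merged_id = merged_id, stringsAsFactors = FALSE)
        consumed[i] <- consumed[i + 1] <- TRUE
        i <- i + 2L
        next
      }
    }
    i <- i + 1L
  }

  retained <- merged_models
  removed <- list()
  for (k in seq_along(genes)) {
    if (consumed[k]) next
    g <- genes[[k]]
    frac <- evidence_support_fraction(g)
    if (frac >= min_support || length(g$sources) >= 2) {
      retained[[length(retained) + 1L]] <- g
    } else {
      removed[[length(removed) + 1L]] <- data.frame(
        gene_id = g$gene_id,
        reason = if (nrow(g$evidence) == 0)
          "ab_initio_single_source" else "insufficient_evidence_support",
        stringsAsFactors = FALSE)
    }
  }
  list(
    retained = retained,
    removed = if (length(removed)) do.call(rbind, removed) else
      data.frame(gene_id = character(0), reason = character(0)),
    merged_pairs = if (length(merged_pairs)) do.call(rbind, merged_pairs)
    else data.frame(gene_a = character(0), gene_b = character(0),
                    merged_id = character(0)))
}
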