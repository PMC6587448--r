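# Reference-assisted scaffolding: place draft fragments onto reference
# chromosomes by a best-vs-second-best score-ratio rule, join placed
# fragments with N linkers, and compute assembly statistics.

#' Convert an outfmt-6 hit table to alignment hits
#'
#' Converts BLAST's 1-based inclusive coordinates to the internal 0-based
#' half-open convention and derives strand from subject coordinates.
#'
#' @param hits outfmt-6 data.frame ([read_outfmt6()]): query = fragment,
#'   subject = reference chromosome.
#' @return data.frame fragment_id, reference_chromosome, fragment_start,
#'   fragment_end, reference_start, reference_end, strand, score,
#'   identity.
#' @export
hits_to_alignments <- function(hits) {
  minus <- hits$sstart > hits$send
  rs <- ifelse(minus, hits$send, hits$sstart)
  re <- ifelse(minus, hits$sstart, hits$send)
  data.frame(fragment_id = hits$qseqid,
             reference_chromosome = hits$sseqid,
             fragment_start = pmin(hits$qstart, hits$qend) - 1L,
             fragment_end = pmax(hits$qstart, hits$qend),
             reference_start = rs - 1L,
             reference_end = re,
             strand = ifelse(minus, "-", "+"),
             score = hits$bitscore,
             identity = hits$pident / 100,
             stringsAsFactors = FALSE)
}

# Merge co-linear hits of one fragment to one chromosome/strand whose
# reference positions fall within a window of the fragment length; summed
# score approximates a whole-fragment placement score.
.merge_fragment_hits <- function(h, fragment_length) {
  groups <- list()
  for (key in unique(paste(h$reference_chromosome, h$strand))) {
    sub <- h[paste(h$reference_chromosome, h$strand) == key, , drop = FALSE]
    sub <- sub[order(sub$reference_start), , drop = FALSE]
    brk <- cumsum(c(1, diff(sub$reference_start) > fragment_length))
    for (b in unique(brk)) {
      g <- sub[brk == b, , drop = FALSE]
      groups[[length(groups) + 1L]] <- data.frame(
        reference_chromosome = g$reference_chromosome[1],
        strand = g$strand[1],
        score = sum(g$score),
        anchor = min(g$reference_start),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, groups)
  out[order(-out$score, out$reference_chromosome, out$anchor), ,
      drop = FALSE]
}

#' Place fragments on reference chromosomes by the score-ratio rule
#'
#' For each fragment, co-linear hits to one chromosome/strand are merged
#' (scores summed) into candidate locations; the fragment is `placed` at
#' its best location iff best/second-best score >= `ratio_threshold`
#' (inclusive; a single candidate always places), otherwise `ambiguous`.
#' Fragments of `fragment_lengths` with no hits are `unplaced`.
#'
#' @param hits alignment-hit data.frame ([hits_to_alignments()]).
#' @param fragment_lengths named vector of fragment lengths (defines the
#'   fragment universe; fragments absent from `hits` are reported
#'   unplaced).
#' @param ratio_threshold minimum best/second-best score ratio (> 1).
#' @return data.frame fragment_id, status (placed/ambiguous/unplaced),
#'   reference_chromosome, orientation, reference_anchor_position.
#' @export
place_fragments <- function(hits, fragment_lengths,
                            ratio_threshold = 1.05) {
  stopifnot(ratio_threshold > 1)
  if (nrow(hits) && any(hits$score <= 0)) stop("scores must be positive")
  res <- list()
  for (fid in unique(hits$fragment_id)) {
    h <- hits[hits$fragment_id == fid, , drop = FALSE]
    flen <- if (fid %in% names(fragment_lengths))
      fragment_lengths[[fid]] else max(h$fragment_end)
    cand <- .merge_fragment_hits(h, flen)
    placed <- nrow(cand) == 1L ||
      cand$score[1] / cand$score[2] >= ratio_threshold
    res[[fid]] <- data.frame(
      fragment_id = fid,
      status = if (placed) "placed" else "ambiguous",
      reference_chromosome = if (placed) cand$reference_chromosome[1]
      else NA_character_,
      orientation = if (placed) cand$strand[1] else NA_character_,
      reference_anchor_position = if (placed) cand$anchor[1] else
        NA_real_,
      stringsAsFactors = FALSE)
  }
  nohit <- setdiff(names(fragment_lengths), unique(hits$fragment_id))
  for (fid in nohit)
    res[[fid]] <- data.frame(fragment_id = fid, status = "unplaced",
                             reference_chromosome = NA_character_,
                             orientation = NA_character_,
                             reference_anchor_position = NA_real_,
                             stringsAsFactors = FALSE)
  out <- do.call(rbind, c(res, list(make.row.names = FALSE)))
  out[match(unique(c(names(fragment_lengths), out$fragment_id)),
            out$fragment_id), , drop = FALSE]
}

#' Build pseudomolecules from placements
#'
#' Concatenates placed fragments per chromosome in order of their
#' reference anchor position (ties broken by fragment id), reverse
#' complementing minus-strand fragments, separated by `gap_length` N
#' characters. Ambiguous and unplaced fragments go to the unplaced bin.
#'
#' @param placements data.frame from [place_fragments()].
#' @param fragments `Biostrings::DNAStringSet` (or named character
#'   vector) of fragment sequences.
#' @param gap_length N-linker length between joined fragments.
#' @return list `pseudomolecules` (DNAStringSet, one per chromosome) and
#'   `unplaced` (DNAStringSet).
#' @export
build_pseudomolecules <- function(placements, fragments, gap_length = 100) {
  if (!methods::is(fragments, "DNAStringSet"))
    fragments <- Biostrings::DNAStringSet(fragments)
  if (anyDuplicated(placements$fragment_id))
    stop("duplicate placement of a fragment")
  placed <- placements[placements$status == "placed", , drop = FALSE]
  rest <- placements$fragment_id[placements$status != "placed"]
  gap <- paste(rep("N", gap_length), collapse = "")
  pieces <- list()
  for (chr in sort(unique(placed$reference_chromosome))) {
    sub <- placed[placed$reference_chromosome == chr, , drop = FALSE]
    sub <- sub[order(sub$reference_anchor_position, sub$fragment_id), ,
               drop = FALSE]
    seqs <- character(nrow(sub))
    for (i in seq_len(nrow(sub))) {
      s <- fragments[[sub$fragment_id[i]]]
      if (sub$orientation[i] == "-") s <- Biostrings::reverseComplement(s)
      seqs[i] <- as.character(s)
    }
    pieces[[chr]] <- paste(seqs, collapse = gap)
  }
  list(pseudomolecules = Biostrings::DNAStringSet(unlist(pieces)),
       unplaced = fragments[rest])
}

#' Assembly statistics (total length, N50, count)
#'
#' N50 is the largest length L such that fragments of length >= L sum to
#' at least half the assembly, found by scanning lengths in decreasing
#' order of cumulative sum.
#'
#' @param lengths positive fragment/scaffold lengths.
#' @return list `total_length`, `N50`, `count`.
#' @export
assembly_stats <- function(lengths) {
  if (!length(lengths)) stop("empty length set")
  if (any(lengths <= 0)) stop("lengths must be positive")
  s <- sort(lengths, decreasing = TRUE)
  cs <- cumsum(s)
  n50 <- s[which(cs >= sum(s) / 2)[1]]
  list(total_length = sum(s), N50 = n50, count = length(s))
}

#' Shred a genome into fragments (synthetic scaffolding input)
#'
#' Cuts each chromosome into consecutive fragments of approximately
#' `mean_length` bp and emits perfect alignment hits recording each
#' fragment's true origin — input for scaffolding round-trip experiments.
#'
#' @param genome `DNAStringSet` of chromosomes.
#' @param mean_length target fragment length.
#' @return list `fragments` (DNAStringSet), `hits` (alignment-hit
#'   data.frame), `truth` (fragment_id, chromosome, start).
#' @export
shred_genome <- function(genome, mean_length = 5000) {
  frags <- list(); rows <- list()
  k <- 0L
  for (chr in names(genome)) {
    len <- length(genome[[chr]])
    starts <- seq(1L, len, by = mean_length)
    for (s in starts) {
      e <- min(s + mean_length - 1L, len)
      if (e - s + 1 < 50) next
      k <- k + 1L
      fid <- sprintf("frag%05d", k)
      frags[[fid]] <- as.character(genome[[chr]][s:e])
      rows[[k]] <- data.frame(
        fragment_id = fid, reference_chromosome = chr,
        fragment_start = 0L, fragment_end = e - s + 1L,
        reference_start = s - 1L, reference_end = e,
        strand = "+", score = (e - s + 1) * 2, identity = 1,
        stringsAsFactors = FALSE)
    }
  }
  truth <- do.call(rbind, rows)
  list(fragments = Biostrings::DNAStringSet(unlist(frags)),
       hits = truth[, c("fragment_id", "reference_chromosome",
                        "fragment_start", "fragment_end",
                        "reference_start", "reference_end", "strand",
                        "score", "identity")],
       truth = truth[, c("fragment_id", "reference_chromosome",
                         "reference_start")])
}
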