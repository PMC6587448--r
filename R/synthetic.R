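# Synthetic multi-variety pan-genome generator. Produces gene sets with
# controlled core/dispensable/variety-specific family structure, planted
# tandem arrays and duplicated (WGD-like) blocks, coding sequences evolved
# under a GY94 codon model along the variety tree, all-vs-all similarity
# hits derived from the evolved sequences, and a shuffled outgroup gene
# order for collinearity detection — everything with planted ground truth.

.default_varieties <- c("zz13", "yz11", "bzm", "mszm", "swetha")

# Variety tree: topology and divergence times follow the five-variety
# design (modern Chinese pair split most recently, the Indian lineage
# basal); branch lengths in expected substitutions per codon assuming a
# uniform rate of 0.01 substitutions/codon/MY.
.default_variety_tree <- paste0(
  "((((zz13:0.009,yz11:0.009):0.038,bzm:0.047):0.008,",
  "mszm:0.055):0.087,swetha:0.142);")

#' Configuration for the synthetic pan-genome generator
#'
#' Collects all knobs of the generator with validation. The defaults model
#' a five-variety panel: a dominant core (ratio of core to dispensable
#' families similar to real pan-genomes), dispensable families present in
#' random proper subsets, and a modest count of variety-specific genes
#' with no homolog anywhere else.
#'
#' @param varieties character vector of variety names.
#' @param tree Newick string over the varieties, branch lengths in
#'   substitutions per codon site.
#' @param n_core_families,n_dispensable_families family counts.
#' @param dispensable_presence optional list of character vectors (one per
#'   dispensable family): which varieties carry the family. Each must be a
#'   proper, non-empty subset of `varieties`. Default: random subsets.
#' @param n_specific_genes variety-specific gene count per variety
#'   (recycled over varieties).
#' @param td_arrays list of `list(variety=, array_size=, chromosome=)`
#'   tandem arrays to plant.
#' @param wgd_blocks list of `list(variety=, block_anchor_count=)`
#'   duplicated blocks to plant.
#' @param omega,kappa GY94 parameters used to evolve family sequences
#'   (omega may be a single background value).
#' @param cds_len gene length in codons.
#' @param n_chromosomes chromosomes per variety.
#' @param intergenic intergenic spacer length (bp).
#' @param copy_divergence per-nucleotide mutation probability applied to
#'   planted duplicate copies.
#' @param seed integer; fully determines the output.
#' @return an object of class `"sim_config"`.
#' @export
sim_config <- function(varieties = .default_varieties,
                       tree = NULL,
                       n_core_families = 500,
                       n_dispensable_families = 100,
                       dispensable_presence = NULL,
                       n_specific_genes = 40,
                       td_arrays = list(),
                       wgd_blocks = list(),
                       omega = 0.2, kappa = 2.5,
                       cds_len = 300,
                       n_chromosomes = 13,
                       intergenic = 200,
                       copy_divergence = 0.02,
                       seed = 1) {
  stopifnot(length(varieties) >= 2, !anyDuplicated(varieties),
            n_core_families >= 0, n_dispensable_families >= 0,
            all(n_specific_genes >= 0), cds_len >= 10,
            n_chromosomes >= 1, intergenic >= 0,
            copy_divergence >= 0, copy_divergence < 1)
  if (is.null(tree)) {
    if (!identical(varieties, .default_varieties))
      stop("supply a tree when using non-default varieties")
    tree <- .default_variety_tree
  }
  phy <- ape::read.tree(text = tree)
  if (!setequal(phy$tip.label, varieties))
    stop("tree tips must match varieties")
  if (!is.null(dispensable_presence)) {
    if (length(dispensable_presence) != n_dispensable_families)
      stop("dispensable_presence must have one subset per dispensable family")
    ok <- vapply(dispensable_presence, function(s)
      length(s) >= 1 && length(s) < length(varieties) &&
        all(s %in% varieties), logical(1))
    if (!all(ok))
      stop("each dispensable presence set must be a proper non-empty subset")
  }
  n_specific_genes <- rep(n_specific_genes, length.out = length(varieties))
  names(n_specific_genes) <- varieties
  for (td in td_arrays)
    stopifnot(td$variety %in% varieties, td$array_size >= 2)
  for (wb in wgd_blocks)
    stopifnot(wb$variety %in% varieties, wb$block_anchor_count >= 2)
  structure(list(varieties = varieties, tree = tree, phy = phy,
                 n_core_families = n_core_families,
                 n_dispensable_families = n_dispensable_families,
                 dispensable_presence = dispensable_presence,
                 n_specific_genes = n_specific_genes,
                 td_arrays = td_arrays, wgd_blocks = wgd_blocks,
                 omega = omega, kappa = kappa, cds_len = cds_len,
                 n_chromosomes = n_chromosomes, intergenic = intergenic,
                 copy_divergence = copy_divergence,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Evolve one gene family along a tree with branch-specific omega
#'
#' Wrapper around the GY94 simulator taking a per-branch omega map keyed
#' by the label of the node/tip each branch leads to.
#'
#' @param ancestor_cds root coding sequence (length divisible by 3, no
#'   internal stops).
#' @param tree `ape::phylo` or Newick string with branch lengths
#'   (substitutions/codon).
#' @param omega_map named numeric vector: child label -> omega. Must cover
#'   every branch (internal branches are keyed by node label, or supply a
#'   single unnamed value for all).
#' @param kappa transition/transversion ratio.
#' @param seed integer seed.
#' @return named character vector of per-taxon CDS (gap-free, aligned by
#'   construction).
#' @export
evolve_family <- function(ancestor_cds, tree, omega_map, kappa = 2.5,
                          seed = 1) {
  if (is.character(tree)) tree <- ape::read.tree(text = tree)
  if (nchar(ancestor_cds) %% 3L != 0L)
    stop("ancestor length must be divisible by 3")
  if (anyNA(codon_index(ancestor_cds)))
    stop("ancestor contains stop codons")
  ne <- nrow(tree$edge)
  if (length(omega_map) == 1L && is.null(names(omega_map))) {
    omega <- rep(omega_map, ne)
  } else {
    labs <- c(tree$tip.label,
              tree$node.label %||% rep(NA_character_, tree$Nnode))
    child_lab <- labs[tree$edge[, 2]]
    omega <- unname(omega_map[child_lab])
    if (anyNA(omega))
      stop("omega_map missing branches: ",
           paste(child_lab[is.na(omega)], collapse = ", "))
  }
  set.seed(seed)
  sim <- sim_codon_alignment(tree, kappa = kappa, omega = omega,
                             ancestor = ancestor_cds)
  sim$sequences
}

# Point-mutate a CDS at the given per-nucleotide rate, rejecting mutations
# that create stop codons (matching the simulator's convention).
mutate_cds <- function(seq, rate) {
  if (rate <= 0) return(seq)
  chars <- strsplit(seq, "")[[1]]
  hit <- which(stats::runif(length(chars)) < rate)
  stops <- codon_tables()$stop_codons
  for (i in hit) {
    old <- chars[i]
    new <- sample(setdiff(c("A", "C", "G", "T"), old), 1)
    cod_start <- 3L * ((i - 1L) %/% 3L) + 1L
    cand <- chars[cod_start:(cod_start + 2L)]
    cand[i - cod_start + 1L] <- new
    if (!paste(cand, collapse = "") %in% stops) chars[i] <- new
  }
  paste(chars, collapse = "")
}

#' Generate a synthetic multi-variety pan-genome with ground truth
#'
#' Lays core families (one gene per variety) and dispensable families
#' (genes only in their presence subset) in a conserved canonical order on
#' `n_chromosomes` chromosomes, inserts variety-specific genes (fresh
#' random coding sequences with no homolog anywhere), plants the
#' configured tandem arrays and duplicated blocks, and derives all-vs-all
#' similarity hits from the evolved sequences. The outgroup gene order is
#' a deterministic shuffle of the family order in which only planted
#' duplicated-block regions remain collinear, so block detection against
#' the outgroup recovers exactly the planted blocks.
#'
#' @param config a [sim_config()] object.
#' @return list with `genes` (data.frame: gene_id, variety, chromosome,
#'   order, start, end, strand, family), `cds` / `proteins` (named
#'   character vectors), `hits` (outfmt-6-style data.frame),
#'   `outgroup` (data.frame gene_id, family, order), `anchors`
#'   (per-variety list of anchor pair data.frames vs the outgroup),
#'   `config`, and `truth` (list: `family_labels`, `gene_family`,
#'   `gene_origin`, `tree`).
#' @export
simulate_pangenome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  vs <- config$varieties
  nv <- length(vs)
  phy <- config$phy

  n_core <- config$n_core_families
  n_disp <- config$n_dispensable_families
  fam_ids <- sprintf("fam%04d", seq_len(n_core + n_disp))
  fam_label <- c(rep("core", n_core), rep("dispensable", n_disp))
  names(fam_label) <- fam_ids

  presence <- vector("list", n_core + n_disp)
  for (i in seq_len(n_core)) presence[[i]] <- vs
  if (n_disp > 0) {
    if (is.null(config$dispensable_presence)) {
      # random proper subsets of size >= 2: singleton families could
      # never form a cluster and would blur the family/specific boundary
      k_lo <- min(2L, nv - 1L)
      for (i in seq_len(n_disp)) {
        k <- if (k_lo >= nv - 1L) nv - 1L else sample(k_lo:(nv - 1L), 1)
        presence[[n_core + i]] <- sort(sample(vs, k))
      }
    } else {
      for (i in seq_len(n_disp))
        presence[[n_core + i]] <- sort(config$dispensable_presence[[i]])
    }
  }
  names(presence) <- fam_ids

  # evolve all families in one pass (same tree and parameters)
  L <- config$cds_len
  nfam <- n_core + n_disp
  tipseq <- NULL
  if (nfam > 0) {
    anc <- random_cds(L * nfam)
    sim <- sim_codon_alignment(phy, kappa = config$kappa,
                               omega = config$omega, ancestor = anc)
    tipseq <- sim$sequences
  }
  fam_cds <- function(variety, fam_i)
    substr(tipseq[[variety]], (fam_i - 1L) * 3L * L + 1L, fam_i * 3L * L)

  # independent family order per variety: planted syntenic runs must be
  # variety-specific, so cross-variety gene-order conservation is not
  # modelled (see the methods vignette)
  genes <- list(); cds <- list()
  for (v in vs) {
    fam_order <- sample(fam_ids)
    fams_v <- fam_order[vapply(fam_order, function(f) v %in% presence[[f]],
                               logical(1))]
    ids <- sprintf("%s_g%04d", v, seq_along(fams_v))
    cds_v <- vapply(seq_along(fams_v), function(k)
      fam_cds(v, match(fams_v[k], fam_ids)), character(1))
    df <- data.frame(gene_id = ids, variety = v, family = fams_v,
                     stringsAsFactors = FALSE)
    # insert variety-specific genes at random positions
    nspec <- config$n_specific_genes[[v]]
    if (nspec > 0) {
      sids <- sprintf("%s_s%03d", v, seq_len(nspec))
      sdf <- data.frame(gene_id = sids, variety = v, family = NA_character_,
                        stringsAsFactors = FALSE)
      pos <- sort(sample(seq_len(nrow(df) + nspec), nspec))
      all_n <- nrow(df) + nspec
      out <- data.frame(gene_id = character(all_n), variety = v,
                        family = NA_character_, stringsAsFactors = FALSE)
      out[pos, ] <- sdf
      out[setdiff(seq_len(all_n), pos), ] <- df
      df <- out
      cds_v <- c(cds_v, vapply(seq_len(nspec), function(i) random_cds(L),
                               character(1)))
      names(cds_v) <- c(ids, sids)
      cds_v <- cds_v[df$gene_id]
    } else {
      names(cds_v) <- ids
    }
    genes[[v]] <- df
    cds[[v]] <- cds_v
  }

  # assign chromosomes (contiguous chunks of the conserved order), then
  # plant duplications on those chromosomes, then lay out coordinates
  origin <- list()
  td_by_var <- split(config$td_arrays,
                     vapply(config$td_arrays, `[[`, "", "variety"))
  wgd_by_var <- split(config$wgd_blocks,
                      vapply(config$wgd_blocks, `[[`, "", "variety"))
  wgd_runs <- list()   # family runs that must stay collinear in the outgroup
  for (v in vs) {
    df <- genes[[v]]
    df$chromosome <- sprintf("chr%02d",
                             sort(rep_len(seq_len(config$n_chromosomes),
                                          nrow(df))))
    pd <- plant_duplications(
      df, cds[[v]],
      td_spec = td_by_var[[v]] %||% list(),
      wgd_spec = wgd_by_var[[v]] %||% list(),
      copy_divergence = config$copy_divergence,
      exclude_families = unique(unlist(wgd_runs)))
    origin[[v]] <- pd$origin
    wgd_runs <- c(wgd_runs, pd$wgd_family_runs)
    cds[[v]] <- pd$cds
    df <- pd$genes
    df$order <- stats::ave(seq_len(nrow(df)), df$chromosome, FUN = seq_along)
    glen <- nchar(cds[[v]][df$gene_id])
    sp <- config$intergenic
    df$start <- NA_integer_; df$end <- NA_integer_
    for (ch in unique(df$chromosome)) {
      sel <- which(df$chromosome == ch)
      starts <- sp + c(0, cumsum(glen[sel] + sp))[seq_along(sel)]
      df$start[sel] <- starts                   # 0-based half-open
      df$end[sel] <- starts + glen[sel]
    }
    df$strand <- "+"
    genes[[v]] <- df
  }

  genes <- do.call(rbind, c(genes, list(make.row.names = FALSE)))
  cds <- unlist(unname(cds))

  # outgroup: one gene per family, shuffled order except planted WGD runs
  og <- .build_outgroup_order(fam_ids, wgd_runs)
  anchors <- lapply(vs, function(v) .variety_outgroup_anchors(genes, v, og))
  names(anchors) <- vs

  hits <- .family_similarity_hits(genes, cds)

  proteins <- vapply(cds, function(s)
    as.character(Biostrings::translate(Biostrings::DNAString(s))),
    character(1))

  gene_origin <- stats::setNames(rep("other", nrow(genes)), genes$gene_id)
  for (v in vs) gene_origin[names(origin[[v]])] <- origin[[v]]

  gene_family <- stats::setNames(genes$family, genes$gene_id)
  fam_label_full <- fam_label
  truth <- list(
    family_labels = fam_label_full,
    gene_family = gene_family,
    gene_origin = gene_origin,
    specific_genes = genes$gene_id[is.na(genes$family)],
    presence = presence,
    tree = phy)

  list(genes = genes, cds = cds, proteins = proteins, hits = hits,
       outgroup = og, anchors = anchors, config = config, truth = truth)
}

# Outgroup order: families shuffled, but each planted WGD family run kept
# contiguous and in order.
.build_outgroup_order <- function(fam_ids, wgd_runs) {
  in_run <- unique(unlist(wgd_runs))
  loose <- setdiff(fam_ids, in_run)
  units <- c(as.list(loose), wgd_runs)
  units <- units[sample(length(units))]
  fams <- unlist(units)
  data.frame(gene_id = paste0("og_", fams), family = fams,
             order = seq_along(fams), stringsAsFactors = FALSE)
}

# Anchor homolog pairs between one variety's genes and the outgroup:
# every gene of a family hits the outgroup gene of the same family.
.variety_outgroup_anchors <- function(genes, v, og) {
  gv <- genes[genes$variety == v & !is.na(genes$family), ]
  m <- match(gv$family, og$family)
  keep <- !is.na(m)
  data.frame(gene_a = gv$gene_id[keep], gene_b = og$gene_id[m[keep]],
             stringsAsFactors = FALSE)
}

# Within-family all-vs-all hits with identity computed from the evolved
# sequences; bitscore/e-value follow a simple Karlin-Altschul-style
# monotone mapping so that downstream e-value cutoffs behave like BLAST's.
.family_similarity_hits <- function(genes, cds, db_size = NULL) {
  fams <- split(genes$gene_id, genes$family)
  if (is.null(db_size)) db_size <- sum(nchar(cds)) / 3
  qs <- character(0); ss <- character(0); pid <- numeric(0)
  laa <- numeric(0)
  for (f in names(fams)) {
    ids <- fams[[f]]
    if (length(ids) < 2) next
    seqs <- strsplit(cds[ids], "")
    n <- length(ids)
    len_aa <- nchar(cds[[ids[1]]]) / 3
    pr <- utils::combn(n, 2)
    p <- vapply(seq_len(ncol(pr)), function(k)
      100 * mean(seqs[[pr[1, k]]] == seqs[[pr[2, k]]]), numeric(1))
    qs <- c(qs, ids[pr[1, ]]); ss <- c(ss, ids[pr[2, ]])
    pid <- c(pid, p); laa <- c(laa, rep(len_aa, ncol(pr)))
  }
  bits <- 2 * laa * pid / 100
  ev <- 10^pmax(log10(laa * db_size) - bits * log10(2), -300)
  data.frame(qseqid = qs, sseqid = ss, pident = round(pid, 2),
             length = as.integer(laa),
             mismatch = as.integer(round(laa * (1 - pid / 100))),
             gapopen = 0L, qstart = 1L, qend = as.integer(laa),
             sstart = 1L, send = as.integer(laa), evalue = ev,
             bitscore = round(bits, 1), stringsAsFactors = FALSE)
}

#' Plant tandem arrays and duplicated blocks into one variety's gene list
#'
#' Tandem arrays insert `array_size - 1` diverged copies immediately after
#' a donor gene on the requested chromosome; duplicated blocks copy a run
#' of `block_anchor_count` consecutive family genes onto a different
#' chromosome preserving their order. Copies stay in the donor's family
#' (so similarity hits link them) and carry slight sequence divergence.
#'
#' @param gene_df data.frame with columns `gene_id`, `variety`, `family`,
#'   `chromosome`, rows in gene order (grouped by chromosome).
#' @param cds named CDS vector for the genes.
#' @param td_spec,wgd_spec lists as in [sim_config()]; `chromosome` in a
#'   TD spec is an index into the variety's chromosomes.
#' @param copy_divergence per-nucleotide mutation rate for copies.
#' @param exclude_families families that must not join a duplicated
#'   block (already used by blocks planted in other varieties; one
#'   family can anchor only one collinear outgroup region).
#' @return list: modified `genes`, `cds`, named `origin` vector over all
#'   affected genes (`"TD"`/`"WGD"`), and `wgd_family_runs` (family-id
#'   runs that must stay collinear in the outgroup).
#' @export
plant_duplications <- function(gene_df, cds, td_spec = list(),
                               wgd_spec = list(),
                               copy_divergence = 0.02,
                               exclude_families = character(0)) {
  stopifnot("chromosome" %in% names(gene_df))
  origin <- character(0)
  wgd_family_runs <- list()
  used <- character(0)   # genes already involved in a planting
  chroms <- unique(gene_df$chromosome)

  insert_after <- function(df, row, newdf) {
    n <- nrow(df)
    rbind(df[seq_len(row), ], newdf,
          df[seq(row + 1, length.out = n - row), ],
          make.row.names = FALSE)
  }

  for (td in td_spec) {
    chr_i <- td$chromosome %||% 1L
    if (chr_i > length(chroms)) stop("TD spec references missing chromosome")
    chr <- chroms[chr_i]
    on_chr <- which(gene_df$chromosome == chr)
    if (td$array_size > length(on_chr) + 1)
      stop("tandem array larger than chromosome gene capacity")
    cand <- on_chr[!is.na(gene_df$family[on_chr]) &
                     !(gene_df$gene_id[on_chr] %in% used)]
    if (!length(cand))
      stop("no available donor gene on ", chr, " for a tandem array")
    donor <- sample(cand, 1)
    did <- gene_df$gene_id[donor]
    copies <- sprintf("%s_td%d", did, seq_len(td$array_size - 1L))
    cdf <- data.frame(gene_id = copies, variety = gene_df$variety[donor],
                      family = gene_df$family[donor], chromosome = chr,
                      stringsAsFactors = FALSE)
    gene_df <- insert_after(gene_df, donor, cdf)
    for (cp in copies)
      cds[[cp]] <- mutate_cds(cds[[did]], copy_divergence)
    origin[c(did, copies)] <- "TD"
    used <- c(used, did, copies)
  }

  for (wb in wgd_spec) {
    k <- wb$block_anchor_count
    # a run of k consecutive unused family genes on one chromosome
    ok_run <- NULL
    for (chr in sample(chroms)) {
      idx <- which(gene_df$chromosome == chr)
      good <- idx[!is.na(gene_df$family[idx]) &
                    !(gene_df$gene_id[idx] %in% used) &
                    !(gene_df$family[idx] %in% exclude_families)]
      runs <- split(good, cumsum(c(1, diff(good) != 1)))
      runs <- Filter(function(r) length(r) >= k, runs)
      if (length(runs)) { ok_run <- runs[[1]][seq_len(k)]; break }
    }
    if (is.null(ok_run))
      stop("no room to plant a duplicated block of ", k, " genes")
    src_ids <- gene_df$gene_id[ok_run]
    fam_run <- gene_df$family[ok_run]
    src_chr <- gene_df$chromosome[ok_run[1]]
    tgt_chr <- chroms[if (match(src_chr, chroms) < length(chroms))
      match(src_chr, chroms) + 1L else match(src_chr, chroms) - 1L]
    copies <- paste0(src_ids, "_wgd")
    cdf <- data.frame(gene_id = copies, variety = gene_df$variety[ok_run[1]],
                      family = fam_run, chromosome = tgt_chr,
                      stringsAsFactors = FALSE)
    gene_df <- insert_after(gene_df, max(which(gene_df$chromosome == tgt_chr)),
                            cdf)
    for (i in seq_along(copies))
      cds[[copies[i]]] <- mutate_cds(cds[[src_ids[i]]], copy_divergence)
    origin[c(src_ids, copies)] <- "WGD"
    used <- c(used, src_ids, copies)
    wgd_family_runs[[length(wgd_family_runs) + 1L]] <- fam_run
  }

  list(genes = gene_df, cds = cds, origin = origin,
       wgd_family_runs = wgd_family_runs)
}
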