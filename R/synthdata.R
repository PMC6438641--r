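# Synthetic reference families, trees and shotgun read sets with known
# ground truth, so that every pipeline stage is testable at desk scale
# without downloading real metagenomes.
#
# Scale choices (deliberately "mini" versions of real genes): a shared
# taxon tree is simulated once per community; each gene family evolves on
# that tree by site-independent JC69 from an independent root sequence.
# Default gene lengths are 450/540/630/720 nt for the four single-copy
# normalizer stand-ins and 600 nt for the target family - close to the
# harmonic mean of the single-copy lengths, which keeps read-end effects
# from biasing the %GE ratio. Reads are single-end 150 nt with i.i.d.
# substitution errors, both strands, drawn from gene loci embedded in
# random flanking sequence plus a background-filler fraction.

#' Simulate a reference taxon tree
#'
#' Pure-birth topology with shifted-exponential branch lengths
#' (`bl_min + Exp(mean = bl_mean - bl_min)`); the floor avoids
#' zero-length edges that would make sister taxa indistinguishable.
#' Deterministic given `seed`.
#'
#' @param n_leaves number of leaves (>= 2).
#' @param bl_mean mean branch length (substitutions/site, default 0.08).
#' @param bl_min minimum branch length (default 0.03).
#' @param seed integer seed.
#' @return a rooted binary `phylo` tree with leaves `taxon01`, ... in
#'   cladewise order (2n - 2 edges).
#' @export
simulate_tree <- function(n_leaves, bl_mean = 0.08, bl_min = 0.03, seed = 1) {
  stopifnot(n_leaves >= 2, bl_mean > bl_min, bl_min >= 0)
  with_seed(seed, {
    phy <- ape::rphylo(n_leaves, birth = 1, death = 0)
    ne <- nrow(phy$edge)
    phy$edge.length <- bl_min + rexp(ne, rate = 1 / (bl_mean - bl_min))
    phy$tip.label <- sprintf("taxon%02d", seq_len(n_leaves))
    ape::reorder.phylo(phy, "cladewise")
  })
}

# JC69 site evolution on integer codes 1..4
mutate_jc69 <- function(codes, t) {
  p_same <- 0.25 + 0.75 * exp(-4 * t / 3)
  hit <- runif(length(codes)) >= p_same
  k <- sum(hit)
  if (k) codes[hit] <- ((codes[hit] - 1L + sample(3L, k, replace = TRUE)) %% 4L) + 1L
  codes
}

#' Evolve a gene family down a tree under JC69
#'
#' A uniform-random root sequence of `root_length` nt evolves
#' site-independently along every branch (no indels), so the true
#' alignment of the leaves is the ungapped stack of leaf sequences.
#'
#' @param tree a `phylo` tree with branch lengths (substitutions/site).
#' @param root_length gene length in nt.
#' @param rate rate multiplier applied to branch lengths (default 1).
#' @param seed integer seed.
#' @param stop_free_root if `TRUE`, the root sequence is built from
#'   codons excluding stop codons (frame +1), so leaf translations are
#'   mostly open; requires `root_length` divisible by 3.
#' @return list with `leaf_seqs` (named character) and `msa` (the true
#'   alignment as an [as_msa()] object).
#' @export
evolve_sequences <- function(tree, root_length, rate = 1, seed = 1,
                             stop_free_root = FALSE) {
  phy <- ape::reorder.phylo(tree, "cladewise")
  ntip <- length(phy$tip.label)
  with_seed(seed, {
    root_codes <- if (stop_free_root) {
      stopifnot(root_length %% 3 == 0)
      stops <- c("TAA", "TAG", "TGA")
      codons <- setdiff(apply(expand.grid(DNA_LETTERS, DNA_LETTERS,
                                          DNA_LETTERS), 1, paste,
                              collapse = ""), stops)
      picked <- sample(codons, root_length / 3, replace = TRUE)
      match(strsplit(paste(picked, collapse = ""), "")[[1]], DNA_LETTERS)
    } else {
      sample.int(4L, root_length, replace = TRUE)
    }
    seqs <- vector("list", ntip + phy$Nnode)
    root <- phy$edge[1, 1]
    seqs[[root]] <- root_codes
    for (ei in seq_len(nrow(phy$edge))) {  # cladewise: parents first
      pa <- phy$edge[ei, 1]; ch <- phy$edge[ei, 2]
      seqs[[ch]] <- mutate_jc69(seqs[[pa]], phy$edge.length[ei] * rate)
    }
    leaf <- vapply(seq_len(ntip),
                   function(i) paste(DNA_LETTERS[seqs[[i]]], collapse = ""), "")
    names(leaf) <- phy$tip.label
    list(leaf_seqs = leaf, msa = as_msa(leaf, "dna"))
  })
}

#' Define a synthetic community
#'
#' Every genome carries one copy of each single-copy gene; the target
#' family is carried (single copy) only by the designated carrier taxa,
#' whose summed relative abundance is `target_fraction` - i.e. the
#' target gene is present in `100 * target_fraction` percent of genomes.
#'
#' @param taxa character vector of taxon names (e.g. tree leaves).
#' @param target_fraction fraction of genomes carrying the target family
#'   (default 0.02).
#' @param carriers indices (or names) of the carrier taxa (default the
#'   first taxon).
#' @return data.frame `taxon`, `abundance`, `target_copy` (0/1); sums to
#'   1.
#' @export
community_spec <- function(taxa, target_fraction = 0.02, carriers = 1L) {
  if (is.character(carriers)) carriers <- match(carriers, taxa)
  stopifnot(length(carriers) >= 1, !anyNA(carriers),
            target_fraction > 0, target_fraction < 1)
  n <- length(taxa)
  ab <- numeric(n)
  ab[carriers] <- target_fraction / length(carriers)
  rest <- setdiff(seq_len(n), carriers)
  ab[rest] <- (1 - target_fraction) / length(rest)
  data.frame(taxon = taxa, abundance = ab,
             target_copy = as.integer(seq_len(n) %in% carriers),
             stringsAsFactors = FALSE)
}

#' Read-simulation settings
#'
#' @param n_reads number of reads.
#' @param read_length read length in nt (default 150, a typical short
#'   Illumina read).
#' @param error_rate i.i.d. per-base substitution error rate in
#'   `[0, 0.2]` (default 0.005).
#' @param quality `"constant"` (Q35 throughout) or `"degrading"`
#'   (Q38 falling to Q2 over the final 30 bases, to exercise trimming).
#' @param background_fraction fraction of reads drawn from non-gene
#'   background sequence (default 0.6).
#' @param flank random flanking sequence on each side of a gene locus in
#'   nt (default 150), so reads may partially overlap gene ends.
#' @param seed integer seed.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_reads = 100000, read_length = 150,
                       error_rate = 0.005,
                       quality = c("constant", "degrading"),
                       background_fraction = 0.6, flank = 150, seed = 1) {
  quality <- match.arg(quality)
  stopifnot(error_rate >= 0, error_rate <= 0.2, n_reads >= 1,
            read_length >= 1, background_fraction >= 0,
            background_fraction < 1)
  structure(list(n_reads = as.integer(n_reads),
                 read_length = as.integer(read_length),
                 error_rate = error_rate, quality = quality,
                 background_fraction = background_fraction,
                 flank = as.integer(flank), seed = as.integer(seed)),
            class = "sim_config")
}

qual_string <- function(config) {
  rl <- config$read_length
  if (config$quality == "constant") {
    strrep(intToUtf8(33L + 35L), rl)
  } else {
    tail_len <- min(30L, rl)
    q <- c(rep(38L, rl - tail_len),
           round(seq(38L, 2L, length.out = tail_len)))
    intToUtf8(33L + q, multiple = FALSE)
  }
}

apply_errors <- function(seqs, error_rate) {
  if (error_rate <= 0) return(seqs)
  rl <- nchar(seqs)
  # i.i.d. errors drawn as global (read, position) pairs; collisions are
  # negligible at the rates used (<= 0.2) and merely overwrite
  n_err <- rbinom(1L, sum(rl), error_rate)
  if (n_err == 0L) return(seqs)
  idx <- sample.int(length(seqs), n_err, replace = TRUE, prob = rl)
  pos <- ceiling(runif(n_err) * rl[idx])
  cur <- match(substring(seqs[idx], pos, pos), DNA_LETTERS)
  cur[is.na(cur)] <- sample.int(4L, sum(is.na(cur)), replace = TRUE)
  repl <- DNA_LETTERS[((cur - 1L + sample(3L, n_err, replace = TRUE)) %% 4L) + 1L]
  # vectorized application; one pass per error rank within a read
  while (length(idx)) {
    first <- !duplicated(idx)
    i <- idx[first]
    s <- seqs[i]
    substr(s, pos[first], pos[first]) <- repl[first]
    seqs[i] <- s
    idx <- idx[!first]; pos <- pos[!first]; repl <- repl[!first]
  }
  seqs
}

#' Fragment a synthetic community into shotgun reads
#'
#' Each gene (per carrying taxon) is embedded in a locus with random
#' flanks; reads fall on loci with probability proportional to
#' `abundance x copy number x available start positions`, uniform start,
#' 50% reverse-complemented, with i.i.d. substitution errors; the stated
#' fraction of reads comes from background filler sequence instead.
#'
#' @param community a [community_spec()] data.frame.
#' @param families named list of gene families, each a named character
#'   vector of per-taxon gene sequences (names = taxa).
#' @param config a [sim_config()].
#' @param target_family name of the family governed by the community's
#'   `target_copy` column (all other families have copy number 1
#'   everywhere); default `"target"`.
#' @return list with `reads` (data.frame `id`, `seq`, `qual`) and `truth`
#'   (data.frame `read_id`, `taxon`, `gene`, `strand`, `start`,
#'   `gene_overlap`; background reads have gene `"background"`).
#' @export
fragment_reads <- function(community, families, config,
                           target_family = "target") {
  rl <- config$read_length
  with_seed(config$seed, {
    # build loci
    loci <- list()
    for (g in names(families)) {
      fam <- families[[g]]
      for (i in seq_len(nrow(community))) {
        tx <- community$taxon[i]
        copy <- if (g == target_family) community$target_copy[i] else 1L
        if (copy < 1L || community$abundance[i] <= 0) next
        if (!tx %in% names(fam)) stopf("family %s lacks taxon %s", g, tx)
        fl <- random_residues(config$flank, DNA_LETTERS)
        fr <- random_residues(config$flank, DNA_LETTERS)
        locus <- paste0(fl, fam[[tx]], fr)
        npos <- nchar(locus) - rl + 1L
        if (npos < 1L) stopf("locus shorter than read length")
        loci[[length(loci) + 1L]] <- list(
          taxon = tx, gene = g, seq = locus, npos = npos,
          glen = nchar(fam[[tx]]),
          weight = community$abundance[i] * copy * npos)
      }
    }
    w <- vapply(loci, `[[`, 0, "weight")
    n <- config$n_reads
    # source: background vs each locus
    probs <- c(w / sum(w) * (1 - config$background_fraction),
               config$background_fraction)
    src <- sample.int(length(loci) + 1L, n, replace = TRUE, prob = probs)
    bg_pool <- random_residues(100000L, DNA_LETTERS)
    seqs <- character(n)
    taxon <- rep("background", n)
    gene <- rep("background", n)
    start <- integer(n)
    overlap <- integer(n)
    for (s in unique(src)) {
      ix <- which(src == s)
      if (s > length(loci)) {
        st <- sample.int(nchar(bg_pool) - rl + 1L, length(ix), replace = TRUE)
        seqs[ix] <- substring(bg_pool, st, st + rl - 1L)
        start[ix] <- st
      } else {
        lc <- loci[[s]]
        st <- sample.int(lc$npos, length(ix), replace = TRUE)
        seqs[ix] <- substring(lc$seq, st, st + rl - 1L)
        taxon[ix] <- lc$taxon
        gene[ix] <- lc$gene
        start[ix] <- st
        overlap[ix] <- pmax(0L, pmin(st + rl - 1L, config$flank + lc$glen) -
                              pmax(st, config$flank + 1L) + 1L)
      }
    }
    seqs <- apply_errors(seqs, config$error_rate)
    minus <- runif(n) < 0.5
    if (any(minus)) seqs[minus] <- revcomp(seqs[minus])
    ids <- sprintf("read%07d", seq_len(n))
    q <- qual_string(config)
    list(reads = data.frame(id = ids, seq = seqs, qual = q,
                            stringsAsFactors = FALSE),
         truth = data.frame(read_id = ids, taxon = taxon, gene = gene,
                            strand = ifelse(minus, "-", "+"), start = start,
                            gene_overlap = overlap,
                            stringsAsFactors = FALSE))
  })
}

#' Default synthetic gene lengths (nt)
#'
#' Mini-gene stand-ins: target 600; single-copy normalizers 450 (recA),
#' 540 (atpD), 630 (gyrB), 720 (rpoB).
#' @return named integer vector.
#' @export
default_gene_lengths <- function() {
  c(target = 600L, recA = 450L, atpD = 540L, gyrB = 630L, rpoB = 720L)
}

#' Simulate a complete synthetic metagenome
#'
#' Convenience wrapper: taxon tree, one gene family per entry of
#' `gene_lengths` evolved on that tree, a spike-in community, and a
#' shotgun read set with ground truth.
#'
#' @param n_taxa number of taxa (default 10).
#' @param gene_lengths named gene lengths; see [default_gene_lengths()].
#' @param target_fraction fraction of genomes carrying the target family
#'   (default 0.02).
#' @param config a [sim_config()]; its seed is overridden by `seed`.
#' @param seed master seed; per-component seeds are derived from it.
#' @return list with `tree`, `families` (per family: `leaf_seqs`, `msa`),
#'   `community`, `reads`, `truth`, `config`, `gene_lengths`.
#' @export
simulate_metagenome <- function(n_taxa = 10,
                                gene_lengths = default_gene_lengths(),
                                target_fraction = 0.02,
                                config = sim_config(), seed = 1) {
  seed <- as.integer(seed)
  tree <- simulate_tree(n_taxa, seed = seed)
  fams <- list()
  for (i in seq_along(gene_lengths)) {
    g <- names(gene_lengths)[i]
    fams[[g]] <- evolve_sequences(tree, gene_lengths[[i]],
                                  seed = seed + 1000L * i,
                                  stop_free_root = g == "target")
  }
  comm <- community_spec(tree$tip.label, target_fraction)
  config$seed <- seed + 7L
  fr <- fragment_reads(comm,
                       lapply(fams, `[[`, "leaf_seqs"),
                       config, target_family = "target")
  list(tree = tree, families = fams, community = comm,
       reads = fr$reads, truth = fr$truth, config = config,
       gene_lengths = gene_lengths)
}

#' Simulate reads from one reference leaf (placement controls)
#'
#' Error-free fragments of a leaf gene, each independently diverged from
#' the leaf by `divergence` substitutions/site under JC69.
#'
#' @param leaf_seq the leaf gene sequence.
#' @param n number of reads.
#' @param read_length read length (default 150).
#' @param divergence JC69 divergence from the leaf (default 0.05).
#' @param seed integer seed.
#' @return character vector of reads (forward strand).
#' @export
simulate_leaf_reads <- function(leaf_seq, n, read_length = 150,
                                divergence = 0.05, seed = 1) {
  stopifnot(nchar(leaf_seq) >= read_length)
  with_seed(seed, {
    vapply(seq_len(n), function(i) {
      st <- sample.int(nchar(leaf_seq) - read_length + 1L, 1L)
      frag <- substr(leaf_seq, st, st + read_length - 1L)
      codes <- match(strsplit(frag, "")[[1]], DNA_LETTERS)
      paste(DNA_LETTERS[mutate_jc69(codes, divergence)], collapse = "")
    }, "")
  })
}

#' Write a simulated metagenome to a directory
#'
#' Emits reads.fastq, tree.nwk, one aligned FASTA per family, the
#' community spec as YAML, and the ground-truth TSV.
#'
#' @param sim a [simulate_metagenome()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fastq(sim$reads, file.path(dir, "reads.fastq"))
  ape::write.tree(sim$tree, file.path(dir, "tree.nwk"))
  for (g in names(sim$families)) {
    write_fasta(setNames(sim$families[[g]]$leaf_seqs,
                         names(sim$families[[g]]$leaf_seqs)),
                file.path(dir, paste0(g, "_aln.fasta")))
  }
  yaml::write_yaml(list(taxa = sim$community$taxon,
                        abundance = sim$community$abundance,
                        target_copy = sim$community$target_copy,
                        gene_lengths = as.list(sim$gene_lengths)),
                   file.path(dir, "community.yaml"))
  write_tsv_stable(sim$truth, file.path(dir, "truth.tsv"))
  invisible(dir)
}
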