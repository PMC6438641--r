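# End-to-end census orchestration: trim -> build/calibrate -> search ->
# confirm -> place -> abundance, from a single config, with per-stage
# attrition logging and deterministic outputs given a seed.

#' Assemble a pipeline configuration
#'
#' All thresholds default to the study-standard values: fragment fraction
#' 0.70 for curation; Q25 / window 4 / 70 nt trimming; cascade P-value
#' thresholds 0.02 / 0.001 / 1e-5 with E < 1e-5 for both the nucleotide
#' search and the protein confirmation.
#'
#' @param reads read set: path to FASTQ/FASTA or data.frame
#'   (`id`,`seq`,`qual`).
#' @param target_name label of the target gene family.
#' @param target_msa reference nucleotide alignment of the target family
#'   (path or [as_msa()] input).
#' @param target_tree reference phylogeny of the target family (newick
#'   path or `phylo`).
#' @param target_protein_msa protein alignment of the family (path or
#'   msa) used for six-frame confirmation.
#' @param single_copy_msas named list (recA, atpD, gyrB, rpoB) of
#'   nucleotide alignments for the normalizer genes.
#' @param modal_lengths optional named modal lengths (nt); computed from
#'   the alignments when `NULL`.
#' @param trim list of trimming settings (`window`, `min_mean_q`,
#'   `min_len`).
#' @param cascade a [cascade_config()].
#' @param confirm_evalue confirmation E-value threshold.
#' @param calibration list: `n_shuffles`, `length` (nucleotide null
#'   length; `NULL` = read length), `protein_length`.
#' @param abundance_mode [percent_GE()] mode.
#' @param count_mode ecotype counting mode (see [aggregate_ecotypes()]).
#' @param sample sample label.
#' @param seed master seed (all stage seeds derive from it).
#' @param out_dir optional output directory for TSV/jplace/log files.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(reads, target_name = "target",
                            target_msa = NULL, target_tree = NULL,
                            target_protein_msa = NULL,
                            single_copy_msas = list(),
                            modal_lengths = NULL,
                            trim = list(window = 4, min_mean_q = 25,
                                        min_len = 70),
                            cascade = cascade_config(),
                            confirm_evalue = 1e-5,
                            calibration = list(n_shuffles = 200,
                                               length = NULL,
                                               protein_length = 50),
                            abundance_mode = "length_ratio",
                            count_mode = "best_edge",
                            sample = "sample1", seed = 1,
                            out_dir = NULL) {
  stopifnot(inherits(cascade, "cascade_config"),
            trim$window >= 1, trim$min_len >= 1, confirm_evalue > 0)
  structure(list(reads = reads, target_name = target_name,
                 target_msa = target_msa, target_tree = target_tree,
                 target_protein_msa = target_protein_msa,
                 single_copy_msas = single_copy_msas,
                 modal_lengths = modal_lengths, trim = trim,
                 cascade = cascade, confirm_evalue = confirm_evalue,
                 calibration = calibration,
                 abundance_mode = abundance_mode, count_mode = count_mode,
                 sample = sample, seed = as.integer(seed),
                 out_dir = out_dir),
            class = "pipeline_config")
}

load_msa_input <- function(x) {
  if (is.character(x) && length(x) == 1L && file.exists(x)) read_msa(x)
  else as_msa(x)
}

load_reads_input <- function(x) {
  if (is.character(x) && length(x) == 1L && file.exists(x)) read_reads(x) else x
}

#' Run the full gene census pipeline
#'
#' Stages: quality trimming; profile-HMM build and calibration for the
#' target family and each single-copy gene; cascade search of the
#' trimmed reads with every nucleotide model; six-frame protein
#' confirmation of target candidates; phylogenetic placement of
#' confirmed target reads; genome-equivalent normalization and the %GE
#' abundance report. Deterministic given `config$seed`.
#'
#' @param config a [pipeline_config()].
#' @param quiet suppress progress messages.
#' @return list with `report` (abundance report data.frame), `ecotypes`,
#'   `placements`, `confirmed`, `searches` (per-family survivor tables),
#'   `attrition` (per-family per-stage read counts), `ge`,
#'   `mean_read_length`, `log` (character vector). If `config$out_dir`
#'   is set, abundance.tsv, ecotypes.tsv, attrition.tsv,
#'   placements.jplace, provenance.yaml and pipeline.log are written.
#' @export
run_pipeline <- function(config, quiet = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  logs <- character(0)
  say <- function(fmt, ...) {
    msg <- sprintf(fmt, ...)
    logs <<- c(logs, msg)
    if (!quiet) message(msg)
    invisible(NULL)
  }
  seed <- config$seed

  reads <- load_reads_input(config$reads)
  say("input: %d reads", nrow(reads))
  trimmed <- trim_reads(reads, config$trim$window, config$trim$min_mean_q,
                        config$trim$min_len)
  say("trimming: %d reads retained (%d dropped)", nrow(trimmed),
      attr(trimmed, "dropped"))
  mean_rl <- if (nrow(trimmed)) mean(nchar(trimmed$seq)) else NA_real_
  db <- nrow(trimmed)

  fam_msas <- c(setNames(list(config$target_msa), config$target_name),
                config$single_copy_msas)
  fam_msas <- lapply(fam_msas, load_msa_input)

  modal <- config$modal_lengths %||%
    vapply(fam_msas, function(a) as.numeric(modal_length(a$seqs)), 0)

  searches <- list()
  attrition <- list()
  hmms <- list()
  for (i in seq_along(fam_msas)) {
    g <- names(fam_msas)[i]
    hmm <- build_phmm(fam_msas[[g]])
    hmm <- calibrate(hmm, config$calibration$n_shuffles,
                     seed = seed + 11L * i,
                     length = config$calibration$length)
    hmms[[g]] <- hmm
    hits <- search_reads(trimmed, hmm, config$cascade, db_size = db)
    searches[[g]] <- hits
    att <- attr(hits, "attrition")
    att$family <- g
    attrition[[g]] <- att
    say("search %s (L=%d): %d survivors", g, hmm$L, nrow(hits))
  }

  # protein confirmation of target candidates
  target <- config$target_name
  confirmed <- searches[[target]]
  if (!is.null(config$target_protein_msa) && nrow(confirmed) > 0L) {
    pmsa <- load_msa_input(config$target_protein_msa)
    phmm <- build_phmm(pmsa)
    phmm <- calibrate(phmm, config$calibration$n_shuffles,
                      seed = seed + 101L,
                      length = config$calibration$protein_length)
    confirmed <- confirm_hits(confirmed, trimmed, phmm,
                              evalue_max = config$confirm_evalue)
    say("confirmation: %d of %d candidates confirmed",
        nrow(confirmed), nrow(searches[[target]]))
  } else {
    say("confirmation: skipped (no protein alignment)")
  }
  attrition[[target]] <- rbind(
    attrition[[target]],
    data.frame(stage = "confirmed", reads = nrow(confirmed), family = target))

  # placement of confirmed target reads
  placements <- NULL
  ecotypes <- NULL
  engine <- NULL
  if (!is.null(config$target_tree) && nrow(confirmed) > 0L) {
    engine <- placement_engine(config$target_tree,
                               project_msa_to_match(fam_msas[[target]],
                                                    hmms[[target]]))
    queries <- lapply(seq_len(nrow(confirmed)), function(i) {
      rs <- trimmed$seq[match(confirmed$read_id[i], trimmed$id)]
      map_read_to_columns(rs, hmms[[target]], confirmed$strand[i])
    })
    names(queries) <- confirmed$read_id
    placements <- place_reads(engine, queries)
    placements$sample <- config$sample
    ecotypes <- aggregate_ecotypes(placements, engine,
                                   count_mode = config$count_mode)
    say("placement: %d reads placed on %d edges", nrow(confirmed),
        length(unique(placements$edge_id[placements$rank == 1L])))
  } else {
    say("placement: skipped")
  }
  attrition[[target]] <- rbind(
    attrition[[target]],
    data.frame(stage = "placed",
               reads = if (is.null(placements)) 0L else
                 length(unique(placements$read_id)),
               family = target))

  # abundance
  sc_genes <- names(config$single_copy_msas)
  counts <- vapply(searches[sc_genes], nrow, 0L)
  panel <- single_copy_panel(counts, modal_lengths = modal[sc_genes],
                             ref_gene = if ("recA" %in% sc_genes) "recA"
                                        else sc_genes[[1]])
  report <- abundance_report(config$sample, target, nrow(confirmed), panel,
                             mode = config$abundance_mode,
                             target_modal_len = modal[[target]],
                             mean_read_length = mean_rl)
  say("abundance: GE = %.2f, %%GE = %.4f (%s mode)", report$GE,
      report$percent_GE, report$mode)

  attrition <- do.call(rbind, unname(attrition))
  attrition <- attrition[, c("family", "stage", "reads")]
  rownames(attrition) <- NULL

  out <- list(report = report, ecotypes = ecotypes, placements = placements,
              confirmed = confirmed, searches = searches,
              attrition = attrition, ge = report$GE,
              mean_read_length = mean_rl, panel = panel, log = logs)

  if (!is.null(config$out_dir)) {
    d <- config$out_dir
    dir.create(d, showWarnings = FALSE, recursive = TRUE)
    write_tsv_stable(report, file.path(d, "abundance.tsv"))
    write_tsv_stable(attrition, file.path(d, "attrition.tsv"))
    if (!is.null(ecotypes)) {
      write_tsv_stable(ecotypes, file.path(d, "ecotypes.tsv"))
    }
    if (!is.null(placements)) {
      write_jplace(placements, engine, file.path(d, "placements.jplace"))
    }
    yaml::write_yaml(list(
      seed = config$seed, sample = config$sample,
      thresholds = list(p_msv = config$cascade$p_msv,
                        p_vit = config$cascade$p_vit,
                        p_fwd = config$cascade$p_fwd,
                        evalue_max = config$cascade$evalue_max,
                        confirm_evalue = config$confirm_evalue,
                        trim = config$trim),
      abundance_mode = config$abundance_mode,
      package_version = as.character(utils::packageVersion("genecensus"))),
      file.path(d, "provenance.yaml"))
    writeLines(paste(format(Sys.time(), "%Y-%m-%d %H:%M:%S"), logs),
               file.path(d, "pipeline.log"))
  }
  out
}

#' Run a spike-in benchmark community through the full census
#'
#' Simulates the default spike-in study (10 taxa, the target family in 2%
#' of genomes, all four single-copy genes in every genome, 100,000 reads)
#' and runs the complete pipeline on it, returning the abundance report
#' together with the simulation ground truth. The %GE estimate should
#' recover `100 * target_fraction` in length-ratio mode.
#'
#' @param seed integer seed for the simulation and all pipeline stages.
#' @param n_reads reads to simulate (default 100000).
#' @param n_taxa community size (default 10).
#' @param target_fraction fraction of genomes carrying the target family
#'   (default 0.02).
#' @param abundance_mode [percent_GE()] mode (default `"length_ratio"`).
#' @param out_dir optional pipeline output directory.
#' @return list with `report`, `result` (the full [run_pipeline()]
#'   output), `sim` (the simulation), and `percent_GE`.
#' @export
run_spike_in <- function(seed, n_reads = 100000, n_taxa = 10,
                         target_fraction = 0.02,
                         abundance_mode = "length_ratio", out_dir = NULL) {
  sim <- simulate_metagenome(n_taxa = n_taxa,
                             target_fraction = target_fraction,
                             config = sim_config(n_reads = n_reads),
                             seed = seed)
  cfg <- pipeline_config(
    reads = sim$reads,
    target_msa = sim$families$target$msa,
    target_tree = sim$tree,
    target_protein_msa = translate_refs(sim$families$target$leaf_seqs),
    single_copy_msas = lapply(sim$families[c("recA", "atpD", "gyrB", "rpoB")],
                              `[[`, "msa"),
    abundance_mode = abundance_mode,
    seed = seed, out_dir = out_dir)
  res <- run_pipeline(cfg)
  list(report = res$report, result = res, sim = sim,
       percent_GE = res$report$percent_GE)
}

# restrict a reference alignment to the model's match columns (the
# coordinate system shared by read projection and placement)
project_msa_to_match <- function(aln, hmm) {
  aln <- as_msa(aln)
  m <- msa_matrix(aln)[, hmm$match_columns, drop = FALSE]
  rownames(m) <- aln$ids
  m
}
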