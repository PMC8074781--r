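#' Pipeline configuration
#'
#' @param outdir output directory (created if needed).
#' @param seed global integer seed; every stochastic stage derives its
#'   seeds from it.
#' @param stages stages to run, in dependency order; a subset of
#'   `c("simulate", "assemble", "numt", "capture", "diversity",
#'   "parsimony")`.
#' @param inputs optional named list of pre-existing input files (checked
#'   before any stage runs).
#' @param numt_background_bp,numt_n nuclear background size and planted
#'   copy count for the numt stage.
#' @param panel_n,panel_divergence panel used by the diversity/parsimony
#'   stages.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(outdir, seed = 1L,
                            stages = c("simulate", "assemble", "numt",
                                       "capture", "diversity", "parsimony"),
                            inputs = list(),
                            numt_background_bp = 200000L, numt_n = 8L,
                            panel_n = 6L, panel_divergence = 0.01) {
  known <- c("simulate", "assemble", "numt", "capture", "diversity", "parsimony")
  bad <- setdiff(stages, known)
  if (length(bad)) {
    stop(errorCondition(sprintf("unknown pipeline stage(s): %s",
                                paste(bad, collapse = ", ")),
                        class = "mitoforge_config_error"))
  }
  in_files <- as.character(unlist(inputs))
  missing_in <- in_files[!file.exists(in_files)]
  if (length(missing_in)) {
    stop(errorCondition(sprintf("missing input file(s): %s",
                                paste(missing_in, collapse = ", ")),
                        class = "mitoforge_config_error"))
  }
  structure(list(outdir = outdir, seed = as.integer(seed), stages = stages,
                 inputs = inputs,
                 numt_background_bp = as.integer(numt_background_bp),
                 numt_n = as.integer(numt_n),
                 panel_n = as.integer(panel_n),
                 panel_divergence = panel_divergence),
            class = "pipeline_config")
}

stage_try <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop(errorCondition(
      sprintf("pipeline stage '%s' failed: %s", stage, conditionMessage(e)),
      class = c("mitoforge_stage_error", "error")), call. = FALSE)
  })
}

#' Run the synthetic end-to-end pipeline
#'
#' Chains simulate, assemble, NUMT discovery, capture/consensus,
#' diversity, and parsimony on one seeded synthetic scenario, writing
#' every artifact under `config$outdir` and returning a manifest with MD5
#' checksums. Identical config + seed reproduces identical checksums.
#'
#' @param config a [pipeline_config()].
#' @return tibble manifest of class `pipeline_manifest`: `file`, `bytes`,
#'   `md5`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  out <- function(...) file.path(config$outdir, ...)
  seed <- config$seed
  sc <- NULL
  assembly <- NULL

  if ("simulate" %in% config$stages) {
    stage_try("simulate", {
      sc <- study_scenario(seed)
      write_fasta(sc$genome, out("mitogenome.fasta"))
      write_features(sc$features, out("features.tsv"))
      write_fastq(sc$reads, out("reads"))
      write_track_tsv(sc$evidence$amplicons, out("amplicons.tsv"),
                      "amplicon design; positions 0-based half-open, bp")
      message(sprintf("[simulate] %d bp genome, %d read pairs, %d long reads",
                      sc$genome$length, nrow(sc$reads$paired),
                      nrow(sc$reads$long)))
    })
  }
  if ("assemble" %in% config$stages) {
    stage_try("assemble", {
      if (is.null(sc)) sc <- study_scenario(seed)
      assembly <- assemble_mitogenome(sc$reads, sc$reference, sc$ref_features,
                                      sc$evidence, mito_cov = 100,
                                      autosomal_cov = 5)
      if (assembly$circularized) {
        write_fasta(assembly$assembled, out("assembly.fasta"))
      }
      forks <- generics::tidy(assembly)
      write_track_tsv(forks, out("forks.tsv"),
                      "assembly fork events; positions 0-based on the contig")
      jsonlite::write_json(as.list(generics::glance(assembly)),
                           out("assembly_report.json"), auto_unbox = TRUE,
                           digits = NA)
      message(sprintf("[assemble] status=%s, %d fork(s)", assembly$status,
                      assembly$n_forks))
    })
  }
  if ("numt" %in% config$stages) {
    stage_try("numt", {
      if (is.null(sc)) sc <- study_scenario(seed)
      bg <- plant_numts(config$numt_background_bp, sc$genome, config$numt_n,
                        length_range = c(150, 1500),
                        identity_range = c(0.70, 0.95),
                        seed = seed + 10L, measure_identity = FALSE)
      hits <- numt_search(sc$genome, bg)
      panel <- simulate_panel(sc$genome, 3L, divergence = c(0.01, 0.02, 0.032),
                              seed = seed + 11L)
      thr <- calibrate_identity_threshold(substring(panel, 1, 4000))
      kept <- filter_and_dedupe(hits, thr)
      report <- summarize_numts(kept, nchar(bg$seq))
      write_track_tsv(bg$planted, out("numt_truth.tsv"),
                      "planted NUMT truth; coordinates 0-based half-open")
      write_numt_hits(kept, out("numt_hits.tsv"))
      jsonlite::write_json(as.list(report), out("numt_report.json"),
                           auto_unbox = TRUE, digits = NA)
      message(sprintf("[numt] %d hits kept at threshold %.1f%%",
                      nrow(kept), thr))
    })
  }
  if ("capture" %in% config$stages) {
    stage_try("capture", {
      if (is.null(sc)) sc <- study_scenario(seed)
      baits <- design_baits(sc$genome)
      write_fasta(setNames(baits$baits$seq,
                           sprintf("bait%05d", baits$baits$start)),
                  out("baits.fasta"))
      write_track_tsv(tibble(seq = sc$genome$id, start = baits$baits$start,
                             end = baits$baits$start + baits$bait_length),
                      out("baits.bed"), "bait tiling; 0-based half-open")
      ind <- circ_seq(simulate_panel(sc$genome, 1L, 0.002, seed = seed + 20L),
                      id = "individual1")
      rs <- simulate_reads(ind, read_profile(coverage = 30, long_n = 0),
                           seed = seed + 21L)
      pl <- place_reads(rs, sc$genome)
      cons <- call_consensus(pl, rs, sc$genome, individual_id = "individual1")
      write_fasta(setNames(cons$seq, cons$individual_id),
                  out("consensus.fasta"))
      write_track_tsv(tibble(pos = seq_along(cons$depth) - 1L,
                             depth = cons$depth),
                      out("consensus_depth.tsv"), "per-position read depth")
      message(sprintf("[capture] %d baits; consensus with %d uncalled sites",
                      nrow(baits$baits),
                      sum(strsplit(cons$seq, "")[[1]] == "N")))
    })
  }
  panel <- NULL
  if ("diversity" %in% config$stages || "parsimony" %in% config$stages) {
    if (is.null(sc)) sc <- study_scenario(seed)
    panel <- simulate_panel(sc$genome, config$panel_n,
                            divergence = config$panel_divergence,
                            seed = seed + 30L)
  }
  if ("diversity" %in% config$stages) {
    stage_try("diversity", {
      aln <- alignment_matrix(panel)
      ref_taxon <- aln$taxa[1]
      for (other in aln$taxa[-1]) {
        d <- pairwise_differences(aln, ref_taxon, other)
        tr <- block_density(d)
        write_density_track(tr, out(sprintf("density_%s_vs_%s.tsv",
                                            ref_taxon, other)))
      }
      pi_val <- nucleotide_diversity(aln)
      im <- identity_matrix(aln)
      utils::write.csv(im, out("identity_matrix.csv"))
      jsonlite::write_json(list(nucleotide_diversity = pi_val),
                           out("diversity.json"), auto_unbox = TRUE,
                           digits = NA)
      message(sprintf("[diversity] pi = %.5g over %d taxa", pi_val,
                      length(aln$taxa)))
    })
  }
  if ("parsimony" %in% config$stages) {
    stage_try("parsimony", {
      aln <- alignment_matrix(panel)
      tree <- ape::read.tree(text = paste0(
        "(", paste(aln$taxa, collapse = ","), ");"))
      stats <- homoplasy_indices(tree, aln)
      jsonlite::write_json(stats, out("parsimony_stats.json"),
                           auto_unbox = TRUE, digits = NA)
      message(sprintf("[parsimony] length %d steps on %d sites",
                      stats$tree_length[1], stats$n_sites[1]))
    })
  }
  files <- list.files(config$outdir, full.names = TRUE)
  manifest <- tibble(
    file = basename(files),
    bytes = file.size(files),
    md5 = unname(tools::md5sum(files))
  )
  class(manifest) <- c("pipeline_manifest", class(manifest))
  manifest
}
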