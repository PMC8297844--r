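#' Assemble and validate a pipeline configuration
#'
#' Inputs may be given as in-memory objects (the native interface; what the
#' synthetic generator produces) or as file paths (FASTA via Biostrings,
#' FASTQ Phred+33, GFF3 via rtracklayer), which are loaded and validated
#' here, before any stage runs.
#'
#' @param reads `fastq_reads` or FASTQ path.
#' @param genome fungal genome, `DNAStringSet` or FASTA path.
#' @param tracks exon/intron/repeat annotation, `GRanges` (with `type`
#'   column) or GFF3 path.
#' @param ncrna named list of `DNAStringSet` structural-RNA reference sets.
#' @param mature_reference known mature-miRNA reference, `DNAStringSet` or
#'   FASTA path; `NULL` skips known-milRNA matching.
#' @param fungal_transcripts fungal transcript set for self-target
#'   verification; `NULL` skips the stage.
#' @param host_genome,host_transcripts host genome and transcript set;
#'   `NULL` skips the transboundary stages.
#' @param cleanse,hairpin,model,self_rules parameter objects (defaults used
#'   when `NULL`).
#' @param rulesets host ruleset names for target prediction.
#' @param flank,stability_mfe transboundary screen settings.
#' @param rng_seed seed recorded in the manifest.
#' @param engine folding engine; created on demand if `NULL`.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(reads, genome, tracks = NULL, ncrna = NULL,
                            mature_reference = NULL,
                            fungal_transcripts = NULL,
                            host_genome = NULL, host_transcripts = NULL,
                            cleanse = NULL, hairpin = NULL, model = NULL,
                            self_rules = NULL,
                            rulesets = c("expectation", "seed17", "allen"),
                            flank = 100L, stability_mfe = -85,
                            rng_seed = 1L, engine = NULL) {
  load_fasta <- function(x, what) {
    if (is.null(x) || !is.character(x)) return(x)
    if (!file.exists(x)) stop("missing ", what, " file: ", x)
    Biostrings::readDNAStringSet(x)
  }
  if (is.character(reads)) {
    if (!file.exists(reads)) stop("missing reads file: ", reads)
    reads <- read_fastq(reads)
  }
  genome <- load_fasta(genome, "genome")
  mature_reference <- load_fasta(mature_reference, "mature reference")
  fungal_transcripts <- load_fasta(fungal_transcripts, "fungal transcripts")
  host_genome <- load_fasta(host_genome, "host genome")
  host_transcripts <- load_fasta(host_transcripts, "host transcripts")
  if (is.character(tracks)) {
    if (!file.exists(tracks)) stop("missing tracks file: ", tracks)
    if (!requireNamespace("rtracklayer", quietly = TRUE)) {
      stop("reading GFF3 tracks requires the rtracklayer package")
    }
    tracks <- rtracklayer::import(tracks)
  }
  structure(list(
    reads = reads, genome = genome, tracks = tracks, ncrna = ncrna,
    mature_reference = mature_reference,
    fungal_transcripts = fungal_transcripts,
    host_genome = host_genome, host_transcripts = host_transcripts,
    cleanse = cleanse %||% cleanse_params(),
    hairpin = hairpin %||% hairpin_params(),
    model = model %||% pairing_model(),
    self_rules = self_rules %||% self_target_rules(),
    rulesets = rulesets, flank = flank, stability_mfe = stability_mfe,
    rng_seed = rng_seed, engine = engine
  ), class = "pipeline_config")
}

#' Run the full milRNA discovery and target-prediction pipeline
#'
#' Executes the stages in fixed order — read cleansing, tag atlas (collapse,
#' map, classify, profile), milRNA discovery (known matching, hairpin
#' calling, TPM), self-target verification, transboundary screen, host
#' target prediction under each ruleset, and the three-ruleset consensus —
#' and returns all stage outputs plus a manifest of per-stage record counts
#' and echoed parameters. Re-running with an identical configuration gives
#' identical results (the folding engine is deterministic).
#'
#' @param config [pipeline_config()].
#' @return list of class `pipeline_result` with elements `cleanse`, `atlas`,
#'   `discovery`, `self_targets`, `transboundary`, `host_targets`,
#'   `consensus`, `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  engine <- config$engine %||% vienna_engine()
  stage_counts <- c()
  note <- function(stage, n) stage_counts[[stage]] <<- n

  cl <- cleanse(config$reads, config$cleanse)
  note("cleanse", cl$report$clean_tags)

  tags <- collapse_tags(cl$inserts)
  loci <- map_tags(tags, config$genome)
  classified <- classify_tags(tags, loci,
                              config$tracks %||% GenomicRanges::GRanges(),
                              config$ncrna %||% list())
  profile <- length_first_base_profile(classified$categories)
  note("atlas", nrow(tags))

  known <- if (!is.null(config$mature_reference) &&
               length(config$mature_reference) > 0L) {
    match_known(classified$categories[classified$categories$category ==
                                        "unannotated", , drop = FALSE],
                config$mature_reference)
  } else {
    data.frame(sequence = character(), count = integer(),
               reference = character(), mismatches = integer())
  }
  novel_pool <- classified$categories[
    classified$categories$category == "unannotated" &
      !(classified$categories$sequence %in% known$sequence), , drop = FALSE]
  candidates <- call_hairpins(novel_pool, loci, config$genome,
                              config$hairpin, engine)
  novel_table <- milrna_table(candidates)
  total_tags <- sum(tags$count)
  if (nrow(novel_table) && total_tags > 0) {
    novel_table$TPM <- round(tpm(novel_table$total_reads, total_tags), 2)
  }
  note("discovery", nrow(novel_table))

  milrnas <- rbind(
    if (nrow(novel_table)) data.frame(id = novel_table$novel_milRNA,
                                      sequence = novel_table$sequence)
    else data.frame(id = character(), sequence = character()),
    if (nrow(known)) data.frame(id = known$reference, sequence = known$sequence)
    else data.frame(id = character(), sequence = character())
  )
  milrnas <- milrnas[!duplicated(milrnas$sequence), , drop = FALSE]

  self_hits <- if (!is.null(config$fungal_transcripts) && nrow(milrnas)) {
    verify_self_targets(milrnas, config$fungal_transcripts,
                        config$self_rules, engine, config$model)
  } else NULL
  note("self_targets", if (is.null(self_hits)) 0L else nrow(self_hits))

  screen <- host_hits <- cons <- NULL
  if (!is.null(config$host_genome) && nrow(milrnas)) {
    screen <- screen_transboundary(milrnas, config$host_genome, config$flank,
                                   config$stability_mfe, engine)
    note("transboundary", nrow(screen))
    eligible <- milrnas[milrnas$id %in% screen$milrna[screen$eligible], ,
                        drop = FALSE]
    if (!is.null(config$host_transcripts) && nrow(eligible)) {
      host_hits <- lapply(config$rulesets, function(rs) {
        predict_host_targets(eligible, config$host_transcripts, rs,
                             config$model)
      })
      names(host_hits) <- config$rulesets
      note("host_targets", sum(vapply(host_hits, nrow, integer(1))))
      cons <- consensus_targets(host_hits)
      note("consensus", nrow(cons$consensus))
    } else {
      note("host_targets", 0L); note("consensus", 0L)
    }
  } else {
    note("transboundary", 0L); note("host_targets", 0L); note("consensus", 0L)
  }

  manifest <- list(
    stages = data.frame(stage = names(stage_counts),
                        records = unlist(stage_counts, use.names = FALSE),
                        completed = TRUE),
    parameters = list(cleanse = config$cleanse, hairpin = config$hairpin,
                      model = config$model, self_rules = config$self_rules,
                      rulesets = config$rulesets, flank = config$flank,
                      stability_mfe = config$stability_mfe),
    rng_seed = config$rng_seed
  )
  structure(list(cleanse = cl, atlas = list(tags = classified$categories,
                                            loci = loci,
                                            summary = classified$summary,
                                            profile = profile),
                 discovery = list(known = known, candidates = candidates,
                                  table = novel_table, milrnas = milrnas),
                 self_targets = self_hits, transboundary = screen,
                 host_targets = host_hits, consensus = cons,
                 manifest = manifest),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  print(x$manifest$stages, row.names = FALSE)
  invisible(x)
}

#' Render the standard pipeline reports
#'
#' Produces the three tabular reports of a milRNA study: the read-filtering
#' accounting (mixed-denominator percentages), the tag-category summary
#' (total and unique counts with percentages of the clean totals), and the
#' novel-milRNA table (name, sequence, precursor location and MFE).
#'
#' @param result `pipeline_result` from [run_pipeline()].
#' @return list of data.frames `table1`, `table2`, `table3`.
#' @export
render_reports <- function(result) {
  list(table1 = report_percentages(result$cleanse$report),
       table2 = result$atlas$summary,
       table3 = result$discovery$table)
}
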