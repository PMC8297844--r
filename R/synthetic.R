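#' Synthetic small-RNA study generator
#'
#' Builds every input the milRNA pipeline consumes — a fungal genome with
#' planted hairpin precursors and annotated decoy loci, a sequencing library
#' with controlled contamination, and a host genome/transcriptome carrying
#' designed target sites — with full ground truth, so downstream stages can be
#' tested end to end without any external data.
#'
#' @name synthetic
NULL

# Evaluate `code` under a fixed RNG state, restoring the caller's stream.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

DECOY_CLASSES <- c("rRNA", "tRNA", "snRNA", "snoRNA", "exon", "intron", "repeat")
NCRNA_CLASSES <- c("rRNA", "tRNA", "snRNA", "snoRNA")

decoy_length <- c(rRNA = 120L, tRNA = 75L, snRNA = 100L, snoRNA = 90L,
                  exon = 200L, intron = 150L, repeat_ = 80L)
names(decoy_length)[7] <- "repeat"

#' Construct one hairpin precursor around a mature sequence
#'
#' The star arm is the reverse complement of the mature with up to
#' `n_wobbles` planted G:U pairs and `bulge_nt` inserted (unpaired)
#' nucleotides; the loop and flanks are random. Arm placement decides whether
#' the mature sits on the 5p or 3p side of the fold-back.
#'
#' @param mature mature sequence (DNA alphabet, 18-25 nt).
#' @param loop_len loop length in nt.
#' @param n_wobbles number of G:U pairs to plant in the duplex.
#' @param bulge_nt nucleotides inserted into the star arm (bulges).
#' @param flank flank length added on both sides.
#' @param arm `"5p"` or `"3p"`.
#' @return list with `precursor`, `mature_start`/`mature_end` (1-based within
#'   the precursor), `star`, `arm`.
#' @export
make_hairpin <- function(mature, loop_len = 25L, n_wobbles = 0L,
                         bulge_nt = 0L, flank = 20L, arm = "5p") {
  L <- nchar(mature)
  star <- chars(revcomp(mature))
  if (n_wobbles > 0L) {
    mat <- chars(mature)
    eligible <- which(mat %in% c("G", "T"))
    # keep wobbles off the duplex ends so folding keeps the register
    eligible <- setdiff(eligible, c(1L, 2L, L - 1L, L))
    if (length(eligible) < n_wobbles) {
      stop("mature sequence has too few G/T positions for ", n_wobbles,
           " wobbles")
    }
    pos <- sort(sample(eligible, n_wobbles))
    for (i in pos) {
      star[L - i + 1L] <- if (mat[i] == "G") "T" else "G"
    }
  }
  if (bulge_nt > 0L) {
    at <- max(3L, L %/% 2L)
    star <- append(star, chars(random_dna(1, bulge_nt)), after = at)
  }
  star <- paste(star, collapse = "")
  loop <- random_dna(1, loop_len)
  f5 <- random_dna(1, flank)
  f3 <- random_dna(1, flank)
  if (arm == "5p") {
    precursor <- paste0(f5, mature, loop, star, f3)
    mstart <- flank + 1L
  } else {
    precursor <- paste0(f5, star, loop, mature, f3)
    mstart <- flank + nchar(star) + loop_len + 1L
  }
  list(precursor = precursor, mature_start = mstart,
       mature_end = mstart + L - 1L, star = star, arm = arm,
       loop_len = loop_len)
}

#' Build a synthetic fungal genome with planted milRNA hairpins and decoys
#'
#' Plants `n_hairpins` validated hairpin precursors (each refolded with the
#' engine and required to pass the full eleven-criterion acceptance test of
#' the hairpin caller) and `n_decoys_per_class` loci for each of the seven
#' decoy classes (rRNA, tRNA, snRNA, snoRNA, exon, intron, repeat) into a
#' random background sequence. Placement is non-overlapping and reproducible
#' from `rng_seed`.
#'
#' @param n_hairpins number of milRNA hairpin loci to plant.
#' @param n_decoys_per_class decoy loci per class.
#' @param genome_length total contig length (nt).
#' @param rng_seed integer seed; the same seed reproduces the genome
#'   byte-for-byte.
#' @param engine folding engine from [vienna_engine()]; created on demand if
#'   `NULL`.
#' @param params hairpin acceptance parameters, see [hairpin_params()].
#' @param max_tries placement/validation retries before giving up.
#' @return list with `genome` (named [Biostrings::DNAStringSet-class]),
#'   `tracks` ([GenomicRanges::GRanges-class] with a `type` column for
#'   exon/intron/repeat intervals), `ncrna` (named list of `DNAStringSet`
#'   reference sets for the four structural-RNA classes) and `truth`
#'   (a `synthetic_truth` object).
#' @export
build_genome <- function(n_hairpins, n_decoys_per_class, genome_length,
                         rng_seed, engine = NULL, params = hairpin_params(),
                         max_tries = 40L) {
  stopifnot(n_hairpins >= 0L, n_decoys_per_class >= 0L)
  if (is.null(engine) && n_hairpins > 0L) engine <- vienna_engine()
  with_seed(rng_seed, {
    contig <- "scaffold_1"
    background <- random_dna(1, genome_length, gc = 0.45)
    occupied <- IRanges::IRanges()

    place <- function(width) {
      for (i in seq_len(max_tries * 5L)) {
        start <- sample.int(genome_length - width - 1L, 1L)
        cand <- IRanges::IRanges(start, width = width)
        if (length(IRanges::findOverlaps(cand, occupied)) == 0L) {
          occupied <<- c(occupied, cand)
          return(start)
        }
      }
      stop("could not place a ", width, " nt locus: genome_length too small")
    }

    genome_chars <- chars(background)
    milrnas <- list()
    for (h in seq_len(n_hairpins)) {
      hp <- NULL
      for (try in seq_len(max_tries)) {
        mature <- paste0("T", random_dna(1, sample(18:25, 1L) - 1L, gc = 0.55))
        # always plant >= 1 duplex imperfection: a perfect palindrome would
        # let the mature tag map onto its own star arm
        n_wob <- sample(0:2, 1L)
        cand <- make_hairpin(mature,
                             loop_len = sample(16:40, 1L),
                             n_wobbles = n_wob,
                             bulge_nt = if (n_wob == 0L) 1L else sample(0:1, 1L),
                             flank = params$flank,
                             arm = sample(c("5p", "3p"), 1L))
        fold <- engine$fold(cand$precursor)
        ok <- assess_hairpin(fold$structure, fold$mfe,
                             cand$mature_start, cand$mature_end, params)
        if (ok$ok) { hp <- c(cand, list(mfe = fold$mfe, mature = mature)); break }
      }
      if (is.null(hp)) stop("failed to construct a valid hairpin after ",
                            max_tries, " tries")
      strand <- sample(c("+", "-"), 1L)
      plen <- nchar(hp$precursor)
      start <- place(plen)
      insert <- if (strand == "+") hp$precursor else revcomp(hp$precursor)
      genome_chars[start:(start + plen - 1L)] <- chars(insert)
      # genomic coordinates of the mature arm (strand-aware)
      if (strand == "+") {
        m1 <- start + hp$mature_start - 1L
        m2 <- start + hp$mature_end - 1L
      } else {
        m2 <- start + plen - hp$mature_start
        m1 <- start + plen - hp$mature_end
      }
      milrnas[[h]] <- data.frame(
        id = sprintf("planted_%03d", h), mature = hp$mature, star = hp$star,
        arm = hp$arm, contig = contig, pre_start = start,
        pre_end = start + plen - 1L, strand = strand,
        mature_start = m1, mature_end = m2,
        loop_len = hp$loop_len, mfe = hp$mfe
      )
    }
    milrnas <- if (length(milrnas)) do.call(rbind, milrnas) else
      data.frame(id = character(), mature = character(), star = character(),
                 arm = character(), contig = character(),
                 pre_start = integer(), pre_end = integer(),
                 strand = character(), mature_start = integer(),
                 mature_end = integer(), loop_len = integer(), mfe = numeric())

    decoys <- list()
    for (cls in DECOY_CLASSES) {
      for (d in seq_len(n_decoys_per_class)) {
        width <- decoy_length[[cls]]
        seq <- random_dna(1, width, gc = 0.5)
        start <- place(width)
        genome_chars[start:(start + width - 1L)] <- chars(seq)
        decoys[[length(decoys) + 1L]] <- data.frame(
          class = cls, contig = contig, start = start,
          end = start + width - 1L, strand = "+", seq = seq
        )
      }
    }
    decoys <- if (length(decoys)) do.call(rbind, decoys) else
      data.frame(class = character(), contig = character(), start = integer(),
                 end = integer(), strand = character(), seq = character())

    genome <- Biostrings::DNAStringSet(paste(genome_chars, collapse = ""))
    names(genome) <- contig

    interval_decoys <- decoys[decoys$class %in% c("exon", "intron", "repeat"), ]
    tracks <- GenomicRanges::GRanges(
      seqnames = interval_decoys$contig,
      ranges = IRanges::IRanges(interval_decoys$start, interval_decoys$end),
      strand = interval_decoys$strand,
      type = interval_decoys$class
    )
    ncrna <- lapply(NCRNA_CLASSES, function(cls) {
      sel <- decoys[decoys$class == cls, ]
      s <- Biostrings::DNAStringSet(sel$seq)
      if (nrow(sel)) names(s) <- sprintf("%s_decoy_%02d", cls, seq_len(nrow(sel)))
      s
    })
    names(ncrna) <- NCRNA_CLASSES

    truth <- structure(
      list(milrnas = milrnas, decoys = decoys,
           target_sites = empty_site_table(), rng_seed = rng_seed),
      class = "synthetic_truth"
    )
    list(genome = genome, tracks = tracks, ncrna = ncrna, truth = truth)
  })
}

empty_site_table <- function() {
  data.frame(milrna = character(), transcript = character(),
             site_start = integer(), site_end = integer(),
             n_mismatch = integer(), n_wobble = integer(),
             mismatch_pos = character(), wobble_pos = character(),
             stringsAsFactors = FALSE)
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat("<synthetic_truth>", nrow(x$milrnas), "planted milRNAs,",
      nrow(x$decoys), "decoy loci,", nrow(x$target_sites),
      "planted target sites (seed", x$rng_seed, ")\n")
  invisible(x)
}

# Contamination class labels, in filter order
CONTAM_CLASSES <- c("low_quality", "adapter3_null", "insert_null",
                    "adapter5", "polyA", "short")

#' Simulate an adapter-ligated small-RNA sequencing library
#'
#' Emits reads of structure `[insert][3' adapter]` with Phred+33 qualities.
#' Clean inserts are drawn from the planted mature milRNAs with per-milRNA
#' abundances sampled log-uniformly over `depth_range` (emulating the dynamic
#' range seen in real libraries, roughly 5 to 25,000 reads per milRNA).
#' Contaminated reads are injected at the given per-class rates:
#' `low_quality` (two bases at Q10), `adapter3_null` (no 3' adapter),
#' `insert_null` (adapter dimer, empty insert), `adapter5` (5' adapter inside
#' the insert), `polyA` (poly-A insert), and `short` (insert < 18 nt). The
#' true class of every read is recorded in its name (`class=<label>`) so
#' filters can be scored against truth.
#'
#' @param truth `synthetic_truth` from [build_genome()].
#' @param n_reads total number of reads to emit.
#' @param contamination_rates named fractions over the six classes; missing
#'   classes default to 0. Must sum to <= 1; the remainder is clean.
#' @param adapter3,adapter5 adapter sequences (defaults: Illumina small-RNA
#'   adapters).
#' @param depth_range log-uniform range for per-milRNA abundance weights.
#' @param min_reads_per_milrna every planted milRNA is guaranteed at least
#'   this many clean reads (deep libraries observe every expressed milRNA;
#'   without a floor a low-weight milRNA could draw zero reads by chance).
#' @param rng_seed integer seed.
#' @return object of class `fastq_reads`: list with `id`, `sequence`,
#'   `quality` (parallel character vectors) and `class` (truth labels).
#' @export
simulate_reads <- function(truth, n_reads = 10000L,
                           contamination_rates = c(),
                           adapter3 = "TGGAATTCTCGGGTGCCAAGG",
                           adapter5 = "GTTCAGAGTTCTACAGTCCGACGATC",
                           depth_range = c(5, 25000),
                           min_reads_per_milrna = 1L,
                           rng_seed = 1L) {
  rates <- setNames(numeric(length(CONTAM_CLASSES)), CONTAM_CLASSES)
  if (length(contamination_rates)) {
    unknown <- setdiff(names(contamination_rates), CONTAM_CLASSES)
    if (length(unknown)) stop("unknown contamination class: ",
                              paste(unknown, collapse = ", "))
    rates[names(contamination_rates)] <- contamination_rates
  }
  if (any(rates < 0) || sum(rates) > 1) {
    stop("contamination rates must be in [0,1] and sum to <= 1")
  }
  with_seed(rng_seed, {
    classes <- sample(c(CONTAM_CLASSES, "clean"), n_reads, replace = TRUE,
                      prob = c(rates, 1 - sum(rates)))
    matures <- truth$milrnas$mature
    if (length(matures)) {
      w <- exp(runif(length(matures), log(depth_range[1]), log(depth_range[2])))
      w <- w / sum(w)
    }
    q_hi <- "G"   # Phred+33 Q38
    q_lo <- "+"   # Phred+33 Q10
    seqs <- character(n_reads); quals <- character(n_reads)
    srcs <- character(n_reads)
    for (i in seq_len(n_reads)) {
      cls <- classes[i]
      src <- "background"
      insert <- switch(cls,
        clean = , low_quality = {
          if (length(matures)) {
            k <- sample.int(length(matures), 1L, prob = w)
            src <- truth$milrnas$id[k]
            matures[k]
          } else random_dna(1, sample(18:25, 1L))
        },
        adapter3_null = random_dna(1, sample(18:25, 1L)),
        insert_null = "",
        adapter5 = paste0(adapter5, random_dna(1, 2L)),
        polyA = strrep("A", sample(18:25, 1L)),
        short = random_dna(1, sample(10:17, 1L))
      )
      read <- if (cls == "adapter3_null") insert else paste0(insert, adapter3)
      qual <- strrep(q_hi, nchar(read))
      if (cls == "low_quality" && nchar(read) >= 2L) {
        pos <- sample.int(nchar(read), 2L)
        qc <- chars(qual); qc[pos] <- q_lo; qual <- paste(qc, collapse = "")
      }
      seqs[i] <- read; quals[i] <- qual; srcs[i] <- src
    }
    # coverage floor: recycle the first clean reads onto unobserved milRNAs
    if (length(matures) && min_reads_per_milrna > 0L) {
      clean_idx <- which(classes == "clean")
      need <- unlist(lapply(seq_along(matures), function(k) {
        id <- truth$milrnas$id[k]
        shortfall <- min_reads_per_milrna - sum(srcs[clean_idx] == id)
        rep(k, max(0L, shortfall))
      }))
      free <- clean_idx[!srcs[clean_idx] %in%
                          truth$milrnas$id[unique(need)]]
      take <- utils::head(free, length(need))
      for (j in seq_along(take)) {
        k <- need[j]
        seqs[take[j]] <- paste0(matures[k], adapter3)
        quals[take[j]] <- strrep(q_hi, nchar(seqs[take[j]]))
        srcs[take[j]] <- truth$milrnas$id[k]
      }
    }
    structure(list(
      id = sprintf("read%06d|class=%s|src=%s", seq_len(n_reads), classes, srcs),
      sequence = seqs, quality = quals, class = classes
    ), class = "fastq_reads")
  })
}

#' @export
print.fastq_reads <- function(x, ...) {
  cat("<fastq_reads>", length(x$sequence), "reads\n")
  invisible(x)
}

#' Write simulated reads as FASTQ (Phred+33)
#' @param reads `fastq_reads` object.
#' @param path output file.
#' @export
write_fastq <- function(reads, path) {
  rec <- rbind(paste0("@", reads$id), reads$sequence, "+", reads$quality)
  writeLines(as.vector(rec), path)
  invisible(path)
}

#' Build the default synthetic study
#'
#' One call that assembles the complete default study used throughout the
#' package's examples and checks: a 60 kb genome with 6 planted hairpins and
#' 2 decoy loci per class; a 10,000-read library with contamination rates
#' 5% low-quality, 5% missing 3' adapter, 2% empty insert, 1% 5'-adapter,
#' 1% poly-A and 5% short inserts; a known-miRNA reference containing the
#' sixth planted mature (so the known-milRNA path is exercised); and a host
#' with 8 transcripts carrying six designed sites — a perfect complement, a
#' single non-seed mismatch, seed wobbles, a single seed mismatch (all four
#' expected to reach three-ruleset consensus), three seed mismatches and a
#' position-10 mismatch (both expected to miss consensus) — plus the sixth
#' milRNA embedded in a deeply stable synthetic host hairpin (expected
#' transboundary-ineligible).
#'
#' @param rng_seed integer master seed; sub-stages derive seeds from it.
#' @param engine folding engine; created on demand if `NULL`.
#' @return list with `genome` (the [build_genome()] output), `reads`,
#'   `host` (the [build_host()] output), `mature_reference`, and `expected`
#'   (list with `consensus_transcripts`, `noncensus_transcripts`,
#'   `host_encoded` — the designed ground truth).
#' @export
synthetic_study <- function(rng_seed = 1L, engine = NULL) {
  if (is.null(engine)) engine <- vienna_engine()
  g <- build_genome(6L, 2L, 60000L, rng_seed = rng_seed, engine = engine)
  reads <- simulate_reads(
    g$truth, n_reads = 10000L,
    contamination_rates = c(low_quality = 0.05, adapter3_null = 0.05,
                            insert_null = 0.02, adapter5 = 0.01,
                            polyA = 0.01, short = 0.05),
    rng_seed = rng_seed + 1L)
  ids <- g$truth$milrnas$id
  matures <- g$truth$milrnas$mature
  seed_gt <- function(k, n) {
    pool <- intersect(which(chars(matures[k]) %in% c("G", "T")), 2:12)
    paste(utils::head(pool, n), collapse = ",")
  }
  design <- data.frame(
    milrna = ids[c(1:5, 1L)],
    mismatch_pos = c("", "14", "", "3", "3,5,7", "10"),
    wobble_pos = c("", "", seed_gt(3L, 2L), "", "", "")
  )
  host <- build_host(g$truth, n_transcripts = 8L, site_design = design,
                     rng_seed = rng_seed + 2L, embed_stable = ids[6])
  ref <- Biostrings::DNAStringSet(c("known-mir-1" = matures[6]))
  list(genome = g, reads = reads, host = host, mature_reference = ref,
       expected = list(
         consensus_transcripts = sprintf("transcript_%03d", 1:4),
         consensus_milrnas = matures[1:4],
         nonconsensus_transcripts = sprintf("transcript_%03d", 5:6),
         host_encoded = "known-mir-1"))
}

#' Design a target site for a milRNA
#'
#' Returns the site sequence (target strand, 5'->3') whose reverse-complement
#' pairing with the milRNA is perfect except at the designed positions.
#' Positions are numbered 1..L from the milRNA 5' end. A designed wobble needs
#' a G or T at that milRNA position (G:U pairs only exist there).
#'
#' @param milrna mature sequence (DNA alphabet).
#' @param mismatch_pos integer positions to turn into mismatches.
#' @param wobble_pos integer positions to turn into G:U wobbles.
#' @return the site sequence.
#' @export
design_site <- function(milrna, mismatch_pos = integer(), wobble_pos = integer()) {
  L <- nchar(milrna)
  if (any(c(mismatch_pos, wobble_pos) < 1) ||
      any(c(mismatch_pos, wobble_pos) > L) ||
      anyDuplicated(c(mismatch_pos, wobble_pos))) {
    stop("site design inconsistent with milRNA length ", L)
  }
  m <- chars(milrna)
  site <- chars(revcomp(milrna))
  for (i in wobble_pos) {
    if (!m[i] %in% c("G", "T")) {
      stop("wobble requires G or T at milRNA position ", i, " (found ", m[i], ")")
    }
    site[L - i + 1L] <- if (m[i] == "G") "T" else "G"
  }
  for (i in mismatch_pos) {
    forbidden <- c(COMPLEMENT[[m[i]]],
                   if (m[i] == "G") "T" else if (m[i] == "T") "G")
    site[L - i + 1L] <- setdiff(c("A", "C", "G", "T"), c(forbidden, m[i]))[1]
  }
  paste(site, collapse = "")
}

#' Build a synthetic host genome and transcriptome with designed target sites
#'
#' Each row of `site_design` yields one transcript carrying one site built by
#' [design_site()]; positions may be given explicitly (comma-separated strings
#' in `mismatch_pos`/`wobble_pos`) or as counts (`n_mismatch`/`n_wobble`) with
#' placement inside the seed region (positions 2-12) when `in_seed` is TRUE
#' and after position 13 otherwise. The host genome is random background; a
#' milRNA listed in `embed_stable` is planted inside a long synthetic inverted
#' repeat (a deeply stable fold-back, for transboundary-ineligibility
#' testing), and one listed in `embed_plain` is planted with random
#' (structure-poor) flanks.
#'
#' @param truth `synthetic_truth`; designed milRNA ids must exist in it.
#' @param n_transcripts total transcripts (>= number of design rows; the
#'   remainder carry no site).
#' @param site_design data.frame, see Details.
#' @param rng_seed integer seed.
#' @param transcript_length transcript length (nt).
#' @param host_genome_length host genome background length (nt).
#' @param embed_stable,embed_plain milRNA ids to plant in the host genome.
#' @return list with `host_genome` (DNAStringSet), `transcripts`
#'   (DNAStringSet) and `truth` (updated with `target_sites`).
#' @export
build_host <- function(truth, n_transcripts, site_design = NULL,
                       rng_seed = 1L, transcript_length = 300L,
                       host_genome_length = 20000L,
                       embed_stable = character(), embed_plain = character()) {
  if (is.null(site_design)) site_design <- data.frame(milrna = character())
  known <- c(truth$milrnas$id, truth$milrnas$mature)
  bad <- setdiff(site_design$milrna, known)
  if (length(bad)) stop("unknown milRNA in site design: ", bad[1])
  if (n_transcripts < nrow(site_design)) {
    stop("n_transcripts must cover all designed sites")
  }
  lookup <- function(id) {
    i <- match(id, truth$milrnas$id)
    if (is.na(i)) id else truth$milrnas$mature[i]
  }
  with_seed(rng_seed, {
    tx <- character(n_transcripts)
    sites <- list()
    for (r in seq_len(nrow(site_design))) {
      row <- site_design[r, , drop = FALSE]
      mseq <- lookup(row$milrna)
      L <- nchar(mseq)
      parse_pos <- function(x) {
        if (is.null(x) || is.na(x) || !nzchar(as.character(x))) integer() else
          as.integer(strsplit(as.character(x), ",")[[1]])
      }
      mm <- parse_pos(row$mismatch_pos %||% NA)
      wb <- parse_pos(row$wobble_pos %||% NA)
      if (!length(mm) && !is.null(row$n_mismatch) && !is.na(row$n_mismatch) &&
          row$n_mismatch > 0) {
        pool <- if (isTRUE(row$in_seed)) seq(3L, 11L, by = 2L) else
          seq(14L, L - 1L, by = 2L)
        mm <- pool[seq_len(row$n_mismatch)]
      }
      if (!length(wb) && !is.null(row$n_wobble) && !is.na(row$n_wobble) &&
          row$n_wobble > 0) {
        gt <- which(chars(mseq) %in% c("G", "T"))
        pool <- if (isTRUE(row$in_seed)) intersect(gt, 2:12) else
          intersect(gt, seq(13L, L))
        pool <- setdiff(pool, mm)
        if (length(pool) < row$n_wobble) {
          stop("cannot place ", row$n_wobble, " wobbles for ", row$milrna)
        }
        wb <- pool[seq_len(row$n_wobble)]
      }
      site <- design_site(mseq, mm, wb)
      offset <- sample.int(transcript_length - L - 20L, 1L) + 10L
      tx[r] <- paste0(random_dna(1, offset - 1L), site,
                      random_dna(1, transcript_length - offset - L + 1L))
      sites[[r]] <- data.frame(
        milrna = row$milrna, transcript = sprintf("transcript_%03d", r),
        site_start = offset, site_end = offset + L - 1L,
        n_mismatch = length(mm), n_wobble = length(wb),
        mismatch_pos = paste(mm, collapse = ","),
        wobble_pos = paste(wb, collapse = ",")
      )
    }
    for (r in seq.int(nrow(site_design) + 1L, length.out = n_transcripts - nrow(site_design))) {
      tx[r] <- random_dna(1, transcript_length)
    }
    transcripts <- Biostrings::DNAStringSet(tx)
    names(transcripts) <- sprintf("transcript_%03d", seq_len(n_transcripts))

    host_chars <- chars(random_dna(1, host_genome_length, gc = 0.4))
    plant <- function(locus) {
      start <- sample.int(host_genome_length - nchar(locus) - 1L, 1L)
      host_chars[start:(start + nchar(locus) - 1L)] <<- chars(locus)
      start
    }
    for (id in embed_stable) {
      m <- lookup(id)
      arm <- paste0(random_dna(1, 40L, gc = 0.6), m, random_dna(1, 40L, gc = 0.6))
      plant(paste0(arm, random_dna(1, 8L), revcomp(arm)))
    }
    for (id in embed_plain) plant(lookup(id))
    host_genome <- Biostrings::DNAStringSet(paste(host_chars, collapse = ""))
    names(host_genome) <- "host_chr_1"

    truth$target_sites <- if (length(sites)) do.call(rbind, sites) else
      empty_site_table()
    list(host_genome = host_genome, transcripts = transcripts, truth = truth)
  })
}
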