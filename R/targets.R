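#' Fungal self-target verification rules
#'
#' The six-rule filter applied to candidate miRNA:target duplexes within the
#' fungus's own transcriptome: (1) at most `max_mismatch_equivalents`
#' mismatch equivalents over the whole duplex, G:U wobbles counting 0.5;
#' (2) no run of more than `max_adjacent_mismatches` consecutive mismatches;
#' (3) no two adjacent mismatches within `no_adjacent_band`; (4) perfect
#' pairing (no mismatch) at `forbidden_mismatch_positions`; (5) at most
#' `max_mismatch_equivalents_5prime` mismatch equivalents over
#' `five_prime_band`; (6) duplex MFE at least `min_energy_ratio` of the
#' perfect-complement duplex MFE. Rules 2-4 count full mismatches only —
#' wobbles base-pair and enter the numeric budgets of rules 1 and 5 at half
#' weight.
#'
#' @param max_mismatch_equivalents,max_adjacent_mismatches,no_adjacent_band,forbidden_mismatch_positions,max_mismatch_equivalents_5prime,five_prime_band,min_energy_ratio rule parameters.
#' @return list of class `self_target_rules`.
#' @export
self_target_rules <- function(max_mismatch_equivalents = 4.0,
                              max_adjacent_mismatches = 2L,
                              no_adjacent_band = 2:12,
                              forbidden_mismatch_positions = 10:11,
                              max_mismatch_equivalents_5prime = 2.5,
                              five_prime_band = 1:12,
                              min_energy_ratio = 0.6) {
  structure(list(max_mismatch_equivalents = max_mismatch_equivalents,
                 max_adjacent_mismatches = max_adjacent_mismatches,
                 no_adjacent_band = no_adjacent_band,
                 forbidden_mismatch_positions = forbidden_mismatch_positions,
                 max_mismatch_equivalents_5prime = max_mismatch_equivalents_5prime,
                 five_prime_band = five_prime_band,
                 min_energy_ratio = min_energy_ratio),
            class = "self_target_rules")
}

max_mismatch_run <- function(st) {
  r <- rle(st == "X")
  if (any(r$values)) max(r$lengths[r$values]) else 0L
}

# rules 1-5 on a gap-free state string; returns named logicals
check_self_rules <- function(states, rules) {
  st <- chars(states)
  mm_eq <- sum(st == "X") + 0.5 * sum(st == "W")
  band <- rules$no_adjacent_band
  adj_in_band <- any(vapply(seq_len(length(st) - 1L), function(k) {
    st[k] == "X" && st[k + 1L] == "X" &&
      k %in% band && (k + 1L) %in% band
  }, logical(1)))
  fp <- rules$forbidden_mismatch_positions
  fp <- fp[fp <= length(st)]
  b5 <- rules$five_prime_band
  b5 <- b5[b5 <= length(st)]
  mm_eq_5p <- sum(st[b5] == "X") + 0.5 * sum(st[b5] == "W")
  c(rule1 = mm_eq <= rules$max_mismatch_equivalents,
    rule2 = max_mismatch_run(st) <= rules$max_adjacent_mismatches,
    rule3 = !adj_in_band,
    rule4 = !any(st[fp] == "X"),
    rule5 = mm_eq_5p <= rules$max_mismatch_equivalents_5prime)
}

#' Verify milRNA self-targets in fungal transcripts
#'
#' Enumerates gap-free candidate sites of every milRNA in every transcript
#' and keeps the sites satisfying all six rules of [self_target_rules()].
#' The duplex energy ratio (rule 6) is only computed for sites that already
#' pass rules 1-5.
#'
#' @param milrnas data.frame with `id` and `sequence` columns.
#' @param transcripts named [Biostrings::DNAStringSet-class].
#' @param rules [self_target_rules()].
#' @param engine [vienna_engine()].
#' @param model [pairing_model()].
#' @return data.frame of verified hits: `milrna`, `transcript`,
#'   `site_start`, `site_end`, `states`, `mismatch_equivalents`,
#'   `energy_ratio`.
#' @export
verify_self_targets <- function(milrnas, transcripts,
                                rules = self_target_rules(),
                                engine = vienna_engine(),
                                model = pairing_model()) {
  if (length(transcripts) == 0L) stop("empty transcript set")
  cand <- list()
  for (i in seq_len(nrow(milrnas))) {
    mseq <- milrnas$sequence[i]
    for (t in seq_along(transcripts)) {
      aln <- align_site(mseq, as.character(transcripts[[t]]), model,
                        allow_gaps = FALSE)
      aln <- aln[aln$mismatch_equivalents <= rules$max_mismatch_equivalents, ,
                 drop = FALSE]
      if (!nrow(aln)) next
      pass15 <- vapply(aln$states, function(s) all(check_self_rules(s, rules)),
                       logical(1), USE.NAMES = FALSE)
      aln <- aln[pass15, , drop = FALSE]
      if (!nrow(aln)) next
      aln$milrna <- milrnas$id[i]
      aln$milrna_seq <- mseq
      aln$transcript <- names(transcripts)[t]
      cand[[length(cand) + 1L]] <- aln
    }
  }
  empty <- data.frame(milrna = character(), transcript = character(),
                      site_start = integer(), site_end = integer(),
                      states = character(), mismatch_equivalents = numeric(),
                      energy_ratio = numeric())
  if (!length(cand)) return(empty)
  cand <- do.call(rbind, cand)
  # batched rule-6 energies: one duplex per candidate + one perfect per milRNA
  perfect <- setNames(
    engine$duplex(milrnas$sequence, revcomp(milrnas$sequence))$mfe,
    milrnas$id)
  site_mfe <- engine$duplex(cand$milrna_seq, cand$site)$mfe
  cand$energy_ratio <- site_mfe / perfect[cand$milrna]
  cand <- cand[cand$energy_ratio >= rules$min_energy_ratio, , drop = FALSE]
  if (!nrow(cand)) return(empty)
  out <- data.frame(milrna = cand$milrna, transcript = cand$transcript,
                    site_start = cand$offset, site_end = cand$site_end,
                    states = cand$states,
                    mismatch_equivalents = cand$mismatch_equivalents,
                    energy_ratio = cand$energy_ratio)
  rownames(out) <- NULL
  out
}

#' Screen milRNAs for host-genome encoding (transboundary eligibility)
#'
#' A milRNA with a full-length exact match in the host genome whose matched
#' region, extended by `flank` nt on both sides, folds to an MFE at or below
#' `stability_mfe` is considered host-encoded (it could be a host hairpin
#' product, not a transferred fungal milRNA) and is ineligible for
#' transboundary target prediction. milRNAs with no host match, or whose
#' matched regions all fold above the threshold, are eligible.
#'
#' @param milrnas data.frame with `id` and `sequence`.
#' @param host_genome named [Biostrings::DNAStringSet-class].
#' @param flank nt of genomic context folded on each side of a match.
#' @param stability_mfe stability threshold (kcal/mol).
#' @param engine [vienna_engine()].
#' @return data.frame with `milrna`, `n_matches`, `min_flank_mfe`,
#'   `is_host_encoded`, `eligible`, `truncated`.
#' @export
screen_transboundary <- function(milrnas, host_genome, flank = 100L,
                                 stability_mfe = -85, engine = vienna_engine()) {
  rows <- list()
  for (i in seq_len(nrow(milrnas))) {
    seq <- milrnas$sequence[i]
    wins <- list()
    for (strand in c("+", "-")) {
      pat <- if (strand == "+") seq else revcomp(seq)
      m <- Biostrings::vmatchPattern(pat, host_genome)
      for (ci in seq_along(m)) {
        r <- m[[ci]]
        for (k in seq_len(length(r))) {
          clen <- Biostrings::width(host_genome)[ci]
          s <- BiocGenerics::start(r)[k] - flank
          e <- BiocGenerics::end(r)[k] + flank
          truncated <- s < 1L || e > clen
          s <- max(1L, s); e <- min(clen, e)
          w <- as.character(Biostrings::subseq(host_genome[[ci]], s, e))
          if (strand == "-") w <- revcomp(w)
          wins[[length(wins) + 1L]] <- list(seq = w, truncated = truncated)
        }
      }
    }
    if (!length(wins)) {
      rows[[i]] <- data.frame(milrna = milrnas$id[i], n_matches = 0L,
                              min_flank_mfe = NA_real_,
                              is_host_encoded = FALSE, eligible = TRUE,
                              truncated = FALSE)
    } else {
      folds <- engine$fold(vapply(wins, `[[`, character(1), "seq"))
      host_encoded <- any(folds$mfe <= stability_mfe)
      rows[[i]] <- data.frame(milrna = milrnas$id[i],
                              n_matches = length(wins),
                              min_flank_mfe = min(folds$mfe),
                              is_host_encoded = host_encoded,
                              eligible = !host_encoded,
                              truncated = any(vapply(wins, `[[`, logical(1),
                                                     "truncated")))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Host target-prediction ruleset
#'
#' Three rulesets mirror the three plant-miRNA target predictors used for
#' cross-kingdom screening, all with a weighted-score cutoff of 4.0:
#' \describe{
#'   \item{expectation}{gap-free alignments; seed band 2-13 (the classical
#'     expectation band; 2-12 may be configured); the tenth miRNA position
#'     must pair perfectly; at most one mismatch or two wobbles within seed
#'     positions 2-12; at most two continuous mismatches.}
#'   \item{seed17}{seed band 2-17 with no gaps at positions 1-17 and at most
#'     one gap after position 17.}
#'   \item{allen}{seed band 2-13; one gap permitted anywhere at penalty 2.}
#' }
#'
#' @param name one of `"expectation"`, `"seed17"`, `"allen"`.
#' @param threshold weighted-score cutoff.
#' @param seed_band override the ruleset's default seed band.
#' @return list of class `host_ruleset`.
#' @export
host_ruleset <- function(name = c("expectation", "seed17", "allen"),
                         threshold = 4.0, seed_band = NULL) {
  name <- match.arg(name)
  defaults <- list(expectation = 2:13, seed17 = 2:17, allen = 2:13)
  structure(list(name = name, threshold = threshold,
                 seed_band = seed_band %||% defaults[[name]]),
            class = "host_ruleset")
}

accept_host_site <- function(states, ruleset, model) {
  st <- chars(states)
  pos <- state_positions(states)
  switch(ruleset$name,
    expectation = {
      if (any(st %in% c("g", "t"))) return(FALSE)
      if (st[10] != "M") return(FALSE)
      seed <- st[pos >= 2 & pos <= 12]
      if (sum(seed == "X") > 1L || sum(seed == "W") > 2L) return(FALSE)
      max_mismatch_run(st) <= 2L
    },
    seed17 = {
      gap <- st %in% c("g", "t")
      if (any(gap & pos <= 17L)) return(FALSE)
      sum(gap) <= 1L
    },
    allen = sum(st %in% c("g", "t")) <= 1L
  )
}

#' Predict host-transcript targets of eligible milRNAs under one ruleset
#'
#' @param milrnas data.frame with `id` and `sequence` (typically the
#'   transboundary-eligible set).
#' @param transcripts named [Biostrings::DNAStringSet-class] of host
#'   transcripts.
#' @param ruleset [host_ruleset()] or a ruleset name.
#' @param model [pairing_model()].
#' @return data.frame of accepted sites: `milrna`, `transcript`,
#'   `site_start`, `site_end`, `states`, `score`, `ruleset`.
#' @export
predict_host_targets <- function(milrnas, transcripts, ruleset = "expectation",
                                 model = pairing_model()) {
  if (is.character(ruleset)) ruleset <- host_ruleset(ruleset)
  allow_gaps <- ruleset$name %in% c("seed17", "allen")
  hits <- list()
  for (i in seq_len(nrow(milrnas))) {
    for (t in seq_along(transcripts)) {
      aln <- align_site(milrnas$sequence[i], as.character(transcripts[[t]]),
                        model, allow_gaps = allow_gaps,
                        seed_band = ruleset$seed_band,
                        max_score = ruleset$threshold)
      if (!nrow(aln)) next
      acc <- vapply(aln$states, accept_host_site, logical(1),
                    ruleset = ruleset, model = model, USE.NAMES = FALSE)
      aln <- aln[acc, , drop = FALSE]
      if (!nrow(aln)) next
      hits[[length(hits) + 1L]] <- data.frame(
        milrna = milrnas$id[i], transcript = names(transcripts)[t],
        site_start = aln$offset, site_end = aln$site_end,
        states = aln$states, score = aln$score, ruleset = ruleset$name)
    }
  }
  if (!length(hits)) {
    return(data.frame(milrna = character(), transcript = character(),
                      site_start = integer(), site_end = integer(),
                      states = character(), score = numeric(),
                      ruleset = character()))
  }
  out <- do.call(rbind, hits)
  rownames(out) <- NULL
  out
}

#' Consensus of the three host-targeting rulesets
#'
#' A (milRNA, transcript) pair is a consensus target when every ruleset
#' accepts at least one site in that transcript. Venn counts are reported
#' over target-gene sets (transcripts collapsed by `gene_map`; without a
#' map, transcript id = gene id).
#'
#' @param hits named list of three hit data.frames from
#'   [predict_host_targets()].
#' @param gene_map optional named character vector transcript -> gene.
#' @return list with `consensus` (data.frame `milrna`, `transcript`, `gene`)
#'   and `venn` (named counts of the seven regions over gene sets, names like
#'   `"100"`, `"110"`, `"111"` following the order of `hits`).
#' @export
consensus_targets <- function(hits, gene_map = NULL) {
  stopifnot(length(hits) == 3L)
  to_gene <- function(tx) {
    if (is.null(gene_map)) tx else unname(gene_map[tx])
  }
  pair_sets <- lapply(hits, function(h) unique(paste(h$milrna, h$transcript,
                                                     sep = "\r")))
  common <- Reduce(intersect, pair_sets)
  consensus <- if (length(common)) {
    parts <- strsplit(common, "\r", fixed = TRUE)
    data.frame(milrna = vapply(parts, `[`, character(1), 1L),
               transcript = vapply(parts, `[`, character(1), 2L))
  } else data.frame(milrna = character(), transcript = character())
  consensus$gene <- to_gene(consensus$transcript)

  gene_sets <- lapply(hits, function(h) unique(to_gene(unique(h$transcript))))
  all_genes <- unique(unlist(gene_sets))
  membership <- vapply(gene_sets, function(s) all_genes %in% s,
                       logical(length(all_genes)))
  if (length(all_genes) == 1L) membership <- matrix(membership, nrow = 1L)
  region <- apply(membership, 1L, function(m) paste(as.integer(m), collapse = ""))
  regions <- c("100", "010", "001", "110", "101", "011", "111")
  venn <- setNames(integer(length(regions)), regions)
  if (length(region)) {
    tab <- table(region)
    venn[names(tab)] <- as.integer(tab)
  }
  list(consensus = consensus, venn = venn)
}
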