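#' Hairpin-precursor acceptance parameters
#'
#' The eleven structural criteria a candidate milRNA precursor must satisfy:
#' mature length within `[min_mature, max_mature]` nt; duplex register
#' (reference) length within `[min_reference, max_reference]` nt; at most
#' `max_copies` genomic loci for the mature tag; precursor minimum free
#' energy at most `max_precursor_energy` kcal/mol (i.e. at least that
#' stable); mature/star spacing within `[min_space, max_space]` nt; at most
#' `max_bulge` bulged nucleotides and `max_asymmetry` nt of arm asymmetry in
#' the mature:star duplex; and `flank` nt of precursor flank on each side.
#'
#' @param min_mature,max_mature mature arm length bounds (nt).
#' @param min_reference,max_reference duplex register length bounds (nt).
#' @param max_copies maximum genomic copy number for a mature tag.
#' @param max_precursor_energy precursor MFE ceiling (kcal/mol, negative).
#' @param min_space,max_space loop spacing bounds between mature and star (nt).
#' @param max_bulge total bulged nucleotides allowed in the duplex (nt).
#' @param max_asymmetry arm-asymmetry ceiling (nt).
#' @param flank precursor flank length (nt).
#' @param space_grid loop spacings to enumerate when building candidate
#'   windows; `NULL` selects a dense-then-coarse grid over
#'   `[min_space, max_space]`.
#' @return list of class `hairpin_params`.
#' @export
hairpin_params <- function(min_mature = 18L, max_mature = 25L,
                           min_reference = 20L, max_reference = 23L,
                           max_copies = 20L, max_precursor_energy = -18,
                           min_space = 16L, max_space = 300L,
                           max_bulge = 4L, max_asymmetry = 4L,
                           flank = 20L, space_grid = NULL) {
  stopifnot(min_mature <= max_mature, min_reference <= max_reference,
            min_space <= max_space, max_precursor_energy <= 0)
  if (is.null(space_grid)) {
    dense_top <- min(60L, max_space)
    space_grid <- seq(min_space, dense_top, by = 4L)
    if (max_space > 60L) {
      space_grid <- c(space_grid, seq(64L, max_space, by = 16L))
    }
  }
  structure(list(min_mature = min_mature, max_mature = max_mature,
                 min_reference = min_reference, max_reference = max_reference,
                 max_copies = max_copies,
                 max_precursor_energy = max_precursor_energy,
                 min_space = min_space, max_space = max_space,
                 max_bulge = max_bulge, max_asymmetry = max_asymmetry,
                 flank = flank, space_grid = space_grid),
            class = "hairpin_params")
}

#' Assess a folded window as a milRNA hairpin
#'
#' Checks the structural criteria on one folded candidate window: the mature
#' arm must base-pair with a single opposite (star) region — every paired
#' mature position partnering strictly 5' or strictly 3' of the mature — with
#' total bulged nucleotides (unpaired positions inside either duplex arm) at
#' most `max_bulge`, arm asymmetry (absolute difference of the two arms'
#' unpaired counts) at most `max_asymmetry`, loop spacing between mature and
#' star within `[min_space, max_space]`, mature length within bounds, and
#' window MFE at most `max_precursor_energy`.
#'
#' @param structure dot-bracket string for the window.
#' @param mfe folding energy (kcal/mol).
#' @param mstart,mend 1-based mature arm span within the window.
#' @param params [hairpin_params()].
#' @return list with `ok` (logical), `reason` (first failed criterion, or
#'   `""`), `arm` (`"5p"`/`"3p"`), `star_start`, `star_end` (pairing span),
#'   `space`, `bulge`, `asymmetry`.
#' @export
assess_hairpin <- function(structure, mfe, mstart, mend, params = hairpin_params()) {
  fail <- function(reason) list(ok = FALSE, reason = reason, arm = NA_character_,
                                star_start = NA_integer_, star_end = NA_integer_,
                                space = NA_integer_, bulge = NA_integer_,
                                asymmetry = NA_integer_)
  mat_len <- mend - mstart + 1L
  if (mat_len < params$min_mature) return(fail("mature_too_short"))
  if (mat_len > params$max_mature) return(fail("mature_too_long"))
  pt <- pair_table(structure)
  if (mend > length(pt)) return(fail("mature_outside_window"))
  partners <- pt[mstart:mend]
  paired <- partners > 0L
  if (sum(paired) < 2L) return(fail("mature_unpaired"))
  p <- partners[paired]
  if (any(p >= mstart & p <= mend)) return(fail("mature_self_paired"))
  if (all(p > mend)) {
    arm <- "5p"
  } else if (all(p < mstart)) {
    arm <- "3p"
  } else {
    return(fail("mature_spans_loop"))
  }
  star_start <- min(p); star_end <- max(p)
  u_m <- sum(!paired)
  # unpaired (or outside-duplex-paired) positions within the star span
  star_partners <- pt[star_start:star_end]
  u_s <- sum(!(star_partners >= mstart & star_partners <= mend))
  bulge <- u_m + u_s
  asym <- abs(u_m - u_s)
  space <- if (arm == "5p") star_start - mend - 1L else mstart - star_end - 1L
  if (bulge > params$max_bulge) return(fail("bulge"))
  if (asym > params$max_asymmetry) return(fail("asymmetry"))
  if (space < params$min_space) return(fail("space_too_small"))
  if (space > params$max_space) return(fail("space_too_large"))
  if (mfe > params$max_precursor_energy) return(fail("mfe"))
  list(ok = TRUE, reason = "", arm = arm, star_start = star_start,
       star_end = star_end, space = space, bulge = bulge, asymmetry = asym)
}

# Extract a genomic window in transcript orientation. left/right extensions
# are in transcript space (left = 5' of the mature on its strand).
extract_window <- function(genome, contig, mstart, mend, strand,
                           left_ext, right_ext) {
  clen <- Biostrings::width(genome)[match(contig, names(genome))]
  if (strand == "+") {
    gstart <- mstart - left_ext; gend <- mend + right_ext
  } else {
    gstart <- mstart - right_ext; gend <- mend + left_ext
  }
  truncated <- gstart < 1L || gend > clen
  gstart <- max(1L, gstart); gend <- min(clen, gend)
  seq <- as.character(Biostrings::subseq(genome[[match(contig, names(genome))]],
                                         gstart, gend))
  if (strand == "-") seq <- revcomp(seq)
  # mature offset within the window, transcript orientation
  moff <- if (strand == "+") mstart - gstart + 1L else gend - mend + 1L
  list(sequence = seq, gstart = gstart, gend = gend, mstart = moff,
       mend = moff + (mend - mstart), truncated = truncated)
}

#' Call novel milRNA hairpin precursors from unannotated tag loci
#'
#' For every unannotated tag locus (tags with more than `max_copies` loci are
#' excluded), candidate precursor windows are enumerated with the tag as the
#' mature arm on either the 5p side (window extends 3' across the loop to a
#' putative star) or the 3p side (mirrored), over the loop spacings of
#' `params$space_grid` and a duplex register clamped to
#' `[min_reference, max_reference]`. All windows are folded in one batch;
#' each is assessed with [assess_hairpin()]; among accepted windows for a
#' locus the lowest-MFE (tie: shortest) wins and is then trimmed to the
#' duplex extent plus `flank` nt and refolded (the trimmed precursor is
#' reported when it still passes). When several tags' accepted precursors
#' overlap on the same arm, the most abundant tag is kept; one record is
#' reported per distinct (precursor, mature) pair.
#'
#' @param tags data.frame with `sequence`, `count` (and optionally
#'   `category`, in which case only `unannotated` tags are used).
#' @param loci data.frame from [map_tags()].
#' @param genome named [Biostrings::DNAStringSet-class].
#' @param params [hairpin_params()].
#' @param engine [vienna_engine()].
#' @return data.frame of hairpin candidates: `mature`, `count`, `arm`,
#'   `contig`, `pre_start`, `pre_end`, `strand`, `precursor`, `structure`,
#'   `mfe`, `star`, `space`, `bulge`, `asymmetry`, `truncated`.
#' @export
call_hairpins <- function(tags, loci, genome, params = hairpin_params(),
                          engine = vienna_engine()) {
  if (!is.null(tags$category)) {
    tags <- tags[tags$category == "unannotated", , drop = FALSE]
  }
  empty <- data.frame(mature = character(), count = integer(),
                      arm = character(), contig = character(),
                      pre_start = integer(), pre_end = integer(),
                      strand = character(), precursor = character(),
                      structure = character(), mfe = numeric(),
                      star = character(), space = integer(),
                      bulge = integer(), asymmetry = integer(),
                      truncated = logical())
  if (nrow(tags) == 0L) return(empty)

  # enumerate candidate windows
  windows <- list()
  for (i in seq_len(nrow(tags))) {
    seq <- tags$sequence[i]
    mat_len <- nchar(seq)
    if (mat_len < params$min_mature || mat_len > params$max_mature) next
    tl <- loci[loci$sequence == seq, , drop = FALSE]
    if (nrow(tl) == 0L || nrow(tl) > params$max_copies) next
    star_len <- min(max(mat_len, params$min_reference), params$max_reference)
    for (j in seq_len(nrow(tl))) {
      for (space in params$space_grid) {
        for (arm in c("5p", "3p")) {
          ext <- params$flank + space + star_len + params$flank
          w <- if (arm == "5p") {
            extract_window(genome, tl$contig[j], tl$start[j], tl$end[j],
                           tl$strand[j], params$flank,
                           space + star_len + params$flank)
          } else {
            extract_window(genome, tl$contig[j], tl$start[j], tl$end[j],
                           tl$strand[j], space + star_len + params$flank,
                           params$flank)
          }
          windows[[length(windows) + 1L]] <- c(
            list(tag = i, locus = j, contig = tl$contig[j],
                 lstart = tl$start[j], lend = tl$end[j],
                 strand = tl$strand[j], space = space, want_arm = arm), w)
        }
      }
    }
  }
  if (!length(windows)) return(empty)

  folds <- engine$fold(vapply(windows, `[[`, character(1), "sequence"))

  assessed <- lapply(seq_along(windows), function(k) {
    w <- windows[[k]]
    a <- assess_hairpin(folds$structure[k], folds$mfe[k], w$mstart, w$mend,
                        params)
    c(w, a, list(structure = folds$structure[k], mfe = folds$mfe[k]))
  })
  ok <- assessed[vapply(assessed, function(a) isTRUE(a$ok), logical(1))]
  if (!length(ok)) return(empty)

  # best accepted window per (tag, locus): lowest MFE, tie shortest
  key <- vapply(ok, function(a) paste(a$tag, a$locus), character(1))
  best <- lapply(split(ok, key), function(grp) {
    mfes <- vapply(grp, `[[`, numeric(1), "mfe")
    lens <- vapply(grp, function(a) nchar(a$sequence), integer(1))
    grp[[order(mfes, lens)[1]]]
  })

  # trim each winner to duplex extent + flank and refold
  trims <- lapply(best, function(a) {
    t1 <- max(1L, min(a$mstart, a$star_start) - params$flank)
    t2 <- min(nchar(a$sequence), max(a$mend, a$star_end) + params$flank)
    # transcript-space trim -> genomic coordinates
    if (a$strand == "+") {
      list(gstart = a$gstart + t1 - 1L, gend = a$gstart + t2 - 1L)
    } else {
      list(gstart = a$gend - t2 + 1L, gend = a$gend - t1 + 1L)
    }
  })
  trim_windows <- lapply(seq_along(best), function(k) {
    a <- best[[k]]; tr <- trims[[k]]
    seq <- as.character(Biostrings::subseq(
      genome[[match(a$contig, names(genome))]], tr$gstart, tr$gend))
    if (a$strand == "-") seq <- revcomp(seq)
    moff <- if (a$strand == "+") a$lstart - tr$gstart + 1L else
      tr$gend - a$lend + 1L
    list(sequence = seq, mstart = moff, mend = moff + (a$lend - a$lstart))
  })
  refolds <- engine$fold(vapply(trim_windows, `[[`, character(1), "sequence"))

  out <- lapply(seq_along(best), function(k) {
    a <- best[[k]]; tw <- trim_windows[[k]]; tr <- trims[[k]]
    ra <- assess_hairpin(refolds$structure[k], refolds$mfe[k],
                         tw$mstart, tw$mend, params)
    if (isTRUE(ra$ok)) {
      data.frame(
        mature = tags$sequence[a$tag], count = tags$count[a$tag],
        arm = ra$arm, contig = a$contig, pre_start = tr$gstart,
        pre_end = tr$gend, strand = a$strand,
        precursor = tw$sequence, structure = refolds$structure[k],
        mfe = refolds$mfe[k],
        star = substr(tw$sequence, ra$star_start, ra$star_end),
        space = ra$space, bulge = ra$bulge, asymmetry = ra$asymmetry,
        truncated = a$truncated
      )
    } else {
      data.frame(
        mature = tags$sequence[a$tag], count = tags$count[a$tag],
        arm = a$arm, contig = a$contig, pre_start = a$gstart,
        pre_end = a$gend, strand = a$strand,
        precursor = a$sequence, structure = a$structure, mfe = a$mfe,
        star = substr(a$sequence, a$star_start, a$star_end),
        space = a$space, bulge = a$bulge, asymmetry = a$asymmetry,
        truncated = a$truncated
      )
    }
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL

  # resolve overlapping matures on the same arm: most abundant tag wins
  keep <- rep(TRUE, nrow(out))
  ord <- order(-out$count, out$mature)
  taken <- list()
  for (i in ord) {
    m1 <- min(out$pre_start[i], out$pre_end[i])
    # mature genomic span
    span <- mature_genomic_span(out[i, ])
    clash <- FALSE
    for (t in taken) {
      if (t$contig == out$contig[i] && t$strand == out$strand[i] &&
          span[1] <= t$end && span[2] >= t$start) { clash <- TRUE; break }
    }
    if (clash) keep[i] <- FALSE else {
      taken[[length(taken) + 1L]] <- list(contig = out$contig[i],
                                          strand = out$strand[i],
                                          start = span[1], end = span[2])
    }
  }
  out <- out[keep, , drop = FALSE]
  # one record per distinct (precursor, mature)
  out <- out[!duplicated(out[, c("contig", "pre_start", "pre_end", "strand",
                                 "mature")]), , drop = FALSE]
  rownames(out) <- NULL
  out
}

mature_genomic_span <- function(row) {
  loc <- regexpr(row$mature, row$precursor, fixed = TRUE)
  off <- as.integer(loc)
  L <- nchar(row$mature)
  if (row$strand == "+") {
    c(row$pre_start + off - 1L, row$pre_start + off + L - 2L)
  } else {
    c(row$pre_end - off - L + 2L, row$pre_end - off + 1L)
  }
}

#' Match tags against a known mature-miRNA reference
#'
#' A tag counts as a known milRNA when it aligns full length within a
#' reference mature sequence, allowing its ends to overhang the reference by
#' at most `end_slack` nt, with at most `max_mismatches` substitutions and no
#' indels (overhanging positions count as mismatches). Each tag reports its
#' best match.
#'
#' @param tags data.frame with `sequence` (and optionally `count`).
#' @param reference named [Biostrings::DNAStringSet-class] of mature miRNAs.
#' @param max_mismatches substitution budget.
#' @param end_slack allowed overhang beyond either reference end (nt).
#' @return data.frame with `sequence`, `count` (if present), `reference`,
#'   `mismatches` for matched tags.
#' @export
match_known <- function(tags, reference, max_mismatches = 2L, end_slack = 2L) {
  if (length(reference) == 0L) stop("empty mature-miRNA reference")
  refs <- toupper(to_dna(as.character(reference)))
  ref_chars <- lapply(refs, chars)
  rows <- list()
  for (i in seq_len(nrow(tags))) {
    tc <- chars(to_dna(tags$sequence[i]))
    L <- length(tc)
    best_mm <- Inf; best_ref <- NA_character_
    for (r in seq_along(refs)) {
      rc <- ref_chars[[r]]; rl <- length(rc)
      for (off in seq(-end_slack, rl - L + end_slack)) {
        idx <- off + seq_len(L)   # positions on the reference
        inside <- idx >= 1L & idx <= rl
        mm <- sum(!inside) + sum(tc[inside] != rc[idx[inside]])
        if (mm < best_mm) { best_mm <- mm; best_ref <- names(refs)[r] }
      }
    }
    if (best_mm <= max_mismatches) {
      rows[[length(rows) + 1L]] <- data.frame(
        sequence = tags$sequence[i],
        count = if (is.null(tags$count)) NA_integer_ else tags$count[i],
        reference = best_ref, mismatches = as.integer(best_mm))
    }
  }
  if (!length(rows)) {
    return(data.frame(sequence = character(), count = integer(),
                      reference = character(), mismatches = integer()))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Transcripts-per-million normalisation
#'
#' `TPM = count / total * 1e6`, so TPM over all clean tags sums to one
#' million.
#'
#' @param count read count(s).
#' @param total total clean-tag read count (> 0).
#' @return TPM value(s).
#' @export
tpm <- function(count, total) {
  if (total <= 0) stop("total clean-tag count must be positive")
  count / total * 1e6
}

#' Format hairpin candidates as a novel-milRNA report
#'
#' Precursors are ranked by their most abundant mature's read count and named
#' `milR001`, `milR002`, ...; each mature takes its precursor's number with a
#' `-5p`/`-3p` arm suffix (two matures from one precursor share the number).
#' Precursor locations print as `contig:start:end:strand` (1-based
#' inclusive), so the printed length always equals `end - start + 1`.
#'
#' @param candidates data.frame from [call_hairpins()].
#' @return data.frame with columns `novel_milRNA`, `sequence`, `length`,
#'   `total_reads`, `precursor_location`, `precursor_length`, `mfe`.
#' @export
milrna_table <- function(candidates) {
  if (nrow(candidates) == 0L) {
    return(data.frame(novel_milRNA = character(), sequence = character(),
                      length = integer(), total_reads = integer(),
                      precursor_location = character(),
                      precursor_length = integer(), mfe = numeric()))
  }
  pre_key <- paste(candidates$contig, candidates$pre_start,
                   candidates$pre_end, candidates$strand, sep = ":")
  pre_order <- unique(pre_key[order(-candidates$count, candidates$mature)])
  pre_num <- setNames(seq_along(pre_order), pre_order)
  out <- data.frame(
    novel_milRNA = sprintf("milR%03d-%s", pre_num[pre_key], candidates$arm),
    sequence = candidates$mature,
    length = nchar(candidates$mature),
    total_reads = candidates$count,
    precursor_location = pre_key,
    precursor_length = candidates$pre_end - candidates$pre_start + 1L,
    mfe = candidates$mfe
  )
  out <- out[order(pre_num[pre_key], out$novel_milRNA), , drop = FALSE]
  rownames(out) <- NULL
  out
}
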