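#' Collapse clean inserts to unique sequence tags
#'
#' @param inserts character vector of cleansed insert sequences (one entry
#'   per surviving read).
#' @return data.frame with columns `sequence` and `count`, sorted by
#'   decreasing count then sequence; the counts sum to `length(inserts)`.
#' @export
collapse_tags <- function(inserts) {
  if (length(inserts) == 0L) {
    return(data.frame(sequence = character(), count = integer()))
  }
  tab <- table(inserts)
  out <- data.frame(sequence = names(tab), count = as.integer(tab))
  out <- out[order(-out$count, out$sequence), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Map sequence tags to a genome (exact, full length, both strands)
#'
#' Every exact full-length occurrence of each tag on either strand is
#' reported with 1-based inclusive coordinates on the plus strand (a minus
#' strand hit spans the positions of its reverse complement).
#'
#' @param tags data.frame from [collapse_tags()].
#' @param genome named [Biostrings::DNAStringSet-class].
#' @return data.frame with columns `sequence`, `contig`, `start`, `end`,
#'   `strand`. Tags with no occurrence are absent (they are `unmapped`).
#' @export
map_tags <- function(tags, genome) {
  if (length(genome) == 0L || sum(Biostrings::width(genome)) == 0L) {
    stop("empty genome")
  }
  hits <- list()
  for (i in seq_len(nrow(tags))) {
    seq <- tags$sequence[i]
    for (strand in c("+", "-")) {
      pat <- if (strand == "+") seq else revcomp(seq)
      m <- Biostrings::vmatchPattern(pat, genome)
      for (ci in seq_along(m)) {
        r <- m[[ci]]
        if (length(r)) {
          hits[[length(hits) + 1L]] <- data.frame(
            sequence = seq, contig = names(genome)[ci],
            start = BiocGenerics::start(r), end = BiocGenerics::end(r),
            strand = strand
          )
        }
      }
    }
  }
  if (!length(hits)) {
    return(data.frame(sequence = character(), contig = character(),
                      start = integer(), end = integer(), strand = character()))
  }
  out <- do.call(rbind, hits)
  rownames(out) <- NULL
  out
}

# Default annotation precedence: abundant structural RNA first.
DEFAULT_PRECEDENCE <- c("rRNA", "tRNA", "snRNA", "snoRNA", "repeat",
                        "exon_sense", "exon_antisense", "intron_sense",
                        "intron_antisense", "unannotated", "unmapped")

#' Classify mapped tags into annotation categories
#'
#' A tag matching a structural-RNA reference set (exact full-length substring
#' of any reference sequence, either strand) or overlapping an annotation
#' interval takes the highest-precedence matching category; mapped tags with
#' no annotation are `unannotated`, tags with no genomic hit `unmapped`.
#' Sense/antisense for exon and intron overlaps is decided by comparing the
#' tag's hit strand with the feature strand.
#'
#' @param tags data.frame from [collapse_tags()].
#' @param loci data.frame from [map_tags()].
#' @param tracks [GenomicRanges::GRanges-class] with a `type` metadata column
#'   over \{exon, intron, repeat\}.
#' @param ncrna named list of [Biostrings::DNAStringSet-class] reference sets
#'   (names among rRNA, tRNA, snRNA, snoRNA).
#' @param precedence ordered category vector; the first matching category
#'   wins.
#' @return list with `categories` (tags data.frame plus a `category` column)
#'   and `summary` (per-category total/unique counts and percentages of the
#'   clean totals, one row per category in precedence order).
#' @export
classify_tags <- function(tags, loci, tracks, ncrna,
                          precedence = DEFAULT_PRECEDENCE) {
  stopifnot(all(precedence %in% DEFAULT_PRECEDENCE))
  ncrna_match <- function(seq, refs) {
    rc <- revcomp(seq)
    any(vapply(as.character(refs), function(ref) {
      grepl(seq, ref, fixed = TRUE) || grepl(rc, ref, fixed = TRUE)
    }, logical(1)))
  }
  track_hit <- function(seq, want_type, want_orient = NULL) {
    h <- loci[loci$sequence == seq, , drop = FALSE]
    if (!nrow(h) || length(tracks) == 0L) return(FALSE)
    gr <- GenomicRanges::GRanges(h$contig, IRanges::IRanges(h$start, h$end))
    sel <- tracks[S4Vectors::mcols(tracks)$type == want_type]
    if (!length(sel)) return(FALSE)
    ov <- GenomicRanges::findOverlaps(gr, sel, ignore.strand = TRUE)
    if (!length(ov)) return(FALSE)
    if (is.null(want_orient)) return(TRUE)
    fs <- as.character(BiocGenerics::strand(sel))[S4Vectors::subjectHits(ov)]
    ts <- h$strand[S4Vectors::queryHits(ov)]
    any(if (want_orient == "sense") ts == fs else ts != fs)
  }
  mapped <- tags$sequence %in% loci$sequence
  category <- character(nrow(tags))
  for (i in seq_len(nrow(tags))) {
    seq <- tags$sequence[i]
    if (!mapped[i]) { category[i] <- "unmapped"; next }
    cat_i <- "unannotated"
    for (p in precedence) {
      hit <- switch(p,
        rRNA = , tRNA = , snRNA = , snoRNA =
          !is.null(ncrna[[p]]) && length(ncrna[[p]]) > 0L &&
            ncrna_match(seq, ncrna[[p]]),
        `repeat` = track_hit(seq, "repeat"),
        exon_sense = track_hit(seq, "exon", "sense"),
        exon_antisense = track_hit(seq, "exon", "antisense"),
        intron_sense = track_hit(seq, "intron", "sense"),
        intron_antisense = track_hit(seq, "intron", "antisense"),
        unannotated = TRUE,
        unmapped = FALSE
      )
      if (isTRUE(hit)) { cat_i <- p; break }
    }
    category[i] <- cat_i
  }
  tags$category <- category
  total_reads <- sum(tags$count)
  total_unique <- nrow(tags)
  summary <- do.call(rbind, lapply(precedence, function(p) {
    sel <- tags$category == p
    data.frame(category = p,
               total = sum(tags$count[sel]),
               total_percent = if (total_reads) round(100 * sum(tags$count[sel]) / total_reads, 2) else NA_real_,
               unique = sum(sel),
               unique_percent = if (total_unique) round(100 * sum(sel) / total_unique, 2) else NA_real_)
  }))
  list(categories = tags, summary = summary)
}

#' Category summary with percentages from raw counts
#'
#' Reporting convenience used for externally supplied count tables:
#' percentages of per-category totals relative to the clean totals, rounded
#' to two decimals.
#'
#' @param counts data.frame with `category`, `total`, `unique`.
#' @param total_reads,total_unique denominators (clean totals).
#' @return `counts` with `total_percent` and `unique_percent` columns.
#' @export
category_percentages <- function(counts, total_reads, total_unique) {
  counts$total_percent <- round(100 * counts$total / total_reads, 2)
  counts$unique_percent <- round(100 * counts$unique / total_unique, 2)
  counts
}

#' Tag length histogram and 5'-nucleotide bias
#'
#' @param tags data.frame from [collapse_tags()] (a `category` column is
#'   ignored).
#' @param lengths length range to tabulate.
#' @return list with `lengths` (data.frame `length`, `n_unique`, `n_total`)
#'   and `first_base` (data.frame `length`, `base`, `fraction`; fractions of
#'   unique tags, summing to 1 within each populated length class).
#' @export
length_first_base_profile <- function(tags, lengths = 18:30) {
  if (nrow(tags) == 0L) {
    return(list(lengths = data.frame(length = integer(), n_unique = integer(),
                                     n_total = integer()),
                first_base = data.frame(length = integer(), base = character(),
                                        fraction = numeric())))
  }
  len <- nchar(tags$sequence)
  first <- substr(tags$sequence, 1L, 1L)
  lens <- data.frame(
    length = lengths,
    n_unique = vapply(lengths, function(l) sum(len == l), integer(1)),
    n_total = vapply(lengths, function(l) sum(tags$count[len == l]), integer(1))
  )
  fb <- do.call(rbind, lapply(lengths, function(l) {
    sel <- len == l
    if (!any(sel)) return(NULL)
    tab <- table(factor(first[sel], levels = c("A", "C", "G", "T")))
    data.frame(length = l, base = names(tab),
               fraction = as.numeric(tab) / sum(tab))
  }))
  if (is.null(fb)) fb <- data.frame(length = integer(), base = character(),
                                    fraction = numeric())
  list(lengths = lens, first_base = fb)
}
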