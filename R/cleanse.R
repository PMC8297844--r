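#' Read-cleansing parameters
#'
#' Bundles the thresholds of the six-step small-RNA read filter: a read is
#' dropped if it (1) has more than `max_low_quality_bases` bases at or below
#' `quality_threshold` or contains an N, (2) lacks the 3' adapter, (3) has an
#' empty insert (adapter dimer), (4) contains the 5' adapter inside the
#' insert, (5) has a poly-A insert (>= `polyA_fraction` adenines), or (6) has
#' an insert shorter than `min_insert_length`. Surviving inserts longer than
#' `max_insert_length` fall into a separate overflow bucket (they lie outside
#' the gel-purified size range).
#'
#' @param quality_threshold Phred score at or below which a base counts as
#'   low quality.
#' @param max_low_quality_bases number of low-quality bases tolerated.
#' @param adapter3,adapter5 adapter sequences.
#' @param min_insert_length,max_insert_length retained insert size range (nt).
#' @param polyA_fraction adenine fraction at which an insert counts as poly-A.
#' @return list of class `cleanse_params`.
#' @export
cleanse_params <- function(quality_threshold = 20L,
                           max_low_quality_bases = 1L,
                           adapter3 = "TGGAATTCTCGGGTGCCAAGG",
                           adapter5 = "GTTCAGAGTTCTACAGTCCGACGATC",
                           min_insert_length = 18L,
                           max_insert_length = 30L,
                           polyA_fraction = 0.8) {
  stopifnot(quality_threshold > 0, min_insert_length > 0,
            nzchar(adapter3), nzchar(adapter5))
  structure(list(quality_threshold = quality_threshold,
                 max_low_quality_bases = max_low_quality_bases,
                 adapter3 = toupper(adapter3), adapter5 = toupper(adapter5),
                 min_insert_length = min_insert_length,
                 max_insert_length = max_insert_length,
                 polyA_fraction = polyA_fraction),
            class = "cleanse_params")
}

read_fastq <- function(path) {
  lines <- readLines(path)
  if (length(lines) %% 4L != 0L) stop("truncated FASTQ: ", path)
  ids <- sub("^@", "", lines[seq(1L, length(lines), 4L)])
  structure(list(id = ids,
                 sequence = toupper(lines[seq(2L, length(lines), 4L)]),
                 quality = lines[seq(4L, length(lines), 4L)],
                 class = NULL),
            class = "fastq_reads")
}

# Count bases with Phred quality <= threshold (Phred+33 encoding)
n_low_quality <- function(quality, threshold) {
  vapply(quality, function(q) sum(utf8ToInt(q) - 33L <= threshold),
         integer(1), USE.NAMES = FALSE)
}

# Locate the 3' adapter: best semi-global overlap of the adapter prefix with
# the read suffix; >= 8 nt overlap, <= 1 mismatch per 10 nt of overlap.
# Returns the 1-based position where the adapter starts, or NA.
find_adapter3 <- function(seq, adapter) {
  n <- nchar(seq); alen <- nchar(adapter)
  sc <- chars(seq); ac <- chars(adapter)
  for (p in seq_len(max(n - 7L, 0L))) {
    L <- min(alen, n - p + 1L)
    if (L < 8L) break
    mm <- sum(sc[p:(p + L - 1L)] != ac[seq_len(L)])
    if (mm <= L %/% 10L) return(p)
  }
  NA_integer_
}

# 5' adapter contamination: adapter found anywhere in the insert under the
# same per-10-nt mismatch allowance.
has_adapter5 <- function(insert, adapter) {
  n <- nchar(insert); alen <- nchar(adapter)
  if (n < 8L) return(FALSE)
  ic <- chars(insert); ac <- chars(adapter)
  allow <- alen %/% 10L
  # full-length occurrences
  if (n >= alen) {
    for (p in seq_len(n - alen + 1L)) {
      if (sum(ic[p:(p + alen - 1L)] != ac) <= allow) return(TRUE)
    }
  }
  # adapter running off either end of the insert (partial, >= 8 nt)
  for (L in seq(min(alen, n), 8L)) {
    if (L == alen && n >= alen) next
    if (sum(ic[seq_len(L)] != ac[(alen - L + 1L):alen]) <= L %/% 10L) return(TRUE)
    if (sum(ic[(n - L + 1L):n] != ac[seq_len(L)]) <= L %/% 10L) return(TRUE)
  }
  FALSE
}

FILTER_CATEGORIES <- c("low_quality", "adapter3_null", "insert_null",
                       "adapter5_contaminant", "polyA", "shorter_than_18nt",
                       "longer_than_max", "clean")

#' Cleanse a small-RNA library
#'
#' Applies the six read filters in fixed order (quality, 3'-adapter presence,
#' empty insert, 5'-adapter contamination, poly-A insert, insert length);
#' every read is charged to exactly one terminal category — the first test it
#' fails, or `clean`. Survivors are adapter-trimmed inserts within the
#' configured size range.
#'
#' @param reads a `fastq_reads` object (see [simulate_reads()]) or a path to
#'   a FASTQ file (Phred+33).
#' @param params [cleanse_params()].
#' @return list with `inserts` (character vector of surviving trimmed
#'   inserts, one per clean read), `category` (per-read terminal category) and
#'   `report` (a `filter_report`, see [filter_report()]).
#' @export
cleanse <- function(reads, params = cleanse_params()) {
  if (is.character(reads) && length(reads) == 1L) reads <- read_fastq(reads)
  seqs <- reads$sequence; quals <- reads$quality
  n <- length(seqs)
  bad <- which(nchar(seqs) != nchar(quals))
  if (length(bad)) {
    stop("malformed FASTQ record ", bad[1],
         ": sequence and quality lengths differ")
  }
  category <- rep("clean", n)
  inserts <- rep(NA_character_, n)

  low <- n_low_quality(quals, params$quality_threshold) >
    params$max_low_quality_bases
  low <- low | grepl("N", seqs, fixed = TRUE)
  category[low] <- "low_quality"

  todo <- which(!low)
  # fast path: exact full-adapter hit; fall back to mismatch-tolerant scan
  apos <- rep(NA_integer_, n)
  hit <- regexpr(params$adapter3, seqs[todo], fixed = TRUE)
  apos[todo] <- ifelse(hit > 0L, hit, NA_integer_)
  miss <- todo[is.na(apos[todo])]
  apos[miss] <- vapply(seqs[miss], find_adapter3, integer(1),
                       adapter = params$adapter3, USE.NAMES = FALSE)
  category[todo][is.na(apos[todo])] <- "adapter3_null"

  todo <- todo[!is.na(apos[todo])]
  ins <- substr(seqs[todo], 1L, apos[todo] - 1L)
  null <- !nzchar(ins)
  category[todo][null] <- "insert_null"
  todo <- todo[!null]; ins <- ins[!null]

  a5 <- vapply(ins, has_adapter5, logical(1), adapter = params$adapter5,
               USE.NAMES = FALSE)
  category[todo][a5] <- "adapter5_contaminant"
  todo <- todo[!a5]; ins <- ins[!a5]

  frac_a <- (nchar(ins) - nchar(gsub("A", "", ins, fixed = TRUE))) / nchar(ins)
  pa <- frac_a >= params$polyA_fraction
  category[todo][pa] <- "polyA"
  todo <- todo[!pa]; ins <- ins[!pa]

  shrt <- nchar(ins) < params$min_insert_length
  category[todo][shrt] <- "shorter_than_18nt"
  long <- !shrt & nchar(ins) > params$max_insert_length
  category[todo][long] <- "longer_than_max"
  keep <- !shrt & !long
  inserts[todo[keep]] <- ins[keep]

  counts <- table(factor(category, levels = FILTER_CATEGORIES))
  report <- filter_report(
    clean_reads = n,
    low_quality_removed = counts[["low_quality"]],
    adapter3_null = counts[["adapter3_null"]],
    insert_null = counts[["insert_null"]],
    adapter5_contaminant = counts[["adapter5_contaminant"]],
    polyA = counts[["polyA"]],
    shorter_than_18nt = counts[["shorter_than_18nt"]],
    longer_than_max = counts[["longer_than_max"]]
  )
  list(inserts = inserts[!is.na(inserts)], category = category,
       report = report)
}

#' Assemble a read-filtering accounting report
#'
#' Derived totals follow the accounting identities of a sequencing QC table:
#' `high_quality = clean_reads - low_quality_removed` and
#' `clean_tags = high_quality - (adapter3_null + insert_null +
#' adapter5_contaminant + polyA + shorter_than_18nt + longer_than_max)`.
#'
#' @param clean_reads total input reads.
#' @param low_quality_removed,adapter3_null,insert_null,adapter5_contaminant,polyA,shorter_than_18nt,longer_than_max per-category removal counts.
#' @return list of class `filter_report`.
#' @export
filter_report <- function(clean_reads, low_quality_removed = 0L,
                          adapter3_null = 0L, insert_null = 0L,
                          adapter5_contaminant = 0L, polyA = 0L,
                          shorter_than_18nt = 0L, longer_than_max = 0L) {
  high_quality <- clean_reads - low_quality_removed
  clean_tags <- high_quality - (adapter3_null + insert_null +
    adapter5_contaminant + polyA + shorter_than_18nt + longer_than_max)
  structure(list(
    clean_reads = as.integer(clean_reads),
    low_quality_removed = as.integer(low_quality_removed),
    high_quality = as.integer(high_quality),
    adapter3_null = as.integer(adapter3_null),
    insert_null = as.integer(insert_null),
    adapter5_contaminant = as.integer(adapter5_contaminant),
    polyA = as.integer(polyA),
    shorter_than_18nt = as.integer(shorter_than_18nt),
    longer_than_max = as.integer(longer_than_max),
    clean_tags = as.integer(clean_tags)
  ), class = "filter_report")
}

#' Percentage table for a filter report
#'
#' Follows the mixed-denominator convention of small-RNA QC tables: the
#' high-quality count and the adapter/poly-A removal classes are expressed
#' relative to total (clean) reads, while the short-read removals and final
#' clean-tag count are relative to high-quality reads. Percentages are
#' rounded to two decimals; zero denominators yield NA.
#'
#' @param report a `filter_report`.
#' @return data.frame with columns `category`, `count`, `percent`,
#'   `denominator`.
#' @export
report_percentages <- function(report) {
  pct <- function(x, d) if (d == 0L) NA_real_ else round(100 * x / d, 2)
  cr <- report$clean_reads; hq <- report$high_quality
  rows <- list(
    c("clean_reads", cr, pct(cr, cr), "clean_reads"),
    c("high_quality", hq, pct(hq, cr), "clean_reads"),
    c("3'adapter_null", report$adapter3_null, pct(report$adapter3_null, cr),
      "clean_reads"),
    c("insert_null", report$insert_null, pct(report$insert_null, cr),
      "clean_reads"),
    c("5'adapter_contaminants", report$adapter5_contaminant,
      pct(report$adapter5_contaminant, cr), "clean_reads"),
    c("polyA", report$polyA, pct(report$polyA, cr), "clean_reads"),
    c("smaller_than_18nt", report$shorter_than_18nt,
      pct(report$shorter_than_18nt, hq), "high_quality"),
    c("clean_tags", report$clean_tags, pct(report$clean_tags, hq),
      "high_quality")
  )
  out <- data.frame(
    category = vapply(rows, `[`, character(1), 1L),
    count = as.integer(vapply(rows, `[`, character(1), 2L)),
    percent = as.numeric(vapply(rows, `[`, character(1), 3L)),
    denominator = vapply(rows, `[`, character(1), 4L)
  )
  out
}

#' @export
print.filter_report <- function(x, ...) {
  tab <- report_percentages(x)
  cat("Read filtering report\n")
  for (i in seq_len(nrow(tab))) {
    cat(sprintf("  %-24s %12d  %7s%%  (of %s)\n", tab$category[i],
                tab$count[i],
                ifelse(is.na(tab$percent[i]), "NA",
                       formatC(tab$percent[i], format = "f", digits = 2)),
                tab$denominator[i]))
  }
  if (x$longer_than_max > 0) {
    cat(sprintf("  %-24s %12d  (outside size range, not in clean_tags)\n",
                "longer_than_max", x$longer_than_max))
  }
  invisible(x)
}
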