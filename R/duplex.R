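#' Penalty model for miRNA:target pairing
#'
#' Plant-style (Allen-type) penalty scheme: a mismatch costs 1, a G:U wobble
#' 0.5, a gap 2, and penalties inside the seed band are doubled. Positions
#' are numbered 1..n from the miRNA 5' end.
#'
#' @param mismatch_penalty,wobble_penalty,gap_penalty penalty constants.
#' @param seed_multiplier factor applied inside the seed band.
#' @return list of class `pairing_model`.
#' @export
pairing_model <- function(mismatch_penalty = 1.0, wobble_penalty = 0.5,
                          gap_penalty = 2.0, seed_multiplier = 2.0) {
  stopifnot(mismatch_penalty >= 0, wobble_penalty >= 0, gap_penalty >= 0,
            wobble_penalty < mismatch_penalty)
  structure(list(mismatch_penalty = mismatch_penalty,
                 wobble_penalty = wobble_penalty,
                 gap_penalty = gap_penalty,
                 seed_multiplier = seed_multiplier),
            class = "pairing_model")
}

# State symbols along the alignment (miRNA 5'->3'):
#   M match, W G:U wobble, X mismatch,
#   g gap in the target opposite a miRNA base (miRNA bulge),
#   t extra target base (target bulge).

#' Enumerate miRNA target-site alignments along a transcript
#'
#' Slides the miRNA's reverse complement along the transcript and reports
#' the antiparallel pairing state vector at every offset (miRNA position 1 is
#' its 5' nucleotide and pairs the 3'-most site base). With
#' `allow_gaps = TRUE`, single-gap variants (one bulged miRNA base or one
#' extra target base at every internal position) are enumerated as well.
#'
#' @param milrna miRNA sequence (5'->3').
#' @param transcript target sequence (5'->3').
#' @param model [pairing_model()].
#' @param allow_gaps also enumerate single-gap alignments.
#' @param seed_band positions whose penalties are doubled by the default
#'   score; scores are recomputed by callers for other bands via
#'   [score_alignment()].
#' @param max_score drop alignments scoring above this (candidate pruning;
#'   the default keeps everything).
#' @return data.frame with one row per alignment: `offset` (site start on
#'   the transcript, 1-based), `site_end`, `site` (target strand, 5'->3'),
#'   `states` (state string), `n_mismatch`, `n_wobble`, `n_gap`,
#'   `mismatch_equivalents` (mismatches + 0.5 per wobble) and `score`
#'   (weighted penalty under `seed_band`).
#' @export
align_site <- function(milrna, transcript, model = pairing_model(),
                       allow_gaps = FALSE, seed_band = 2:13,
                       max_score = Inf) {
  if (!nzchar(milrna) || !nzchar(transcript)) stop("empty sequence")
  mi <- chars(to_dna(milrna)); n <- length(mi)
  txs <- to_dna(transcript); txc <- chars(txs); m <- length(txc)
  if (m < n && !allow_gaps) {
    stop("transcript shorter than miRNA and gaps disallowed")
  }

  # state of miRNA position i against transcript position k, precomputed once
  C <- matrix("X", nrow = n, ncol = m)
  for (i in seq_len(n)) {
    C[i, txc == COMPLEMENT[[mi[i]]]] <- "M"
    if (mi[i] == "G") C[i, txc == "T"] <- "W"
    if (mi[i] == "T") C[i, txc == "G"] <- "W"
  }
  penalty <- c(M = 0, W = model$wobble_penalty, X = model$mismatch_penalty,
               g = model$gap_penalty, t = model$gap_penalty)

  # assemble one block of alignments sharing a row layout. K: row x offset
  # matrix of transcript indices (NA = gap row); mi_row: miRNA position
  # compared in each row (NA = gap row); pos: miRNA position each row counts
  # as for seed-band weighting.
  block <- function(offsets, K, mi_row, pos, gap_state, width) {
    nr <- nrow(K)
    S <- matrix(gap_state, nrow = nr, ncol = length(offsets))
    idx <- !is.na(K)
    row_of <- matrix(mi_row, nrow = nr, ncol = ncol(K))
    S[idx] <- C[cbind(row_of[idx], K[idx])]
    P <- matrix(penalty[S], nrow = nr)
    mult <- ifelse(pos %in% seed_band, model$seed_multiplier, 1)
    score <- colSums(P * mult)
    keep <- score <= max_score
    if (!any(keep)) return(NULL)
    S <- S[, keep, drop = FALSE]; offsets <- offsets[keep]
    data.frame(
      offset = offsets, site_end = offsets + width - 1L,
      site = substring(txs, offsets, offsets + width - 1L),
      states = do.call(paste0, asplit(S, 1L)),
      n_mismatch = colSums(S == "X"), n_wobble = colSums(S == "W"),
      n_gap = colSums(S == "g" | S == "t"),
      score = score[keep]
    )
  }

  out <- list()
  if (m >= n) {
    offsets <- seq_len(m - n + 1L)
    K <- outer(seq_len(n), offsets, function(i, o) o + n - i)
    out[[1L]] <- block(offsets, K, seq_len(n), seq_len(n), NA, n)
  }

  if (allow_gaps && n >= 3L) {
    for (g in 2:(n - 1L)) {
      # one bulged miRNA base at position g: site window n-1 nt
      if (m >= n - 1L) {
        offsets <- seq_len(m - n + 2L)
        j <- ifelse(seq_len(n) < g, seq_len(n), seq_len(n) - 1L)
        K <- outer(j, offsets, function(jj, o) o + n - 1L - jj)
        K[g, ] <- NA
        out[[length(out) + 1L]] <- block(offsets, K, seq_len(n), seq_len(n),
                                         "g", n - 1L)
      }
      # one extra target base after position g: site window n+1 nt
      if (m >= n + 1L) {
        offsets <- seq_len(m - n)
        cols <- seq_len(n + 1L)
        mi_row <- ifelse(cols <= g, cols, cols - 1L)
        mi_row[g + 1L] <- NA
        pos <- ifelse(cols <= g, cols, cols - 1L)
        pos[g + 1L] <- g + 1L  # the bulged base carries the next position
        K <- outer(cols, offsets, function(cc, o) o + n + 1L - cc)
        K[g + 1L, ] <- NA
        out[[length(out) + 1L]] <- block(offsets, K, mi_row, pos, "t", n + 1L)
      }
    }
  }

  df <- do.call(rbind, out)
  if (is.null(df) || nrow(df) == 0L) {
    return(data.frame(offset = integer(), site_end = integer(),
                      site = character(), states = character(),
                      n_mismatch = integer(), n_wobble = integer(),
                      n_gap = integer(), mismatch_equivalents = numeric(),
                      score = numeric()))
  }
  rownames(df) <- NULL
  df$mismatch_equivalents <- df$n_mismatch + 0.5 * df$n_wobble
  df
}

#' Weighted penalty score of an alignment state string
#'
#' Sums the model penalties over the state string, doubling (by
#' `seed_multiplier`) every penalty whose miRNA position falls in
#' `seed_band`. An extra target base (`t` state) carries the position of the
#' next miRNA nucleotide.
#'
#' @param states state string from [align_site()].
#' @param model [pairing_model()].
#' @param seed_band integer positions (miRNA 5'->3' numbering).
#' @return the weighted score.
#' @export
score_alignment <- function(states, model = pairing_model(), seed_band = 2:13) {
  st <- chars(states)
  pos <- integer(length(st))
  mi_pos <- 1L
  for (k in seq_along(st)) {
    pos[k] <- mi_pos
    if (st[k] != "t") mi_pos <- mi_pos + 1L
  }
  pen <- c(M = 0, W = model$wobble_penalty, X = model$mismatch_penalty,
           g = model$gap_penalty, t = model$gap_penalty)[st]
  mult <- ifelse(pos %in% seed_band, model$seed_multiplier, 1)
  sum(pen * mult)
}

# miRNA positions (1..n) covered by each state-string entry
state_positions <- function(states) {
  st <- chars(states)
  pos <- integer(length(st)); mi_pos <- 1L
  for (k in seq_along(st)) {
    pos[k] <- mi_pos
    if (st[k] != "t") mi_pos <- mi_pos + 1L
  }
  pos
}

#' Duplex-to-perfect free-energy ratio
#'
#' Ratio of the hybridisation MFE of the miRNA bound to a candidate site
#' over the MFE of the miRNA bound to its exact complement. Both energies
#' are negative, so a ratio near 1 means near-perfect pairing energy; the
#' conventional pass criterion (evaluated by callers) is ratio >= 0.6. The
#' ratio is scale-free.
#'
#' @param milrna miRNA sequence.
#' @param site candidate site sequence (target strand, 5'->3').
#' @param engine [vienna_engine()].
#' @return numeric ratio.
#' @export
energy_ratio <- function(milrna, site, engine = vienna_engine()) {
  d <- engine$duplex(c(milrna, milrna), c(site, revcomp(milrna)))
  d$mfe[1] / d$mfe[2]
}

#' Render an alignment as a duplex diagram
#'
#' Three text lines: the miRNA written 3'->5' over the target site written
#' 5'->3', with `|` marking Watson-Crick pairs, `o` wobbles, and spaces
#' elsewhere.
#'
#' @param milrna miRNA sequence.
#' @param alignment one row of the data.frame from [align_site()].
#' @return character vector of three lines.
#' @export
format_duplex <- function(milrna, alignment) {
  st <- chars(alignment$states)
  mi <- chars(to_dna(milrna)); site <- chars(alignment$site)
  top <- character(length(st)); mid <- character(length(st))
  bot <- character(length(st))
  i <- 1L; j <- length(site)
  for (k in seq_along(st)) {
    top[k] <- if (st[k] == "t") "-" else mi[i]
    bot[k] <- if (st[k] == "g") "-" else site[j]
    mid[k] <- switch(st[k], M = "|", W = "o", " ")
    if (st[k] != "t") i <- i + 1L
    if (st[k] != "g") j <- j - 1L
  }
  c(paste0("miRNA  3' ", paste(rev(top), collapse = ""), " 5'"),
    paste0("          ", paste(rev(mid), collapse = "")),
    paste0("target 5' ", paste(rev(bot), collapse = ""), " 3'"))
}
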