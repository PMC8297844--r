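#' Thermodynamic folding engine backed by ViennaRNA
#'
#' Constructs the folding-engine object used throughout the pipeline: a pair
#' of deterministic functions, `fold()` for single-sequence minimum-free-energy
#' (MFE) secondary structure prediction and `duplex()` for intermolecular
#' miRNA:target hybridisation, both delegating to the ViennaRNA command-line
#' programs `RNAfold` and `RNAduplex`.
#'
#' Sequences are converted to RNA (T -> U) before folding. Both functions are
#' vectorised and batch all inputs into a single subprocess invocation, which
#' matters: process start-up dominates for short sequences.
#'
#' @param rnafold path to the `RNAfold` executable.
#' @param rnaduplex path to the `RNAduplex` executable.
#' @return An object of class `folding_engine`: a list with elements
#'   \describe{
#'     \item{fold(seqs)}{character vector in, data.frame out with columns
#'       `sequence`, `structure` (dot-bracket) and `mfe` (kcal/mol).}
#'     \item{duplex(a, b)}{two character vectors (recycled to equal length) in,
#'       data.frame out with columns `structure`, `i_start`, `i_end`,
#'       `j_start`, `j_end` (1-based pairing intervals on the two sequences)
#'       and `mfe` (kcal/mol).}
#'   }
#' @examples
#' \dontrun{
#' eng <- vienna_engine()
#' eng$fold("GGGGAAAACCCC")
#' eng$duplex("UGAAACCGCGAACAAACUUG", "CAAGUUUGUUCGCGGUUUCA")
#' }
#' @export
vienna_engine <- function(rnafold = "RNAfold", rnaduplex = "RNAduplex") {
  if (Sys.which(rnafold) == "" || Sys.which(rnaduplex) == "") {
    stop("ViennaRNA executables not found on PATH (need RNAfold and RNAduplex)")
  }
  engine <- list(
    fold = function(seqs) vienna_fold(seqs, rnafold),
    duplex = function(a, b) vienna_duplex(a, b, rnaduplex)
  )
  class(engine) <- "folding_engine"
  engine
}

#' @export
print.folding_engine <- function(x, ...) {
  cat("<folding_engine> ViennaRNA (RNAfold/RNAduplex)\n")
  invisible(x)
}

to_rna <- function(x) chartr("acgtuT", "ACGUUU", x)

vienna_fold <- function(seqs, rnafold = "RNAfold") {
  seqs <- as.character(seqs)
  if (length(seqs) == 0L) {
    return(data.frame(sequence = character(), structure = character(),
                      mfe = numeric()))
  }
  if (any(!nzchar(seqs))) stop("cannot fold an empty sequence")
  rna <- to_rna(seqs)
  out <- system2(rnafold, args = c("--noPS"), input = rna,
                 stdout = TRUE, stderr = FALSE)
  status <- attr(out, "status")
  if (!is.null(status) && status != 0L) {
    stop("RNAfold failed with status ", status)
  }
  # output alternates: sequence line, then "structure ( mfe)"
  struct_lines <- out[seq(2L, length(out), by = 2L)]
  m <- regmatches(struct_lines,
                  regexec("^([.()]+)\\s+\\(\\s*(-?[0-9]+\\.[0-9]+)\\)",
                          struct_lines))
  bad <- vapply(m, length, integer(1)) != 3L
  if (any(bad)) stop("unparseable RNAfold output: ", struct_lines[bad][1])
  data.frame(
    sequence = seqs,
    structure = vapply(m, `[`, character(1), 2L),
    mfe = as.numeric(vapply(m, `[`, character(1), 3L))
  )
}

vienna_duplex <- function(a, b, rnaduplex = "RNAduplex") {
  n <- max(length(a), length(b))
  if (n == 0L) {
    return(data.frame(structure = character(), i_start = integer(),
                      i_end = integer(), j_start = integer(),
                      j_end = integer(), mfe = numeric()))
  }
  a <- rep_len(as.character(a), n)
  b <- rep_len(as.character(b), n)
  if (any(!nzchar(a)) || any(!nzchar(b))) stop("cannot duplex an empty sequence")
  input <- as.vector(rbind(to_rna(a), to_rna(b)))
  out <- system2(rnaduplex, input = input, stdout = TRUE, stderr = FALSE)
  status <- attr(out, "status")
  if (!is.null(status) && status != 0L) {
    stop("RNAduplex failed with status ", status, " on ", a[1], " / ", b[1])
  }
  out <- out[nzchar(out)]
  if (length(out) != n) stop("RNAduplex returned ", length(out),
                             " records for ", n, " sequence pairs")
  pat <- paste0("^([.(&)]+)\\s+([0-9]+),([0-9]+)\\s*:\\s*([0-9]+),([0-9]+)",
                "\\s+\\(\\s*(-?[0-9.]+)\\)")
  m <- regmatches(out, regexec(pat, out))
  bad <- vapply(m, length, integer(1)) != 7L
  if (any(bad)) stop("unparseable RNAduplex output: ", out[bad][1])
  f <- function(i, as_num = FALSE) {
    v <- vapply(m, `[`, character(1), i)
    if (as_num) as.numeric(v) else as.integer(v)
  }
  data.frame(
    structure = vapply(m, `[`, character(1), 2L),
    i_start = f(3L), i_end = f(4L), j_start = f(5L), j_end = f(6L),
    mfe = f(7L, as_num = TRUE)
  )
}

#' Parse a dot-bracket string into a base-pair table
#'
#' @param structure a balanced dot-bracket string.
#' @return integer vector `p` with `p[i] = j` if position `i` pairs with `j`,
#'   and 0 if unpaired.
#' @export
pair_table <- function(structure) {
  chars <- strsplit(structure, "", fixed = TRUE)[[1]]
  n <- length(chars)
  pt <- integer(n)
  stack <- integer(0)
  for (i in seq_len(n)) {
    if (chars[i] == "(") {
      stack <- c(stack, i)
    } else if (chars[i] == ")") {
      if (length(stack) == 0L) stop("unbalanced dot-bracket string")
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      pt[i] <- j
      pt[j] <- i
    }
  }
  if (length(stack) > 0L) stop("unbalanced dot-bracket string")
  pt
}
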