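# Shared small helpers. Sequences are handled as plain uppercase DNA strings
# (A/C/G/T) internally; conversion to RNA happens only at the folding boundary.

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(to_dna(x))))
}

to_dna <- function(x) chartr("acgtuU", "ACGTTT", x)

random_dna <- function(n, length, gc = 0.5) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  vapply(seq_len(n), function(i) {
    paste(sample(names(p), length, replace = TRUE, prob = p), collapse = "")
  }, character(1))
}

chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

# Watson-Crick complement lookup on DNA alphabet
COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

is_wc_pair <- function(a, b) COMPLEMENT[a] == b

# G:U wobble on DNA alphabet: miRNA G with target T, or miRNA T with target G
is_wobble_pair <- function(a, b) (a == "G" & b == "T") | (a == "T" & b == "G")

`%||%` <- function(a, b) if (is.null(a)) b else a
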