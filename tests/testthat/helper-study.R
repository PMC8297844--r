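# Shared folding engine and a lazily built, cached default study + pipeline
# run (several test files interrogate the same end-to-end result).

engine <- vienna_engine()

.cache <- new.env(parent = emptyenv())

get_study <- function() {
  if (is.null(.cache$study)) .cache$study <- synthetic_study(1L, engine)
  .cache$study
}

study_config <- function(study) {
  pipeline_config(
    reads = study$reads, genome = study$genome$genome,
    tracks = study$genome$tracks, ncrna = study$genome$ncrna,
    mature_reference = study$mature_reference,
    host_genome = study$host$host_genome,
    host_transcripts = study$host$transcripts,
    rng_seed = 1L, engine = engine)
}

get_result <- function() {
  if (is.null(.cache$result)) {
    .cache$result <- run_pipeline(study_config(get_study()))
  }
  .cache$result
}

rand_seq <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

# naive reverse complement used as an independent check
naive_rc <- function(x) {
  paste(rev(chartr("ACGT", "TGCA", strsplit(x, "")[[1]])), collapse = "")
}

# naive gap-free duplex state enumeration (independent oracle for align_site)
naive_align <- function(mi, tx) {
  mic <- strsplit(mi, "")[[1]]; txc <- strsplit(tx, "")[[1]]
  n <- length(mic); m <- length(txc)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  vapply(seq_len(m - n + 1L), function(o) {
    st <- vapply(seq_len(n), function(i) {
      b <- txc[o + n - i]
      if (b == comp[[mic[i]]]) "M"
      else if ((mic[i] == "G" && b == "T") || (mic[i] == "T" && b == "G")) "W"
      else "X"
    }, character(1))
    paste(st, collapse = "")
  }, character(1))
}
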