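#!/usr/bin/env Rscript

# Stage 1 -- build the synthetic study.
#
# Generates the default study: a 60 kb fungal genome with 6 planted milRNA
# hairpins and 14 decoy loci, a 10,000-read adapter-ligated library with the
# six contamination classes, a known-miRNA reference, and a host genome +
# 8-transcript host set carrying designed target sites (four expected to
# reach three-ruleset consensus, two expected to fail, and one milRNA
# embedded in a stable host hairpin). Writes every input in its standard
# format plus the ground-truth tables.

suppressPackageStartupMessages(library(milkit))

seed <- 1L
out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

message("building synthetic study (seed ", seed, ") ...")
study <- synthetic_study(seed)

Biostrings::writeXStringSet(study$genome$genome,
                            file.path(out, "fungal_genome.fasta"))
Biostrings::writeXStringSet(study$host$host_genome,
                            file.path(out, "host_genome.synthetic.fasta"))
Biostrings::writeXStringSet(study$host$transcripts,
                            file.path(out, "host_transcripts.fasta"))
Biostrings::writeXStringSet(study$mature_reference,
                            file.path(out, "known_mature.fasta"))
for (cls in names(study$genome$ncrna)) {
  Biostrings::writeXStringSet(study$genome$ncrna[[cls]],
                              file.path(out, paste0(cls, ".fasta")))
}
write_fastq(study$reads, file.path(out, "reads.fastq"))
if (requireNamespace("rtracklayer", quietly = TRUE)) {
  rtracklayer::export(study$genome$tracks, file.path(out, "tracks.gff3"),
                      format = "gff3")
}

truth <- study$genome$truth
write.table(truth$milrnas, file.path(out, "truth_milrnas.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(truth$decoys[, setdiff(names(truth$decoys), "seq")],
            file.path(out, "truth_decoys.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(study$host$truth$target_sites,
            file.path(out, "truth_target_sites.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

message("planted ", nrow(truth$milrnas), " milRNA hairpins (MFE range ",
        min(truth$milrnas$mfe), " .. ", max(truth$milrnas$mfe),
        " kcal/mol), ", nrow(truth$decoys), " decoy loci, ",
        length(study$reads$sequence), " reads, ",
        nrow(study$host$truth$target_sites), " designed host sites")
message("inputs written under ", out)
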