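#!/usr/bin/env Rscript
# Stage 1: validate the nine packaged oligos against their domain
# formulas, map the duplexes of the two-strand complexes, and derive the
# hairpin reporter geometry. Writes results/strand_validation.json,
# results/duplex_maps.tsv, results/strands.fasta, results/domains.tsv.

suppressPackageStartupMessages(library(seesawleak))
dir.create("results", showWarnings = FALSE)

rep <- validate_strands_report("results/strand_validation.json")
cat(sprintf("validated %d strands: %d exact matches (status: %s)\n",
            rep$n_strands, rep$n_match, rep$status))
p5 <- validate_strand("P5")
cat(sprintf("P5 assembles with a %d-nt tail discrepancy at 0-based %s:\n",
            length(p5$mismatch_positions),
            paste(range(p5$mismatch_positions), collapse = "-")),
    sprintf("  assembled ...%s vs printed ...%s\n",
            substr(p5$assembled, 19, 21), substr(p5$printed, 19, 21)))

maps <- do.call(rbind, lapply(c("T2", "T3"), function(id) {
  m <- duplex_map(id)
  m$sample_id <- id
  m
}))
write.table(maps, "results/duplex_maps.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("duplexes: Threshold T2 pairs", maps$length[maps$sample_id == "T2"],
    "bp; Gate T3 pairs", maps$length[maps$sample_id == "T3"],
    "bp (the Gate's s3 output domain stays single-stranded)\n")

g <- hairpin_geometry("P9")
cat(sprintf("hairpin reporter P9: stem %d bp, loop %d nt, toehold %d nt (sum %d)\n",
            g$stem_bp, g$loop_nt, g$toehold_nt,
            2L * g$stem_bp + g$loop_nt + g$toehold_nt))

export_fasta("results/strands.fasta")
export_domains("results/domains.tsv")
cat("wrote results/strand_validation.json, duplex_maps.tsv, strands.fasta, domains.tsv\n")
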