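#!/usr/bin/env Rscript

# Build the three perturbation libraries on the 601-based 40N40 construct:
# poly(dA:dT) tracts of 3-15 bp tiled over every core position, 1-5
# consecutive mismatches per strand, and single-A insertions per gap per
# strand. Writes FASTA + TSV manifests under results/library/.

suppressMessages(library(nucleoslide))

outdir <- "results/library"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

ref <- reference_601_40N40()
print(ref)

polyA <- build_polyA_library(ref, 3:15)
mm <- build_mismatch_library(ref, 1:5)
ins <- build_insertion_library(ref)

cat(sprintf("poly(dA:dT) variants: %d (expect 1781 = sum over L of 146 - L)\n",
            nrow(polyA)))
cat(sprintf("mismatch variants:    %d (2 strands x non-A:T windows)\n",
            nrow(mm)))
cat(sprintf("insertion variants:   %d (2 strands x 144 core gaps)\n",
            nrow(ins)))

write_library(polyA, file.path(outdir, "polyA.fa"),
              file.path(outdir, "polyA.tsv"))
write_library(mm, file.path(outdir, "mismatch.fa"),
              file.path(outdir, "mismatch.tsv"))
write_library(ins, file.path(outdir, "insertion.fa"),
              file.path(outdir, "insertion.tsv"))

write_run_manifest(file.path(outdir, "manifest.yaml"), "build-libraries",
                   list(reference = "601_40N40", polyA_lengths = "3:15",
                        mismatch_windows = "1:5"),
                   seed = NA,
                   outputs = file.path(outdir, c("polyA.fa", "polyA.tsv",
                                                 "mismatch.fa", "mismatch.tsv",
                                                 "insertion.fa",
                                                 "insertion.tsv")))
cat("written to", outdir, "\n")
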