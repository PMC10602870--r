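#!/usr/bin/env Rscript

# Simulate site-specific cleavage sequencing for the bundled toy library:
# 12 variants with planted dyad distributions, 300 events each, two reads
# per event (one per strand, each starting 53 nt 5' of the dyad and running
# 3'). Writes FASTQ + ground-truth TSV under results/toy/.

suppressMessages(library(nucleoslide))

outdir <- "results/toy"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

cfg <- read_pipeline_config(toy_config_path())
ref <- ref_construct(cfg$construct$core_seq, cfg$construct$left_flank,
                     cfg$construct$right_flank, name = cfg$name)
labels <- vapply(cfg$variants, `[[`, "", "label")
strands <- vapply(cfg$variants, function(v)
  if (is.null(v$strand)) "top" else v$strand, "")
lib <- library_from_labels(ref, labels, strands)
dists <- lapply(cfg$variants, function(v) {
  w <- if (is.null(v$weights)) rep(1, length(v$peaks)) else unlist(v$weights)
  mixture_dyad_distribution(ref, unlist(v$peaks), w, sd = 0)
})
names(dists) <- lib$uid

reads <- simulate_library_reads(lib, dists, depth = cfg$depth,
                                error_rate = cfg$error_rate,
                                read_length = cfg$read_length,
                                seed = derive_seed(cfg$seed, "simulate"))
cat(sprintf("simulated %d reads for %d variants (%d events dropped)\n",
            nrow(reads), nrow(lib), attr(reads, "n_dropped")))

emit_fastq(reads, file.path(outdir, "reads.fastq"))
utils::write.table(parse_read_truth(reads$read_id),
                   file.path(outdir, "truth.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
write_library(lib, file.path(outdir, "library.fa"),
              file.path(outdir, "library.tsv"))
write_run_manifest(file.path(outdir, "manifest_simulate.yaml"), "simulate",
                   cfg, derive_seed(cfg$seed, "simulate"),
                   file.path(outdir, c("reads.fastq", "truth.tsv",
                                       "library.fa", "library.tsv")))
cat("written to", outdir, "\n")
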