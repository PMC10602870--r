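#!/usr/bin/env Rscript

# Pattern analytics on the called toy signals: NMF decomposition into basis
# dyad patterns with geographic score maps, exp(-JSD) spectral clustering
# (with silhouettes over candidate k), and the KL-divergence map against
# the planted unperturbed positioning. Requires 03_call_dyads.R outputs.

suppressMessages(library(nucleoslide))

outdir <- "results/toy"
cfg <- read_pipeline_config(toy_config_path())
ref <- ref_construct(cfg$construct$core_seq, cfg$construct$left_flank,
                     cfg$construct$right_flank, name = cfg$name)
labels <- vapply(cfg$variants, `[[`, "", "label")
strands <- vapply(cfg$variants, function(v)
  if (is.null(v$strand)) "top" else v$strand, "")
lib <- library_from_labels(ref, labels, strands)

sig_long <- utils::read.delim(file.path(outdir, "signals.tsv"))
uids <- unique(sig_long$uid)
X <- matrix(0, length(uids), ref$total_length,
            dimnames = list(uids, NULL))
X[cbind(match(sig_long$uid, uids), sig_long$position + 1L)] <- sig_long$prob
X <- X[setdiff(rownames(X), "reference"), , drop = FALSE]

dec <- nmf_decompose(X, rank = cfg$nmf_rank,
                     seed = derive_seed(cfg$seed, "nmf"))
cat(sprintf("NMF rank %d: %d iterations, final error %.4g\n",
            cfg$nmf_rank, dec$iterations, min(dec$error_trace)))
meta <- lib[, c("uid", "kind", "strand", "start_dyad", "length")]
for (b in seq_len(cfg$nmf_rank)) {
  sm <- nmf_score_map(dec, meta, b)
  peak <- which(dec$basis[b, ] == max(dec$basis[b, ])) - 1L
  cat(sprintf("  basis %d peaks at construct position %d (dyad-relative %+d)\n",
              b, peak[1], peak[1] - dyad_construct_index(ref)))
}

S <- js_similarity_matrix(X)
sil <- cluster_silhouettes(S, ks = 2:5, seed = derive_seed(cfg$seed, "cluster"))
print(sil)
clusters <- spectral_cluster(S, cfg$cluster_k,
                             seed = derive_seed(cfg$seed, "cluster"))
cat("cluster sizes:", paste(table(clusters), collapse = ", "), "\n")

ref_w <- if (is.null(cfg$reference_weights)) {
  rep(1, length(cfg$reference_peaks))
} else {
  unlist(cfg$reference_weights)
}
ref_dist <- mixture_dyad_distribution(ref, unlist(cfg$reference_peaks),
                                      ref_w, sd = 0)
kl <- kl_divergence_map(X, ref_dist, meta)
cat("KL vs unperturbed positioning (top 3):\n")
print(head(sort(kl$kl, decreasing = TRUE), 3))

utils::write.table(data.frame(uid = rownames(dec$weights), dec$weights),
                   file.path(outdir, "nmf_weights.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
utils::write.table(data.frame(basis = seq_len(nrow(dec$basis)), dec$basis),
                   file.path(outdir, "nmf_basis.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
utils::write.table(data.frame(uid = names(clusters),
                              cluster = unname(clusters)),
                   file.path(outdir, "clusters.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
utils::write.table(data.frame(uid = names(kl$kl), kl = unname(kl$kl)),
                   file.path(outdir, "kl.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
write_run_manifest(file.path(outdir, "manifest_patterns.yaml"), "patterns",
                   cfg, cfg$seed,
                   file.path(outdir, c("nmf_weights.tsv", "nmf_basis.tsv",
                                       "clusters.tsv", "kl.tsv")))
cat("written to", outdir, "\n")
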