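#' Derive a per-stage seed from a global seed
#'
#' Every pipeline stage draws its own seed deterministically from the single
#' global seed and the stage name, so stages can be rerun in isolation while
#' a whole run stays reproducible. The derivation is a small string hash
#' folded into the global seed, kept within the 32-bit integer range.
#'
#' @param global_seed integer global seed.
#' @param stage stage name (character).
#' @return integer seed in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(global_seed, stage) {
  h <- 0
  for (cc in utf8ToInt(stage)) h <- (h * 131 + cc) %% 2147483647
  as.integer((abs(global_seed) %% 2147483647 * 48271 + h) %% 2147483645 + 1)
}

#' Read and validate a pipeline configuration
#'
#' YAML configuration with keys: `name`, `seed`, `construct` (list with
#' `core_seq`, `left_flank`, `right_flank`), `variants` (list of
#' `label`/`strand`/`peaks`/`weights` entries; peaks are dyad-relative),
#' `reference_peaks`/`reference_weights` (planted unperturbed positioning),
#' `depth`, `error_rate`, `read_length`, `max_mismatches`, `bg_quantile`,
#' `combine`, `nmf_rank`, `cluster_k`.
#'
#' @param path YAML file path, or a pre-parsed list.
#' @return validated config list.
#' @export
read_pipeline_config <- function(path) {
  config <- if (is.character(path)) yaml::read_yaml(path) else path
  required <- c("name", "seed", "construct", "variants", "reference_peaks",
                "depth", "error_rate", "read_length", "max_mismatches",
                "bg_quantile", "combine", "nmf_rank", "cluster_k")
  missing <- setdiff(required, names(config))
  if (length(missing) > 0L)
    stop("config is missing required key(s): ", paste(missing, collapse = ", "))
  for (key in c("core_seq", "left_flank", "right_flank"))
    if (is.null(config$construct[[key]]))
      stop("config is missing required key: construct$", key)
  config
}

#' Path of the bundled toy pipeline configuration
#' @return file path under the installed package.
#' @export
toy_config_path <- function() {
  system.file("extdata", "toy_config.yaml", package = "nucleoslide")
}

# Build a single variant record from a perturbation on a reference.
variant_from_perturbation <- function(ref, p) {
  top_ref <- construct_top(ref)
  bottom_ref <- revcomp(top_ref)
  Tn <- ref$total_length
  off <- nchar(ref$left_flank)
  s0 <- p$start_dyad + ref$dyad_core_index
  C <- nchar(ref$core_seq)
  if (p$kind == "polyA") {
    if (s0 < 0L || s0 + p$length > C) stop("tract outside the core")
    top <- substr_assign(top_ref, off + s0 + 0:(p$length - 1L), "A")
    return(variant_row(ref, p, top, revcomp(top)))
  }
  if (p$kind == "mismatch") {
    if (s0 < 0L || s0 + p$length > C) stop("mismatch window outside the core")
    core <- strsplit(ref$core_seq, "")[[1]]
    win <- s0 + 0:(p$length - 1L)
    subs <- win[!(core[win + 1L] %in% c("A", "T"))]
    if (length(subs) == 0L) stop("all-A:T window carries no mismatch")
    if (p$strand == "top")
      return(variant_row(ref, p, substr_assign(top_ref, off + subs, "A"),
                         bottom_ref))
    return(variant_row(ref, p, top_ref,
                       substr_assign(bottom_ref, Tn - 1L - (off + subs), "T")))
  }
  if (p$kind == "insertion") {
    if (s0 < 0L || s0 + 1L > C - 1L) stop("insertion gap outside the core")
    ca <- off + s0
    if (p$strand == "top") {
      top <- paste0(substr(top_ref, 1L, ca + 1L), "A",
                    substr(top_ref, ca + 2L, Tn))
      return(variant_row(ref, p, top, bottom_ref))
    }
    ib <- Tn - 1L - ca
    bot <- paste0(substr(bottom_ref, 1L, ib), "A",
                  substr(bottom_ref, ib + 1L, Tn))
    return(variant_row(ref, p, top_ref, bot))
  }
  stop("no builder for perturbation kind '", p$kind, "'")
}

#' Build a variant library from labels
#'
#' @param ref a [ref_construct()].
#' @param labels character vector of variant labels.
#' @param strands strand per label (ignored for duplex `A_` labels).
#' @return variant data.frame with attribute `"ref"`.
#' @export
library_from_labels <- function(ref, labels, strands = rep("top", length(labels))) {
  rows <- lapply(seq_along(labels), function(j)
    variant_from_perturbation(ref, parse_variant_label(labels[j], strands[j])))
  lib <- do.call(rbind, rows)
  if (anyDuplicated(lib$uid)) stop("duplicate variant uids")
  attr(lib, "ref") <- ref
  lib
}

#' Write a run manifest
#'
#' Records the package version, stage, config snapshot, seed, timestamps and
#' md5 checksums of every output file, tying outputs to their inputs.
#'
#' @param path manifest file path (YAML).
#' @param stage stage name.
#' @param config config list used.
#' @param seed seed used.
#' @param outputs character vector of output file paths.
#' @return `path`, invisibly.
#' @export
write_run_manifest <- function(path, stage, config, seed, outputs) {
  outputs <- outputs[file.exists(outputs)]
  manifest <- list(
    tool = "nucleoslide",
    version = as.character(utils::packageVersion("nucleoslide")),
    stage = stage,
    seed = seed,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = config,
    outputs = lapply(outputs, function(f)
      list(path = f, md5 = unname(tools::md5sum(f)))))
  yaml::write_yaml(manifest, path)
  invisible(path)
}

planted_distributions <- function(ref, config) {
  dists <- lapply(config$variants, function(v) {
    w <- if (is.null(v$weights)) rep(1, length(v$peaks)) else unlist(v$weights)
    mixture_dyad_distribution(ref, unlist(v$peaks), w, sd = 0)
  })
  names(dists) <- vapply(config$variants, function(v)
    variant_uid(v$label,
                parse_variant_label(v$label, v$strand %||% "top")$strand), "")
  dists
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full pipeline on a configuration
#'
#' End-to-end orchestration: builds the construct and variant library,
#' plants per-variant dyad distributions, simulates cleavage reads, calls
#' per-variant positioning signals, and runs the pattern analytics (NMF,
#' exp(-JSD) spectral clustering, KL map against the planted unperturbed
#' positioning). Deterministic given the config (one global seed expanded
#' into per-stage seeds). When `outdir` is given, TSV tables, FASTQ reads
#' and a YAML run manifest are written there.
#'
#' @param config config list or YAML path (see [read_pipeline_config()]).
#' @param outdir optional output directory (created if needed).
#' @return list with `ref`, `lib`, `truth_dists`, `reads`, `called`
#'   (signals/profiles/qc), `nmf`, `clusters`, `kl`, and `files` (paths
#'   written, or `NULL`).
#' @export
run_pipeline <- function(config, outdir = NULL) {
  config <- read_pipeline_config(config)
  ref <- ref_construct(config$construct$core_seq,
                       config$construct$left_flank,
                       config$construct$right_flank,
                       name = config$name)
  labels <- vapply(config$variants, `[[`, "", "label")
  strands <- vapply(config$variants, function(v) v$strand %||% "top", "")
  lib <- library_from_labels(ref, labels, strands)
  dists <- planted_distributions(ref, config)

  reads <- simulate_library_reads(
    lib, dists, depth = config$depth, error_rate = config$error_rate,
    read_length = config$read_length,
    seed = derive_seed(config$seed, "simulate"))

  called <- call_positioning_signals(
    reads, lib, max_mismatches = config$max_mismatches,
    require_variation = TRUE, bg_quantile = config$bg_quantile,
    combine = config$combine)

  X <- called$signals[setdiff(rownames(called$signals), "reference"), ,
                      drop = FALSE]
  nmf <- nmf_decompose(X, rank = config$nmf_rank,
                       seed = derive_seed(config$seed, "nmf"))
  S <- js_similarity_matrix(X)
  clusters <- spectral_cluster(S, k = config$cluster_k,
                               seed = derive_seed(config$seed, "cluster"))
  ref_w <- if (is.null(config$reference_weights))
    rep(1, length(config$reference_peaks)) else unlist(config$reference_weights)
  ref_dist <- mixture_dyad_distribution(ref, unlist(config$reference_peaks),
                                        ref_w, sd = 0)
  meta <- lib[, c("uid", "kind", "strand", "start_dyad", "length")]
  kl <- kl_divergence_map(X, ref_dist, meta)

  files <- NULL
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    fp <- function(x) file.path(outdir, x)
    emit_fastq(reads, fp("reads.fastq"))
    utils::write.table(parse_read_truth(reads$read_id),
                       fp("truth.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    write_library(lib, fasta = fp("library.fa"), manifest = fp("library.tsv"))
    sig_long <- data.frame(
      uid = rep(rownames(called$signals), ncol(called$signals)),
      position = rep(0:(ncol(called$signals) - 1L),
                     each = nrow(called$signals)),
      prob = as.vector(called$signals))
    utils::write.table(sig_long, fp("signals.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(data.frame(metric = names(called$qc),
                                  value = unname(called$qc)),
                       fp("qc.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    utils::write.table(data.frame(uid = rownames(nmf$weights), nmf$weights),
                       fp("nmf_weights.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    utils::write.table(data.frame(uid = names(clusters),
                                  cluster = unname(clusters)),
                       fp("clusters.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    utils::write.table(data.frame(uid = names(kl$kl), kl = unname(kl$kl)),
                       fp("kl.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    files <- fp(c("reads.fastq", "truth.tsv", "library.fa", "library.tsv",
                  "signals.tsv", "qc.tsv", "nmf_weights.tsv",
                  "clusters.tsv", "kl.tsv"))
    write_run_manifest(fp("manifest.yaml"), "pipeline", config,
                       config$seed, files)
    files <- c(files, fp("manifest.yaml"))
  }

  list(ref = ref, lib = lib, truth_dists = dists, reads = reads,
       called = called, nmf = nmf, clusters = clusters, kl = kl,
       files = files)
}
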