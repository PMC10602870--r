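#' Dyad position distributions
#'
#' A dyad distribution assigns a probability to every construct position
#' (0-based, length `ref$total_length`); it stands in for the outcome of
#' reconstitution or remodeler-driven sliding. `point_dyad_distribution()`
#' puts all mass at one dyad-relative position; `mixture_dyad_distribution()`
#' mixes discretized Gaussian peaks, which emulates the sharp ~10-bp-spaced
#' peaks seen in positioning data.
#'
#' @param ref a [ref_construct()].
#' @param probs nonnegative numeric vector of length `ref$total_length`.
#' @return numeric probability vector (sums to 1).
#' @export
dyad_distribution <- function(ref, probs) {
  if (length(probs) != ref$total_length)
    stop("probs must have length ", ref$total_length)
  if (any(probs < 0) || any(!is.finite(probs)))
    stop("probs must be finite and nonnegative")
  s <- sum(probs)
  if (s <= 0) stop("all-zero dyad distribution")
  probs / s
}

#' @rdname dyad_distribution
#' @param dyad_rel dyad-relative position(s) of the peak(s).
#' @export
point_dyad_distribution <- function(ref, dyad_rel) {
  p <- numeric(ref$total_length)
  p[from_dyad_frame(ref, dyad_rel) + 1L] <- 1
  dyad_distribution(ref, p)
}

#' @rdname dyad_distribution
#' @param weights mixture weights, one per peak.
#' @param sd per-peak spread in bp (0 gives point masses).
#' @export
mixture_dyad_distribution <- function(ref, dyad_rel, weights = NULL, sd = 0.8) {
  if (is.null(weights)) weights <- rep(1, length(dyad_rel))
  stopifnot(length(weights) == length(dyad_rel))
  pos <- 0:(ref$total_length - 1L)
  ctr <- from_dyad_frame(ref, dyad_rel)
  p <- numeric(ref$total_length)
  for (j in seq_along(ctr)) {
    p <- p + weights[j] * if (sd > 0)
      stats::dnorm(pos, ctr[j], sd) else as.numeric(pos == ctr[j])
  }
  dyad_distribution(ref, p)
}

#' Sample dyad positions from a distribution
#'
#' @param probs probability vector over construct positions (0-based grid).
#' @param depth number of nucleosome events to draw.
#' @param seed optional integer seed for reproducibility.
#' @return integer vector of 0-based construct dyad positions.
#' @export
sample_dyad_positions <- function(probs, depth, seed = NULL) {
  if (depth < 1L) stop("depth must be >= 1")
  if (sum(probs) <= 0) stop("all-zero dyad distribution")
  if (!is.null(seed)) set.seed(seed)
  sample.int(length(probs), depth, replace = TRUE, prob = probs) - 1L
}

sequencing_errors <- function(seqs, error_rate) {
  if (error_rate <= 0) return(seqs)
  bases <- c("A", "C", "G", "T")
  vapply(seqs, function(s) {
    n <- nchar(s)
    hit <- which(stats::runif(n) < error_rate)
    if (length(hit) == 0L) return(s)
    ch <- strsplit(s, "")[[1]]
    ch[hit] <- vapply(ch[hit], function(b)
      sample(setdiff(bases, b), 1L), "")
    paste(ch, collapse = "")
  }, "", USE.NAMES = FALSE)
}

#' Simulate site-specific cleavage reads for one variant
#'
#' Each nucleosome event cleaves both backbones 53 nt 5' of the dyad, one
#' site per strand; only the sequence 3' of the cleavage is retained and
#' sequenced, so each event yields one top-strand read starting at construct
#' index `dyad - 53` (running rightward) and one bottom-strand read whose 5'
#' end maps to construct index `dyad + 53` (running leftward in top-strand
#' coordinates, emitted as the bottom-strand sequence, i.e. the reverse
#' complement of the covered top-strand segment). Events whose cleavage
#' sites fall off the construct are dropped and counted.
#'
#' Ground truth is kept in the read id as
#' `<serial>;<variant uid>;<strand>;<dyad>;<cleavage>` with cleavage given as
#' the construct index (top-strand frame) of the first retained base.
#'
#' @param dyad_positions integer vector of 0-based construct dyad positions.
#' @param ref a [ref_construct()].
#' @param variant one-row variant record (as a list or data.frame row) from a
#'   `build_*_library()` data.frame, or `NULL` for the unperturbed reference.
#' @param error_rate per-base substitution error probability (default 0.001).
#' @param read_length read-length cap in nt (default 150, as in 150x150
#'   paired-end sequencing).
#' @param seed optional integer seed.
#' @param cleavage_offset distance from dyad to each cleavage site (53 nt).
#' @return data.frame of reads (`read_id`, `strand`, `sequence`, `qualities`,
#'   `variant_uid`, `dyad`, `cleavage`) with attribute `"n_dropped"`.
#' @export
simulate_cleavage_events <- function(dyad_positions, ref, variant = NULL,
                                     error_rate = 0.001, read_length = 150L,
                                     seed = NULL, cleavage_offset = 53L) {
  if (!is.null(seed)) set.seed(seed)
  Tn <- ref$total_length
  keep <- dyad_positions - cleavage_offset >= 0L &
    dyad_positions + cleavage_offset <= Tn - 1L
  n_dropped <- sum(!keep)
  d <- dyad_positions[keep]
  if (is.null(variant)) {
    uid <- "reference"
    top_seq <- construct_top(ref)
    bottom_seq <- revcomp(top_seq)
    vrec <- NULL
  } else {
    variant <- as.list(variant)
    uid <- variant$uid
    top_seq <- variant$top_seq
    bottom_seq <- variant$bottom_seq
    vrec <- variant
  }
  n <- length(d)
  out <- if (n == 0L) {
    data.frame(read_id = character(), strand = character(),
               sequence = character(), qualities = character(),
               variant_uid = character(), dyad = integer(),
               cleavage = integer(), stringsAsFactors = FALSE)
  } else {
    v_top <- vapply(d - cleavage_offset, function(r)
      ref_to_strand_idx(ref, vrec, "top", r), integer(1))
    v_bot <- vapply(d + cleavage_offset, function(r)
      ref_to_strand_idx(ref, vrec, "bottom", r), integer(1))
    top_reads <- substr(rep(top_seq, n), v_top + 1L, v_top + read_length)
    bot_reads <- substr(rep(bottom_seq, n), v_bot + 1L, v_bot + read_length)
    top_reads <- sequencing_errors(top_reads, error_rate)
    bot_reads <- sequencing_errors(bot_reads, error_rate)
    cle_top <- d - cleavage_offset
    cle_bot <- d + cleavage_offset
    ids_top <- sprintf("%06d;%s;top;%d;%d", seq_len(n), uid, d, cle_top)
    ids_bot <- sprintf("%06d;%s;bottom;%d;%d", seq_len(n), uid, d, cle_bot)
    data.frame(
      read_id = c(ids_top, ids_bot),
      strand = rep(c("top", "bottom"), each = n),
      sequence = c(top_reads, bot_reads),
      qualities = strrep("I", nchar(c(top_reads, bot_reads))),
      variant_uid = uid,
      dyad = c(d, d),
      cleavage = c(cle_top, cle_bot),
      stringsAsFactors = FALSE)
  }
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Simulate reads for a whole variant library
#'
#' @param lib variant data.frame from the `build_*_library()` functions (with
#'   attribute `"ref"`).
#' @param dists named list mapping variant `uid` to a dyad probability
#'   vector, or a single vector recycled for all variants.
#' @param depth events per variant (default 2000).
#' @param error_rate,read_length,seed as in [simulate_cleavage_events()].
#' @return combined read data.frame with attribute `"n_dropped"`.
#' @export
simulate_library_reads <- function(lib, dists, depth = 2000L,
                                   error_rate = 0.001, read_length = 150L,
                                   seed = NULL) {
  ref <- attr(lib, "ref")
  if (is.null(ref)) stop("library has no attached ref_construct")
  if (!is.null(seed)) set.seed(seed)
  single <- is.numeric(dists)
  pieces <- vector("list", nrow(lib))
  dropped <- 0L
  for (i in seq_len(nrow(lib))) {
    p <- if (single) dists else dists[[lib$uid[i]]]
    if (is.null(p)) stop("no dyad distribution for variant ", lib$uid[i])
    dy <- sample_dyad_positions(p, depth)
    rd <- simulate_cleavage_events(dy, ref, lib[i, ], error_rate = error_rate,
                                   read_length = read_length)
    rd$read_id <- sprintf("v%03d_%s", i, rd$read_id)
    dropped <- dropped + attr(rd, "n_dropped")
    pieces[[i]] <- rd
  }
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  attr(out, "n_dropped") <- dropped
  out
}

#' Recover planted ground truth from read ids
#' @param read_id character vector of simulated read ids.
#' @return data.frame with `variant_uid`, `strand`, `dyad`, `cleavage`.
#' @export
parse_read_truth <- function(read_id) {
  parts <- strsplit(read_id, ";", fixed = TRUE)
  bad <- lengths(parts) != 5L
  if (any(bad)) stop("read id without truth fields: ", read_id[which(bad)[1]])
  m <- do.call(rbind, parts)
  data.frame(variant_uid = m[, 2], strand = m[, 3],
             dyad = as.integer(m[, 4]), cleavage = as.integer(m[, 5]),
             stringsAsFactors = FALSE)
}

#' Write / read FASTQ (Phred+33)
#'
#' Thin wrappers over Biostrings quality-scaled string sets; read ids carry
#' the simulation ground truth and round-trip unchanged.
#'
#' @param reads read data.frame with `read_id`, `sequence`, `qualities`.
#' @param path FASTQ file path.
#' @return `emit_fastq()` returns `path` invisibly; `read_fastq()` returns a
#'   read data.frame with `read_id`, `sequence`, `qualities`.
#' @export
emit_fastq <- function(reads, path) {
  seqs <- Biostrings::DNAStringSet(reads$sequence)
  # the constructor warns about dropping (empty) mcols; nothing is lost
  qs <- suppressWarnings(Biostrings::QualityScaledDNAStringSet(
    seqs, Biostrings::PhredQuality(reads$qualities)))
  names(qs) <- reads$read_id
  Biostrings::writeQualityScaledXStringSet(qs, path)
  invisible(path)
}

#' @rdname emit_fastq
#' @export
read_fastq <- function(path) {
  # the reader warns about dropping (empty) mcols; nothing is lost
  qs <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(path))
  data.frame(read_id = names(qs), sequence = as.character(qs),
             qualities = as.character(Biostrings::quality(qs)),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Simulate a twist-defect coordinate time series
#'
#' Generates a fixture for the defect-energetics estimators: the defect
#' coordinate `d2` is drawn i.i.d. Normal(mean, sd); phosphate progress at
#' SHL2.5 is pinned to 0 and SHL1.5 follows from `d2 = s15 - s25 + 1`.
#'
#' @param mean,sd Normal parameters of `d2` in nt (`sd > 0`).
#' @param n_frames number of frames (>= 100; fewer makes the tail-probability
#'   estimator meaningless).
#' @param seed optional integer seed.
#' @return object of class `defect_series`: list with `s15`, `s25`, `d2`.
#' @export
simulate_defect_series <- function(mean, sd, n_frames, seed = NULL) {
  if (sd <= 0) stop("sd must be > 0")
  if (n_frames < 100L) stop("n_frames must be >= 100")
  if (!is.null(seed)) set.seed(seed)
  d2 <- stats::rnorm(n_frames, mean, sd)
  structure(list(s15 = d2 - 1, s25 = rep(0, n_frames), d2 = d2),
            class = "defect_series")
}
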