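#' Assign cleavage reads to library variants
#'
#' Each read starts at the cleavage (truncation) site and runs 3'; it is
#' matched against every variant strand sequence in the library (plus the
#' unperturbed reference strands) at all offsets, scored by Hamming
#' mismatches. The best candidate is chosen by fewest mismatches, breaking
#' ties in favour of candidates whose perturbed window overlaps the read
#' (the read then certifies its variant). Reads that only match canonical
#' sequence -- e.g. the perturbation lies 5' of the cleavage site -- are
#' indistinguishable between variants by construction; with
#' `collapse_reference = TRUE` (default) they are assigned to the
#' `"reference"` pool with their cleavage position retained (the
#' one-cleavage-one-strand rule), otherwise they are left ambiguous.
#'
#' Cleavage positions are reported as the construct index (top-strand frame)
#' of the first retained base; for insertion variants the position is mapped
#' back through the variant's gap map.
#'
#' @param reads data.frame with `read_id` and `sequence` (e.g. from
#'   [read_fastq()] or [simulate_library_reads()]).
#' @param lib variant data.frame (attribute `"ref"` required).
#' @param max_mismatches maximum Hamming mismatches tolerated (default 2).
#' @param collapse_reference assign variation-less reads to the reference
#'   pool instead of discarding them as ambiguous.
#' @param min_read_length reads shorter than this are not matched.
#' @return data.frame with one row per read: `read_id`, `variant_uid` (`""`
#'   when unassigned), `status` (`assigned`/`ambiguous`/`no_hit`/
#'   `too_short`), `strand`, `cleavage_pos`, `variation_seen`,
#'   `n_mismatches`.
#' @export
match_reads <- function(reads, lib, max_mismatches = 2L,
                        collapse_reference = TRUE, min_read_length = 20L) {
  ref <- attr(lib, "ref")
  if (is.null(ref)) stop("library has no attached ref_construct")
  top_ref <- construct_top(ref)
  bottom_ref <- revcomp(top_ref)
  nv <- nrow(lib)
  subj_seq <- c(lib$top_seq, lib$bottom_seq, top_ref, bottom_ref)
  subj_strand <- c(rep("top", nv), rep("bottom", nv), "top", "bottom")
  subj_uid <- c(lib$uid, lib$uid, "reference", "reference")
  subj_is_ref <- c(rep(FALSE, 2L * nv), TRUE, TRUE)
  subj_var <- c(lapply(seq_len(nv), function(i) as.list(lib[i, ])),
                lapply(seq_len(nv), function(i) as.list(lib[i, ])),
                list(NULL), list(NULL))
  subj_pert <- lapply(seq_along(subj_seq), function(j) {
    if (subj_is_ref[j]) integer(0)
    else perturbed_strand_positions(ref, subj_var[[j]], subj_strand[j])
  })
  subj_set <- Biostrings::DNAStringSet(subj_seq)

  match_one <- function(s) {
    len <- nchar(s)
    if (len < min_read_length)
      return(list(status = "too_short", uid = "", strand = NA_character_,
                  cleavage = NA_integer_, seen = FALSE, mm = NA_integer_))
    pat <- Biostrings::DNAString(s)
    cand <- NULL
    m0 <- Biostrings::vmatchPattern(pat, subj_set, max.mismatch = 0)
    st0 <- Biostrings::startIndex(m0)
    hits <- which(lengths(st0) > 0L)
    if (length(hits) > 0L) {
      cand <- do.call(rbind, lapply(hits, function(j)
        data.frame(j = j, start = st0[[j]], mm = 0L)))
    } else if (max_mismatches > 0L) {
      m1 <- Biostrings::vmatchPattern(pat, subj_set,
                                      max.mismatch = max_mismatches)
      st1 <- Biostrings::startIndex(m1)
      hits <- which(lengths(st1) > 0L)
      if (length(hits) > 0L)
        cand <- do.call(rbind, lapply(hits, function(j) {
          st <- st1[[j]]
          mm <- Biostrings::neditStartingAt(pat, subj_set[[j]],
                                            starting.at = st)
          data.frame(j = j, start = st, mm = mm)
        }))
    }
    if (is.null(cand) || nrow(cand) == 0L)
      return(list(status = "no_hit", uid = "", strand = NA_character_,
                  cleavage = NA_integer_, seen = FALSE, mm = NA_integer_))
    cand <- cand[cand$mm == min(cand$mm), , drop = FALSE]
    v0 <- cand$start - 1L
    seen <- vapply(seq_len(nrow(cand)), function(i) {
      pp <- subj_pert[[cand$j[i]]]
      length(pp) > 0L && any(pp >= v0[i] & pp <= v0[i] + len - 1L)
    }, logical(1))
    cleav <- vapply(seq_len(nrow(cand)), function(i)
      as.integer(strand_to_ref_idx(ref, subj_var[[cand$j[i]]],
                                   subj_strand[cand$j[i]], v0[i])),
      integer(1))
    strand <- subj_strand[cand$j]
    if (any(seen)) {
      w <- which(seen)
      if (length(w) == 1L)
        return(list(status = "assigned", uid = subj_uid[cand$j[w]],
                    strand = strand[w], cleavage = cleav[w], seen = TRUE,
                    mm = cand$mm[w]))
      return(list(status = "ambiguous", uid = "", strand = NA_character_,
                  cleavage = NA_integer_, seen = TRUE, mm = cand$mm[1]))
    }
    # all candidates are canonical-sequence matches
    key <- unique(paste(strand, cleav))
    if (collapse_reference && length(key) == 1L)
      return(list(status = "assigned", uid = "reference",
                  strand = strand[1], cleavage = cleav[1], seen = FALSE,
                  mm = cand$mm[1]))
    list(status = "ambiguous", uid = "", strand = NA_character_,
         cleavage = NA_integer_, seen = FALSE, mm = cand$mm[1])
  }

  useq <- unique(reads$sequence)
  res <- lapply(useq, match_one)
  idx <- match(reads$sequence, useq)
  data.frame(
    read_id = reads$read_id,
    variant_uid = vapply(res, `[[`, "", "uid")[idx],
    status = vapply(res, `[[`, "", "status")[idx],
    strand = vapply(res, `[[`, "", "strand")[idx],
    cleavage_pos = vapply(res, `[[`, integer(1), "cleavage")[idx],
    variation_seen = vapply(res, `[[`, logical(1), "seen")[idx],
    n_mismatches = vapply(res, `[[`, integer(1), "mm")[idx],
    stringsAsFactors = FALSE)
}

#' Filter read assignments and tally QC categories
#'
#' Keeps reads that were assigned, have an identified cleavage site, and --
#' when `require_variation` -- exhibit the variant-certifying sequence
#' variation (reference-collapsed reads are dropped in that mode, mirroring
#' the discard rule "variation or cleavage not identified").
#'
#' @param assignments data.frame from [match_reads()].
#' @param require_variation drop reads whose variation was not seen.
#' @param require_cleavage drop reads without a mapped cleavage position.
#' @return list with `kept` (filtered data.frame) and `qc` (named counts and
#'   `kept_fraction`).
#' @export
filter_assignments <- function(assignments, require_variation = TRUE,
                               require_cleavage = TRUE) {
  a <- assignments
  keep <- a$status == "assigned" &
    (!require_cleavage | !is.na(a$cleavage_pos)) &
    (!require_variation | a$variation_seen)
  qc <- c(
    n_total = nrow(a),
    n_assigned = sum(a$status == "assigned"),
    n_reference_collapsed = sum(a$status == "assigned" &
                                  a$variant_uid == "reference"),
    n_ambiguous = sum(a$status == "ambiguous"),
    n_no_hit = sum(a$status %in% c("no_hit", "too_short")),
    n_kept = sum(keep))
  qc <- c(qc, kept_fraction = if (nrow(a) > 0) unname(qc["n_kept"]) / nrow(a) else 0)
  list(kept = a[keep, , drop = FALSE], qc = qc)
}

#' Accumulate per-variant, per-strand cleavage-site count profiles
#'
#' @param kept filtered assignment data.frame (see [filter_assignments()]).
#' @param ref a [ref_construct()] defining the position grid.
#' @return object of class `cleavage_profiles`: named list (by variant uid)
#'   of lists with integer vectors `top` and `bottom` of length
#'   `ref$total_length` (index 1 = construct position 0).
#' @export
accumulate_profiles <- function(kept, ref) {
  Tn <- ref$total_length
  uids <- unique(kept$variant_uid)
  prof <- lapply(uids, function(u) {
    sub <- kept[kept$variant_uid == u, ]
    list(
      top = tabulate(sub$cleavage_pos[sub$strand == "top"] + 1L, nbins = Tn),
      bottom = tabulate(sub$cleavage_pos[sub$strand == "bottom"] + 1L,
                        nbins = Tn))
  })
  names(prof) <- uids
  structure(prof, class = "cleavage_profiles", total_length = Tn)
}

#' Uniform background subtraction
#'
#' Subtracts the given per-profile quantile of the counts uniformly from the
#' whole profile and clips at zero -- a simple way of boosting signal over a
#' flat noise floor.
#'
#' @param counts nonnegative numeric vector.
#' @param level_quantile quantile in `[0, 1)` defining the floor
#'   (default 0.10).
#' @return numeric vector, same length, floored at 0.
#' @export
background_subtract <- function(counts, level_quantile = 0.10) {
  if (level_quantile < 0 || level_quantile >= 1)
    stop("level_quantile must be in [0, 1)")
  pmax(counts - stats::quantile(counts, level_quantile, names = FALSE), 0)
}

#' Plain-sum dyad signal from strand profiles
#'
#' The raw positioning signal at candidate dyad position `d` is the sum of
#' the top-strand cleavage counts at `d - offset` and the bottom-strand
#' counts at `d + offset` (offset 53 nt); out-of-range contributions are
#' zero. With only one strand populated this reduces to the shifted single
#' profile (single-strand mode).
#'
#' @param top_counts,bottom_counts numeric vectors of length T over
#'   construct positions (index 1 = position 0).
#' @param offset cleavage-to-dyad distance in nt.
#' @return numeric signal vector of length T.
#' @export
dyad_signal <- function(top_counts, bottom_counts, offset = 53L) {
  Tn <- length(top_counts)
  stopifnot(length(bottom_counts) == Tn)
  shift_left <- function(x, k) c(rep(0, k), x)[seq_len(Tn)]          # x[d-k]
  shift_right <- function(x, k) c(x[-seq_len(k)], rep(0, k))         # x[d+k]
  shift_left(top_counts, offset) + shift_right(bottom_counts, offset)
}

#' Combine strand profiles by least-squares regression
#'
#' Shifts both strand profiles onto the dyad frame and finds nonnegative
#' per-strand scale factors `a_top`, `a_bottom` and a common signal `s`
#' minimizing `sum_d (top[d-offset] - a_top s[d])^2 + (bottom[d+offset] -
#' a_bottom s[d])^2`. This is the best rank-1 approximation of the 2 x T
#' shifted-profile matrix (computed by SVD; nonnegativity comes for free on
#' nonnegative data by Perron-Frobenius), normalized so `a_top + a_bottom =
#' 2`; equal strand weights make the result proportional to [dyad_signal()].
#' With one empty strand it degenerates to the shifted single profile.
#'
#' @inheritParams dyad_signal
#' @return list with `signal` (length T), `scales` (named c(top, bottom))
#'   and `singular_value`.
#' @export
combine_strands_regression <- function(top_counts, bottom_counts,
                                       offset = 53L) {
  Tn <- length(top_counts)
  stopifnot(length(bottom_counts) == Tn)
  if (sum(top_counts) == 0 && sum(bottom_counts) == 0)
    stop("both strand profiles are empty")
  shift_left <- function(x, k) c(rep(0, k), x)[seq_len(Tn)]
  shift_right <- function(x, k) c(x[-seq_len(k)], rep(0, k))
  M <- rbind(top = shift_left(top_counts, offset),
             bottom = shift_right(bottom_counts, offset))
  sv <- svd(M, nu = 1, nv = 1)
  u <- sv$u[, 1]; v <- sv$v[, 1]
  if (sum(v) < 0) { u <- -u; v <- -v }
  u <- pmax(u, 0); v <- pmax(v, 0)
  w <- u * sv$d[1]                      # per-strand scales before norming
  cfac <- 2 / sum(w)
  list(signal = v / cfac, scales = c(top = w[1], bottom = w[2]) * cfac,
       singular_value = sv$d[1])
}

#' Convert a raw signal to a dyad probability vector
#' @param signal nonnegative numeric vector.
#' @return probability vector summing to 1.
#' @export
normalize_to_probability <- function(signal) {
  if (any(signal < 0)) stop("signal must be nonnegative")
  s <- sum(signal)
  if (s <= 0) stop("zero-sum signal cannot be normalized")
  signal / s
}

#' Full calling pipeline: reads to per-variant positioning signals
#'
#' Convenience wrapper chaining [match_reads()], [filter_assignments()],
#' [accumulate_profiles()], per-strand [background_subtract()], strand
#' combination and [normalize_to_probability()].
#'
#' @inheritParams match_reads
#' @param require_variation,bg_quantile,combine pipeline knobs; `combine` is
#'   `"regression"` (default) or `"sum"`.
#' @param offset cleavage-to-dyad distance (53 nt).
#' @return list with `signals` (matrix, rows = variant uid, columns =
#'   construct positions 0..T-1), `profiles`, `assignments`, `qc`.
#' @export
call_positioning_signals <- function(reads, lib, max_mismatches = 2L,
                                     collapse_reference = TRUE,
                                     require_variation = TRUE,
                                     bg_quantile = 0.10,
                                     combine = c("regression", "sum"),
                                     offset = 53L) {
  combine <- match.arg(combine)
  asg <- match_reads(reads, lib, max_mismatches = max_mismatches,
                     collapse_reference = collapse_reference)
  flt <- filter_assignments(asg, require_variation = require_variation)
  prof <- accumulate_profiles(flt$kept, attr(lib, "ref"))
  Tn <- attr(prof, "total_length")
  sig <- matrix(0, nrow = length(prof), ncol = Tn,
                dimnames = list(names(prof), NULL))
  drop <- logical(length(prof))
  for (i in seq_along(prof)) {
    topc <- background_subtract(prof[[i]]$top, bg_quantile)
    botc <- background_subtract(prof[[i]]$bottom, bg_quantile)
    raw <- if (combine == "sum") dyad_signal(topc, botc, offset)
    else if (sum(topc) == 0 && sum(botc) == 0) rep(0, Tn)
    else combine_strands_regression(topc, botc, offset)$signal
    if (sum(raw) <= 0) { drop[i] <- TRUE; next }
    sig[i, ] <- normalize_to_probability(raw)
  }
  list(signals = sig[!drop, , drop = FALSE], profiles = prof,
       assignments = asg, qc = flt$qc)
}
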