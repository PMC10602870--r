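#' Reference construct for a nucleosome positioning experiment
#'
#' A construct is a core positioning sequence (e.g. the 145-bp Widom 601)
#' flanked by linker DNA on both sides (the 40N40 design uses 40 bp each).
#' The dyad is placed at the centre of the core; all dyad-relative
#' coordinates are measured from it, with negative values on the TA-poor
#' side by convention.
#'
#' @param core_seq core positioning sequence (character, A/C/G/T, odd length).
#' @param left_flank,right_flank flanking linker sequences (may be `""`).
#' @param name construct name used in variant manifests.
#' @return An object of class `ref_construct` with fields `name`, `core_seq`,
#'   `left_flank`, `right_flank`, `dyad_core_index` (0-based offset of the
#'   dyad within the core) and `total_length`.
#' @examples
#' ref <- ref_construct("TTTTTTTTTTGCGCATGCGCA", strrep("C", 60), strrep("G", 60))
#' ref$total_length
#' @export
ref_construct <- function(core_seq, left_flank = "", right_flank = "",
                          name = "construct") {
  core_seq <- toupper(core_seq)
  left_flank <- toupper(left_flank)
  right_flank <- toupper(right_flank)
  for (s in c(core_seq, left_flank, right_flank)) {
    if (nchar(s) > 0L && grepl("[^ACGT]", s))
      stop("sequence contains characters outside {A,C,G,T}")
  }
  C <- nchar(core_seq)
  if (C < 1L) stop("empty core sequence")
  if (C %% 2L == 0L)
    stop("core length must be odd so the dyad is a single base pair")
  structure(list(
    name = name,
    core_seq = core_seq,
    left_flank = left_flank,
    right_flank = right_flank,
    dyad_core_index = (C - 1L) %/% 2L,
    total_length = nchar(left_flank) + C + nchar(right_flank)
  ), class = "ref_construct")
}

#' @export
print.ref_construct <- function(x, ...) {
  cat(sprintf("ref_construct '%s': core %d bp, flanks %d/%d bp, total %d bp, dyad at construct index %d\n",
              x$name, nchar(x$core_seq), nchar(x$left_flank),
              nchar(x$right_flank), x$total_length, dyad_construct_index(x)))
  invisible(x)
}

#' Full top strand (5' to 3') of a reference construct
#' @param ref a [ref_construct()].
#' @return character scalar of length `ref$total_length`.
#' @export
construct_top <- function(ref) {
  paste0(ref$left_flank, ref$core_seq, ref$right_flank)
}

#' Reverse complement of a DNA string
#' @param x character vector of DNA sequences.
#' @return character vector.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' 0-based construct index of the dyad
#' @param ref a [ref_construct()].
#' @export
dyad_construct_index <- function(ref) {
  nchar(ref$left_flank) + ref$dyad_core_index
}

#' Convert between construct and dyad-relative coordinate frames
#'
#' Construct indices are 0-based over the full construct (flanks included);
#' the dyad-relative frame is signed base pairs from the dyad, negative on
#' the left (TA-poor) side. `shl_of()` converts dyad-relative bp to a
#' continuous super-helix location using the 10.45 bp/turn nucleosomal pitch,
#' so that SHL2 sits roughly 16-24 bp from the dyad.
#'
#' @param ref a [ref_construct()].
#' @param construct_index integer vector of 0-based construct positions.
#' @param dyad_rel integer vector of dyad-relative positions (bp).
#' @return `to_dyad_frame()` and `from_dyad_frame()` return integer vectors;
#'   `shl_of()` returns a numeric vector of continuous SHL values.
#' @export
to_dyad_frame <- function(ref, construct_index) {
  if (any(construct_index < 0L | construct_index >= ref$total_length))
    stop("construct index out of range [0, ", ref$total_length - 1L, "]")
  as.integer(construct_index) - dyad_construct_index(ref)
}

#' @rdname to_dyad_frame
#' @export
from_dyad_frame <- function(ref, dyad_rel) {
  idx <- as.integer(dyad_rel) + dyad_construct_index(ref)
  if (any(idx < 0L | idx >= ref$total_length))
    stop("dyad-relative position maps outside the construct")
  idx
}

#' @rdname to_dyad_frame
#' @export
shl_of <- function(dyad_rel) dyad_rel / 10.45

#' Describe a single DNA perturbation
#'
#' @param kind one of `"polyA"`, `"mismatch"`, `"insertion"`, `"deletion"`,
#'   `"abasic"`. Library builders exist for the first three; deletion and
#'   abasic perturbations are representable for completeness (they were used
#'   in gel assays only) but have no builder.
#' @param strand `"top"`, `"bottom"` or `"duplex"`.
#' @param start_dyad dyad-relative coordinate of the first perturbed base
#'   (for insertions, of the base 5' of the inserted nucleotide on the top
#'   strand frame).
#' @param length perturbation length in bp (1 for insertions).
#' @param payload substituted/inserted base, `"A"` by default.
#' @return object of class `perturbation`.
#' @export
perturbation <- function(kind, strand, start_dyad, length, payload = "A") {
  kind <- match.arg(kind, c("polyA", "mismatch", "insertion", "deletion", "abasic"))
  strand <- match.arg(strand, c("top", "bottom", "duplex"))
  if (length < 1L) stop("perturbation length must be >= 1")
  if (kind == "polyA") {
    if (strand != "duplex") stop("poly(dA:dT) tracts are duplex perturbations")
    if (length < 3L || length > 15L)
      stop("poly(dA:dT) tract length must be within 3..15 bp")
  }
  structure(list(kind = kind, strand = strand,
                 start_dyad = as.integer(start_dyad),
                 length = as.integer(length), payload = payload),
            class = "perturbation")
}

## ---- variant label notation -------------------------------------------------
## polyA:     A_L[a:b]   inclusive dyad-relative range, b - a + 1 = L
## mismatch:  M_n[a:b]   window of n consecutive positions
## insertion: I_1[a^b]   inserted base between adjacent positions a and b

#' Format a perturbation as a variant label
#'
#' Labels follow the `A_L[a:b]`, `M_n[a:b]`, `I_1[a^b]` notation with
#' inclusive dyad-relative coordinates, e.g. an 8-bp tract whose first base
#' sits 36 bp left of the dyad is `A_8[-36:-29]`.
#'
#' @param p a [perturbation()].
#' @return character label.
#' @export
format_variant_label <- function(p) {
  stopifnot(inherits(p, "perturbation"))
  a <- p$start_dyad
  switch(p$kind,
    polyA     = sprintf("A_%d[%d:%d]", p$length, a, a + p$length - 1L),
    mismatch  = sprintf("M_%d[%d:%d]", p$length, a, a + p$length - 1L),
    insertion = sprintf("I_1[%d^%d]", a, a + 1L),
    stop("no label notation for perturbation kind '", p$kind, "'"))
}

#' Parse a variant label into a perturbation
#'
#' @param label character scalar in `A_L[a:b]`, `M_n[a:b]` or `I_1[a^b]` form.
#' @param strand strand to attach for mismatch/insertion labels (the notation
#'   itself does not carry strand); ignored for `A_` labels, which are duplex.
#' @return a [perturbation()].
#' @export
parse_variant_label <- function(label, strand = "top") {
  m <- regmatches(label, regexec(
    "^([AMI])_([0-9]+)\\[(-?[0-9]+)(:|\\^)(-?[0-9]+)\\]$", label))[[1]]
  if (length(m) == 0L)
    stop("malformed variant label: '", label, "'")
  kind_chr <- m[2]; L <- as.integer(m[3]); sep <- m[5]
  a <- as.integer(m[4]); b <- as.integer(m[6])
  if (kind_chr == "I") {
    if (sep != "^" || L != 1L || b != a + 1L)
      stop("malformed insertion label: '", label,
           "' (expected I_1[a^b] with b = a + 1)")
    return(perturbation("insertion", strand, a, 1L))
  }
  if (sep != ":")
    stop("malformed variant label: '", label, "' (expected ':' range separator)")
  if (b - a + 1L != L)
    stop("malformed variant label: '", label, "': range [", a, ":", b,
         "] is inconsistent with declared length ", L)
  if (kind_chr == "A") perturbation("polyA", "duplex", a, L)
  else perturbation("mismatch", strand, a, L)
}

variant_uid <- function(variant_id, strand) {
  ifelse(strand == "duplex", variant_id, paste0(variant_id, "|", strand))
}

variant_row <- function(ref, p, top_seq, bottom_seq) {
  id <- format_variant_label(p)
  data.frame(uid = variant_uid(id, p$strand), variant_id = id, kind = p$kind,
             strand = p$strand, start_dyad = p$start_dyad, length = p$length,
             payload = p$payload, top_seq = top_seq, bottom_seq = bottom_seq,
             construct = ref$name, stringsAsFactors = FALSE)
}

substr_assign <- function(s, pos0, base) {
  # pos0: 0-based positions within s
  for (p in pos0) substr(s, p + 1L, p + 1L) <- base
  s
}

#' Poly(dA:dT) tract library
#'
#' One variant per (start, length) placement where the tract lies fully
#' within the core: every core position is a potential tract start. The
#' tract replaces both strands, A on the top strand and T on the bottom.
#'
#' @param ref a [ref_construct()].
#' @param lengths integer vector of tract lengths, default 3:15.
#' @return A `data.frame` of variant records (one row per variant) with the
#'   construct attached as attribute `"ref"`. Columns: `uid`, `variant_id`,
#'   `kind`, `strand`, `start_dyad`, `length`, `payload`, `top_seq`,
#'   `bottom_seq`, `construct`.
#' @examples
#' ref <- ref_construct("GCGCATGCGCATGCGCATGCG")
#' nrow(build_polyA_library(ref, 3:4))
#' @export
build_polyA_library <- function(ref, lengths = 3:15) {
  lengths <- sort(unique(as.integer(lengths)))
  C <- nchar(ref$core_seq)
  if (length(lengths) == 0L) stop("empty tract length range")
  if (any(lengths < 1L) || any(lengths > C))
    stop("tract lengths must lie within [1, core length]")
  top_ref <- construct_top(ref)
  off <- nchar(ref$left_flank)
  rows <- vector("list", sum(pmax(C - lengths + 1L, 0L)))
  k <- 0L
  for (L in lengths) {
    for (s in 0:(C - L)) {
      p <- perturbation("polyA", "duplex",
                        s - ref$dyad_core_index, L)
      top <- substr_assign(top_ref, off + s + 0:(L - 1L), "A")
      k <- k + 1L
      rows[[k]] <- variant_row(ref, p, top, revcomp(top))
    }
  }
  lib <- do.call(rbind, rows)
  attr(lib, "ref") <- ref
  lib
}

#' Consecutive-mismatch library
#'
#' For each window of `n` consecutive core positions (n in `n_range`) and
#' each strand, every non-A:T base pair in the window is substituted on that
#' strand only: A on the top strand, or T on the bottom strand, leaving the
#' other strand canonical so the duplex carries mismatches. Windows that are
#' entirely A:T yield no variant.
#'
#' @param ref a [ref_construct()].
#' @param n_range window sizes, subset of 1:5.
#' @return variant `data.frame` as in [build_polyA_library()].
#' @export
build_mismatch_library <- function(ref, n_range = 1:5) {
  n_range <- sort(unique(as.integer(n_range)))
  if (length(n_range) == 0L || any(n_range < 1L) || any(n_range > 5L))
    stop("mismatch window sizes must be a nonempty subset of 1..5")
  C <- nchar(ref$core_seq)
  top_ref <- construct_top(ref)
  bottom_ref <- revcomp(top_ref)
  Tn <- ref$total_length
  off <- nchar(ref$left_flank)
  core <- strsplit(ref$core_seq, "")[[1]]
  rows <- list(); k <- 0L
  for (n in n_range) {
    if (n > C) next
    for (s in 0:(C - n)) {
      win <- s + 0:(n - 1L)
      subs <- win[!(core[win + 1L] %in% c("A", "T"))]
      if (length(subs) == 0L) next        # all-A:T window, not a perturbation
      # top-strand variant: non-A:T bases -> A on top, bottom canonical
      p_top <- perturbation("mismatch", "top", s - ref$dyad_core_index, n)
      top_var <- substr_assign(top_ref, off + subs, "A")
      k <- k + 1L; rows[[k]] <- variant_row(ref, p_top, top_var, bottom_ref)
      # bottom-strand variant: -> T on bottom, top canonical
      p_bot <- perturbation("mismatch", "bottom", s - ref$dyad_core_index, n)
      bot_var <- substr_assign(bottom_ref, Tn - 1L - (off + subs), "T")
      k <- k + 1L; rows[[k]] <- variant_row(ref, p_bot, top_ref, bot_var)
    }
  }
  lib <- if (k == 0L) empty_library() else do.call(rbind, rows)
  attr(lib, "ref") <- ref
  lib
}

#' Single-nucleotide insertion library
#'
#' One variant per inter-base gap of the core per strand: an extra A is
#' inserted on either the top or the bottom strand, the other strand staying
#' canonical, so the duplex carries a one-nucleotide bulge.
#'
#' @param ref a [ref_construct()].
#' @return variant `data.frame` as in [build_polyA_library()]; the perturbed
#'   strand's sequence is one nucleotide longer than the construct.
#' @export
build_insertion_library <- function(ref) {
  C <- nchar(ref$core_seq)
  if (C < 2L) stop("core too short to have internal gaps")
  top_ref <- construct_top(ref)
  bottom_ref <- revcomp(top_ref)
  Tn <- ref$total_length
  off <- nchar(ref$left_flank)
  rows <- list(); k <- 0L
  for (s in 0:(C - 2L)) {              # gap between core positions s and s+1
    ca <- off + s                      # construct index of the 5' neighbour
    a_dyad <- s - ref$dyad_core_index
    p_top <- perturbation("insertion", "top", a_dyad, 1L)
    top_var <- paste0(substr(top_ref, 1L, ca + 1L), "A",
                      substr(top_ref, ca + 2L, Tn))
    k <- k + 1L; rows[[k]] <- variant_row(ref, p_top, top_var, bottom_ref)
    p_bot <- perturbation("insertion", "bottom", a_dyad, 1L)
    ib <- Tn - 1L - ca                 # bottom index the inserted base takes
    bot_var <- paste0(substr(bottom_ref, 1L, ib), "A",
                      substr(bottom_ref, ib + 1L, Tn))
    k <- k + 1L; rows[[k]] <- variant_row(ref, p_bot, top_ref, bot_var)
  }
  lib <- do.call(rbind, rows)
  attr(lib, "ref") <- ref
  lib
}

empty_library <- function() {
  data.frame(uid = character(), variant_id = character(), kind = character(),
             strand = character(), start_dyad = integer(), length = integer(),
             payload = character(), top_seq = character(),
             bottom_seq = character(), construct = character(),
             stringsAsFactors = FALSE)
}

#' Combine variant libraries built on the same construct
#' @param ... variant data.frames from the `build_*_library()` functions.
#' @return single variant data.frame with the shared `"ref"` attribute.
#' @export
combine_libraries <- function(...) {
  libs <- list(...)
  refs <- lapply(libs, attr, "ref")
  if (length(unique(vapply(refs, function(r) r$name, ""))) != 1L)
    stop("libraries were built on different constructs")
  out <- do.call(rbind, libs)
  if (anyDuplicated(out$uid)) stop("duplicate variant uids after combination")
  attr(out, "ref") <- refs[[1]]
  out
}

## ---- insertion gap maps -----------------------------------------------------
## For a given variant and strand, convert between reference construct
## coordinates (always in top-strand frame) and 0-based indices into that
## variant's strand string. Only insertion variants shift coordinates.

# 0-based strand-string index holding the base that pairs reference top
# coordinate r. For "bottom", indices are into the bottom 5'->3' string.
ref_to_strand_idx <- function(ref, variant, strand, r) {
  Tn <- ref$total_length
  base <- if (strand == "top") r else Tn - 1L - r
  if (!is.null(variant) && variant$kind == "insertion" && variant$strand == strand) {
    ca <- from_dyad_frame(ref, variant$start_dyad)
    if (strand == "top") base + as.integer(r > ca)
    else base + as.integer(r <= ca)
  } else base
}

# Inverse map; the inserted base itself (which has no reference partner) maps
# to the reference coordinate of the next reference base 3' of it on that
# strand, so cleavage positions stay "first retained reference position".
strand_to_ref_idx <- function(ref, variant, strand, v) {
  Tn <- ref$total_length
  if (!is.null(variant) && variant$kind == "insertion" && variant$strand == strand) {
    ca <- from_dyad_frame(ref, variant$start_dyad)
    if (strand == "top") {
      ins <- ca + 1L
      ifelse(v < ins, v, ifelse(v == ins, ca + 1L, v - 1L))
    } else {
      ins <- Tn - 1L - ca
      ifelse(v < ins, Tn - 1L - v, ifelse(v == ins, ca, Tn - v))
    }
  } else {
    if (strand == "top") v else Tn - 1L - v
  }
}

# 0-based positions in the given strand string that differ from (or are
# inserted relative to) the canonical reference strand. Empty when the strand
# is canonical for this variant.
perturbed_strand_positions <- function(ref, variant, strand) {
  Tn <- ref$total_length
  off <- nchar(ref$left_flank)
  s0 <- variant$start_dyad + ref$dyad_core_index     # core-frame start
  cs <- off + s0                                     # construct index
  if (variant$kind == "polyA") {
    win <- cs + 0:(variant$length - 1L)
    if (strand == "top") return(win) else return(Tn - 1L - rev(win))
  }
  if (variant$kind == "mismatch") {
    if (strand != variant$strand) return(integer(0))
    core <- strsplit(ref$core_seq, "")[[1]]
    win <- s0 + 0:(variant$length - 1L)
    subs <- win[!(core[win + 1L] %in% c("A", "T"))]
    if (strand == "top") return(off + subs) else return(Tn - 1L - (off + subs))
  }
  if (variant$kind == "insertion") {
    if (strand != variant$strand) return(integer(0))
    ca <- cs
    if (strand == "top") return(ca + 1L) else return(Tn - 1L - ca)
  }
  integer(0)
}

## ---- FASTA / manifest I/O ---------------------------------------------------

#' Write a variant library to FASTA and a TSV manifest
#'
#' The FASTA holds one record per variant (id = variant uid) with the top
#' strand sequence; the manifest records the perturbation metadata.
#'
#' @param lib variant data.frame.
#' @param fasta,manifest output paths (either may be `NULL` to skip).
#' @return invisibly, the paths written.
#' @export
write_library <- function(lib, fasta = NULL, manifest = NULL) {
  if (!is.null(fasta)) {
    seqs <- Biostrings::DNAStringSet(lib$top_seq)
    names(seqs) <- lib$uid
    Biostrings::writeXStringSet(seqs, fasta)
  }
  if (!is.null(manifest)) {
    utils::write.table(
      lib[, c("uid", "variant_id", "kind", "strand", "start_dyad",
              "length", "payload", "construct")],
      manifest, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(c(fasta = fasta, manifest = manifest))
}

#' Load a reference sequence from a FASTA asset
#'
#' @param path FASTA file; the first record is used.
#' @return character scalar DNA sequence.
#' @export
read_reference_fasta <- function(path) {
  s <- Biostrings::readDNAStringSet(path)
  if (length(s) == 0L) stop("no sequences in ", path)
  as.character(s[[1]])
}

#' Bundled Widom-601-based reference construct
#'
#' Builds the default 40N40 construct: the central 145 bp of the widely
#' published 147-bp Widom 601 positioning sequence flanked by 40-bp synthetic
#' linkers (the study-specific linkers are not part of this package; the
#' FASTA assets under `inst/extdata` are editable). Total length 225 bp,
#' dyad at construct index 112.
#'
#' @return a [ref_construct()].
#' @export
reference_601_40N40 <- function() {
  core147 <- read_reference_fasta(
    system.file("extdata", "widom601.fa", package = "nucleoslide"))
  core <- substr(core147, 2L, 146L)
  fl <- read_reference_fasta(
    system.file("extdata", "flank40_left_synthetic.fa", package = "nucleoslide"))
  fr <- read_reference_fasta(
    system.file("extdata", "flank40_right_synthetic.fa", package = "nucleoslide"))
  ref_construct(core, fl, fr, name = "601_40N40")
}
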