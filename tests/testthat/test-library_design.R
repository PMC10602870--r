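test_that("poly(dA:dT) library enumerates every in-core placement", {
  ref <- toy_ref(core = paste0(strrep("GC", 10), "G"))  # 21 bp, no A/T
  lib <- build_polyA_library(ref, 3:5)
  # brute-force oracle: sum over L of (C - L + 1) placements
  expect_equal(nrow(lib), sum(21 - (3:5) + 1))
  # whole-core tract: exactly one placement
  ref11 <- toy_ref(core = "GCGCGCGCGCG")
  lib11 <- build_polyA_library(ref11, 11)
  expect_equal(nrow(lib11), 1L)
  core_of <- function(v, r) substr(v, nchar(r$left_flank) + 1L,
                                   nchar(r$left_flank) + nchar(r$core_seq))
  expect_equal(core_of(lib11$top_seq, ref11), strrep("A", 11))
  # tracts replace both strands: A on top, T on bottom
  expect_equal(core_of(lib11$bottom_seq[1],
                       list(left_flank = ref11$right_flank,
                            core_seq = ref11$core_seq)),
               strrep("T", 11))
  expect_error(build_polyA_library(ref, integer(0)), "empty")
})

test_that("the 145-bp core yields 1781 poly(dA:dT) variants with field-notation labels", {
  set.seed(3)
  core <- paste(sample(c("A", "C", "G", "T"), 145, TRUE), collapse = "")
  ref <- ref_construct(core, strrep("C", 40), strrep("G", 40))
  lib <- build_polyA_library(ref, 3:15)
  expect_equal(nrow(lib), 1781L)   # sum_{L=3}^{15} (146 - L)
  v <- lib[lib$start_dyad == -36L & lib$length == 8L, ]
  expect_equal(v$variant_id, "A_8[-36:-29]")
  # maximal A-run on the top strand covers the declared window
  win0 <- from_dyad_frame(ref, v$start_dyad)
  run <- regmatches(v$top_seq, gregexpr("A+", v$top_seq))[[1]]
  starts <- gregexpr("A+", v$top_seq)[[1]]
  k <- which(starts - 1L <= win0 & starts - 1L + nchar(run) - 1L >= win0 + 7L)
  expect_length(k, 1L)
  expect_gte(nchar(run[k]), 8L)
})

test_that("mismatch builder substitutes only non-A:T positions, per strand", {
  ref <- ref_construct("GCA", strrep("T", 55), strrep("T", 55))
  lib <- build_mismatch_library(ref, 1L)
  # windows G, C give variants on each strand; window A gives none
  expect_equal(nrow(lib), 4L)
  top_vars <- lib[lib$strand == "top", ]
  core_of <- function(v) substr(v, 56L, 58L)
  expect_setequal(core_of(top_vars$top_seq), c("ACA", "GAA"))
  # bottom-strand variants leave the top strand canonical
  bot_vars <- lib[lib$strand == "bottom", ]
  expect_true(all(bot_vars$top_seq == construct_top(ref)))
  # all-A:T window yields nothing
  refat <- ref_construct("ATA", strrep("G", 55), strrep("G", 55))
  expect_equal(nrow(build_mismatch_library(refat, 2L)), 0L)
  # field-notation window label
  set.seed(5)
  core <- paste(sample(c("G", "C"), 145, TRUE), collapse = "")
  big <- ref_construct(core, strrep("A", 40), strrep("A", 40))
  mm <- build_mismatch_library(big, 2L)
  expect_true("M_2[-29:-28]" %in% mm$variant_id)
})

test_that("insertion builder makes one variant per core gap per strand", {
  ref <- ref_construct("GCA", strrep("T", 55), strrep("T", 55))
  lib <- build_insertion_library(ref)
  expect_equal(nrow(lib), 4L)  # 2 gaps x 2 strands
  topins <- lib[lib$strand == "top", ]
  expect_true(all(nchar(topins$top_seq) == ref$total_length + 1L))
  expect_true(all(nchar(topins$bottom_seq) == ref$total_length))
  botins <- lib[lib$strand == "bottom", ]
  expect_true(all(botins$top_seq == construct_top(ref)))
  expect_true(all(nchar(botins$bottom_seq) == ref$total_length + 1L))
})

test_that("variant labels parse and format as inverse functions", {
  p <- parse_variant_label("A_8[-36:-29]")
  expect_equal(p$kind, "polyA")
  expect_equal(p$length, 8L)
  expect_equal(p$start_dyad, -36L)
  pi <- parse_variant_label("I_1[13^14]")
  expect_equal(pi$kind, "insertion")
  expect_equal(pi$start_dyad, 13L)
  expect_error(parse_variant_label("A_8[-36:-30]"), "inconsistent")
  expect_error(parse_variant_label("I_1[13^15]"), "I_1")
  expect_error(parse_variant_label("X_8[1:8]"), "malformed")
  # round-trip over a whole mixed library
  ref <- toy_ref()
  lib <- rbind(build_polyA_library(ref, 3:4),
               build_mismatch_library(ref, 1:2),
               build_insertion_library(ref))
  relabel <- vapply(seq_len(nrow(lib)), function(i)
    format_variant_label(parse_variant_label(lib$variant_id[i],
                                             lib$strand[i])), "")
  expect_equal(relabel, lib$variant_id)
})

test_that("perturbed windows map back to label coordinates over the library", {
  ref <- toy_ref()
  lib <- rbind(build_polyA_library(ref, 3:4), build_mismatch_library(ref, 2L))
  for (i in seq_len(nrow(lib))) {
    p <- parse_variant_label(lib$variant_id[i], lib$strand[i])
    strand <- if (p$strand == "duplex") "top" else p$strand
    pos <- perturbed_strand_positions(ref, as.list(lib[i, ]), strand)
    # map strand coordinates back to dyad frame
    back <- sort(to_dyad_frame(ref, vapply(pos, function(v)
      strand_to_ref_idx(ref, as.list(lib[i, ]), strand, v), integer(1))))
    lab_window <- p$start_dyad + 0:(p$length - 1L)
    expect_true(all(back %in% lab_window))
    expect_equal(min(back), min(lab_window[
      !(strsplit(ref$core_seq, "")[[1]][lab_window + ref$dyad_core_index + 1L]
        %in% if (p$kind == "mismatch") c("A", "T") else character(0))]))
  }
})

test_that("coordinate frames convert construct, dyad and SHL consistently", {
  set.seed(3)
  core <- paste(sample(c("A", "C", "G", "T"), 145, TRUE), collapse = "")
  ref <- ref_construct(core, strrep("C", 40), strrep("G", 40))
  expect_equal(ref$total_length, 225L)
  expect_equal(dyad_construct_index(ref), 112L)
  expect_equal(to_dyad_frame(ref, 112L), 0L)
  expect_equal(from_dyad_frame(ref, 53L), 165L)
  expect_equal(shl_of(-21), -2.0, tolerance = 0.025)
  expect_error(to_dyad_frame(ref, 225L), "out of range")
  expect_error(from_dyad_frame(ref, 150L), "outside")
})

test_that("library FASTA/manifest round-trips through Biostrings", {
  ref <- toy_ref()
  lib <- build_insertion_library(ref)
  fa <- tempfile(fileext = ".fa"); tsv <- tempfile(fileext = ".tsv")
  write_library(lib, fasta = fa, manifest = tsv)
  seqs <- Biostrings::readDNAStringSet(fa)
  expect_equal(names(seqs), lib$uid)
  expect_equal(as.character(seqs), lib$top_seq, ignore_attr = TRUE)
  man <- utils::read.delim(tsv)
  expect_equal(man$start_dyad, lib$start_dyad)
})
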