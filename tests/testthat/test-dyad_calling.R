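make_toy_reads <- function(depth = 30L, error_rate = 0, seed = 21L) {
  ref <- toy_ref()
  lib <- toy_library(ref)
  reads <- simulate_library_reads(lib, toy_distributions(ref), depth = depth,
                                  error_rate = error_rate, seed = seed)
  list(ref = ref, lib = lib, reads = reads)
}

test_that("error-free reads are assigned to their variant with exact cleavage", {
  fx <- make_toy_reads(depth = 15L)
  asg <- match_reads(fx$reads, fx$lib)
  truth <- parse_read_truth(fx$reads$read_id)
  # reads whose perturbation is on the sequenced strand certify the variant
  certif <- asg$variation_seen & asg$status == "assigned"
  expect_gt(sum(certif), 0L)
  expect_equal(asg$variant_uid[certif], truth$variant_uid[certif])
  # cleavage recovered exactly for every assigned read (incl. collapsed)
  ok <- asg$status == "assigned"
  expect_true(all(ok))
  expect_equal(asg$cleavage_pos[ok], truth$cleavage[ok])
  expect_equal(asg$strand[ok], truth$strand[ok])
})

test_that("reads with a sequencing error within tolerance are still assigned", {
  fx <- make_toy_reads(depth = 4L)
  rd <- fx$reads[1, ]
  s <- rd$sequence
  # plant one substitution mid-read
  mid <- 60L
  old <- substr(s, mid, mid)
  substr(s, mid, mid) <- setdiff(c("A", "C", "G", "T"), old)[1]
  rd$sequence <- s
  asg <- match_reads(rd, fx$lib, max_mismatches = 2L)
  expect_equal(asg$status, "assigned")
  expect_equal(asg$n_mismatches, 1L)
  expect_equal(asg$cleavage_pos, parse_read_truth(rd$read_id)$cleavage)
  # zero tolerance rejects the same read
  asg0 <- match_reads(rd, fx$lib, max_mismatches = 0L)
  expect_true(asg0$status != "assigned" | asg0$variant_uid == "reference")
})

test_that("variation-less reads collapse to reference or stay ambiguous", {
  fx <- make_toy_reads(depth = 10L)
  # bottom-strand reads of a top-strand mismatch variant carry no variation
  truth <- parse_read_truth(fx$reads$read_id)
  sel <- truth$variant_uid == "M_2[-2:-1]|top" & truth$strand == "bottom"
  rd <- fx$reads[sel, ][1, , drop = FALSE]
  asg <- match_reads(rd, fx$lib, collapse_reference = TRUE)
  expect_equal(asg$status, "assigned")
  expect_equal(asg$variant_uid, "reference")
  expect_false(asg$variation_seen)
  expect_equal(asg$cleavage_pos, parse_read_truth(rd$read_id)$cleavage)
  strict <- match_reads(rd, fx$lib, collapse_reference = FALSE)
  expect_equal(strict$status, "ambiguous")
})

test_that("filtering applies the discard rules and tallies QC", {
  fx <- make_toy_reads(depth = 10L)
  asg <- match_reads(fx$reads, fx$lib)
  flt <- filter_assignments(asg, require_variation = FALSE)
  expect_equal(unname(flt$qc["kept_fraction"]), 1)
  flt2 <- filter_assignments(asg, require_variation = TRUE)
  expect_true(all(flt2$kept$variation_seen))
  expect_lt(flt2$qc[["kept_fraction"]], 1)
  # pure-noise reads are dropped entirely
  set.seed(9)
  noise <- data.frame(
    read_id = sprintf("n%02d;none;top;0;0", 1:5),
    sequence = vapply(1:5, function(i)
      paste(sample(c("A", "C", "G", "T"), 120, TRUE), collapse = ""), ""))
  nasg <- match_reads(noise, fx$lib)
  nflt <- filter_assignments(nasg)
  expect_equal(unname(nflt$qc["kept_fraction"]), 0)
})

test_that("kept fraction is monotone in the mismatch tolerance", {
  fx <- make_toy_reads(depth = 8L, error_rate = 0.01, seed = 33L)
  kept <- vapply(c(0L, 1L, 2L, 4L), function(mm) {
    a <- match_reads(fx$reads, fx$lib, max_mismatches = mm)
    filter_assignments(a, require_variation = FALSE)$qc[["kept_fraction"]]
  }, numeric(1))
  expect_true(all(diff(kept) >= 0))
})

test_that("profiles accumulate counts at cleavage sites and conserve totals", {
  ref <- toy_ref()
  kept <- data.frame(
    read_id = sprintf("r%d", 1:12),
    variant_uid = rep(c("v1", "v2"), each = 6L),
    status = "assigned",
    strand = rep(c("top", "bottom"), 6L),
    cleavage_pos = c(rep(17L, 6L), rep(25L, 6L)),
    variation_seen = TRUE, n_mismatches = 0L)
  prof <- accumulate_profiles(kept, ref)
  expect_equal(prof[["v1"]]$top[17L + 1L], 3L)
  expect_equal(sum(prof[["v1"]]$top) + sum(prof[["v1"]]$bottom), 6L)
  expect_equal(sum(vapply(prof, function(p) sum(p$top) + sum(p$bottom), 0)),
               nrow(kept))
  empty <- accumulate_profiles(kept[0, ], ref)
  expect_length(empty, 0L)
})

test_that("uniform background subtraction preserves spikes and removes floors", {
  expect_equal(background_subtract(rep(4, 10), 0.5), rep(0, 10))
  spike <- c(rep(0, 9), 50)
  expect_equal(background_subtract(spike, 0.5), spike)
  prof <- c(0, 0, 10, 40, 10, 0, 0)
  expect_equal(background_subtract(prof + 3, 0), prof)
  expect_error(background_subtract(prof, 1), "level_quantile")
})

test_that("dyad signal sums strand counts at the +/-53 offsets", {
  Tn <- 225L
  top <- numeric(Tn); bottom <- numeric(Tn)
  top[59L + 1L] <- 7; bottom[165L + 1L] <- 5
  s <- dyad_signal(top, bottom)
  expect_equal(which.max(s) - 1L, 112L)
  expect_equal(s[112L + 1L], 12)
  # single-strand mode: signal is the shifted single profile
  expect_equal(dyad_signal(top, numeric(Tn)),
               c(rep(0, 53L), top)[seq_len(Tn)])
  expect_equal(dyad_signal(numeric(Tn), numeric(Tn)), numeric(Tn))
})

test_that("regression combination recovers scales and matches the plain sum", {
  Tn <- 225L
  # profile supported well inside the grid so both shifted windows see it all
  prof <- stats::dnorm(0:(Tn - 1L), 112, 8)
  top <- c(prof[-seq_len(53L)], rep(0, 53L))        # top[d-53] = prof[d]
  bottom <- c(rep(0, 53L), prof)[seq_len(Tn)]       # bottom[d+53] = prof[d]
  eq <- combine_strands_regression(top, bottom)
  expect_equal(unname(eq$scales), c(1, 1), tolerance = 1e-10)
  expect_equal(eq$signal, prof, tolerance = 1e-10)
  # doubled bottom strand: scale ratio 2, signal direction unchanged
  dbl <- combine_strands_regression(top, 2 * bottom)
  expect_equal(unname(dbl$scales["bottom"] / dbl$scales["top"]), 2,
               tolerance = 1e-8)
  cs <- sum(dbl$signal * prof) / sqrt(sum(dbl$signal^2) * sum(prof^2))
  expect_equal(cs, 1, tolerance = 1e-10)
  # equal scales: proportional to the plain-sum signal
  ds <- dyad_signal(top, bottom)
  expect_equal(eq$signal / sum(eq$signal), ds / sum(ds), tolerance = 1e-10)
  expect_error(combine_strands_regression(numeric(10), numeric(10)), "empty")
})

test_that("probability normalization validates its input", {
  expect_equal(normalize_to_probability(c(1, 3)), c(0.25, 0.75))
  p <- c(0.2, 0.8)
  expect_equal(normalize_to_probability(p), p)
  expect_error(normalize_to_probability(numeric(5)), "zero-sum")
  expect_error(normalize_to_probability(c(-1, 2)), "nonnegative")
})

test_that("noiseless calling reproduces planted distributions exactly", {
  fx <- make_toy_reads(depth = 40L, seed = 55L)
  called <- call_positioning_signals(fx$reads, fx$lib, bg_quantile = 0)
  truth <- parse_read_truth(fx$reads$read_id)
  for (u in fx$lib$uid) {
    sig <- called$signals[u, ]
    emp <- tabulate(truth$dyad[truth$variant_uid == u] + 1L,
                    nbins = fx$ref$total_length)
    expect_equal(which.max(sig) - 1L, which.max(emp) - 1L, label = u)
    expect_equal(sig, emp / sum(emp), tolerance = 1e-9,
                 ignore_attr = TRUE, label = u)
  }
})

test_that("per-strand cleavage offsets regress to -53 and +53 exactly", {
  fx <- make_toy_reads(depth = 25L, seed = 66L)
  asg <- match_reads(fx$reads, fx$lib)
  truth <- parse_read_truth(fx$reads$read_id)
  ok <- asg$status == "assigned"
  for (st in c("top", "bottom")) {
    sel <- ok & asg$strand == st
    fit <- stats::lm(asg$cleavage_pos[sel] ~ truth$dyad[sel])
    expect_equal(unname(stats::coef(fit)[2]), 1, tolerance = 1e-9)
    expect_equal(unname(stats::coef(fit)[1]),
                 if (st == "top") -53 else 53, tolerance = 1e-9)
  }
})
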