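# Shared fixtures: all built in code, none depend on the shipped FASTA assets.

# Small construct with a mixed-content odd-length core and flanks long enough
# that both cleavage sites (dyad +/- 53 nt) stay on the construct.
toy_ref <- function(core = "GGCGATCAGCTGACTGCAGGC", flank = 60L, seed = 7L) {
  set.seed(seed)
  rand_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                                collapse = "")
  ref_construct(core, rand_seq(flank), rand_seq(flank), name = "toy")
}

# Twelve-variant toy library with sequence-distinct members whose
# perturbations sit near the dyad (so both reads certify them when duplex).
toy_library <- function(ref = toy_ref()) {
  library_from_labels(
    ref,
    labels = c("A_4[-6:-3]", "A_4[1:4]", "A_5[-8:-4]", "A_6[-3:2]",
               "M_2[-2:-1]", "M_3[0:2]", "M_2[-2:-1]", "M_1[3:3]",
               "I_1[-1^0]", "I_1[-1^0]", "I_1[2^3]", "I_1[4^5]"),
    strands = c("top", "top", "top", "top",
                "top", "top", "bottom", "top",
                "top", "bottom", "top", "bottom"))
}

# Planted dyad distributions: point-mass mixtures at canonical / ~1-turn
# shifted positions, one per variant of toy_library().
toy_distributions <- function(ref = toy_ref()) {
  mk <- function(peaks, w = rep(1, length(peaks)))
    mixture_dyad_distribution(ref, peaks, w, sd = 0)
  list(
    "A_4[-6:-3]"        = mk(0),
    "A_4[1:4]"          = mk(0),
    "A_5[-8:-4]"        = mk(-11),
    "A_6[-3:2]"         = mk(-11),
    "M_2[-2:-1]|top"    = mk(c(0, -11), c(0.5, 0.5)),
    "M_3[0:2]|top"      = mk(c(0, -11), c(0.5, 0.5)),
    "M_2[-2:-1]|bottom" = mk(0),
    "M_1[3:3]|top"      = mk(0),
    "I_1[-1^0]|top"     = mk(11),
    "I_1[-1^0]|bottom"  = mk(11),
    "I_1[2^3]|top"      = mk(c(0, 11), c(0.7, 0.3)),
    "I_1[4^5]|bottom"   = mk(0))
}

# Signal matrix with `per_group` near-copies of each of three disjoint
# block patterns; returns the matrix and the planted group labels.
planted_signal_matrix <- function(per_group = 6L, width = 60L, seed = 11L) {
  set.seed(seed)
  blocks <- list(1:15, 21:35, 41:55)
  rows <- list(); labels <- integer(0)
  for (g in seq_along(blocks)) {
    for (r in seq_len(per_group)) {
      x <- rep(1e-4, width)
      x[blocks[[g]]] <- 1 + stats::runif(length(blocks[[g]]), 0, 0.05)
      rows[[length(rows) + 1L]] <- x / sum(x)
      labels <- c(labels, g)
    }
  }
  X <- do.call(rbind, rows)
  rownames(X) <- sprintf("v%02d", seq_len(nrow(X)))
  list(X = X, labels = labels)
}

cosine_sim <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))

# Best cosine similarity of each planted pattern to any basis row under
# one-to-one assignment (small ranks: exhaustive permutation).
matched_cosines <- function(basis, patterns) {
  r <- nrow(patterns)
  perms <- gtools_permutations <- NULL
  idx <- seq_len(r)
  allperms <- function(v) {
    if (length(v) == 1L) return(list(v))
    out <- list()
    for (k in seq_along(v))
      for (rest in allperms(v[-k])) out[[length(out) + 1L]] <- c(v[k], rest)
    out
  }
  best <- -Inf; best_cos <- NULL
  for (p in allperms(idx)) {
    cs <- vapply(idx, function(j) cosine_sim(patterns[j, ], basis[p[j], ]),
                 numeric(1))
    if (sum(cs) > best) { best <- sum(cs); best_cos <- cs }
  }
  best_cos
}
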