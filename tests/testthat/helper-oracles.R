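# Independent oracles used by the folding and covariation tests.
# These deliberately use naive enumeration, not the package's DP path.

# All non-crossing pairings of residues `res` (character vector) with
# canonical pairs only and a minimum hairpin loop of 3 nt.
# Returns a list of pairing vectors.
enumerate_structures <- function(res) {
  n <- length(res)
  memo <- new.env(parent = emptyenv())
  rec <- function(i, j) {
    if (j - i < 4L) return(list(integer(0)))
    key <- sprintf("%d_%d", i, j)
    if (!is.null(memo[[key]])) return(memo[[key]])
    out <- lapply(rec(i + 1L, j), function(s) s)           # i unpaired
    for (k in (i + 4L):j) {
      if (!canonical_pair(res[i], res[k])) next
      inner <- rec(i + 1L, k - 1L)
      outer <- rec(k + 1L, j)
      for (a in inner) for (b in outer)
        out[[length(out) + 1L]] <- rbind(c(i, k),
                                         matrix(a, ncol = 2L),
                                         matrix(b, ncol = 2L))
    }
    out <- lapply(out, function(m) matrix(m, ncol = 2L))
    memo[[key]] <- out
    out
  }
  lapply(rec(1L, n), function(m) {
    p <- integer(n)
    if (nrow(m) > 0L) { p[m[, 1L]] <- m[, 2L]; p[m[, 2L]] <- m[, 1L] }
    p
  })
}

# Best achievable score over all enumerated structures, under the same
# energy model the backend uses (score_structure is the shared scorer).
oracle_best_score <- function(residues) {
  res <- strsplit(residues, "")[[1]]
  max(vapply(enumerate_structures(res), function(p)
    score_structure(res, p), 1L))
}

# Brute-force covariation recount: for every model pair and every
# ordered row pair, compare realized canonical pair types directly.
oracle_covarying <- function(aln, pairs) {
  col_of <- reference_columns(aln)
  rows <- lapply(aln$rows, function(r) strsplit(r, "")[[1]])
  n_cov <- 0L
  for (k in seq_len(nrow(pairs))) {
    ci <- col_of[pairs[k, 1L]]; cj <- col_of[pairs[k, 2L]]
    covary <- FALSE
    for (r1 in seq_along(rows)) for (r2 in seq_along(rows)) {
      a1 <- rows[[r1]][ci]; b1 <- rows[[r1]][cj]
      a2 <- rows[[r2]][ci]; b2 <- rows[[r2]][cj]
      if (a1 == "-" || b1 == "-" || a2 == "-" || b2 == "-") next
      if (!canonical_pair(a1, b1) || !canonical_pair(a2, b2)) next
      if (a1 != a2 && b1 != b2) covary <- TRUE
    }
    n_cov <- n_cov + covary
  }
  n_cov
}

# Random alignment over a small planted pair set, used by the
# covariation oracle tests.
random_alignment <- function(n_pos = 12L, n_rows = 8L, pairs = NULL) {
  bases <- c("A", "C", "G", "U")
  ref <- sample(bases, n_pos, replace = TRUE)
  if (is.null(pairs))
    pairs <- cbind(1:3, n_pos - (0:2))
  for (k in seq_len(nrow(pairs)))
    ref[pairs[k, 2L]] <- c(A = "U", C = "G", G = "C", U = "A")[ref[pairs[k, 1L]]]
  rows <- c(list(reference = paste(ref, collapse = "")),
            lapply(seq_len(n_rows - 1L), function(h) {
              row <- ref
              for (i in seq_len(n_pos)) {
                if (runif(1) < 0.3) row[i] <- sample(bases, 1L)
                if (runif(1) < 0.1) row[i] <- "-"
              }
              paste(row, collapse = "")
            }))
  names(rows)[-1L] <- sprintf("h%02d", seq_len(n_rows - 1L))
  list(aln = homolog_alignment(unlist(rows)), pairs = pairs)
}

# small deterministic bundle cache so expensive generation is shared
# across test files within a run
.bundle_cache <- new.env(parent = emptyenv())
cached_bundle <- function(seed, noise_free = FALSE, ...) {
  key <- paste0(seed, "_", noise_free, "_",
                paste(c(...), collapse = "_"))
  if (is.null(.bundle_cache[[key]]))
    .bundle_cache[[key]] <- generate(
      sim_config(noise_free = noise_free, ...), seed = seed)
  .bundle_cache[[key]]
}
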