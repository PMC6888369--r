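# Stockholm IO, helix presence/conservation, covariation counting.

test_that("stockholm round-trip preserves rows and SS_cons", {
  b <- cached_bundle(1L)
  f <- tempfile(fileext = ".sto")
  write_stockholm(b$alignment, f)
  a2 <- read_stockholm(f)
  expect_equal(a2$rows, b$alignment$rows)
  expect_equal(a2$ss_cons, b$alignment$ss_cons)
  expect_error(read_stockholm(textConnectionPath <- f2 <- {
    f3 <- tempfile(); writeLines("no header", f3); f3
  }), "STOCKHOLM")
})

test_that("helix_presence accepts identical and compensatory homologs", {
  ref <- c("G","G","G","G","G", rep("A", 7), "C","C","C","C","C", "A","A","A")
  pairs <- cbind(1:5, 17:13)  # G-C stack around a 7-nt loop
  comp <- ref; comp[2] <- "A"; comp[16] <- "U"  # G-C -> A-U, both sides
  gone <- ref; gone[c(1:5, 13:17)] <- "-"
  rows <- c(reference = paste(ref, collapse = ""),
            same = paste(ref, collapse = ""),
            comp = paste(comp, collapse = ""),
            gone = paste(gone, collapse = ""))
  aln <- homolog_alignment(rows)
  h <- helix(pairs)
  expect_true(helix_presence(h, aln, "same"))
  expect_true(helix_presence(h, aln, "comp"))
  expect_false(helix_presence(h, aln, "gone"))
})

test_that("helix_conserved applies presence and identity thresholds", {
  set.seed(5)
  n_rows <- 53L
  ref <- "GGGGGAAAACCCCC"
  pairs <- cbind(1:5, 14:10)
  make_aln <- function(n_present) {
    rows <- c(reference = ref)
    for (k in seq_len(n_rows - 1L)) {
      rows[sprintf("h%02d", k)] <- if (k <= n_present) ref else
        "-----AAAA-----"
    }
    homolog_alignment(rows)
  }
  h <- helix(pairs)
  thr <- conservation_thresholds(min_presence = 43L, group_size = 53L)
  # 52 + reference present, identity 1
  expect_true(helix_conserved(h, make_aln(52L), thr))
  # present in 42 of 53 at threshold 43 -> not conserved (boundary)
  expect_false(helix_conserved(h, make_aln(41L), thr))
  expect_true(helix_conserved(h, make_aln(42L), thr))  # 42 + ref = 43
})

test_that("identity below 75% blocks conservation despite presence", {
  # helix pairs all realized canonically but with different nucleotides
  ref <- "GGGGGAAAACCCCC"
  alt <- "UUUUUAAAAAAAAA"  # U-A pairs, 0 identity on helix columns
  rows <- c(reference = ref)
  for (k in 1:52) rows[sprintf("h%02d", k)] <- alt
  aln <- homolog_alignment(rows)
  h <- helix(cbind(1:5, 14:10))
  cons <- helix_conserved(h, aln)
  expect_false(cons)
  cts <- attr(cons, "counts")
  expect_equal(unname(cts["presence"]), 53)  # present everywhere
  expect_lt(cts["identity"], 0.75)
})

test_that("presence_fraction matches the printed percentages", {
  expect_equal(presence_fraction(43, 53), 81L)
  expect_equal(presence_fraction(42, 51), 82L)
  expect_equal(presence_fraction(12, 17), 71L)
  expect_equal(presence_fraction(0, 17), 0L)
  expect_error(presence_fraction(1, 0), "empty group")
})

test_that("conservation is monotone in added presence rows", {
  ref <- "GGGGGAAAACCCCC"
  h <- helix(cbind(1:5, 14:10))
  rows <- c(reference = ref)
  for (k in 1:42) rows[sprintf("h%02d", k)] <- ref
  thr <- conservation_thresholds(min_presence = 43L, group_size = 53L)
  base <- helix_conserved(h, homolog_alignment(rows), thr)
  expect_true(base)  # 42 + reference = 43
  rows["extra"] <- ref
  expect_true(helix_conserved(h, homolog_alignment(rows), thr))
})

test_that("count_covarying_pairs follows the two-type definition", {
  ref <- "GAAAAC"  # pair (1,6) G-C
  rows <- c(reference = ref, a = "GAAAAC", b = "GAAAAC")
  aln <- homolog_alignment(rows)
  pairs <- cbind(1L, 6L)
  expect_equal(count_covarying_pairs(aln, pairs)$covarying, 0L)
  # half the rows realize A-U: covariation
  rows <- c(reference = ref, a = "AAAAAU", b = "AAAAAU")
  expect_equal(count_covarying_pairs(homolog_alignment(rows),
                                     pairs)$covarying, 1L)
  # G-C -> G-U: one side changes, counted as co-mutation not covariation
  rows <- c(reference = ref, a = "GAAAAU", b = "GAAAAC")
  cc <- count_covarying_pairs(homolog_alignment(rows), pairs)
  expect_equal(cc$covarying, 0L)
  expect_equal(cc$co_mutated, 1L)
})

test_that("covariation counts equal the brute-force oracle", {
  set.seed(99)
  for (rep in 1:50) {
    ra <- random_alignment(n_pos = 12L, n_rows = 8L)
    got <- count_covarying_pairs(ra$aln, ra$pairs)$covarying
    want <- oracle_covarying(ra$aln, ra$pairs)
    expect_equal(got, want, info = sprintf("replicate %d", rep))
    expect_lte(got, nrow(ra$pairs))
  }
})

test_that("planted conservation labels are recovered exactly", {
  b <- cached_bundle(3L)
  th <- b$truth$helices
  called <- vapply(seq_len(nrow(th)), function(r) {
    h <- helix(cbind(th$five_start[r]:th$five_end[r],
                     th$three_end[r]:th$three_start[r]))
    isTRUE(helix_conserved(h, b$alignment))
  }, logical(1))
  expect_equal(called, b$conserved_labels)
})

test_that("conservation_report summarizes per helix", {
  b <- cached_bundle(3L)
  df <- conservation_report(b$truth$model, b$alignment)
  expect_equal(nrow(df), length(b$truth$model$helices))
  expect_true(all(df$presence <= length(b$alignment$rows)))
  expect_true(all(df$covarying_pairs <= df$n_pairs))
  expect_equal(sum(df$conserved), sum(b$conserved_labels))
})
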