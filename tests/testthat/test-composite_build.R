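# Duplex acceptance, clustering, registry, per-nucleotide resolution,
# pseudoknot calling, and full assembly.

test_that("accept_duplex pins the strict-inequality boundaries", {
  expect_true(accept_duplex(c(8, 0, 0)))   # criterion (ii): 8 > 5
  expect_true(accept_duplex(c(4, 4, 0)))   # criterion (i): two datasets > 3
  expect_false(accept_duplex(c(3, 3, 3)))  # 3 is not > 3
  expect_false(accept_duplex(c(5, 0, 0)))  # 5 is not > 5
  expect_false(accept_duplex(integer(0)))  # empty -> rejected, not error
  expect_true(accept_duplex(c(6, 1, 1)))
  expect_false(accept_duplex(c(4, 3, 0)))  # only one dataset > 3
})

make_duplexes <- function(rows) {
  df <- do.call(rbind, lapply(rows, function(r)
    data.frame(dataset_id = r[[1]], left_start = r[[2]], left_end = r[[3]],
               right_start = r[[4]], right_end = r[[5]], reads = r[[6]])))
  validate_duplexes(df)
}

test_that("cluster_duplexes merges within slack and splits beyond", {
  d <- make_duplexes(list(list("A", 100, 120, 300, 320, 6),
                          list("B", 100, 120, 300, 320, 4)))
  cl <- cluster_duplexes(d)
  expect_equal(nrow(cl), 1L)
  expect_equal(sort(names(cl$reads[[1]])), c("A", "B"))
  expect_equal(unname(unlist(cl$reads[[1]])[c("A", "B")]), c(6, 4))

  d <- make_duplexes(list(list("A", 100, 120, 300, 320, 6),
                          list("B", 130, 150, 300, 320, 4)))
  expect_equal(nrow(cluster_duplexes(d)), 2L)
})

test_that("jittered duplexes cluster back to the planted count", {
  set.seed(7)
  b <- cached_bundle(7L)
  true_n <- sum(b$truth$helices$type %in% c("long_range", "pseudoknot"))
  d <- b$duplexes
  jit <- sample(-2:2, nrow(d), replace = TRUE)
  d$left_start <- d$left_start + jit
  d$left_end <- d$left_end + jit
  d$right_start <- d$right_start + jit
  d$right_end <- d$right_end + jit
  cl <- cluster_duplexes(validate_duplexes(d))
  # background singletons may add clusters; true duplexes must not split
  members <- cl$n_members
  expect_equal(sum(members >= 2L), true_n)
})

test_that("duplex_to_pairs registers the antiparallel registry", {
  s <- transcript_seq("t", "GGGGGGAAAAAAAAAACCCCCC")
  pp <- duplex_to_pairs(s, interval(1, 6), interval(17, 22))
  expect_equal(nrow(pp), 6L)
  expect_equal(unname(pp[, "i"] + pp[, "j"]), rep(23L, 6))  # antiparallel
  expect_true(all(pp[, "j"] %in% 17:22))

  s2 <- transcript_seq("t", "AAAAAAGGGGGGGGGGAAAAAA")
  expect_warning(pp2 <- duplex_to_pairs(s2, interval(1, 6), interval(17, 22)),
                 "no canonical complementarity")
  expect_equal(nrow(pp2), 0L)
})

test_that("planted long-range duplexes register >= 15 pairs", {
  b <- cached_bundle(1L, noise_free = TRUE)
  th <- b$truth$helices
  lr <- th[th$type == "long_range", ][1, ]
  pp <- duplex_to_pairs(b$seq, interval(lr$five_start, lr$five_end),
                        interval(lr$three_start, lr$three_end))
  expect_gte(nrow(pp), 15L)
})

test_that("resolve_nucleotide follows the evidence precedence", {
  r <- resolve_nucleotide("single", "unprotected", FALSE, TRUE)
  expect_equal(r, list(state = "unpaired", provenance = "pars+dms"))
  r <- resolve_nucleotide("double", "protected", FALSE, FALSE)
  expect_equal(r, list(state = "paired", provenance = "pars+dms"))
  # PARIS overrides a single-stranded PARS call (the long-range helix
  # detected by crosslinking despite in-vitro refolding)
  r <- resolve_nucleotide("single", "protected", TRUE, FALSE)
  expect_equal(r, list(state = "paired", provenance = "paris"))
  # discordant channels fall to the MFE tiebreak
  r <- resolve_nucleotide("single", "protected", FALSE, TRUE)
  expect_equal(r, list(state = "paired", provenance = "mfe_resolved"))
  r <- resolve_nucleotide("double", "unprotected", FALSE, FALSE)
  expect_equal(r, list(state = "unpaired", provenance = "mfe_resolved"))
  # lone paired-type call without an assignable partner is designated
  # unstructured in the final model
  r <- resolve_nucleotide("double", "no_data", FALSE, FALSE)
  expect_equal(r, list(state = "unpaired",
                       provenance = "default_unstructured"))
  r <- resolve_nucleotide("double", "no_data", FALSE, TRUE)
  expect_equal(r, list(state = "paired", provenance = "pars+dms"))
  # no evidence at all
  r <- resolve_nucleotide("no_data", "no_data", FALSE, FALSE, TRUE)
  expect_equal(r, list(state = "unpaired",
                       provenance = "default_unstructured"))
  r <- resolve_nucleotide("no_data", "no_data", FALSE, FALSE, FALSE)
  expect_equal(r$state, "no_data")
})

test_that("call_pseudoknots layers crossing helices deterministically", {
  s <- transcript_seq("t", paste(rep("A", 100), collapse = ""))
  # H-type geometry: B crosses A's closing span; equal sizes -> the more
  # 5' helix (A) stays nested
  hs <- list(helix(cbind(10:12, 70:68)), helix(cbind(40:42, 90:88), pk_layer = 1L))
  m <- call_pseudoknots(structure_model(s, hs))
  layers <- vapply(m$helices, function(h) h$pk_layer, 1L)
  starts <- vapply(m$helices, function(h) min(h$pairs), 1L)
  expect_equal(layers[order(starts)], c(0L, 1L))
  expect_equal(vapply(m$helices, function(h) h$name, "")[order(starts)],
               c("H1", "PK1"))

  # fully nested model: zero pseudoknots
  hs <- list(helix(cbind(10:12, 90:88)), helix(cbind(30:32, 60:58)))
  m <- call_pseudoknots(structure_model(s, hs))
  expect_true(all(vapply(m$helices, function(h) h$pk_layer, 1L) == 0L))

  # the larger helix stays nested even when 3'-ward
  hs <- list(helix(cbind(10:11, 70:69), pk_layer = 1L),
             helix(cbind(40:45, 95:90)))
  m <- call_pseudoknots(structure_model(s, hs))
  layers <- vapply(m$helices, function(h) h$pk_layer, 1L)
  sizes <- vapply(m$helices, function(h) nrow(h$pairs), 1L)
  expect_equal(layers[which.max(sizes)], 0L)
  expect_equal(layers[which.min(sizes)], 1L)
})

test_that("planted crossings are recovered as pseudoknot layers", {
  b <- cached_bundle(2L, noise_free = TRUE, n_pk = 3L)
  m <- b$truth$model
  n_pk_layers <- sum(vapply(m$helices, function(h) h$pk_layer > 0L,
                            logical(1)))
  expect_equal(n_pk_layers, 3L)
  asm <- assemble(b$track, b$duplexes, b$seq)
  expect_equal(sum(vapply(asm$helices, function(h) h$pk_layer > 0L,
                          logical(1))), 3L)
})

test_that("loop_distance counts intervening nucleotides", {
  expect_equal(loop_distance(interval(5037, 5063), interval(6612, 6641)),
               1548L)
  expect_equal(loop_distance(interval(10, 20), interval(21, 30)), 0L)
  expect_error(loop_distance(interval(10, 25), interval(21, 30)),
               "strictly before")
  h <- helix(cbind(10:12, 40:38))
  expect_equal(loop_distance(h), 38L - 12L - 1L)  # inner strand gap
})

test_that("planted long-range separations match the generator bookkeeping", {
  b <- cached_bundle(4L, noise_free = TRUE)
  th <- b$truth$helices
  lr <- th[th$type == "long_range", ]
  for (r in seq_len(nrow(lr))) {
    expect_equal(loop_distance(interval(lr$five_start[r], lr$five_end[r]),
                               interval(lr$three_start[r], lr$three_end[r])),
                 lr$three_start[r] - lr$five_end[r] - 1L)
    expect_gte(lr$three_start[r] - lr$five_end[r] - 1L, 100L)
  }
})

test_that("assemble recovers the noise-free planted structure exactly", {
  b <- cached_bundle(1L, noise_free = TRUE)
  m <- assemble(b$track, b$duplexes, b$seq)
  tc <- truth_compare(m, b$truth)
  expect_equal(tc$sensitivity, 1.0)
  expect_equal(tc$ppv, 1.0)
  expect_equal(tc$accuracy, 1.0)
})

test_that("assemble with PARIS only yields exactly the accepted duplexes", {
  b <- cached_bundle(1L, noise_free = TRUE)
  empty_track <- validate_track(data.frame(
    position = integer(0), base = character(0), s1 = numeric(0),
    v1 = numeric(0), dms = numeric(0)))
  m <- assemble(empty_track, b$duplexes, b$seq)
  pp <- attr(m, "paris_pairs")
  expect_gt(nrow(pp), 0L)
  expect_equal(sum(m$pairing > 0L), 2L * nrow(pp))
  expect_true(all(m$pairing[pp[, 1]] == pp[, 2]))
})

test_that("assemble is deterministic and PARIS-monotone", {
  b <- cached_bundle(7L)
  m1 <- assemble(b$track, b$duplexes, b$seq)
  m2 <- assemble(b$track, b$duplexes, b$seq)
  expect_equal(m1$pairing, m2$pairing)
  expect_equal(write_dotbracket(m1), write_dotbracket(m2))
  # removing all PARIS input can only remove paris-provenance pairing
  m0 <- assemble(b$track, NULL, b$seq)
  paris_pos <- which(m1$provenance == "paris")
  expect_gt(length(paris_pos), 0L)
  expect_equal(sum(m0$provenance == "paris"), 0L)
})

test_that("default-noise assembly stays above 0.90 base-level accuracy", {
  b <- cached_bundle(7L)
  m <- assemble(b$track, b$duplexes, b$seq)
  tc <- truth_compare(m, b$truth)
  expect_gte(tc$accuracy, 0.90)
})

test_that("assemble validates coordinate ranges", {
  b <- cached_bundle(1L, noise_free = TRUE)
  bad <- b$track
  bad$position[nrow(bad)] <- 5000L
  expect_error(assemble(validate_track(bad), b$duplexes, b$seq),
               "outside transcript")
  expect_error(assemble(b$track, b$duplexes, b$seq,
                        uncovered_regions = list(interval(900, 1200))),
               "outside transcript")
})
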