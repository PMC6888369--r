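# Domain types, dot-bracket parsing/writing, and element naming.

test_that("transcript_seq and interval enforce their invariants", {
  s <- transcript_seq("t", "acgtu")
  expect_equal(s$residues, "ACGUU")  # T converted, uppercased
  expect_error(transcript_seq("t", ""), "at least one")
  expect_error(transcript_seq("t", "ACGX"), "invalid residues")
  expect_equal(length(interval(3, 7)), 5L)
  expect_error(interval(5, 4), "start <= end")
  expect_error(interval(0, 4), "start <= end")
})

test_that("parse_dotbracket reconstructs forced examples", {
  m <- parse_dotbracket("((..))", transcript_seq("t", "GGAACC"))
  expect_length(m$helices, 1L)
  expect_equal(m$helices[[1]]$pairs,
               matrix(c(1L, 2L, 6L, 5L), ncol = 2,
                      dimnames = list(NULL, c("i", "j"))))
  expect_equal(m$helices[[1]]$pk_layer, 0L)

  m2 <- parse_dotbracket("((..[[..))..]]",
                         transcript_seq("t", "GGGGAAAACCCCAA"))
  expect_length(m2$helices, 2L)
  layers <- vapply(m2$helices, function(h) h$pk_layer, 1L)
  expect_equal(sort(layers), c(0L, 1L))
  # the layer-1 helix crosses the layer-0 helix (H-type pseudoknot)
  expect_equal(m2$pairing[5], 14L)
  expect_equal(m2$pairing[1], 10L)
})

test_that("parse_dotbracket reports offending columns and length mismatch", {
  s <- transcript_seq("t", "GGAACC")
  expect_error(parse_dotbracket("((..)", transcript_seq("t", "GGAAC")),
               "column 1")
  expect_error(parse_dotbracket(")(....", s), "column 1")
  expect_error(parse_dotbracket("((..))", transcript_seq("t", "GGAACCA")),
               "length")
})

test_that("write_dotbracket handles empty and pseudoknotted models", {
  s <- transcript_seq("t", "AAAAA")
  expect_equal(write_dotbracket(structure_model(s)), ".....")
  txt <- "((..[[..))..]]"
  m <- parse_dotbracket(txt, transcript_seq("t", "GGGGAAAACCCCAA"))
  expect_equal(write_dotbracket(m), txt)
})

test_that("parse/write round-trips on generated structures", {
  for (seed in c(1L, 5L)) {
    b <- cached_bundle(seed, noise_free = TRUE)
    m <- b$truth$model
    txt <- write_dotbracket(m)
    m2 <- parse_dotbracket(txt, m$seq)
    expect_equal(m2$pairing, m$pairing)
    expect_equal(write_dotbracket(m2), txt)
  }
  # a 500-nt fragment round-trips byte-identically
  b <- cached_bundle(11L, noise_free = TRUE, transcript_len = 500L)
  txt <- write_dotbracket(b$truth$model)
  expect_equal(nchar(txt), 500L)
  expect_equal(write_dotbracket(parse_dotbracket(txt, b$seq)), txt)
})

test_that("deep pseudoknot stacks use one tier per crossing class", {
  # 13 mutually crossing helices: tier count must stay within the
  # bracket alphabet (<= 14 tiers incl. the nested one)
  n <- 600L
  hs <- lapply(1:13, function(k)
    helix(cbind(10L * k + 0:1, 300L + 10L * k + 1:0), pk_layer = k))
  hs[[1]]$pk_layer <- 0L
  s <- transcript_seq("t", paste(rep("A", n), collapse = ""))
  m <- structure_model(s, hs)
  txt <- write_dotbracket(m)
  tiers <- unique(strsplit(gsub("\\.", "", txt), "")[[1]])
  expect_lte(length(tiers), 2L * 14L)
  m2 <- parse_dotbracket(txt, s)
  expect_equal(m2$pairing, m$pairing)
})

test_that("name_elements names 5' to 3' and splits H from PK", {
  s <- transcript_seq("t", paste(rep("A", 100), collapse = ""))
  hs <- list(helix(cbind(10:12, 30:28)), helix(cbind(50:52, 70:68)))
  m <- name_elements(structure_model(s, hs))
  expect_equal(vapply(m$helices, function(h) h$name, ""), c("H1", "H2"))

  # crossing helix that is 5'-most still gets PK1
  hs <- list(helix(cbind(5:6, 40:39), pk_layer = 1L),
             helix(cbind(20:22, 60:58)),
             helix(cbind(70:71, 90:89)))
  m <- name_elements(structure_model(s, hs))
  nm <- vapply(m$helices, function(h) h$name, "")
  expect_equal(nm, c("PK1", "H1", "H2"))
})

test_that("element names form a gap-free 5'-sorted series", {
  b <- cached_bundle(2L, noise_free = TRUE, n_pk = 2L)
  m <- b$truth$model
  nm <- vapply(m$helices, function(h) h$name, "")
  hn <- nm[grepl("^H", nm)]
  pk <- nm[grepl("^PK", nm)]
  expect_equal(hn, sprintf("H%d", seq_along(hn)))
  expect_equal(pk, sprintf("PK%d", seq_along(pk)))
  expect_false(anyDuplicated(nm) > 0)
  # 5'-sorted within each class
  starts <- vapply(m$helices, function(h) min(h$pairs), 1L)
  expect_true(all(diff(starts[grepl("^H", nm)]) > 0))
})

test_that("junctions are labelled by degree", {
  s <- transcript_seq("t", paste(rep("A", 100), collapse = ""))
  hs <- list(helix(cbind(1:3, 99:97)),   # parent
             helix(cbind(10:12, 30:28)), # child 1
             helix(cbind(40:42, 60:58))) # child 2
  m <- name_elements(structure_model(s, hs))
  expect_length(m$junctions, 1L)
  expect_match(m$junctions[[1]]$name, "^3WJ")
  expect_setequal(m$junctions[[1]]$members, c("H1", "H2", "H3"))
})

test_that("structure_model rejects broken pairings", {
  s <- transcript_seq("t", paste(rep("A", 50), collapse = ""))
  expect_error(structure_model(s, list(helix(cbind(1:2, 20:19)),
                                       helix(cbind(2:3, 40:39)))),
               "more than one pair")
  expect_error(structure_model(s, list(helix(cbind(1, 20)),
                                       helix(cbind(10, 30)))),
               "non-crossing")
})

test_that("CT and BED export write the documented formats", {
  m <- name_elements(parse_dotbracket("((..))", transcript_seq("t", "GGAACC")))
  ct <- tempfile(fileext = ".ct"); bed <- tempfile(fileext = ".bed")
  write_ct(m, ct)
  lines <- readLines(ct)
  expect_length(lines, 7L)
  expect_match(lines[2], "^1 G 0 2 6 1$")
  write_helix_bed(m, bed)
  bl <- readLines(bed)
  expect_equal(bl[1], "t\t0\t2\tH1_5p\t0\t+")  # 0-based half-open
  expect_equal(bl[2], "t\t4\t6\tH1_3p\t0\t+")
})
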