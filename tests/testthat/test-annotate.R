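# Annotation overlay, modification matrix, differential duplexes,
# mutation impact, and site accessibility.

test_that("structural_context classifies stem and loop sites", {
  m <- name_elements(parse_dotbracket("..((((....))))..",
                                      transcript_seq("t", "AAGGGGAAAACCCCAA")))
  stem <- structural_context(m, annotation("protein_site", interval(3, 6)))
  expect_equal(stem$fraction_paired, 1.0)
  expect_equal(stem$class, "structured")
  expect_equal(stem$elements, "H1")

  loop <- structural_context(m, annotation("mirna_site", interval(7, 10)))
  expect_equal(loop$fraction_paired, 0)
  expect_equal(loop$class, "unstructured")
  expect_equal(loop$enclosing, "H1")

  expect_error(structural_context(m, annotation("mirna_site",
                                                interval(10, 99))),
               "outside")
})

test_that("a planted loop site reports its enclosing hairpin", {
  b <- cached_bundle(1L, noise_free = TRUE)
  m <- b$truth$model
  site <- b$annotations[[1]]  # miRNA site in the last hairpin's loop
  ctx <- structural_context(m, site)
  expect_equal(ctx$class, "unstructured")
  expect_match(ctx$enclosing, "^H[0-9]+$")
})

test_that("matrix_summary reproduces the m6A cell-line table", {
  f <- system.file("extdata", "m6a_marks_celllines.tsv",
                   package = "rnacomposer")
  m <- read_modification_matrix(f)
  s <- matrix_summary(m)
  expect_equal(unname(s$per_column["HEK293T"]), 12)
  expect_equal(rownames(m)[s$per_row == max(s$per_row)], "2611")
  present <- colnames(m)[m["5044", ]]
  expect_setequal(present, c("CD8T", "HEK293T", "Neuro", "A549"))
  absent <- colnames(m)[!m["5044", ]]
  expect_setequal(absent, c("AML", "H1299", "HepG2", "HeLa", "PA-HeLa",
                            "GM", "hESC"))
  # differential rows: present in normal-like, absent in all cancer lines
  d <- matrix_summary(m, group_a = c("CD8T", "GM", "HEK293T", "hESC",
                                     "Neuro"),
                      group_b = c("AML", "H1299", "HepG2"))
  expect_true("5044" %in% d$differential)
  expect_false("2515" %in% d$differential)
})

test_that("matrix_summary of an empty matrix is all zeros", {
  m <- matrix(logical(0), nrow = 0, ncol = 2,
              dimnames = list(NULL, c("A", "B")))
  s <- matrix_summary(m)
  expect_equal(unname(s$per_column), c(0, 0))
  expect_length(s$per_row, 0L)
})

make_duplex_df <- function(...) {
  rows <- list(...)
  validate_duplexes(do.call(rbind, lapply(rows, function(r)
    data.frame(dataset_id = r[[1]], left_start = r[[2]], left_end = r[[3]],
               right_start = r[[4]], right_end = r[[5]], reads = r[[6]]))))
}

test_that("differential_duplexes flags modification-linked switches", {
  # condition A: pseudoknot-like duplex with 8 reads in one dataset
  a <- make_duplex_df(list("HEK_1", 5037, 5063, 6612, 6641, 8),
                      list("HEK_2", 100, 120, 400, 420, 6),
                      list("HEK_3", 100, 120, 400, 420, 5))
  # condition B: only the local duplex remains
  b <- make_duplex_df(list("HeLa_1", 100, 120, 400, 420, 7))
  out <- differential_duplexes(a, b, modifications = 5044L)
  expect_equal(nrow(out), 1L)
  expect_equal(out$left_start, 5037L)
  expect_true(out$switch_candidate)
  expect_equal(out$modification_positions, "5044")

  # identical conditions: empty report
  expect_equal(nrow(differential_duplexes(a, a)), 0L)

  # lost duplex without modification overlap: reported, unflagged
  out2 <- differential_duplexes(a, b, modifications = 9999L)
  expect_equal(nrow(out2), 1L)
  expect_false(out2$switch_candidate)
})

test_that("parse_mutation handles both printed notations", {
  expect_equal(parse_mutation("U4056C"),
               list(type = "sub", pos = 4056L, ref = "U", alt = "C"))
  d <- parse_mutation("ΔAA4040-4041")
  expect_equal(d[c("type", "start", "end", "ref")],
               list(type = "del", start = 4040L, end = 4041L, ref = "AA"))
  expect_equal(parse_mutation("dAA4040-4041")$type, "del")
  expect_error(parse_mutation("A10"), "cannot parse")
  expect_error(parse_mutation("dAAA4040-4041"), "does not match")
})

test_that("mutation_impact is zero for identity edits and positive for damage", {
  # perfect 10-bp stem with a tetraloop
  s <- transcript_seq("t", paste0(paste(rep("G", 10), collapse = ""),
                                  "AAAA",
                                  paste(rep("C", 10), collapse = "")))
  m <- name_elements(parse_dotbracket(
    paste0(strrep("(", 10), "....", strrep(")", 10)), s))
  # identity edit
  imp0 <- mutation_impact(s, m, "G2G")
  expect_equal(imp0$ddG, 0)
  expect_equal(imp0$n_pair_changes, 0L)
  # deletion of 2 stem nucleotides destabilizes
  impd <- mutation_impact(s, m, "dGG2-3")
  expect_gt(impd$ddG, 0)
  # G-C -> G-U substitution destabilizes
  s2 <- transcript_seq("t", "GGGGGGAAAACCCCCC")
  m2 <- name_elements(parse_dotbracket("((((((....))))))", s2))
  impu <- mutation_impact(s2, m2, "C11U")
  expect_gt(impu$ddG, 0)
  # reference-base mismatch errors
  expect_error(mutation_impact(s, m, "A2G"), "not A")
})

test_that("site_accessibility_delta reports unpaired-fraction changes", {
  s <- transcript_seq("t", "GGGGAAAACCCC")
  wt <- parse_dotbracket("((((....))))", s)
  mut <- parse_dotbracket("............", s)
  d <- site_accessibility_delta(wt, mut, interval(1, 4))
  expect_equal(d$delta, 1.0)
  expect_equal(site_accessibility_delta(wt, wt, interval(1, 4))$delta, 0)
})

test_that("a planted destabilizing edit increases site accessibility", {
  b <- cached_bundle(1L, noise_free = TRUE)
  mut_ann <- b$annotations[[length(b$annotations)]]
  expect_equal(mut_ann$kind, "mutation")
  imp <- mutation_impact(b$seq, b$truth$model, mut_ann)
  expect_gt(imp$ddG, 0)  # breaking a planted stem pair destabilizes
})

test_that("annotations round-trip through the BED-like TSV", {
  b <- cached_bundle(1L, noise_free = TRUE)
  f <- tempfile(fileext = ".tsv")
  write_annotations(b$annotations, f)
  anns <- read_annotations(f)
  expect_length(anns, length(b$annotations))
  expect_equal(anns[[1]]$kind, b$annotations[[1]]$kind)
  expect_equal(anns[[1]]$region$start, b$annotations[[1]]$region$start)
})
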