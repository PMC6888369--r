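# Overlay of functional annotations on the composite model:
# protein/miRNA/RNA-RNA sites, RNA modifications (with a cell-line
# presence matrix), differential-duplex "structural switch" candidates,
# and mutation/SNP refolding impact.

#' Functional annotation
#'
#' @param kind one of `protein_site`, `mirna_site`, `rna_rna_site`,
#'   `modification`, `mutation`, `snp`.
#' @param region an [interval()] in transcript coordinates.
#' @param label free-text label (e.g. `miR-101-3p`, `m6A`, `U4056C`).
#' @param payload kind-specific extra data (e.g. modification type, or
#'   a mutation edit string).
#' @return object of class `annotation`.
#' @export
annotation <- function(kind = c("protein_site", "mirna_site",
                                "rna_rna_site", "modification",
                                "mutation", "snp"),
                       region, label = "", payload = NULL) {
  kind <- match.arg(kind)
  stopifnot(inherits(region, "interval"))
  structure(list(kind = kind, region = region, label = label,
                 payload = payload), class = "annotation")
}

#' Read / write BED-like annotation tables
#'
#' Tab-separated with header: `start`, `end` (1-based inclusive),
#' `kind`, `label`, `payload`.
#'
#' @param path file path.
#' @return list of [annotation()] objects.
#' @export
read_annotations <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  lapply(seq_len(nrow(df)), function(r)
    annotation(df$kind[r], interval(df$start[r], df$end[r]), df$label[r],
               if ("payload" %in% names(df)) df$payload[r] else NULL))
}

#' @rdname read_annotations
#' @param annotations list of [annotation()].
#' @export
write_annotations <- function(annotations, path) {
  df <- do.call(rbind, lapply(annotations, function(a)
    data.frame(start = a$region$start, end = a$region$end, kind = a$kind,
               label = a$label,
               payload = if (is.null(a$payload)) "" else as.character(a$payload),
               stringsAsFactors = FALSE)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Structural context of an annotation
#'
#' Reports the fraction of the annotated positions that are paired in
#' the model, the overlapping element names, and a classification:
#' `structured` iff more than half of the positions are paired,
#' `unstructured` iff none are... strictly: > 0.5 structured, 0 < f <=
#' 0.5 `mixed` unless f = 0 (`unstructured`). When the site is fully
#' inside a hairpin loop the enclosing helix is also reported.
#'
#' @param model a named [structure_model()].
#' @param ann an [annotation()].
#' @return list(fraction_paired=, class=, elements=, enclosing=).
#' @export
structural_context <- function(model, ann) {
  n <- length(model$seq)
  if (ann$region$end > n) stop("structural_context: region outside transcript")
  pos <- ann$region$start:ann$region$end
  paired <- model$pairing[pos] > 0L
  frac <- mean(paired)
  cls <- if (frac > 0.5) "structured" else if (frac == 0) "unstructured"
         else "mixed"
  elements <- character(0)
  enclosing <- NA_character_
  enclosing_w <- Inf
  for (h in model$helices) {
    hp <- c(h$pairs)
    if (any(pos %in% hp)) elements <- c(elements, h$name)
    # enclosing hairpin: site inside the loop spanned by the innermost pair
    inner_i <- max(h$pairs[, 1L]); inner_j <- min(h$pairs[, 2L])
    if (ann$region$start > inner_i && ann$region$end < inner_j &&
        (inner_j - inner_i) < enclosing_w) {
      enclosing <- h$name
      enclosing_w <- inner_j - inner_i
    }
  }
  list(fraction_paired = frac, class = cls,
       elements = unique(elements), enclosing = enclosing)
}

#' Read a modification presence/absence matrix
#'
#' Tab-separated: first column = modification position, remaining
#' columns = cell lines / conditions, cells `+` (present) / `-`
#' (absent).
#'
#' @param path file path.
#' @return a `modification_matrix`: logical matrix, rownames =
#'   positions, colnames = conditions.
#' @export
read_modification_matrix <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE]) == "+"
  rownames(m) <- as.character(df[[1L]])
  if (anyDuplicated(rownames(m))) stop("modification matrix: duplicate rows")
  class(m) <- c("modification_matrix", class(m))
  m
}

#' Summarize a modification matrix
#'
#' @param m a `modification_matrix` (logical matrix).
#' @param group_a,group_b optional column sets; when given, rows present
#'   in at least one column of `group_a` and absent in all of `group_b`
#'   are reported as `differential`.
#' @return list(per_column=, per_row=, differential=).
#' @export
matrix_summary <- function(m, group_a = NULL, group_b = NULL) {
  per_col <- colSums(m)
  per_row <- rowSums(m)
  differential <- character(0)
  if (!is.null(group_a) && !is.null(group_b)) {
    sel <- apply(m, 1L, function(r)
      any(r[group_a]) && !any(r[group_b]))
    differential <- rownames(m)[sel]
  }
  list(per_column = per_col, per_row = per_row, differential = differential)
}

#' Differential duplexes between two conditions
#'
#' Duplex clusters accepted in condition A but not matched by any
#' accepted cluster in condition B (span matching within `slack`, as in
#' [cluster_duplexes()]). Each lost duplex is flagged as a structural
#' "switch candidate" when a modification position falls inside either
#' span.
#'
#' @param duplexes_a,duplexes_b `duplex_table`s for the two conditions.
#' @param modifications integer positions of modifications (or a list of
#'   `modification` [annotation()]s).
#' @param criteria a [paris_criteria()].
#' @param slack cluster/matching slack in nt.
#' @return data.frame of lost duplexes with `switch_candidate` and
#'   `modification_positions` columns.
#' @export
differential_duplexes <- function(duplexes_a, duplexes_b,
                                  modifications = integer(0),
                                  criteria = paris_criteria(), slack = 5L) {
  if (is.list(modifications) && length(modifications) &&
      inherits(modifications[[1L]], "annotation"))
    modifications <- vapply(modifications, function(a) a$region$start, 1L)
  accepted <- function(dx) {
    cl <- cluster_duplexes(dx, slack)
    if (nrow(cl) == 0L) return(cl)
    keep <- vapply(seq_len(nrow(cl)), function(k)
      accept_duplex(unname(unlist(cl$reads[[k]])), criteria), logical(1))
    cl[keep, , drop = FALSE]
  }
  ca <- accepted(duplexes_a); cb <- accepted(duplexes_b)
  lost <- logical(nrow(ca))
  for (k in seq_len(nrow(ca))) {
    matched <- FALSE
    for (q in seq_len(nrow(cb))) {
      if (iv_near(ca$left_start[k], ca$left_end[k],
                  cb$left_start[q], cb$left_end[q], slack) &&
          iv_near(ca$right_start[k], ca$right_end[k],
                  cb$right_start[q], cb$right_end[q], slack)) {
        matched <- TRUE; break
      }
    }
    lost[k] <- !matched
  }
  out <- ca[lost, , drop = FALSE]
  if (nrow(out) == 0L) {
    out$switch_candidate <- logical(0)
    out$modification_positions <- character(0)
    return(out)
  }
  hits <- lapply(seq_len(nrow(out)), function(k)
    modifications[(modifications >= out$left_start[k] &
                   modifications <= out$left_end[k]) |
                  (modifications >= out$right_start[k] &
                   modifications <= out$right_end[k])])
  out$switch_candidate <- vapply(hits, function(h) length(h) > 0L, logical(1))
  out$modification_positions <- vapply(hits, paste, "", collapse = ",")
  rownames(out) <- NULL
  out
}

#' Parse a mutation edit string
#'
#' Accepts substitutions `XnY` (e.g. `U4056C`) and deletions
#' `dXXn-m` / unicode-delta `ΔXXn-m` (e.g. `ΔAA4040-4041`).
#'
#' @param edit edit string.
#' @return list(type= sub|del, pos=, ref=, alt= for substitutions;
#'   start=, end=, ref= for deletions).
#' @export
parse_mutation <- function(edit) {
  edit <- sub("^Δ", "d", edit)
  m <- regmatches(edit, regexec("^([ACGU])([0-9]+)([ACGU])$", edit))[[1]]
  if (length(m) == 4L)
    return(list(type = "sub", pos = as.integer(m[3L]),
                ref = m[2L], alt = m[4L]))
  m <- regmatches(edit,
                  regexec("^d([ACGU]+)([0-9]+)-([0-9]+)$", edit))[[1]]
  if (length(m) == 4L) {
    start <- as.integer(m[3L]); end <- as.integer(m[4L])
    if (end - start + 1L != nchar(m[2L]))
      stop("parse_mutation: deletion span does not match deleted bases")
    return(list(type = "del", start = start, end = end, ref = m[2L]))
  }
  stop("parse_mutation: cannot parse edit '", edit, "'")
}

apply_mutation <- function(seq, mut) {
  res <- seq_chars(seq)
  if (mut$type == "sub") {
    if (mut$pos > length(res) || res[mut$pos] != mut$ref)
      stop(sprintf("mutation: position %d is %s, not %s",
                   mut$pos, res[min(mut$pos, length(res))], mut$ref))
    res[mut$pos] <- mut$alt
  } else {
    if (mut$end > length(res) ||
        paste(res[mut$start:mut$end], collapse = "") != mut$ref)
      stop("mutation: reference bases do not match deletion")
    res <- res[-(mut$start:mut$end)]
  }
  transcript_seq(paste0(seq$id, "_mut"), paste(res, collapse = ""))
}

#' Fold-based impact of a mutation on its enclosing element
#'
#' Extracts the enclosing element's window (the smallest helix spanning
#' the edit, or the edit itself) padded by `window_pad` nt, folds the
#' wild-type and mutant windows, and reports the free energies, the
#' difference, and the per-position pairing diff. Sign convention:
#' `ddG > 0` means the mutation is destabilizing.
#'
#' @param seq the wild-type [transcript_seq()].
#' @param model a [structure_model()] used to locate the enclosing
#'   element (may be NULL: the edit region itself is used).
#' @param mutation an [annotation()] of kind `mutation`/`snp` whose
#'   `payload` is the edit string, or the edit string itself.
#' @param window_pad padding in nt (default 20).
#' @return list(window=, dG_wt=, dG_mut=, ddG=, n_pair_changes=,
#'   pairing_wt=, pairing_mut=).
#' @export
mutation_impact <- function(seq, model = NULL, mutation, window_pad = 20L) {
  edit <- if (inherits(mutation, "annotation")) {
    if (!is.null(mutation$payload)) mutation$payload else mutation$label
  } else mutation
  mut <- parse_mutation(edit)
  span <- if (mut$type == "sub") c(mut$pos, mut$pos) else c(mut$start, mut$end)
  if (span[2L] > length(seq)) stop("mutation_impact: edit outside transcript")
  # enclosing element window
  lo <- span[1L]; hi <- span[2L]
  if (!is.null(model)) {
    best <- NULL; bestw <- Inf
    for (h in model$helices) {
      a <- min(h$pairs); b <- max(h$pairs)
      if (a <= lo && hi <= b && (b - a) < bestw) { best <- c(a, b); bestw <- b - a }
    }
    if (!is.null(best)) { lo <- best[1L]; hi <- best[2L] }
  }
  lo <- max(1L, lo - window_pad)
  hi <- min(length(seq), hi + window_pad)
  res <- seq_chars(seq)
  wt_win <- paste(res[lo:hi], collapse = "")
  mutseq <- apply_mutation(seq, mut)
  mres <- seq_chars(mutseq)
  hi_m <- if (mut$type == "del") hi - (span[2L] - span[1L] + 1L) else hi
  mut_win <- paste(mres[lo:min(hi_m, length(mres))], collapse = "")
  fwt <- fold(wt_win); fmt <- fold(mut_win)
  # per-position pairing diff over the common 5' part of the window
  ncmp <- min(length(fwt$pairing), length(fmt$pairing))
  diffs <- sum((fwt$pairing[seq_len(ncmp)] > 0L) !=
               (fmt$pairing[seq_len(ncmp)] > 0L))
  list(window = interval(lo, hi), dG_wt = fwt$energy, dG_mut = fmt$energy,
       ddG = round(fmt$energy - fwt$energy, 1L),
       n_pair_changes = diffs,
       pairing_wt = fwt$pairing, pairing_mut = fmt$pairing)
}

#' Accessibility change of a site between two models
#'
#' Accessibility is the unpaired fraction of the site; positive delta
#' means the site is more accessible in the second (mutant) model.
#'
#' @param model_wt,model_mut [structure_model()]s over the same
#'   coordinates.
#' @param site an [interval()].
#' @return list(unpaired_wt=, unpaired_mut=, delta=).
#' @export
site_accessibility_delta <- function(model_wt, model_mut, site) {
  pos <- site$start:site$end
  uw <- mean(model_wt$pairing[pos] == 0L)
  um <- mean(model_mut$pairing[pos] == 0L)
  list(unpaired_wt = uw, unpaired_mut = um, delta = um - uw)
}
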