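# Helix-conservation calls and compensatory-covariation counting over
# homolog alignments. The alignment is an input (Stockholm with a
# consensus-structure line); covariance-model homology search and
# statistical covariation testing are out of scope.

#' Read a Stockholm alignment
#'
#' Minimal single-block Stockholm reader: sequence rows plus the
#' `#=GC SS_cons` consensus-structure line. Multi-block files are
#' concatenated by row name.
#'
#' @param path file path.
#' @return a `homolog_alignment`: list(rows= named character vector of
#'   gapped sequences, ss_cons= consensus structure string or NA).
#' @export
read_stockholm <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0L || !grepl("^# STOCKHOLM", lines[1L]))
    stop("read_stockholm: missing '# STOCKHOLM 1.0' header")
  rows <- list(); ss <- character(0)
  for (ln in lines[-1L]) {
    if (ln == "//" || ln == "" ) next
    if (grepl("^#=GC\\s+SS_cons\\s+", ln)) {
      ss <- c(ss, sub("^#=GC\\s+SS_cons\\s+", "", ln))
    } else if (startsWith(ln, "#")) {
      next
    } else {
      f <- strsplit(trimws(ln), "\\s+")[[1]]
      if (length(f) != 2L) stop("read_stockholm: malformed row: ", ln)
      rows[[f[1L]]] <- paste0(if (is.null(rows[[f[1L]]])) "" else rows[[f[1L]]],
                              f[2L])
    }
  }
  homolog_alignment(unlist(rows),
                    ss_cons = if (length(ss)) paste(ss, collapse = "") else NA)
}

#' Write a Stockholm alignment
#' @param aln a `homolog_alignment`.
#' @param path output path.
#' @return `path` invisibly.
#' @export
write_stockholm <- function(aln, path) {
  w <- max(nchar(names(aln$rows)), nchar("#=GC SS_cons"))
  lines <- c("# STOCKHOLM 1.0",
             sprintf(sprintf("%%-%ds %%s", w), names(aln$rows), aln$rows))
  if (!is.na(aln$ss_cons))
    lines <- c(lines, sprintf(sprintf("%%-%ds %%s", w), "#=GC SS_cons",
                              aln$ss_cons))
  writeLines(c(lines, "//"), path)
  invisible(path)
}

#' Homolog alignment container
#'
#' @param rows named character vector of equal-length gapped sequences;
#'   the first row is taken as the reference (model) sequence unless a
#'   row named `reference` exists.
#' @param ss_cons consensus structure over columns (dot-bracket/WUSS).
#' @param reference name of the reference row.
#' @return object of class `homolog_alignment`.
#' @export
homolog_alignment <- function(rows, ss_cons = NA,
                              reference = if ("reference" %in% names(rows))
                                "reference" else names(rows)[1L]) {
  if (length(unique(nchar(rows))) != 1L)
    stop("homolog_alignment: rows must have equal aligned length")
  if (!is.na(ss_cons) && nchar(ss_cons) != nchar(rows[1L]))
    stop("homolog_alignment: SS_cons length mismatch")
  rows <- toupper(gsub("\\.", "-", rows))
  rows <- gsub("T", "U", rows)
  structure(list(rows = rows, ss_cons = ss_cons, reference = reference),
            class = "homolog_alignment")
}

#' @export
print.homolog_alignment <- function(x, ...) {
  cat(sprintf("<homolog_alignment> %d rows x %d columns (reference: %s)\n",
              length(x$rows), nchar(x$rows[1L]), x$reference))
  invisible(x)
}

#' Map reference (model) positions to alignment columns
#' @param aln a `homolog_alignment`.
#' @return integer vector: `col_of[pos]` = alignment column of ungapped
#'   reference position `pos`.
#' @export
reference_columns <- function(aln) {
  ref <- strsplit(aln$rows[[aln$reference]], "")[[1]]
  which(ref != "-")
}

#' Presence of a helix in one homolog row
#'
#' A helix is present in a homolog iff at least `min_intact` of its
#' pairs have canonical (Watson-Crick or G-U) partners in the homolog
#' after gap removal, and an MFE re-check on the homolog's local window
#' (the two strands co-folded) recovers at least `min_intact` of those
#' pairs. The MFE re-check is what lets a gapped-but-still-folding helix
#' count as present.
#'
#' @param h a [helix()] with pairs in reference coordinates.
#' @param aln a `homolog_alignment`.
#' @param row_name name of the homolog row.
#' @param min_intact fraction of pairs required (default 0.9).
#' @return logical; attribute `detail` carries the two fractions.
#' @export
helix_presence <- function(h, aln, row_name, min_intact = 0.9) {
  col_of <- reference_columns(aln)
  if (max(h$pairs) > length(col_of))
    stop("helix_presence: helix outside the aligned reference")
  row <- strsplit(aln$rows[[row_name]], "")[[1]]
  np <- nrow(h$pairs)
  ci <- col_of[h$pairs[, 1L]]; cj <- col_of[h$pairs[, 2L]]
  a <- row[ci]; b <- row[cj]
  ok <- a != "-" & b != "-" & mapply(canonical_pair, a, b)
  frac_canonical <- sum(ok) / np
  if (frac_canonical < min_intact) {
    out <- FALSE
    attr(out, "detail") <- c(canonical = frac_canonical, refolded = 0)
    return(out)
  }
  # MFE re-check: co-fold the homolog's two strand segments
  seg <- function(cols) {
    s <- row[min(cols):max(cols)]
    s[s != "-"]
  }
  left <- seg(ci); right <- seg(cj)
  if (length(left) == 0L || length(right) == 0L) {
    out <- FALSE
    attr(out, "detail") <- c(canonical = frac_canonical, refolded = 0)
    return(out)
  }
  win <- paste(c(left, "N", "N", "N", right), collapse = "")
  fr <- fold(win)
  nl <- length(left)
  cross <- sum(fr$pairing[seq_len(nl)] > nl + 3L)
  frac_refold <- cross / np
  out <- frac_canonical >= min_intact && frac_refold >= min_intact
  attr(out, "detail") <- c(canonical = frac_canonical, refolded = frac_refold)
  out
}

#' Conservation thresholds
#'
#' Presence thresholds are absolute counts (the printed percentages are
#' descriptive): 43 of 53 vertebrate homologs, 12 of 17 primates, 42 of
#' 51 mammals; nucleotide identity >= 0.75 over helix columns; >= 0.90
#' of the helix intact per homolog.
#'
#' @param min_presence required number of homologs containing the helix.
#' @param group_size homolog group size (for reporting).
#' @param min_identity pooled nucleotide identity over helix columns.
#' @param min_intact per-homolog intact-pair fraction.
#' @return object of class `conservation_thresholds`.
#' @export
conservation_thresholds <- function(min_presence = 43L, group_size = 53L,
                                    min_identity = 0.75, min_intact = 0.9) {
  stopifnot(min_identity > 0, min_identity <= 1, min_intact > 0,
            min_intact <= 1, min_presence <= group_size)
  structure(list(min_presence = as.integer(min_presence),
                 group_size = as.integer(group_size),
                 min_identity = min_identity, min_intact = min_intact),
            class = "conservation_thresholds")
}

#' Is a helix conserved across an alignment?
#'
#' Conserved iff the helix is present (see [helix_presence()]) in at
#' least `min_presence` homolog rows AND the pooled nucleotide identity
#' to the reference over the helix's paired columns is at least
#' `min_identity` (gaps count as mismatches; terminal-loop columns are
#' not part of a helix and are never considered).
#'
#' @param h a [helix()] in reference coordinates.
#' @param aln a `homolog_alignment`.
#' @param thresholds a [conservation_thresholds()].
#' @return logical; attribute `counts` = c(presence, n_rows, identity).
#' @export
helix_conserved <- function(h, aln, thresholds = conservation_thresholds()) {
  others <- setdiff(names(aln$rows), aln$reference)
  present <- vapply(others, function(rn)
    isTRUE(helix_presence(h, aln, rn, thresholds$min_intact)), logical(1))
  # reference row always contains its own helix
  presence <- sum(present) + 1L
  col_of <- reference_columns(aln)
  cols <- c(col_of[h$pairs[, 1L]], col_of[h$pairs[, 2L]])
  ref <- strsplit(aln$rows[[aln$reference]], "")[[1]]
  idn <- vapply(others, function(rn) {
    row <- strsplit(aln$rows[[rn]], "")[[1]]
    sum(row[cols] == ref[cols])
  }, 1)
  identity <- sum(idn) / (length(others) * length(cols))
  out <- presence >= thresholds$min_presence &&
    identity >= thresholds$min_identity
  attr(out, "counts") <- c(presence = presence,
                           n_rows = length(aln$rows),
                           identity = identity)
  out
}

#' Integer percentage of homologs containing a feature
#'
#' @param count number of homologs with the feature.
#' @param group_size total homologs in the group.
#' @return `round(100 * count / group_size)` as integer percent.
#' @export
presence_fraction <- function(count, group_size) {
  if (group_size == 0L) stop("presence_fraction: empty group")
  stopifnot(count >= 0L, count <= group_size)
  as.integer(round(100 * count / group_size))
}

#' Count covarying base pairs
#'
#' A model pair is covarying iff at least two distinct canonical pair
#' types (of AU, UA, GC, CG, GU, UG) occupy its column pair across
#' rows, counting only rows where both columns are ungapped and the
#' realized pair is canonical, and the two realizations differ on both
#' sides. Pairs whose realizations differ on one side only (pairing
#' preserved via wobble, e.g. GC vs GU) are counted separately as
#' co-mutations.
#'
#' @param aln a `homolog_alignment`.
#' @param model a [structure_model()] in reference coordinates (or a
#'   two-column pair matrix).
#' @return list(covarying=, co_mutated=, detail= per-pair data.frame).
#' @export
count_covarying_pairs <- function(aln, model) {
  pairs <- if (inherits(model, "structure_model")) {
    do.call(rbind, lapply(model$helices, function(h) h$pairs))
  } else model
  if (is.null(pairs) || nrow(pairs) == 0L)
    return(list(covarying = 0L, co_mutated = 0L,
                detail = data.frame(i = integer(0))))
  col_of <- reference_columns(aln)
  rows <- lapply(aln$rows, function(r) strsplit(r, "")[[1]])
  detail <- lapply(seq_len(nrow(pairs)), function(k) {
    ci <- col_of[pairs[k, 1L]]; cj <- col_of[pairs[k, 2L]]
    types <- unique(vapply(rows, function(r) {
      a <- r[ci]; b <- r[cj]
      if (a == "-" || b == "-" || !canonical_pair(a, b)) NA_character_
      else paste0(a, b)
    }, ""))
    types <- types[!is.na(types)]
    covary <- FALSE; comut <- FALSE
    if (length(types) >= 2L) {
      for (x in seq_len(length(types) - 1L)) for (y in (x + 1L):length(types)) {
        d <- (substr(types[x], 1L, 1L) != substr(types[y], 1L, 1L)) +
             (substr(types[x], 2L, 2L) != substr(types[y], 2L, 2L))
        if (d == 2L) covary <- TRUE
        if (d == 1L) comut <- TRUE
      }
    }
    data.frame(i = pairs[k, 1L], j = pairs[k, 2L],
               n_types = length(types), covarying = covary,
               co_mutated = comut & !covary)
  })
  detail <- do.call(rbind, detail)
  list(covarying = sum(detail$covarying),
       co_mutated = sum(detail$co_mutated), detail = detail)
}

#' Per-helix conservation report
#'
#' @param model a named [structure_model()].
#' @param aln a `homolog_alignment`.
#' @param thresholds a [conservation_thresholds()].
#' @param path optional TSV output path.
#' @return data.frame: helix, presence count, identity, conserved flag,
#'   covarying-pair count.
#' @export
conservation_report <- function(model, aln,
                                thresholds = conservation_thresholds(),
                                path = NULL) {
  rows <- lapply(model$helices, function(h) {
    cons <- helix_conserved(h, aln, thresholds)
    cts <- attr(cons, "counts")
    cov <- count_covarying_pairs(aln, h$pairs)
    data.frame(helix = ifelse(is.na(h$name), "?", h$name),
               n_pairs = nrow(h$pairs),
               presence = as.integer(cts["presence"]),
               presence_pct = presence_fraction(as.integer(cts["presence"]),
                                                length(aln$rows)),
               identity = round(cts["identity"], 4L),
               conserved = isTRUE(cons),
               covarying_pairs = cov$covarying,
               co_mutated_pairs = cov$co_mutated,
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  rownames(df) <- NULL
  if (!is.null(path))
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  df
}
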