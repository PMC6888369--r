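#' Transcript sequence
#'
#' A single-stranded RNA sequence with 1-based inclusive coordinates.
#' All printed spans throughout the package (helix strands, duplex spans,
#' annotation regions) are 1-based inclusive; conversion to 0-based
#' half-open happens only inside the BED writers.
#'
#' @param id character scalar identifier.
#' @param residues character scalar over the alphabet `A,C,G,U,N`
#'   (`T` is accepted on input and converted to `U`).
#' @param numbering_offset coordinate of the first residue (default 1).
#' @return An object of class `transcript_seq`.
#' @export
transcript_seq <- function(id, residues, numbering_offset = 1L) {
  stopifnot(is.character(id), length(id) == 1L,
            is.character(residues), length(residues) == 1L)
  residues <- toupper(residues)
  residues <- gsub("T", "U", residues, fixed = TRUE)
  if (nchar(residues) < 1L)
    stop("transcript_seq: sequence must contain at least one residue")
  bad <- gsub("[ACGUN]", "", residues)
  if (nchar(bad) > 0L)
    stop("transcript_seq: invalid residues: ",
         paste(unique(strsplit(bad, "")[[1]]), collapse = ","))
  structure(list(id = id, residues = residues,
                 numbering_offset = as.integer(numbering_offset)),
            class = "transcript_seq")
}

#' @export
length.transcript_seq <- function(x) nchar(x$residues)

#' Sequence residues as a character vector
#' @param seq a [transcript_seq()].
#' @return character vector of single residues.
#' @export
seq_chars <- function(seq) strsplit(seq$residues, "")[[1]]

#' @export
print.transcript_seq <- function(x, ...) {
  cat(sprintf("<transcript_seq> %s: %d nt (offset %d)\n",
              x$id, length(x), x$numbering_offset))
  invisible(x)
}

#' Closed interval in transcript coordinates
#'
#' @param start,end 1-based inclusive endpoints, `1 <= start <= end`.
#' @return An object of class `interval`.
#' @export
interval <- function(start, end) {
  start <- as.integer(start); end <- as.integer(end)
  if (is.na(start) || is.na(end) || start < 1L || start > end)
    stop(sprintf("interval: need 1 <= start <= end, got [%s, %s]", start, end))
  structure(list(start = start, end = end), class = "interval")
}

#' @export
length.interval <- function(x) x$end - x$start + 1L

#' @export
format.interval <- function(x, ...) sprintf("%d-%d", x$start, x$end)

#' @export
print.interval <- function(x, ...) { cat("<interval>", format(x), "\n"); invisible(x) }

iv_overlap <- function(a, b) max(0L, min(a$end, b$end) - max(a$start, b$start) + 1L)

#' Helix: a run of stacked base pairs
#'
#' A helix is stored as an explicit pair list `(i, j)` with `i < j`.
#' A run of stacked pairs broken by any internal loop or bulge is
#' represented as multiple `helix` records, keeping the non-crossing
#' invariant checkable at the pair level.
#'
#' @param pairs two-column integer matrix of `(i, j)` pairs, `i < j`;
#'   pairs within one helix must be mutually non-crossing.
#' @param name element name (`H<k>` or `PK<k>`), may be `NA` before
#'   [name_elements()] has run.
#' @param pk_layer integer >= 0; 0 means nested.
#' @param noncanonical logical vector flagging non-Watson-Crick pairs;
#'   these are displayed but excluded from energy accounting.
#' @return An object of class `helix`.
#' @export
helix <- function(pairs, name = NA_character_, pk_layer = 0L,
                  noncanonical = NULL) {
  pairs <- matrix(as.integer(pairs), ncol = 2L,
                  dimnames = list(NULL, c("i", "j")))
  if (nrow(pairs) < 1L) stop("helix: needs at least one pair")
  if (any(pairs[, 1L] >= pairs[, 2L])) stop("helix: every pair needs i < j")
  ord <- order(pairs[, 1L])
  pairs <- pairs[ord, , drop = FALSE]
  # mutual non-crossing within the helix: i ascending implies j descending
  # for stacked runs; general check below
  for (a in seq_len(nrow(pairs) - 1L)) {
    if (pairs_cross(pairs[a, ], pairs[a + 1L, ]))
      stop("helix: pairs within one helix must be non-crossing")
  }
  if (is.null(noncanonical)) noncanonical <- rep(FALSE, nrow(pairs))
  structure(list(pairs = pairs, name = name,
                 pk_layer = as.integer(pk_layer),
                 noncanonical = noncanonical),
            class = "helix")
}

#' @export
print.helix <- function(x, ...) {
  cat(sprintf("<helix> %s: %d pairs, 5' %s / 3' %s, layer %d\n",
              ifelse(is.na(x$name), "?", x$name), nrow(x$pairs),
              format(helix_five_prime(x)), format(helix_three_prime(x)),
              x$pk_layer))
  invisible(x)
}

#' 5' and 3' strand intervals of a helix
#' @param h a [helix()].
#' @return an [interval()].
#' @export
helix_five_prime <- function(h) interval(min(h$pairs[, 1L]), max(h$pairs[, 1L]))

#' @rdname helix_five_prime
#' @export
helix_three_prime <- function(h) interval(min(h$pairs[, 2L]), max(h$pairs[, 2L]))

# do two individual pairs cross (interleave)?
pairs_cross <- function(p, q) {
  (p[1L] < q[1L] && q[1L] < p[2L] && p[2L] < q[2L]) ||
  (q[1L] < p[1L] && p[1L] < q[2L] && q[2L] < p[2L])
}

# Do two helices cross? For helices occupying disjoint positions this is
# decided by their outermost pairs (strand intervals of distinct helices
# never interleave partially).
helices_cross <- function(a, b) {
  pa <- c(min(a$pairs[, 1L]), max(a$pairs[, 2L]))
  pb <- c(min(b$pairs[, 1L]), max(b$pairs[, 2L]))
  pairs_cross(pa, pb)
}

#' Composite structure model
#'
#' Ordered helices plus a per-nucleotide state track. Invariants: each
#' position belongs to at most one pair; helices with `pk_layer` 0 are
#' mutually non-crossing; every paired position lies in exactly one helix.
#'
#' @param seq a [transcript_seq()].
#' @param helices list of [helix()] records.
#' @param per_nt_state character vector, one of `paired`, `unpaired`,
#'   `no_data` per position; derived from the helices when omitted.
#' @param junctions list of multiway-junction records
#'   (`list(name=, members=)`), normally filled by [name_elements()].
#' @param provenance optional per-position evidence tag (see
#'   [resolve_nucleotide()]).
#' @return An object of class `structure_model`.
#' @export
structure_model <- function(seq, helices = list(), per_nt_state = NULL,
                            junctions = list(), provenance = NULL) {
  n <- length(seq)
  pairing <- integer(n)
  for (h in helices) {
    if (max(h$pairs) > n) stop("structure_model: pair outside transcript")
    for (r in seq_len(nrow(h$pairs))) {
      i <- h$pairs[r, 1L]; j <- h$pairs[r, 2L]
      if (pairing[i] != 0L || pairing[j] != 0L)
        stop(sprintf("structure_model: position %d or %d in more than one pair",
                     i, j))
      pairing[i] <- j; pairing[j] <- i
    }
  }
  layer0 <- Filter(function(h) h$pk_layer == 0L, helices)
  if (length(layer0) > 1L) {
    for (a in seq_len(length(layer0) - 1L))
      for (b in seq((a + 1L), length(layer0)))
        if (helices_cross(layer0[[a]], layer0[[b]]))
          stop("structure_model: pk_layer-0 helices must be non-crossing")
  }
  if (is.null(per_nt_state)) {
    per_nt_state <- ifelse(pairing > 0L, "paired", "unpaired")
  }
  stopifnot(length(per_nt_state) == n)
  structure(list(seq = seq, helices = helices, pairing = pairing,
                 per_nt_state = per_nt_state, junctions = junctions,
                 provenance = provenance),
            class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  npk <- sum(vapply(x$helices, function(h) h$pk_layer > 0L, logical(1)))
  cat(sprintf("<structure_model> %s: %d nt, %d helices (%d pseudoknotted), %d junctions\n",
              x$seq$id, length(x$seq), length(x$helices), npk,
              length(x$junctions)))
  cat(sprintf("  paired %d | unpaired %d | no_data %d\n",
              sum(x$per_nt_state == "paired"),
              sum(x$per_nt_state == "unpaired"),
              sum(x$per_nt_state == "no_data")))
  invisible(x)
}

#' Split a pairing vector into stacked-run helices
#'
#' Consecutive stacked pairs `(i, j), (i+1, j-1)` form one helix record;
#' any bulge or internal loop starts a new record.
#'
#' @param pairing integer vector, `pairing[i] = j` if `(i, j)` paired,
#'   0 otherwise.
#' @return list of [helix()] records ordered by 5'-most position.
#' @export
helices_from_pairing <- function(pairing) {
  n <- length(pairing)
  seen <- logical(n)
  out <- list()
  for (i in seq_len(n)) {
    j <- pairing[i]
    if (j <= i || seen[i]) next
    run <- matrix(c(i, j), ncol = 2L)
    seen[i] <- TRUE; seen[j] <- TRUE
    ii <- i; jj <- j
    while (ii + 1L <= n && jj - 1L >= 1L && ii + 1L < jj - 1L &&
           pairing[ii + 1L] == jj - 1L && !seen[ii + 1L]) {
      ii <- ii + 1L; jj <- jj - 1L
      run <- rbind(run, c(ii, jj))
      seen[ii] <- TRUE; seen[jj] <- TRUE
    }
    out[[length(out) + 1L]] <- helix(run)
  }
  out
}

#' Reference structure for cutoff calibration
#'
#' A validated local structure (e.g. a protein-bound hairpin) with known
#' per-position paired/unpaired truth, used to evaluate and calibrate
#' probing-classification cutoffs.
#'
#' @param name character scalar.
#' @param region an [interval()].
#' @param truth character vector of `paired`/`unpaired`, one per position
#'   of `region`.
#' @return An object of class `reference_structure`.
#' @export
reference_structure <- function(name, region, truth) {
  stopifnot(inherits(region, "interval"))
  if (!all(truth %in% c("paired", "unpaired")))
    stop("reference_structure: truth values must be 'paired' or 'unpaired'")
  if (length(truth) != length(region))
    stop("reference_structure: region length must equal length of truth")
  structure(list(name = name, region = region, truth = truth),
            class = "reference_structure")
}
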