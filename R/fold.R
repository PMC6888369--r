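# Minimum-free-energy folding contract.
#
# The built-in backend ("bpmax-stack") maximizes base-pair score with a
# stacking bonus and a minimum hairpin loop of 3 nt. It is documented as
# an approximation of a Turner-parameter folder: pair scores G-C = 3.0,
# A-U = 2.0, G-U = 1.0, each stacked pair adds 1.0, reported as negative
# free energy in tenths of kcal/mol. N never pairs. An external Turner
# folder can be plugged in via `options(rnacomposer.fold_backend = fn)`
# where `fn(window_string)` returns `list(pairing=, energy=)`.

.res_code <- c(A = 1L, C = 2L, G = 3L, U = 4L, N = 0L)

encode_residues <- function(x) {
  chars <- if (length(x) == 1L && nchar(x[1L]) > 1L) strsplit(x, "")[[1]] else x
  codes <- .res_code[chars]
  if (anyNA(codes))
    stop("fold: sequence contains characters outside {A,C,G,U,N}")
  unname(codes)
}

#' Is a pair of residues canonical (Watson-Crick or G-U wobble)?
#' @param a,b single residue characters.
#' @return logical.
#' @export
canonical_pair <- function(a, b) {
  p <- paste0(a, b)
  p %in% c("AU", "UA", "GC", "CG", "GU", "UG")
}

#' Score a structure under the built-in energy model
#'
#' Used both by the folding backend and by the exhaustive test oracle so
#' that the two search strategies are compared under one energy model.
#'
#' @param residues character scalar or vector of residues.
#' @param pairing integer pairing vector (`pairing[i] = j` or 0).
#' @return total score in tenths of kcal/mol (higher = more stable);
#'   the reported free energy is `-score / 10`.
#' @export
score_structure <- function(residues, pairing) {
  s <- encode_residues(residues)
  score_tab <- matrix(0L, 5L, 5L)
  score_tab[3L + 1L, 2L + 1L] <- score_tab[2L + 1L, 3L + 1L] <- 30L
  score_tab[1L + 1L, 4L + 1L] <- score_tab[4L + 1L, 1L + 1L] <- 20L
  score_tab[3L + 1L, 4L + 1L] <- score_tab[4L + 1L, 3L + 1L] <- 10L
  total <- 0L
  n <- length(pairing)
  for (i in seq_len(n)) {
    j <- pairing[i]
    if (j > i) {
      total <- total + score_tab[s[i] + 1L, s[j] + 1L]
      if (i + 1L < j - 1L && pairing[i + 1L] == j - 1L)
        total <- total + 10L
    }
  }
  total
}

#' Fold a sequence window at minimum free energy
#'
#' @param seq_window character scalar of residues (`A,C,G,U,N`), or a
#'   [transcript_seq()].
#' @param forbidden optional integer positions that must stay unpaired
#'   (treated as N by the backend).
#' @param min_loop minimum hairpin loop length (default 3).
#' @return A `fold_result` list: `pairing` (integer vector), `energy`
#'   (kcal/mol, <= 0, reported to 0.1), `backend`, `n`.
#' @export
fold <- function(seq_window, forbidden = integer(0), min_loop = 3L) {
  residues <- if (inherits(seq_window, "transcript_seq"))
    seq_window$residues else seq_window
  if (nchar(residues) < 1L) stop("fold: empty window")
  codes <- encode_residues(residues)
  if (length(forbidden) > 0L) codes[forbidden] <- 0L
  backend <- getOption("rnacomposer.fold_backend", NULL)
  if (!is.null(backend) && length(forbidden) == 0L) {
    r <- backend(residues)
    return(structure(list(pairing = as.integer(r$pairing),
                          energy = round(r$energy, 1L),
                          backend = "external", n = length(codes)),
                     class = "fold_result"))
  }
  r <- .nussinov_fold(codes, min_loop = as.integer(min_loop))
  structure(list(pairing = as.integer(r$pairing),
                 energy = round(-r$score / 10, 1L),
                 backend = "bpmax-stack", n = length(codes)),
            class = "fold_result")
}

#' @export
print.fold_result <- function(x, ...) {
  cat(sprintf("<fold_result> %d nt, %d pairs, %.1f kcal/mol [%s]\n",
              x$n, sum(x$pairing > 0) %/% 2L, x$energy, x$backend))
  invisible(x)
}

# window starts covering [start, end]: step = window - overlap; stop as
# soon as a window reaches the region end.
fold_windows <- function(start, end, window, overlap) {
  if (window <= overlap) stop("fold_uncovered_region: window must exceed overlap")
  step <- window - overlap
  starts <- integer(0)
  s <- start
  repeat {
    starts <- c(starts, s)
    if (s + window - 1L >= end) break
    s <- s + step
  }
  cbind(start = starts, end = pmin(starts + window - 1L, end))
}

#' Fold a region by 5'-to-3' window scanning
#'
#' Scans `region` in `window`-nt increments with `overlap`-nt overlap
#' from 5' to 3'. Overlapping window predictions are merged
#' conservatively: a pair is kept iff it is predicted by every window
#' that fully contains both partners; remaining per-position conflicts
#' are resolved in favor of the more 5' window.
#'
#' @param seq a [transcript_seq()].
#' @param region an [interval()] within the transcript.
#' @param window window length in nt (default 100).
#' @param overlap overlap between consecutive windows in nt (default 20).
#' @return A [structure_model()] fragment covering the whole transcript
#'   length, with pairs only inside `region`; attribute `windows` holds
#'   the window table.
#' @export
fold_uncovered_region <- function(seq, region, window = 100L, overlap = 20L) {
  n <- length(seq)
  if (region$end > n) stop("fold_uncovered_region: region outside transcript")
  wins <- fold_windows(region$start, region$end, as.integer(window),
                       as.integer(overlap))
  res <- seq_chars(seq)
  # collect per-window predictions as global (i, j, window_index)
  pred <- vector("list", nrow(wins))
  for (w in seq_len(nrow(wins))) {
    a <- wins[w, 1L]; b <- wins[w, 2L]
    fr <- fold(paste(res[a:b], collapse = ""))
    p <- fr$pairing
    ii <- which(p > seq_along(p))
    pred[[w]] <- if (length(ii) == 0L)
      matrix(integer(0), ncol = 2L) else
      cbind(ii + a - 1L, p[ii] + a - 1L)
  }
  # a candidate pair survives iff predicted in every window fully
  # containing both partners
  keyed <- new.env(parent = emptyenv())
  for (w in seq_len(nrow(wins))) {
    m <- pred[[w]]
    for (r in seq_len(nrow(m)))
      assign(sprintf("%d_%d_%d", m[r, 1L], m[r, 2L], w), TRUE, envir = keyed)
  }
  pairing <- integer(n)
  claimed_by <- integer(n)  # window index that set each position
  for (w in seq_len(nrow(wins))) {
    m <- pred[[w]]
    for (r in seq_len(nrow(m))) {
      i <- m[r, 1L]; j <- m[r, 2L]
      covering <- which(wins[, 1L] <= i & wins[, 2L] >= j)
      ok <- all(vapply(covering, function(cw)
        exists(sprintf("%d_%d_%d", i, j, cw), envir = keyed), logical(1)))
      if (!ok) next
      # conflicts (occupied positions or crossings against already-kept
      # pairs) resolved in favor of the more 5' window: first claim wins
      if (pairing[i] != 0L || pairing[j] != 0L) next
      kept_i <- which(pairing > seq_len(n))
      crosses <- any((kept_i < i & i < pairing[kept_i] & pairing[kept_i] < j) |
                     (i < kept_i & kept_i < j & j < pairing[kept_i]))
      if (crosses) next
      pairing[i] <- j; pairing[j] <- i
      claimed_by[i] <- w; claimed_by[j] <- w
    }
  }
  state <- rep("no_data", n)
  state[region$start:region$end] <- ifelse(
    pairing[region$start:region$end] > 0L, "paired", "unpaired")
  model <- structure_model(seq, helices_from_pairing(pairing),
                           per_nt_state = state)
  attr(model, "windows") <- wins
  model
}
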