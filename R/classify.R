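# Per-nucleotide single/double-stranded classification from the PARS
# (RNase S1:V1 ratio) and DMS (reactivity count) channels, and
# evaluation/calibration of the cutoffs against reference structures.
#
# The classification rules are strict inequalities: a ratio exactly at
# the cutoff, or a DMS count exactly at the cutoff, is undetermined.

#' Classification cutoffs
#'
#' @param pars_ratio S1:V1 ratio above which a nucleotide is called
#'   single-stranded and below which double-stranded (default 1).
#' @param dms_count DMS count above which an A/C is called unprotected
#'   and below which protected (default 20).
#' @param pseudocount value substituted for V1 = 0 when S1 > 0, so a
#'   strongly cleaved nucleotide still yields a finite ratio (default 0.5).
#' @return object of class `cutoffs`.
#' @export
cutoffs <- function(pars_ratio = 1, dms_count = 20, pseudocount = 0.5) {
  stopifnot(pars_ratio > 0, dms_count > 0, pseudocount > 0)
  structure(list(pars_ratio = pars_ratio, dms_count = dms_count,
                 pseudocount = pseudocount), class = "cutoffs")
}

#' Classify a nucleotide from the PARS channel
#'
#' Ratio `r = s1/v1` (with `v1` replaced by the pseudocount when
#' `v1 = 0` and `s1 > 0`): `r` above the cutoff is `single`, below is
#' `double`, exactly at the cutoff is `undetermined`; both counts zero
#' or missing is `no_data`.
#'
#' @param s1,v1 mean read counts (>= 0), possibly `NA`. Vectorized.
#' @param cut a [cutoffs()].
#' @return character vector of `single`/`double`/`undetermined`/`no_data`.
#' @export
classify_pars <- function(s1, v1, cut = cutoffs()) {
  if (any(!is.na(s1) & s1 < 0) || any(!is.na(v1) & v1 < 0))
    stop("classify_pars: negative counts")
  out <- rep("no_data", length(s1))
  has <- !is.na(s1) & !is.na(v1) & (s1 > 0 | v1 > 0)
  v1e <- ifelse(!is.na(v1) & v1 == 0, cut$pseudocount, v1)
  r <- s1 / v1e
  out[has & r > cut$pars_ratio] <- "single"
  out[has & r < cut$pars_ratio] <- "double"
  out[has & r == cut$pars_ratio] <- "undetermined"
  out
}

#' Classify a nucleotide from the DMS channel
#'
#' DMS modifies unpaired A and C only: on A/C a count above the cutoff
#' is `unprotected` (unpaired), below is `protected` (paired), exactly
#' at the cutoff is `undetermined`; G/U (or missing counts) are `no_data`.
#'
#' @param base residue character vector.
#' @param dms mean DMS stop counts, possibly `NA`. Vectorized.
#' @param cut a [cutoffs()].
#' @return character vector of
#'   `unprotected`/`protected`/`undetermined`/`no_data`.
#' @export
classify_dms <- function(base, dms, cut = cutoffs()) {
  out <- rep("no_data", length(base))
  ac <- base %in% c("A", "C") & !is.na(dms)
  out[ac & dms > cut$dms_count] <- "unprotected"
  out[ac & dms < cut$dms_count] <- "protected"
  out[ac & dms == cut$dms_count] <- "undetermined"
  out
}

#' Classify every covered position of a track
#'
#' @param track a `probing_track`.
#' @param cut a [cutoffs()].
#' @return data.frame with columns position, base, pars_call, dms_call.
#' @export
classify_track <- function(track, cut = cutoffs()) {
  data.frame(position = track$position, base = track$base,
             pars_call = classify_pars(track$s1, track$v1, cut),
             dms_call = classify_dms(track$base, track$dms, cut),
             stringsAsFactors = FALSE)
}

#' Evaluate classification cutoffs against reference structures
#'
#' For each channel, counts positions inside the reference regions whose
#' call matches the known truth (`single`/`unprotected` vs `unpaired`,
#' `double`/`protected` vs `paired`). Positions without channel coverage
#' are excluded from the denominator; `undetermined` calls count as
#' covered but incorrect. The DMS denominator is restricted to covered
#' A/C positions.
#'
#' @param track a `probing_track`.
#' @param references list of [reference_structure()].
#' @param cut a [cutoffs()].
#' @return list with per-channel confusion counts and accuracies.
#' @export
evaluate_against_references <- function(track, references, cut = cutoffs()) {
  if (length(references) == 0L)
    stop("evaluate_against_references: no references given")
  calls <- classify_track(track, cut)
  idx <- match(unlist(lapply(references, function(r)
    r$region$start:r$region$end)), calls$position)
  truth <- unlist(lapply(references, function(r) r$truth))
  conf <- function(call_vec, single_lab, double_lab) {
    covered <- !is.na(idx) & call_vec[idx] != "no_data"
    cl <- call_vec[idx][covered]; tr <- truth[covered]
    correct <- (cl == single_lab & tr == "unpaired") |
               (cl == double_lab & tr == "paired")
    list(n_covered = sum(covered), n_correct = sum(correct),
         accuracy = if (sum(covered) == 0L) NA_real_
                    else sum(correct) / sum(covered))
  }
  pars <- conf(calls$pars_call, "single", "double")
  dms <- conf(calls$dms_call, "unprotected", "protected")
  structure(list(pars = pars, dms = dms,
                 mean_accuracy = mean(c(pars$accuracy, dms$accuracy),
                                      na.rm = TRUE)),
            class = "accuracy_report")
}

#' @export
print.accuracy_report <- function(x, ...) {
  cat(sprintf("<accuracy_report> PARS %d/%d (%.1f%%) | DMS %d/%d (%.1f%%)\n",
              x$pars$n_correct, x$pars$n_covered, 100 * x$pars$accuracy,
              x$dms$n_correct, x$dms$n_covered, 100 * x$dms$accuracy))
  invisible(x)
}

#' Calibrate cutoffs on reference structures by grid search
#'
#' Returns the grid point maximizing the unweighted mean of the two
#' channel accuracies. Ties are broken toward the default cutoffs
#' (1, 20) if present in the grid, then toward the smallest values.
#'
#' @param track a `probing_track`.
#' @param references list of [reference_structure()].
#' @param pars_grid,dms_grid numeric vectors of candidate cutoffs.
#' @return a [cutoffs()] object; attribute `report` holds the full grid
#'   (data.frame: pars_ratio, dms_count, channel accuracies, objective).
#' @export
calibrate <- function(track, references,
                      pars_grid = c(0.25, 0.5, 1, 2, 4),
                      dms_grid = c(5, 10, 20, 40, 80)) {
  if (length(references) == 0L) stop("calibrate: empty references")
  if (length(pars_grid) == 0L || length(dms_grid) == 0L)
    stop("calibrate: empty grid")
  grid <- expand.grid(pars_ratio = pars_grid, dms_count = dms_grid,
                      KEEP.OUT.ATTRS = FALSE)
  res <- lapply(seq_len(nrow(grid)), function(k) {
    rep_k <- evaluate_against_references(
      track, references, cutoffs(grid$pars_ratio[k], grid$dms_count[k]))
    c(pars_acc = rep_k$pars$accuracy, dms_acc = rep_k$dms$accuracy,
      objective = rep_k$mean_accuracy,
      n_pars = rep_k$pars$n_covered, n_dms = rep_k$dms$n_covered)
  })
  report <- cbind(grid, do.call(rbind, res))
  if (all(report$n_pars == 0 & report$n_dms == 0))
    stop("calibrate: references have zero coverage in the track")
  best <- max(report$objective, na.rm = TRUE)
  cand <- which(!is.na(report$objective) & report$objective == best)
  is_default <- report$pars_ratio[cand] == 1 & report$dms_count[cand] == 20
  pick <- if (any(is_default)) cand[is_default][1L] else
    cand[order(report$pars_ratio[cand], report$dms_count[cand])][1L]
  out <- cutoffs(report$pars_ratio[pick], report$dms_count[pick])
  attr(out, "report") <- report
  out
}

#' Write a calibration grid report as TSV
#' @param calibrated result of [calibrate()].
#' @param path output path.
#' @return `path` invisibly.
#' @export
write_calibration_report <- function(calibrated, path) {
  utils::write.table(attr(calibrated, "report"), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
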