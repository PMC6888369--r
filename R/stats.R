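# Agreement and coverage statistics of the composite model against the
# individual probing channels. Undetermined calls are excluded from
# both numerators and denominators; only explicit single/double-stranded
# annotations are compared.

#' PARS vs DMS agreement
#'
#' Denominator: covered A/C positions (optionally restricted to
#' `subranges`); numerator: positions where both channels are determined
#' and concordant (single & unprotected, or double & protected).
#'
#' @param track a `probing_track`.
#' @param calls output of [classify_track()] (recomputed when omitted).
#' @param cut a [cutoffs()] used when `calls` is omitted.
#' @param subranges optional list of [interval()]s restricting the
#'   denominator.
#' @return list(fraction=, numerator=, denominator=).
#' @export
agreement_pars_dms <- function(track, calls = NULL, cut = cutoffs(),
                               subranges = NULL) {
  if (is.null(calls)) calls <- classify_track(track, cut)
  keep <- calls$base %in% c("A", "C") & !is.na(track$dms)
  if (!is.null(subranges)) {
    inr <- rep(FALSE, nrow(calls))
    for (r in subranges)
      inr <- inr | (calls$position >= r$start & calls$position <= r$end)
    keep <- keep & inr
  }
  if (sum(keep) == 0L)
    stop("agreement_pars_dms: no covered A/C positions in denominator")
  p <- calls$pars_call[keep]; d <- calls$dms_call[keep]
  agree <- (p == "single" & d == "unprotected") |
           (p == "double" & d == "protected")
  list(fraction = sum(agree) / sum(keep),
       numerator = sum(agree), denominator = sum(keep))
}

#' Channel agreement with the composite model
#'
#' Fraction of channel-determined positions whose channel state matches
#' the composite per-nucleotide state. For `paris` the positions are the
#' registered pair members of accepted duplexes, whose channel state is
#' `paired` by definition; [assemble()] guarantees these remain paired,
#' so this fraction is exactly 1 on every pipeline output.
#'
#' @param channel one of `pars`, `dms`, `paris`.
#' @param calls output of [classify_track()] on the same track.
#' @param composite a [structure_model()] from [assemble()].
#' @return list(fraction=, numerator=, denominator=, ss=, ds=) where
#'   `ss`/`ds` split the agreement by single/double-stranded channel
#'   state (NA for paris, which asserts only double-stranded).
#' @export
agreement_with_composite <- function(channel = c("pars", "dms", "paris"),
                                     calls, composite) {
  channel <- match.arg(channel)
  state <- composite$per_nt_state
  if (channel == "paris") {
    pp <- attr(composite, "paris_pairs")
    pos <- unique(c(pp))
    if (length(pos) == 0L)
      return(list(fraction = NA_real_, numerator = 0L, denominator = 0L,
                  ss = NA_real_, ds = NA_real_))
    ok <- state[pos] == "paired"
    return(list(fraction = sum(ok) / length(pos), numerator = sum(ok),
                denominator = length(pos), ss = NA_real_,
                ds = sum(ok) / length(pos)))
  }
  col <- if (channel == "pars") calls$pars_call else calls$dms_call
  ss_lab <- if (channel == "pars") "single" else "unprotected"
  ds_lab <- if (channel == "pars") "double" else "protected"
  det <- col %in% c(ss_lab, ds_lab)
  pos <- calls$position[det]
  chan_state <- ifelse(col[det] == ss_lab, "unpaired", "paired")
  comp <- state[pos]
  decided <- comp %in% c("paired", "unpaired")
  agree <- decided & comp == chan_state
  frac_of <- function(mask) if (sum(mask) == 0L) NA_real_ else
    sum(agree & mask) / sum(mask)
  list(fraction = if (sum(det) == 0L) NA_real_ else sum(agree) / sum(det),
       numerator = sum(agree), denominator = sum(det),
       ss = frac_of(chan_state == "unpaired"),
       ds = frac_of(chan_state == "paired"))
}

#' Structural-information coverage
#'
#' Fraction of the transcript with any structural information: union of
#' covered track positions, registered spans of accepted duplexes, and
#' MFE-folded regions.
#'
#' @param track a `probing_track`.
#' @param clusters accepted-duplex cluster table (the `clusters`
#'   attribute of [assemble()] output), or NULL.
#' @param mfe_regions list of [interval()]s folded by MFE.
#' @param transcript_len transcript length in nt.
#' @return list(fraction=, numerator=, denominator=).
#' @export
coverage <- function(track, clusters = NULL, mfe_regions = list(),
                     transcript_len) {
  covered <- logical(transcript_len)
  has <- !(is.na(track$s1) & is.na(track$v1) & is.na(track$dms))
  covered[track$position[has]] <- TRUE
  if (!is.null(clusters) && nrow(clusters) > 0L) {
    acc <- if ("accepted" %in% names(clusters)) which(clusters$accepted)
           else seq_len(nrow(clusters))
    for (k in acc) {
      covered[clusters$left_start[k]:clusters$left_end[k]] <- TRUE
      covered[clusters$right_start[k]:clusters$right_end[k]] <- TRUE
    }
  }
  for (r in mfe_regions) covered[r$start:r$end] <- TRUE
  list(fraction = sum(covered) / transcript_len,
       numerator = sum(covered), denominator = transcript_len)
}

#' Full agreement/coverage report
#'
#' @param track a `probing_track`.
#' @param composite output of [assemble()] on that track.
#' @param cut the [cutoffs()] used by the assembly.
#' @return An `agreement_report` list with pars_dms, pars/dms/paris vs
#'   composite, and coverage entries (all with denominators).
#' @export
agreement_report <- function(track, composite, cut = cutoffs()) {
  calls <- classify_track(track, cut)
  pd <- tryCatch(agreement_pars_dms(track, calls),
                 error = function(e) list(fraction = NA_real_,
                                          numerator = 0L, denominator = 0L))
  out <- list(
    pars_dms_agree = pd,
    pars_vs_composite = agreement_with_composite("pars", calls, composite),
    dms_vs_composite = agreement_with_composite("dms", calls, composite),
    paris_vs_composite = agreement_with_composite("paris", calls, composite),
    coverage = coverage(track, attr(composite, "clusters"),
                        attr(composite, "mfe_regions"),
                        length(composite$seq)))
  class(out) <- "agreement_report"
  out
}

#' @export
print.agreement_report <- function(x, ...) {
  pct <- function(e) if (is.na(e$fraction)) "NA" else
    sprintf("%.1f%% (%d/%d)", 100 * e$fraction, e$numerator, e$denominator)
  cat("<agreement_report>\n",
      " PARS~DMS concordance: ", pct(x$pars_dms_agree), "\n",
      " PARS vs composite:    ", pct(x$pars_vs_composite), "\n",
      " DMS vs composite:     ", pct(x$dms_vs_composite), "\n",
      " PARIS vs composite:   ", pct(x$paris_vs_composite), "\n",
      " coverage:             ", pct(x$coverage), "\n", sep = "")
  invisible(x)
}

#' Serialize an agreement report
#' @param report an `agreement_report`.
#' @param path output path (`.json` or `.tsv` by extension).
#' @return `path` invisibly.
#' @export
write_agreement_report <- function(report, path) {
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                         digits = NA)
  } else {
    rows <- do.call(rbind, lapply(names(report), function(nm) {
      e <- report[[nm]]
      data.frame(statistic = nm, fraction = e$fraction,
                 numerator = e$numerator, denominator = e$denominator)
    }))
    utils::write.table(rows, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}
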