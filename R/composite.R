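# The core inference: accept PARIS duplex groups, reconcile PARS / DMS /
# MFE evidence per nucleotide, harvest helices, call pseudoknots, and
# assemble the named composite model.

#' PARIS duplex acceptance criteria
#'
#' A duplex group is accepted as double-stranded evidence iff
#' (i) more than `multi_dataset_reads` reads are present in at least
#' `multi_dataset_min` datasets, or (ii) more than `single_dataset_reads`
#' reads are present in at least one dataset. Both thresholds are strict
#' (reads > 3 means >= 4 reads).
#'
#' @param multi_dataset_reads strict read threshold for criterion (i)
#'   (default 3).
#' @param multi_dataset_min number of datasets required by criterion (i)
#'   (default 2).
#' @param single_dataset_reads strict read threshold for criterion (ii)
#'   (default 5).
#' @return object of class `paris_criteria`.
#' @export
paris_criteria <- function(multi_dataset_reads = 3L, multi_dataset_min = 2L,
                           single_dataset_reads = 5L) {
  stopifnot(multi_dataset_reads >= 1L, multi_dataset_min >= 1L,
            single_dataset_reads >= 1L)
  structure(list(multi_dataset_reads = as.integer(multi_dataset_reads),
                 multi_dataset_min = as.integer(multi_dataset_min),
                 single_dataset_reads = as.integer(single_dataset_reads)),
            class = "paris_criteria")
}

#' Accept or reject a clustered duplex group
#'
#' @param reads_per_dataset integer vector of read counts, one per
#'   dataset (0 for datasets without support).
#' @param criteria a [paris_criteria()].
#' @return logical scalar; an empty vector is rejected, not an error.
#' @export
accept_duplex <- function(reads_per_dataset, criteria = paris_criteria()) {
  if (length(reads_per_dataset) == 0L) return(FALSE)
  sum(reads_per_dataset > criteria$multi_dataset_reads) >=
    criteria$multi_dataset_min ||
    any(reads_per_dataset > criteria$single_dataset_reads)
}

# are intervals [a1,a2] and [b1,b2] within `slack` nt of overlapping?
iv_near <- function(a1, a2, b1, b2, slack)
  max(a1, b1) - min(a2, b2) <= slack

#' Cluster duplex groups across datasets
#'
#' Records whose left spans and right spans each lie within `slack` nt
#' of one another are merged into one cluster (transitively). The
#' cluster span is the union of member spans; reads are summed within
#' each dataset.
#'
#' @param duplexes a `duplex_table` (see [read_duplexes()]).
#' @param slack matching slack in nt (default 5).
#' @return data.frame of clusters: left/right spans, `n_members`, and a
#'   `reads` list-column of named per-dataset read totals.
#' @export
cluster_duplexes <- function(duplexes, slack = 5L) {
  n <- nrow(duplexes)
  if (n == 0L)
    return(data.frame(left_start = integer(0), left_end = integer(0),
                      right_start = integer(0), right_end = integer(0),
                      n_members = integer(0)))
  cluster <- seq_len(n)
  find <- function(x) { while (cluster[x] != x) x <- cluster[x]; x }
  if (n > 1L) for (a in seq_len(n - 1L)) for (b in (a + 1L):n) {
    if (iv_near(duplexes$left_start[a], duplexes$left_end[a],
                duplexes$left_start[b], duplexes$left_end[b], slack) &&
        iv_near(duplexes$right_start[a], duplexes$right_end[a],
                duplexes$right_start[b], duplexes$right_end[b], slack)) {
      ra <- find(a); rb <- find(b)
      if (ra != rb) cluster[max(ra, rb)] <- min(ra, rb)
    }
  }
  roots <- vapply(seq_len(n), find, 1L)
  out <- lapply(unique(roots), function(r) {
    m <- duplexes[roots == r, , drop = FALSE]
    list(left_start = as.integer(min(m$left_start)),
         left_end = as.integer(max(m$left_end)),
         right_start = as.integer(min(m$right_start)),
         right_end = as.integer(max(m$right_end)),
         reads = c(tapply(m$reads, m$dataset_id, sum)),
         n_members = nrow(m))
  })
  df <- data.frame(
    left_start = vapply(out, `[[`, 1L, "left_start"),
    left_end = vapply(out, `[[`, 1L, "left_end"),
    right_start = vapply(out, `[[`, 1L, "right_start"),
    right_end = vapply(out, `[[`, 1L, "right_end"),
    n_members = vapply(out, `[[`, 1L, "n_members"))
  df$reads <- lapply(out, `[[`, "reads")
  df <- df[order(df$left_start, df$right_start), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Assign base pairs to an accepted duplex by constrained co-folding
#'
#' PARIS spans bound a duplex but do not register individual pairs.
#' The two spans are concatenated with a 3-nt unpairable linker and
#' folded at MFE; only pairs with one partner in each span are returned.
#'
#' @param seq a [transcript_seq()].
#' @param left,right [interval()] spans of the duplex (left strictly 5').
#' @return two-column matrix of global `(i, j)` pairs; empty (with a
#'   warning) when the spans have no canonical complementarity.
#' @export
duplex_to_pairs <- function(seq, left, right) {
  res <- seq_chars(seq)
  ls <- res[left$start:left$end]
  rs <- res[right$start:right$end]
  nl <- length(ls)
  win <- paste(c(ls, "N", "N", "N", rs), collapse = "")
  fr <- fold(win)
  p <- fr$pairing
  ii <- which(p > seq_along(p))
  jj <- p[ii]
  cross <- ii <= nl & jj > nl + 3L
  ii <- ii[cross]; jj <- jj[cross]
  if (length(ii) == 0L) {
    warning(sprintf("duplex %s/%s: no canonical complementarity",
                    format(left), format(right)))
    return(matrix(integer(0), ncol = 2L, dimnames = list(NULL, c("i", "j"))))
  }
  cbind(i = ii + left$start - 1L, j = jj - nl - 3L + right$start - 1L)
}

#' Resolve the composite state of one nucleotide
#'
#' Evidence precedence: (1) membership in an accepted PARIS duplex
#' forces `paired`; (2) concordant PARS and DMS calls
#' (single+unprotected -> unpaired, double+protected -> paired) give
#' that state; (3) discordant determined channels adopt the MFE
#' prediction as tiebreak; a lone paired-type call
#' (`double` or `protected`) is honoured only when the MFE fold can
#' supply a partner, otherwise the position is designated unstructured;
#' a lone unpaired-type call is honoured as is; (4) with no evidence at
#' all the position is designated unstructured (`unpaired`) inside
#' probed regions and `no_data` outside.
#'
#' @param pars_call,dms_call channel calls (see [classify_pars()],
#'   [classify_dms()]).
#' @param paris_paired logical: member of an accepted PARIS duplex pair.
#' @param mfe_paired logical: paired in the MFE reference fold (inside
#'   [assemble()] this is the evidence-constrained fold).
#' @param in_probed_region logical: within the declared extent of the
#'   probing data.
#' @return list(state=, provenance=) with provenance one of `paris`,
#'   `pars+dms`, `mfe_resolved`, `default_unstructured`, `no_data`.
#' @export
resolve_nucleotide <- function(pars_call, dms_call, paris_paired,
                               mfe_paired, in_probed_region = TRUE) {
  if (isTRUE(paris_paired))
    return(list(state = "paired", provenance = "paris"))
  pars_det <- pars_call %in% c("single", "double")
  dms_det <- dms_call %in% c("unprotected", "protected")
  if (pars_det && dms_det) {
    if (pars_call == "single" && dms_call == "unprotected")
      return(list(state = "unpaired", provenance = "pars+dms"))
    if (pars_call == "double" && dms_call == "protected")
      return(list(state = "paired", provenance = "pars+dms"))
    return(list(state = if (isTRUE(mfe_paired)) "paired" else "unpaired",
                provenance = "mfe_resolved"))
  }
  if (pars_det || dms_det) {
    chan_paired <- (pars_det && pars_call == "double") ||
                   (dms_det && dms_call == "protected")
    if (!chan_paired)
      return(list(state = "unpaired", provenance = "pars+dms"))
    if (isTRUE(mfe_paired))
      return(list(state = "paired", provenance = "pars+dms"))
    return(list(state = "unpaired", provenance = "default_unstructured"))
  }
  if (in_probed_region)
    return(list(state = "unpaired", provenance = "default_unstructured"))
  list(state = "no_data", provenance = "no_data")
}

# Layering logic shared by call_pseudoknots() and assemble(): every
# helix that crosses another is pushed to pk_layer >= 1; among crossing
# helices the one whose removal leaves more pairs nested (i.e. the
# larger one) stays at layer 0, ties keeping the more 5' helix.
assign_pk_layers <- function(hs) {
  if (length(hs) == 0L) return(hs)
  npairs <- vapply(hs, function(h) nrow(h$pairs), 1L)
  starts <- vapply(hs, function(h) min(h$pairs), 1L)
  ord <- order(-npairs, starts)
  layer0 <- logical(length(hs))
  for (k in ord) {
    conflict <- any(layer0 & vapply(hs, helices_cross, logical(1),
                                    b = hs[[k]]))
    layer0[k] <- !conflict
  }
  for (k in seq_along(hs)) hs[[k]]$pk_layer <- 0L
  rest <- which(!layer0)
  rest <- rest[order(starts[rest])]
  layers <- list(which(layer0))
  for (k in rest) {
    t <- 2L
    repeat {
      members <- if (t <= length(layers)) layers[[t]] else integer(0)
      if (!any(vapply(hs[members], helices_cross, logical(1), b = hs[[k]])))
        break
      t <- t + 1L
    }
    hs[[k]]$pk_layer <- t - 1L
    if (length(layers) < t) layers[[t]] <- integer(0)
    layers[[t]] <- c(layers[[t]], k)
  }
  hs
}

#' Call pseudoknots by layering crossing helices
#'
#' Every helix that crosses another is assigned `pk_layer >= 1`; among a
#' crossing set, the helix whose removal leaves more pairs nested stays
#' at layer 0 (ties keep the more 5' helix nested). Elements are then
#' renamed by [name_elements()].
#'
#' @param model a [structure_model()].
#' @return the model with layers set and elements named.
#' @export
call_pseudoknots <- function(model) {
  model$helices <- assign_pk_layers(model$helices)
  name_elements(model)
}

#' Intervening nucleotides between the two strands of a duplex
#'
#' @param left a [helix()], or the left [interval()] span.
#' @param right the right [interval()] span (`left$end < right$start`);
#'   ignored when `left` is a helix.
#' @return integer count of intervening nucleotides
#'   (`right$start - left$end - 1`).
#' @export
loop_distance <- function(left, right = NULL) {
  if (inherits(left, "helix")) {
    h <- left
    left <- helix_five_prime(h); right <- helix_three_prime(h)
  }
  if (left$end >= right$start)
    stop("loop_distance: left span must end strictly before right span")
  right$start - left$end - 1L
}

# constrained MFE fold over `allowed` positions; transcripts longer than
# 3000 nt are folded in 1500-nt blocks with 250-nt overlap (first block
# to claim a position wins)
constrained_fold_pairs <- function(res, allowed) {
  n <- length(res)
  pairing <- integer(n)
  if (!any(allowed)) return(pairing)
  if (n <= 3000L) {
    fr <- fold(paste(res, collapse = ""), forbidden = which(!allowed))
    return(fr$pairing)
  }
  blocks <- fold_windows(1L, n, 1500L, 250L)
  for (b in seq_len(nrow(blocks))) {
    a <- blocks[b, 1L]; z <- blocks[b, 2L]
    local_forbidden <- which(!allowed[a:z])
    fr <- fold(paste(res[a:z], collapse = ""), forbidden = local_forbidden)
    add <- which(fr$pairing > seq_along(fr$pairing))
    for (ii in add) {
      i <- ii + a - 1L; j <- fr$pairing[ii] + a - 1L
      if (pairing[i] == 0L && pairing[j] == 0L) {
        kept <- which(pairing > seq_len(n))
        crosses <- any((kept < i & i < pairing[kept] & pairing[kept] < j) |
                       (i < kept & kept < j & j < pairing[kept]))
        if (!crosses) { pairing[i] <- j; pairing[j] <- i }
      }
    }
  }
  pairing
}

#' Assemble the composite structure model
#'
#' Pipeline: classify the probing track; cluster PARIS duplex groups,
#' apply the acceptance criteria, and register pairs of accepted
#' duplexes by co-folding; fold declared uncovered regions by windowed
#' MFE scanning; build the evidence-constrained MFE reference fold of
#' the probed region (positions whose probing evidence is unpaired are
#' forbidden from pairing); resolve each nucleotide under the precedence
#' of [resolve_nucleotide()]; demote paired calls that found no partner
#' (designated unstructured); layer pseudoknots and name elements.
#'
#' @param track a `probing_track` covering the probed region.
#' @param duplexes a `duplex_table` of PARIS duplex groups (may be
#'   empty: `NULL` or 0 rows).
#' @param seq a [transcript_seq()].
#' @param criteria a [paris_criteria()].
#' @param cut a [cutoffs()].
#' @param uncovered_regions list of [interval()]s without probing
#'   coverage, folded by windowed MFE scanning
#'   (provenance `mfe_only_region`).
#' @param window,overlap windowed-fold parameters for uncovered regions.
#' @param slack duplex clustering slack in nt.
#' @return A named [structure_model()] with per-position `provenance`;
#'   attributes: `clusters` (duplex cluster table with `accepted`),
#'   `paris_pairs` (registered PARIS pair matrix), `rule_counts`
#'   (provenance tabulation), `mfe_regions`.
#' @export
assemble <- function(track, duplexes, seq, criteria = paris_criteria(),
                     cut = cutoffs(), uncovered_regions = list(),
                     window = 100L, overlap = 20L, slack = 5L) {
  n <- length(seq)
  if (is.null(duplexes))
    duplexes <- data.frame(dataset_id = character(0), left_start = integer(0),
                           left_end = integer(0), right_start = integer(0),
                           right_end = integer(0), reads = integer(0))
  if (nrow(track) > 0L && (max(track$position) > n || min(track$position) < 1L))
    stop("assemble: track positions outside transcript")
  if (nrow(duplexes) > 0L && max(duplexes$right_end) > n)
    stop("assemble: duplex spans outside transcript")
  for (r in uncovered_regions) if (r$end > n)
    stop("assemble: uncovered region outside transcript")
  res <- seq_chars(seq)

  calls <- classify_track(track, cut)
  pars_call <- rep("no_data", n); dms_call <- rep("no_data", n)
  pars_call[calls$position] <- calls$pars_call
  dms_call[calls$position] <- calls$dms_call

  # -- PARIS: cluster, accept, register pairs ------------------------
  clusters <- cluster_duplexes(duplexes, slack = slack)
  paris_pairs <- matrix(integer(0), ncol = 2L)
  if (nrow(clusters) > 0L) {
    clusters$accepted <- vapply(seq_len(nrow(clusters)), function(k)
      accept_duplex(unname(unlist(clusters$reads[[k]])), criteria),
      logical(1))
    for (k in which(clusters$accepted)) {
      pp <- duplex_to_pairs(
        seq, interval(clusters$left_start[k], clusters$left_end[k]),
        interval(clusters$right_start[k], clusters$right_end[k]))
      if (nrow(pp) > 0L) paris_pairs <- rbind(paris_pairs, pp)
    }
  }
  pairing <- integer(n)
  registered <- logical(nrow(paris_pairs))
  if (nrow(paris_pairs) > 0L) {
    for (r in seq_len(nrow(paris_pairs))) {
      i <- paris_pairs[r, 1L]; j <- paris_pairs[r, 2L]
      if (pairing[i] == 0L && pairing[j] == 0L) {
        pairing[i] <- j; pairing[j] <- i
        registered[r] <- TRUE
      }
    }
  }
  paris_pairs <- paris_pairs[registered, , drop = FALSE]
  paris_paired <- pairing > 0L

  # -- MFE-only (uncovered) regions ----------------------------------
  mfe_region_mask <- logical(n)
  mfe_pairing <- integer(n)
  for (r in uncovered_regions) {
    frag <- fold_uncovered_region(seq, r, window = window, overlap = overlap)
    sel <- r$start:r$end
    keep <- sel[frag$pairing[sel] > 0L & !paris_paired[sel] &
                  !paris_paired[pmax(1L, frag$pairing[sel])]]
    mfe_pairing[keep] <- frag$pairing[keep]
    mfe_region_mask[sel] <- TRUE
  }

  # -- evidence-constrained reference fold of the probed region ------
  # allowed: evidence compatible with pairing (double/protected calls,
  # discordant channels); forbidden: unpaired evidence, no evidence,
  # PARIS positions (their partners are fixed), MFE-only regions
  probed <- track$position
  in_probed <- logical(n)
  if (length(probed) > 0L) in_probed[min(probed):max(probed)] <- TRUE
  suggests_paired <- (pars_call == "double" | dms_call == "protected")
  discordant <- (pars_call == "single" & dms_call == "protected") |
                (pars_call == "double" & dms_call == "unprotected")
  allowed <- in_probed & !paris_paired & !mfe_region_mask &
    (suggests_paired | discordant) &
    !(pars_call == "single" & dms_call == "unprotected")
  cons_pairing <- constrained_fold_pairs(res, allowed)
  mfe_paired <- (cons_pairing > 0L) | (mfe_pairing > 0L)

  # -- per-nucleotide resolution -------------------------------------
  state <- character(n); prov <- character(n)
  for (i in seq_len(n)) {
    if (mfe_region_mask[i] && !in_probed[i] && !paris_paired[i]) {
      state[i] <- if (mfe_pairing[i] > 0L) "paired" else "unpaired"
      prov[i] <- "mfe_only_region"
      next
    }
    r <- resolve_nucleotide(pars_call[i], dms_call[i], paris_paired[i],
                            cons_pairing[i] > 0L, in_probed[i])
    state[i] <- r$state; prov[i] <- r$provenance
  }

  # -- partner harvesting --------------------------------------------
  for (i in which(cons_pairing > seq_len(n))) {
    j <- cons_pairing[i]
    if (state[i] == "paired" && state[j] == "paired" &&
        pairing[i] == 0L && pairing[j] == 0L) {
      pairing[i] <- j; pairing[j] <- i
    }
  }
  for (i in which(mfe_pairing > seq_len(n))) {
    j <- mfe_pairing[i]
    if (pairing[i] == 0L && pairing[j] == 0L) {
      pairing[i] <- j; pairing[j] <- i
    }
  }
  orphans <- which(state == "paired" & pairing == 0L)
  state[orphans] <- "unpaired"
  prov[orphans] <- "default_unstructured"

  hs <- assign_pk_layers(helices_from_pairing(pairing))
  model <- structure_model(seq, hs, per_nt_state = state, provenance = prov)
  model <- name_elements(model)
  attr(model, "clusters") <- clusters
  attr(model, "paris_pairs") <- paris_pairs
  attr(model, "rule_counts") <- table(prov)
  attr(model, "mfe_regions") <- uncovered_regions
  model
}

#' Write the element table of a named model
#'
#' One row per helix: name, 5' span, 3' span, pair count, pk layer, and
#' the dominant provenance among its positions.
#'
#' @param model output of [assemble()] (or any named model).
#' @param path optional output TSV path.
#' @return the table (data.frame), invisibly.
#' @export
element_table <- function(model, path = NULL) {
  rows <- lapply(model$helices, function(h) {
    pos <- c(h$pairs)
    prov <- if (!is.null(model$provenance))
      names(sort(table(model$provenance[pos]), decreasing = TRUE))[1L]
      else NA_character_
    data.frame(name = h$name,
               five_prime = format(helix_five_prime(h)),
               three_prime = format(helix_three_prime(h)),
               n_pairs = nrow(h$pairs), pk_layer = h$pk_layer,
               provenance = prov, stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  if (is.null(df)) df <- data.frame(name = character(0))
  if (!is.null(path))
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}
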