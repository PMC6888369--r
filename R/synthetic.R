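# Generator of ground-truth transcripts, structures, probing tracks,
# duplex tables, homolog alignments, and annotations with the
# statistical structure the analysis assumes: higher V1/lower S1 counts
# on paired nucleotides and the reverse on unpaired ones; DMS counts
# well above the cutoff on unpaired A/C and low on paired A/C; PARIS
# read support concentrated on true duplexes across replicate datasets;
# homolog alignments with compensatory substitutions inside helices.

#' Simulation configuration
#'
#' Count models are Poisson with means chosen to straddle the default
#' classification cutoffs with ~5-fold separation (unpaired S1:V1 ~ 5 >
#' 1 > paired ~ 0.2; DMS 60 > 20 > 5), so that calibration is
#' recoverable and noise is meaningful.
#'
#' @param transcript_len transcript length in nt (default 1000).
#' @param n_helices number of nested hairpin helices (default 15).
#' @param n_long_range number of long-range duplexes (loop distance of
#'   at least 100 nt; default 2), emitted as PARIS duplex groups.
#' @param n_pk number of H-type pseudoknots (default 1), emitted as
#'   PARIS duplex groups crossing a host hairpin.
#' @param helix_len 2-vector range of helix lengths in bp.
#' @param loop_len 2-vector range of hairpin-loop lengths in nt.
#' @param lr_len 2-vector range of long-range duplex lengths in bp.
#' @param pk_len pseudoknot duplex length in bp.
#' @param s1_unpaired,s1_paired,v1_unpaired,v1_paired,dms_unpaired,dms_paired
#'   Poisson means of the count channels by true state.
#' @param paris_read_mean Poisson mean of PARIS reads per true duplex
#'   per dataset (default 8).
#' @param paris_background expected number of false duplex groups per
#'   dataset (default 1), with low read support.
#' @param n_datasets number of PARIS replicate datasets (default 3).
#' @param coverage_fraction fraction of positions with track coverage
#'   (default 1.0; uncovered rows carry NA counts).
#' @param n_homologs total alignment rows including the reference
#'   (default 53).
#' @param substitution_rate per-position substitution probability in
#'   homolog rows (default 0.15).
#' @param p_cov probability that an in-helix substitution is
#'   compensatory, preserving a canonical pair (default 1.0).
#' @param conserved_fraction fraction of hairpin helices planted as
#'   conserved; the rest are deleted from most homologs (default 0.75).
#' @param noise_free logical: deterministic, fully separated counts,
#'   full coverage, fixed PARIS reads, no background (default FALSE).
#' @return object of class `sim_config`.
#' @export
sim_config <- function(transcript_len = 1000L, n_helices = 15L,
                       n_long_range = 2L, n_pk = 1L,
                       helix_len = c(5L, 12L), loop_len = c(4L, 8L),
                       lr_len = c(18L, 25L), pk_len = 6L,
                       s1_unpaired = 10, s1_paired = 2,
                       v1_unpaired = 2, v1_paired = 10,
                       dms_unpaired = 60, dms_paired = 5,
                       paris_read_mean = 8, paris_background = 1,
                       n_datasets = 3L, coverage_fraction = 1.0,
                       n_homologs = 53L, substitution_rate = 0.15,
                       p_cov = 1.0, conserved_fraction = 0.75,
                       noise_free = FALSE) {
  cfg <- as.list(environment())
  stopifnot(transcript_len >= 100L, n_helices >= 1L,
            coverage_fraction > 0, coverage_fraction <= 1,
            s1_unpaired / max(v1_unpaired, 0.1) > 1,
            s1_paired / v1_paired < 1,
            dms_unpaired > 20, dms_paired < 20)
  class(cfg) <- "sim_config"
  cfg
}

.complement <- c(A = "U", C = "G", G = "C", U = "A")

#' Generate a synthetic ground-truth bundle
#'
#' Plants nested hairpins, long-range duplexes, and H-type pseudoknots
#' along a random transcript; makes planted pairs exactly
#' Watson-Crick complementary; draws probing counts from the configured
#' Poisson models; emits PARIS duplex records per replicate dataset;
#' and mutates homolog rows with compensatory changes inside helices.
#' Deterministic for a fixed seed.
#'
#' @param config a [sim_config()].
#' @param seed integer RNG seed.
#' @return A `sim_bundle` list: `seq` ([transcript_seq()]), `truth`
#'   (list: pairing, state, helices table, model), `track`
#'   (`probing_track`), `duplexes` (`duplex_table`), `alignment`
#'   (`homolog_alignment`), `annotations`, `conserved_labels`, `config`.
#' @export
generate <- function(config = sim_config(), seed = 1L) {
  set.seed(seed)
  cfg <- config
  n <- cfg$transcript_len

  # ---- plan blocks 5' to 3' ---------------------------------------
  rint <- function(rng) if (rng[1L] == rng[2L]) rng[1L] else
    sample(rng[1L]:rng[2L], 1L)
  blocks <- list()
  add <- function(type, size, id) blocks[[length(blocks) + 1L]] <<-
    list(type = type, size = size, id = id)
  n_h <- cfg$n_helices
  first_batch <- ceiling(n_h / 2)
  pk_host <- if (cfg$n_pk > 0L) seq_len(min(cfg$n_pk, first_batch)) else integer(0)
  hp_len <- vapply(seq_len(n_h), function(i) rint(cfg$helix_len), 1L)
  hp_loop <- vapply(seq_len(n_h), function(i) rint(cfg$loop_len), 1L)
  hp_loop[pk_host] <- cfg$pk_len + 6L  # room for the pseudoknot arm
  # the host stem must out-size the pseudoknot duplex so that the
  # layering rule (more pairs stay nested) keeps the host at layer 0
  hp_len[pk_host] <- pmax(hp_len[pk_host], cfg$pk_len + 2L)
  lr_len <- vapply(seq_len(cfg$n_long_range), function(i) rint(cfg$lr_len), 1L)
  if (cfg$n_long_range > 0L) add("lr_left", lr_len[1L], 1L)
  for (i in seq_len(first_batch)) add("hairpin", 2L * hp_len[i] + hp_loop[i], i)
  if (cfg$n_long_range > 1L)
    for (k in 2L:cfg$n_long_range) add("lr_left", lr_len[k], k)
  if (n_h > first_batch)
    for (i in (first_batch + 1L):n_h)
      add("hairpin", 2L * hp_len[i] + hp_loop[i], i)
  for (k in seq_len(cfg$n_pk)) add("pk_arm", cfg$pk_len, k)
  if (cfg$n_long_range > 1L)
    for (k in cfg$n_long_range:2L) add("lr_right", lr_len[k], k)
  if (cfg$n_long_range > 0L) add("lr_right", lr_len[1L], 1L)

  total <- sum(vapply(blocks, `[[`, 1L, "size"))
  nb <- length(blocks)
  free <- n - total
  if (free < 2L * (nb + 1L))
    stop("generate: infeasible packing -- too many helices for the length")
  gaps <- as.vector(stats::rmultinom(1L, free - 2L * (nb + 1L),
                                     rep(1, nb + 1L))) + 2L

  pairing <- integer(n)
  helices <- list()
  lr_left_span <- vector("list", cfg$n_long_range)
  pk_arm_span <- vector("list", cfg$n_pk)
  pos <- 0L
  plant <- function(i1, i2, j1, j2) {
    # pair [i1,i2] with [j1,j2] antiparallel
    L <- i2 - i1 + 1L
    for (t in 0:(L - 1L)) {
      pairing[i1 + t] <<- j2 - t
      pairing[j2 - t] <<- i1 + t
    }
  }
  truth_rows <- list()
  for (b in seq_along(blocks)) {
    pos <- pos + gaps[b]
    blk <- blocks[[b]]
    a <- pos + 1L; z <- pos + blk$size
    if (blk$type == "hairpin") {
      L <- hp_len[blk$id]
      plant(a, a + L - 1L, z - L + 1L, z)
      truth_rows[[length(truth_rows) + 1L]] <- data.frame(
        type = "hairpin", id = blk$id, five_start = a, five_end = a + L - 1L,
        three_start = z - L + 1L, three_end = z, len = L)
      if (blk$id %in% pk_host) {
        # pseudoknot arm inside this loop, 3 nt after the 5' stem
        k <- which(pk_host == blk$id)
        s <- a + L + 3L
        pk_arm_span[[k]] <- c(s, s + cfg$pk_len - 1L)
      }
    } else if (blk$type == "lr_left") {
      lr_left_span[[blk$id]] <- c(a, z)
    } else if (blk$type == "lr_right") {
      ls <- lr_left_span[[blk$id]]
      plant(ls[1L], ls[2L], a, z)
      truth_rows[[length(truth_rows) + 1L]] <- data.frame(
        type = "long_range", id = blk$id, five_start = ls[1L],
        five_end = ls[2L], three_start = a, three_end = z,
        len = ls[2L] - ls[1L] + 1L)
    } else if (blk$type == "pk_arm") {
      as_ <- pk_arm_span[[blk$id]]
      plant(as_[1L], as_[2L], a, z)
      truth_rows[[length(truth_rows) + 1L]] <- data.frame(
        type = "pseudoknot", id = blk$id, five_start = as_[1L],
        five_end = as_[2L], three_start = a, three_end = z,
        len = cfg$pk_len)
    }
    pos <- z
  }
  truth_helices <- do.call(rbind, truth_rows)

  # ---- sequence: random, then complementary inside planted pairs ---
  res <- sample(c("A", "C", "G", "U"), n, replace = TRUE)
  up <- which(pairing > seq_len(n))
  res[pairing[up]] <- .complement[res[up]]
  seq <- transcript_seq(sprintf("synthetic_%d", seed),
                        paste(res, collapse = ""))
  state <- ifelse(pairing > 0L, "paired", "unpaired")

  # ---- probing track ----------------------------------------------
  paired <- pairing > 0L
  if (cfg$noise_free) {
    s1 <- ifelse(paired, 0, 50)
    v1 <- ifelse(paired, 50, 0)
    dms <- ifelse(paired, 0, 100)
    covered <- rep(TRUE, n)
  } else {
    s1 <- stats::rpois(n, ifelse(paired, cfg$s1_paired, cfg$s1_unpaired))
    v1 <- stats::rpois(n, ifelse(paired, cfg$v1_paired, cfg$v1_unpaired))
    dms <- stats::rpois(n, ifelse(paired, cfg$dms_paired, cfg$dms_unpaired))
    covered <- stats::runif(n) <= cfg$coverage_fraction
  }
  dms[!(res %in% c("A", "C"))] <- NA
  s1[!covered] <- NA; v1[!covered] <- NA; dms[!covered] <- NA
  track <- validate_track(data.frame(
    position = seq_len(n), base = res, s1 = as.numeric(s1),
    v1 = as.numeric(v1), dms = as.numeric(dms), stringsAsFactors = FALSE))

  # ---- PARIS duplex tables ----------------------------------------
  emit <- truth_helices[truth_helices$type %in% c("long_range", "pseudoknot"), ,
                        drop = FALSE]
  dup_rows <- list()
  for (d in seq_len(cfg$n_datasets)) {
    ds <- sprintf("DS%d", d)
    for (r in seq_len(nrow(emit))) {
      reads <- if (cfg$noise_free) 8L else
        stats::rpois(1L, cfg$paris_read_mean)
      if (reads >= 1L)
        dup_rows[[length(dup_rows) + 1L]] <- data.frame(
          dataset_id = ds, left_start = emit$five_start[r],
          left_end = emit$five_end[r], right_start = emit$three_start[r],
          right_end = emit$three_end[r], reads = reads)
    }
    if (!cfg$noise_free && cfg$paris_background > 0) {
      nb_bg <- stats::rpois(1L, cfg$paris_background)
      for (q in seq_len(nb_bg)) {
        a <- sample.int(n - 200L, 1L)
        w <- sample(10:20, 1L)
        gap <- sample(60:150, 1L)
        if (a + w + gap + w > n) next
        dup_rows[[length(dup_rows) + 1L]] <- data.frame(
          dataset_id = ds, left_start = a, left_end = a + w - 1L,
          right_start = a + w + gap, right_end = a + w + gap + w - 1L,
          reads = 1L + stats::rpois(1L, 1))
      }
    }
  }
  duplexes <- validate_duplexes(do.call(rbind, dup_rows))

  # ---- homolog alignment ------------------------------------------
  n_hp <- sum(truth_helices$type == "hairpin")
  n_cons <- round(cfg$conserved_fraction * n_hp)
  hp_idx <- which(truth_helices$type == "hairpin")
  conserved <- rep(TRUE, nrow(truth_helices))
  if (n_cons < n_hp)
    conserved[hp_idx[(n_cons + 1L):n_hp]] <- FALSE
  n_other <- cfg$n_homologs - 1L
  canon_types <- c("AU", "UA", "GC", "CG", "GU", "UG")
  rows <- list(reference = paste(res, collapse = ""))
  # rows deleting each non-conserved helix: all but 5 homologs
  del_rows <- lapply(seq_len(nrow(truth_helices)), function(r)
    if (conserved[r]) integer(0) else sample.int(n_other, n_other - 5L))
  for (h in seq_len(n_other)) {
    row <- res
    mut <- stats::runif(n) < cfg$substitution_rate
    # unpaired positions: free substitution
    for (i in which(mut & !paired))
      row[i] <- sample(setdiff(c("A", "C", "G", "U"), res[i]), 1L)
    # paired positions: compensatory with prob p_cov (both sides move to
    # another canonical pair type), otherwise one-sided
    for (i in which(mut & pairing > seq_len(n))) {
      j <- pairing[i]
      if (stats::runif(1L) < cfg$p_cov) {
        old <- paste0(res[i], res[j])
        newt <- sample(setdiff(canon_types, old), 1L)
        row[i] <- substr(newt, 1L, 1L); row[j] <- substr(newt, 2L, 2L)
      } else {
        row[i] <- sample(setdiff(c("A", "C", "G", "U"), res[i]), 1L)
      }
    }
    for (r in seq_len(nrow(truth_helices))) {
      if (h %in% del_rows[[r]]) {
        row[truth_helices$five_start[r]:truth_helices$five_end[r]] <- "-"
        row[truth_helices$three_start[r]:truth_helices$three_end[r]] <- "-"
      }
    }
    rows[[sprintf("homolog_%02d", h)]] <- paste(row, collapse = "")
  }

  # ---- truth model and annotations --------------------------------
  truth_model <- structure_model(
    seq, assign_pk_layers(helices_from_pairing(pairing)),
    per_nt_state = state)
  truth_model <- name_elements(truth_model)
  aln <- homolog_alignment(unlist(rows),
                           ss_cons = write_dotbracket(truth_model))

  # annotation host: the last hairpin, which is never a pseudoknot host,
  # so its loop is genuinely single-stranded
  hp_rows <- truth_helices[truth_helices$type == "hairpin", ]
  host <- hp_rows[nrow(hp_rows), ]
  loop_iv <- interval(host$five_end + 1L, host$three_start - 1L)
  stem_iv <- interval(host$five_start, host$five_end)
  pk_row <- truth_helices[truth_helices$type == "pseudoknot", ]
  annotations <- list(
    annotation("mirna_site",
               interval(loop_iv$start, min(loop_iv$start + 5L, loop_iv$end)),
               label = "synthetic-miR-site"),
    annotation("protein_site", stem_iv, label = "synthetic-protein-site"))
  if (nrow(pk_row) > 0L) {
    mpos <- pk_row$five_start[1L] + 2L
    annotations <- c(annotations, list(
      annotation("modification", interval(mpos, mpos), label = "m6A",
                 payload = "m6A")))
  }
  # substitution destroying a stem pair (reference base at that position)
  mut_pos <- stem_iv$start + 1L
  annotations <- c(annotations, list(
    annotation("mutation", interval(mut_pos, mut_pos),
               label = sprintf("%s%d%s", res[mut_pos], mut_pos,
                               setdiff(c("A", "C", "G", "U"),
                                       c(res[mut_pos],
                                         .complement[res[mut_pos]]))[1L]),
               payload = sprintf("%s%d%s", res[mut_pos], mut_pos,
                                 setdiff(c("A", "C", "G", "U"),
                                         c(res[mut_pos],
                                           .complement[res[mut_pos]]))[1L]))))

  structure(list(seq = seq, track = track, duplexes = duplexes,
                 alignment = aln, annotations = annotations,
                 truth = list(pairing = pairing, state = state,
                              helices = truth_helices, model = truth_model),
                 conserved_labels = conserved, config = cfg, seed = seed),
            class = "sim_bundle")
}

#' @export
print.sim_bundle <- function(x, ...) {
  cat(sprintf("<sim_bundle> seed %d: %d nt, %d planted helices (%d PK), %d duplex records\n",
              x$seed, length(x$seq), nrow(x$truth$helices),
              sum(x$truth$helices$type == "pseudoknot"), nrow(x$duplexes)))
  invisible(x)
}

#' Write a bundle to disk
#'
#' Emits transcript FASTA, truth dot-bracket, track TSV, duplex TSV,
#' Stockholm alignment, and annotation TSV in the formats consumed by
#' the other modules.
#'
#' @param bundle a `sim_bundle`.
#' @param outdir output directory (created if needed).
#' @return named character vector of written paths.
#' @export
write_bundle <- function(bundle, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    fasta = file.path(outdir, "transcript.fa"),
    truth = file.path(outdir, "truth.dbn"),
    track = file.path(outdir, "track.tsv"),
    duplexes = file.path(outdir, "duplexes.tsv"),
    stockholm = file.path(outdir, "homologs.sto"),
    annotations = file.path(outdir, "annotations.tsv"))
  write_fasta(bundle$seq, paths["fasta"])
  write_dotbracket_file(bundle$truth$model, paths["truth"])
  write_track(bundle$track, paths["track"])
  write_duplexes(bundle$duplexes, paths["duplexes"])
  write_stockholm(bundle$alignment, paths["stockholm"])
  write_annotations(bundle$annotations, paths["annotations"])
  paths
}

#' Compare a model against the planted truth
#'
#' @param model a [structure_model()].
#' @param truth the `truth` element of a `sim_bundle` (or a pairing
#'   vector).
#' @return list: base-level `sensitivity`, `ppv`, `accuracy` (state
#'   match over all positions), and `helix_recall` (a planted helix is
#'   recovered iff >= 90% of its pairs are present with identical
#'   partners).
#' @export
truth_compare <- function(model, truth) {
  pairing_t <- if (is.list(truth)) truth$pairing else truth
  pairing_m <- model$pairing
  stopifnot(length(pairing_t) == length(pairing_m))
  tp <- sum(pairing_t > 0L & pairing_m > 0L)
  sens <- if (sum(pairing_t > 0L) == 0L) NA_real_ else
    tp / sum(pairing_t > 0L)
  ppv <- if (sum(pairing_m > 0L) == 0L) NA_real_ else
    tp / sum(pairing_m > 0L)
  state_t <- ifelse(pairing_t > 0L, "paired", "unpaired")
  acc <- mean(state_t == model$per_nt_state)
  helix_recall <- NA_real_
  if (is.list(truth) && !is.null(truth$helices)) {
    th <- truth$helices
    rec <- vapply(seq_len(nrow(th)), function(r) {
      ii <- th$five_start[r]:th$five_end[r]
      mean(pairing_m[ii] == pairing_t[ii]) >= 0.9
    }, logical(1))
    helix_recall <- mean(rec)
  }
  list(sensitivity = sens, ppv = ppv, accuracy = acc,
       helix_recall = helix_recall)
}
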