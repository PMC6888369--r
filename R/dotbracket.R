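# Dot-bracket serialization with pseudoknot layers, element naming,
# and connect-table / BED export.

.db_open  <- c("(", "[", "{", "<", LETTERS)
.db_close <- c(")", "]", "}", ">", letters)

#' Parse a dot-bracket string into a structure model
#'
#' The bracket alphabet is `()` for the nested layer plus pseudoknot
#' tiers `[]`, `{}`, `<>`, then `Aa` .. `Zz`, in that order. Each tier
#' must be balanced on its own; `pk_layer` of the resulting helices is
#' the bracket tier.
#'
#' @param text dot-bracket string, same length as `seq`.
#' @param seq a [transcript_seq()].
#' @return A [structure_model()] that reproduces `text` on round-trip
#'   through [write_dotbracket()].
#' @export
parse_dotbracket <- function(text, seq) {
  stopifnot(is.character(text), length(text) == 1L)
  n <- length(seq)
  if (nchar(text) != n)
    stop(sprintf("parse_dotbracket: string length %d != sequence length %d",
                 nchar(text), n))
  chars <- strsplit(text, "")[[1]]
  known <- c(".", "-", ",", "_", ":", "~", .db_open, .db_close)
  bad <- which(!(chars %in% known))
  if (length(bad) > 0L)
    stop(sprintf("parse_dotbracket: unknown character '%s' at column %d",
                 chars[bad[1L]], bad[1L]))
  pair_rows <- list()
  for (tier in seq_along(.db_open)) {
    op <- .db_open[tier]; cl <- .db_close[tier]
    if (!any(chars == op) && !any(chars == cl)) next
    stack <- integer(0)
    for (k in seq_len(n)) {
      if (chars[k] == op) {
        stack <- c(stack, k)
      } else if (chars[k] == cl) {
        if (length(stack) == 0L)
          stop(sprintf("parse_dotbracket: unbalanced '%s' at column %d", cl, k))
        i <- stack[length(stack)]
        stack <- stack[-length(stack)]
        pair_rows[[length(pair_rows) + 1L]] <- c(i, k, tier - 1L)
      }
    }
    if (length(stack) > 0L)
      stop(sprintf("parse_dotbracket: unbalanced '%s' at column %d",
                   op, stack[1L]))
  }
  if (length(pair_rows) == 0L)
    return(structure_model(seq, list()))
  tab <- do.call(rbind, pair_rows)
  pairing_by_tier <- split.data.frame(as.data.frame(tab), tab[, 3L])
  helices <- list()
  for (grp in pairing_by_tier) {
    pv <- integer(n)
    pv[grp[[1L]]] <- grp[[2L]]
    pv[grp[[2L]]] <- grp[[1L]]
    hs <- helices_from_pairing(pv)
    tier <- grp[[3L]][1L]
    hs <- lapply(hs, function(h) { h$pk_layer <- as.integer(tier); h })
    helices <- c(helices, hs)
  }
  helices <- helices[order(vapply(helices, function(h) min(h$pairs), 1L))]
  structure_model(seq, helices)
}

#' Write a structure model as a dot-bracket string
#'
#' Inverse of [parse_dotbracket()]. Tier assignment is deterministic:
#' helices with `pk_layer` 0 use `()`; every other helix gets the lowest
#' available tier >= 1 in which it crosses no helix already placed there
#' (helices visited 5' to 3').
#'
#' @param model a [structure_model()].
#' @return dot-bracket character scalar.
#' @export
write_dotbracket <- function(model) {
  n <- length(model$seq)
  chars <- rep(".", n)
  hs <- model$helices
  if (length(hs) == 0L) return(paste(chars, collapse = ""))
  ord <- order(vapply(hs, function(h) min(h$pairs), 1L))
  hs <- hs[ord]
  tiers <- integer(length(hs))
  placed <- list()  # tier -> list of helices
  for (k in seq_along(hs)) {
    h <- hs[[k]]
    if (h$pk_layer == 0L) {
      t <- 1L
    } else {
      t <- 2L
      repeat {
        conflict <- length(placed) >= t &&
          any(vapply(placed[[t]], helices_cross, logical(1), a = h))
        if (!conflict) break
        t <- t + 1L
      }
    }
    if (t > length(.db_open))
      stop("write_dotbracket: ran out of bracket tiers")
    if (length(placed) < t) placed[[t]] <- list()
    if (h$pk_layer == 0L &&
        any(vapply(placed[[1L]], helices_cross, logical(1), a = h)))
      stop("write_dotbracket: crossing helices on pk_layer 0")
    placed[[t]] <- c(placed[[t]], list(h))
    tiers[k] <- t
  }
  for (k in seq_along(hs)) {
    h <- hs[[k]]; t <- tiers[k]
    chars[h$pairs[, 1L]] <- .db_open[t]
    chars[h$pairs[, 2L]] <- .db_close[t]
  }
  paste(chars, collapse = "")
}

#' Name structural elements 5' to 3'
#'
#' Nested helices (pk_layer 0) are named `H1..Hn` ordered by their
#' 5'-most position; pseudoknotted helices are named `PK1..PKm` in the
#' same order. Multiway junctions are detected from the nesting forest
#' of layer-0 helices: a loop closed by one helix and containing `k >= 2`
#' child helices is a `(k+1)WJ`.
#'
#' @param model a [structure_model()].
#' @return The model with helix names and `junctions` filled in.
#' @export
name_elements <- function(model) {
  hs <- model$helices
  if (length(hs) == 0L) return(model)
  starts <- vapply(hs, function(h) min(h$pairs), 1L)
  ord <- order(starts)
  hs <- hs[ord]
  hn <- 0L; pkn <- 0L
  for (k in seq_along(hs)) {
    if (hs[[k]]$pk_layer == 0L) {
      hn <- hn + 1L
      hs[[k]]$name <- sprintf("H%d", hn)
    } else {
      pkn <- pkn + 1L
      hs[[k]]$name <- sprintf("PK%d", pkn)
    }
  }
  # junctions among layer-0 helices: direct-containment forest
  l0 <- Filter(function(h) h$pk_layer == 0L, hs)
  junctions <- list()
  if (length(l0) >= 2L) {
    span <- t(vapply(l0, function(h) c(min(h$pairs), max(h$pairs)),
                     integer(2)))
    parent <- rep(NA_integer_, length(l0))
    for (a in seq_along(l0)) {
      best <- NA_integer_; bestw <- Inf
      for (b in seq_along(l0)) {
        if (a == b) next
        if (span[b, 1L] < span[a, 1L] && span[a, 2L] < span[b, 2L]) {
          w <- span[b, 2L] - span[b, 1L]
          if (w < bestw) { bestw <- w; best <- b }
        }
      }
      parent[a] <- best
    }
    jn <- 0L
    for (b in seq_along(l0)) {
      kids <- which(!is.na(parent) & parent == b)
      if (length(kids) >= 2L) {
        jn <- jn + 1L
        junctions[[jn]] <- list(
          name = sprintf("%dWJ-%d", length(kids) + 1L, jn),
          members = c(l0[[b]]$name,
                      vapply(l0[kids], function(h) h$name, "")))
      }
    }
  }
  model$helices <- hs
  model$junctions <- junctions
  model
}

#' Write a connect-table (CT) file
#'
#' @param model a [structure_model()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_ct <- function(model, path) {
  n <- length(model$seq)
  res <- seq_chars(model$seq)
  con <- file(path, "w")
  on.exit(close(con))
  energy <- attr(model, "energy")
  writeLines(sprintf("%d %s%s", n, model$seq$id,
                     if (is.null(energy)) "" else
                       sprintf(" ENERGY = %.1f", energy)), con)
  lines <- sprintf("%d %s %d %d %d %d",
                   seq_len(n), res, seq_len(n) - 1L,
                   c(seq_len(n - 1L) + 1L, 0L), model$pairing, seq_len(n))
  writeLines(lines, con)
  invisible(path)
}

#' Export helix strands as BED6
#'
#' Coordinates are converted to 0-based half-open on write; everything
#' else in the package is 1-based inclusive.
#'
#' @param model a named [structure_model()] (run [name_elements()] first).
#' @param path output file path.
#' @param chrom chromosome/transcript name for column 1.
#' @return `path`, invisibly.
#' @export
write_helix_bed <- function(model, path, chrom = model$seq$id) {
  rows <- character(0)
  for (h in model$helices) {
    nm <- ifelse(is.na(h$name), "helix", h$name)
    for (side in list(c(helix_five_prime(h), "5p"),
                      c(helix_three_prime(h), "3p"))) {
      iv <- interval(side[[1L]], side[[2L]])
      rows <- c(rows, sprintf("%s\t%d\t%d\t%s_%s\t0\t+",
                              chrom, iv$start - 1L, iv$end, nm, side[[3L]]))
    }
  }
  writeLines(rows, path)
  invisible(path)
}

#' Write / read dot-bracket files with a FASTA-style header
#'
#' @param model a [structure_model()].
#' @param path file path.
#' @param energy optional free energy written as a comment line.
#' @return For the writer, `path` invisibly; for the reader, a
#'   [structure_model()].
#' @export
write_dotbracket_file <- function(model, path, energy = NULL) {
  lines <- c(sprintf(">%s", model$seq$id), model$seq$residues,
             write_dotbracket(model))
  if (!is.null(energy)) lines <- c(lines, sprintf("# energy %.1f", energy))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_dotbracket_file
#' @export
read_dotbracket_file <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines)]
  if (length(lines) < 3L || !startsWith(lines[1L], ">"))
    stop("read_dotbracket_file: expected >id, sequence, structure lines")
  seq <- transcript_seq(sub("^>", "", lines[1L]), lines[2L])
  parse_dotbracket(lines[3L], seq)
}
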