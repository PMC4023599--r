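# bZIP domain grammar: basic region (N-x7-R/K-x9), hinge, leucine zipper
# heptads. Frame numbering follows the Vinson convention used throughout the
# package: the invariant Asn is position -18, the invariant Arg/Lys is -10,
# the first zipper residue is +1; consecutive residues advance the frame by
# one and there is no position 0.

#' Hydrophobic residues accepted at a canonical heptad position
#' @keywords internal
.ZIPPER_CANONICAL <- c("L", "I", "V", "F", "M")

#' Convert a domain-frame position to a 0-based sequence index
#'
#' Frame positions run -18..-1, +1..+n (no 0); the invariant Asn anchors the
#' frame at -18.
#'
#' @param frame Integer frame position (non-zero).
#' @param asn_index 0-based index of the invariant Asn.
#' @return 0-based sequence index.
#' @export
frame_to_index <- function(frame, asn_index) {
  stopifnot(all(frame != 0L))
  ifelse(frame < 0L, asn_index + frame + 18L, asn_index + frame + 17L)
}

#' Convert a 0-based sequence index to a domain-frame position
#'
#' @param index 0-based sequence index.
#' @param asn_index 0-based index of the invariant Asn.
#' @return Integer frame position (never 0).
#' @export
index_to_frame <- function(index, asn_index) {
  off <- index - asn_index
  ifelse(off < 18L, off - 18L, off - 17L)
}

## Extend heptads from the zipper start. Interior non-canonical heptads are
## tolerated up to `max_interruptions`, but only when a later canonical
## heptad follows; the first heptad must be canonical.
.extend_heptads <- function(chars, zipper_start, max_interruptions) {
  n <- length(chars)
  pos <- seq(zipper_start, n - 1L, by = 7L)
  if (length(pos) == 0L) return(NULL)
  canonical <- chars[pos + 1L] %in% .ZIPPER_CANONICAL
  if (!canonical[1L]) return(NULL)
  keep <- 0L
  interruptions <- 0L
  for (k in seq_along(pos)) {
    if (canonical[k]) {
      keep <- k
    } else {
      if (interruptions >= max_interruptions) break
      interruptions <- interruptions + 1L
    }
  }
  idx <- seq_len(keep)
  list(
    index = pos[idx],
    canonical = canonical[idx],
    n_canonical = sum(canonical[idx]),
    n_total = keep,
    interruptions = sum(!canonical[idx])
  )
}

#' Annotate the bZIP domain of a protein sequence
#'
#' Searches for the structural grammar of the bZIP domain: an invariant Asn
#' (frame -18) followed by seven arbitrary residues and an invariant Arg/Lys
#' (frame -10), a nine-residue hinge, and a leucine zipper made of heptad
#' repeats with Leu (or Ile/Val/Phe/Met) at the first position of each
#' heptad (+1, +8, +15, ...). Up to \code{max_interruptions} non-canonical
#' heptads are tolerated when a later canonical heptad follows. Among all
#' qualifying anchors the one with the most canonical heptads wins; ties go
#' to the leftmost anchor.
#'
#' @param sequence Amino-acid string (single-letter, uppercase) or a single
#'   named element of an \code{AAStringSet}.
#' @param id Protein identifier carried into the annotation; defaults to the
#'   sequence name when available.
#' @param min_heptads Minimum number of canonical-or-tolerated heptads for
#'   an anchor to qualify (default 3).
#' @param max_interruptions Maximum tolerated non-canonical heptads
#'   (default 2).
#' @param relaxed_basic Accept any residue at frame -10 (substitutions such
#'   as Ile are always flagged downstream); default \code{FALSE} accepts
#'   Arg or Lys.
#' @param heptad_counting Count only canonical heptads (\code{"canonical"},
#'   default) or canonical plus tolerated (\code{"all"}) towards
#'   \code{heptad_count}.
#' @return A \code{bzip_annotation} object, or \code{NULL} when no anchor
#'   qualifies. Fields: \code{protein_id}, \code{asn_index},
#'   \code{basic_residue_index}, \code{zipper_start_index} (all 0-based),
#'   \code{heptads} (data frame: frame_position, index, residue, canonical),
#'   \code{heptad_count}, \code{interruptions}, and \code{spans}, a list of
#'   0-based half-open index intervals for the basic region, hinge and
#'   leucine zipper.
#' @export
annotate_bzip_domain <- function(sequence, id = NULL,
                                 min_heptads = 3L,
                                 max_interruptions = 2L,
                                 relaxed_basic = FALSE,
                                 heptad_counting = c("canonical", "all")) {
  heptad_counting <- match.arg(heptad_counting)
  if (min_heptads < 1L) stop("min_heptads must be >= 1")
  if (max_interruptions < 0L) stop("max_interruptions must be >= 0")
  if (is.null(id)) id <- names(sequence) %||% NA_character_
  sequence <- as.character(sequence)
  stopifnot(length(sequence) == 1L)
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  n <- length(chars)
  # minimal span: N + x7 + R/K + x9 + one heptad start
  if (n < 19L) return(NULL)

  anchors <- which(chars == "N")
  anchors <- anchors[anchors + 8L <= n]
  if (!relaxed_basic) {
    anchors <- anchors[chars[anchors + 8L] %in% c("R", "K")]
  }
  if (length(anchors) == 0L) return(NULL)

  best <- NULL
  for (a in anchors) {
    asn_index <- a - 1L                      # 0-based
    zipper_start <- asn_index + 18L
    if (zipper_start >= n) next
    hep <- .extend_heptads(chars, zipper_start, max_interruptions)
    if (is.null(hep) || hep$n_total < min_heptads) next
    if (is.null(best) || hep$n_canonical > best$hep$n_canonical) {
      best <- list(asn_index = asn_index, hep = hep)
    }
  }
  if (is.null(best)) return(NULL)

  asn_index <- best$asn_index
  hep <- best$hep
  zipper_start <- asn_index + 18L
  last_hep <- hep$index[hep$n_total]
  zipper_end <- min(n, last_hep + 7L)
  heptads <- data.frame(
    frame_position = 1L + 7L * (seq_len(hep$n_total) - 1L),
    index = hep$index,
    residue = chars[hep$index + 1L],
    canonical = hep$canonical,
    stringsAsFactors = FALSE
  )
  structure(list(
    protein_id = id,
    asn_index = asn_index,
    basic_residue_index = asn_index + 8L,
    zipper_start_index = zipper_start,
    heptads = heptads,
    heptad_count = if (heptad_counting == "canonical") hep$n_canonical else hep$n_total,
    interruptions = hep$interruptions,
    spans = list(
      basic = c(asn_index, asn_index + 9L),
      hinge = c(asn_index + 9L, zipper_start),
      zipper = c(zipper_start, zipper_end)
    )
  ), class = "bzip_annotation")
}

#' @export
print.bzip_annotation <- function(x, ...) {
  cat(sprintf(
    "bZIP domain annotation for %s\n  Asn (-18) at index %d; %s (-10) at %d; zipper start (+1) at %d\n  %d heptads (%d interruption%s)\n",
    x$protein_id, x$asn_index, "R/K", x$basic_residue_index,
    x$zipper_start_index, x$heptad_count, x$interruptions,
    if (x$interruptions == 1L) "" else "s"))
  invisible(x)
}

#' Classify leucine-zipper length into gradients I-IX
#'
#' Zipper lengths of 3 to 11 heptad ("leucine") units map bijectively onto
#' nine gradients I to IX.
#'
#' @param x A \code{bzip_annotation} or an integer heptad count.
#' @return Roman-numeral gradient label; counts outside 3..11 yield
#'   \code{"out-of-range"} with a warning.
#' @export
classify_zipper_gradient <- function(x) {
  count <- if (inherits(x, "bzip_annotation")) x$heptad_count else as.integer(x)
  if (count < 3L || count > 11L) {
    warning("heptad count ", count, " outside the 3..11 gradient range")
    return("out-of-range")
  }
  as.character(utils::as.roman(count - 2L))
}

#' Report DNA-binding residues at the key bZIP frame positions
#'
#' Extracts the residues at frame positions -18, -10, +1, +8 and +15 and
#' flags substitutions relative to the invariant residues (Asn at -18, Arg
#' at -10, Leu at the three zipper sites). Lys at -10 is a substitution but
#' noted as a conservative basic replacement.
#'
#' @param annotation A \code{bzip_annotation}.
#' @param sequence The protein sequence the annotation belongs to.
#' @return A \code{data.frame} with columns \code{protein_id},
#'   \code{frame_position}, \code{residue} (NA when the position lies beyond
#'   the sequence end), \code{canonical}, \code{substituted}, \code{note}.
#' @export
report_binding_specificity <- function(annotation, sequence) {
  stopifnot(inherits(annotation, "bzip_annotation"))
  chars <- strsplit(as.character(sequence), "", fixed = TRUE)[[1]]
  frames <- c(-18L, -10L, 1L, 8L, 15L)
  canonical <- c("N", "R", "L", "L", "L")
  idx <- frame_to_index(frames, annotation$asn_index)
  residue <- ifelse(idx < length(chars), chars[idx + 1L], NA_character_)
  substituted <- !is.na(residue) & residue != canonical
  note <- character(length(frames))
  note[is.na(residue)] <- "position beyond sequence end"
  cons <- which(!is.na(residue) & frames == -10L & residue == "K")
  note[cons] <- "Lys at -10: conservative basic substitution"
  zip_sub <- which(substituted & frames > 0L &
                     residue %in% .ZIPPER_CANONICAL)
  note[zip_sub] <- "hydrophobic substitution at a zipper site"
  data.frame(
    protein_id = annotation$protein_id,
    frame_position = frames,
    residue = residue,
    canonical = canonical,
    substituted = substituted,
    note = note,
    stringsAsFactors = FALSE
  )
}

#' Scan a protein for kinase phosphorylation-site motifs
#'
#' Reports every 4-mer matching R/KxxS/T (Ca2+-independent protein kinase
#' site) or S/TxxD/E (casein kinase II site), including overlapping hits.
#'
#' @param sequence Amino-acid string.
#' @param id Protein identifier for the report.
#' @return \code{data.frame} with columns \code{protein_id}, \code{motif}
#'   (\code{"RK-xx-ST"} or \code{"ST-xx-DE"}), \code{start} (0-based) and
#'   \code{match}.
#' @export
scan_phospho_sites <- function(sequence, id = NULL) {
  if (is.null(id)) id <- names(sequence) %||% NA_character_
  sequence <- as.character(sequence)
  hits_for <- function(pattern, label) {
    m <- gregexpr(pattern, sequence, perl = TRUE)[[1]]
    if (m[1] == -1L) return(NULL)
    start <- as.integer(m) - 1L
    data.frame(
      protein_id = id, motif = label, start = start,
      match = substring(sequence, start + 1L, start + 4L),
      stringsAsFactors = FALSE
    )
  }
  out <- rbind(
    hits_for("(?=[RK]..[ST])", "RK-xx-ST"),
    hits_for("(?=[ST]..[DE])", "ST-xx-DE")
  )
  if (is.null(out)) {
    out <- data.frame(protein_id = character(), motif = character(),
                      start = integer(), match = character(),
                      stringsAsFactors = FALSE)
  }
  out[order(out$start, out$motif), , drop = FALSE]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
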