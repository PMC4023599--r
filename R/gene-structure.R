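# Intron phases, domain-to-genome mapping and the nine intron/exon
# structural patterns (a-i) of the bZIP domain.
#
# Phase convention: an intron falling after cumulative CDS length c has
# phase c mod 3 -- phase 0 between codons, phase 1/2 after the first/second
# nucleotide of a codon. The affected protein residue is codon c %/% 3 (for
# a phase-0 junction this is the residue downstream of the junction).

#' Compute intron positions and phases of a gene model
#'
#' @param model A \code{gene_model} whose CDS length is divisible by 3.
#' @return \code{data.frame} with one row per intron (5'->3' in transcript
#'   order): \code{gene_id}, \code{ordinal}, \code{genomic_position}
#'   (0-based coordinate of the donor-side exon/intron junction),
#'   \code{cds_offset} (nucleotides of CDS upstream of the junction),
#'   \code{phase} and \code{codon_offset} (0-based protein residue
#'   interrupted by, or immediately downstream of, the junction). A
#'   zero-intron gene yields zero rows.
#' @export
compute_intron_phases <- function(model) {
  stopifnot(inherits(model, "gene_model"))
  if (cds_length(model) %% 3L != 0L) {
    stop(model$gene_id, ": CDS length not divisible by 3")
  }
  iv <- model$cds
  n <- nrow(iv)
  if (n < 2L) {
    return(data.frame(gene_id = character(), ordinal = integer(),
                      genomic_position = integer(), cds_offset = integer(),
                      phase = integer(), codon_offset = integer(),
                      stringsAsFactors = FALSE))
  }
  lens <- iv[, 2] - iv[, 1]
  cum <- cumsum(lens)[-n]
  data.frame(
    gene_id = model$gene_id,
    ordinal = seq_len(n - 1L),
    genomic_position = if (model$strand == "+") iv[-n, 2] else iv[-n, 1],
    cds_offset = cum,
    phase = cum %% 3L,
    codon_offset = cum %/% 3L,
    stringsAsFactors = FALSE
  )
}

.map_cds_range_to_genomic <- function(model, nt_start, nt_end) {
  iv <- model$cds
  lens <- iv[, 2] - iv[, 1]
  cum <- c(0L, cumsum(lens))
  out <- list()
  for (k in seq_len(nrow(iv))) {
    a <- max(nt_start, cum[k]); b <- min(nt_end, cum[k + 1L])
    if (a >= b) next
    if (model$strand == "+") {
      g <- c(iv[k, 1] + (a - cum[k]), iv[k, 1] + (b - cum[k]))
    } else {
      g <- c(iv[k, 2] - (b - cum[k]), iv[k, 2] - (a - cum[k]))
    }
    out[[length(out) + 1L]] <- g
  }
  m <- do.call(rbind, out)
  m[order(m[, 1]), , drop = FALSE]
}

#' Map bZIP domain subregions onto genomic coordinates
#'
#' Protein residue i (0-based) occupies CDS nucleotides [3i, 3i+3), walked
#' across the CDS intervals in transcription order (3'->5' in genomic
#' coordinates on the minus strand). Subregion spans may split across
#' exons.
#'
#' @param model A \code{gene_model}.
#' @param annotation The \code{bzip_annotation} of the protein translated
#'   from the model's CDS.
#' @return Named list (\code{basic}, \code{hinge}, \code{zipper}) of
#'   two-column matrices of genomic intervals, 0-based half-open, sorted by
#'   genomic start.
#' @export
map_domain_to_genome <- function(model, annotation) {
  stopifnot(inherits(annotation, "bzip_annotation"))
  n_res <- cds_length(model) %/% 3L
  if (annotation$spans$zipper[2] > n_res) {
    stop("annotation span exceeds the CDS of ", model$gene_id)
  }
  lapply(annotation$spans, function(sp) {
    .map_cds_range_to_genomic(model, 3L * sp[1], 3L * sp[2])
  })
}

#' Locate introns falling inside the bZIP domain
#'
#' Each intron whose junction lies within the basic region, hinge or
#' leucine zipper is reported with its subregion, domain-frame position,
#' phase and flanking residues; introns outside the domain are excluded.
#' Subregion assignment uses the codon containing the junction; a phase-0
#' junction exactly at a subregion boundary belongs to the downstream
#' subregion.
#'
#' @param model A \code{gene_model}.
#' @param annotation The \code{bzip_annotation} of the encoded protein.
#' @param protein The protein sequence (character or \code{AAString});
#'   defaults to translating the model's CDS when a contig is supplied.
#' @return \code{data.frame}: \code{gene_id}, \code{ordinal}, \code{phase},
#'   \code{codon_offset}, \code{subregion}, \code{frame_position},
#'   \code{aa_before}, \code{aa_after}.
#' @export
locate_domain_introns <- function(model, annotation, protein) {
  stopifnot(inherits(annotation, "bzip_annotation"))
  introns <- compute_intron_phases(model)
  chars <- strsplit(as.character(protein), "", fixed = TRUE)[[1]]
  spans <- annotation$spans
  rows <- lapply(seq_len(nrow(introns)), function(i) {
    r <- introns$codon_offset[i]
    sub <- if (r >= spans$basic[1] && r < spans$basic[2]) "basic"
    else if (r >= spans$hinge[1] && r < spans$hinge[2]) "hinge"
    else if (r >= spans$zipper[1] && r < spans$zipper[2]) "zipper"
    else NA_character_
    if (is.na(sub)) return(NULL)
    c_off <- introns$cds_offset[i]
    data.frame(
      gene_id = model$gene_id,
      ordinal = introns$ordinal[i],
      phase = introns$phase[i],
      codon_offset = r,
      subregion = sub,
      frame_position = index_to_frame(r, annotation$asn_index),
      aa_before = chars[(c_off - 1L) %/% 3L + 1L],
      aa_after = chars[c_off %/% 3L + 1L],
      stringsAsFactors = FALSE
    )
  })
  rows <- Filter(Negate(is.null), rows)
  if (length(rows) == 0L) {
    return(data.frame(gene_id = character(), ordinal = integer(),
                      phase = integer(), codon_offset = integer(),
                      subregion = character(), frame_position = integer(),
                      aa_before = character(), aa_after = character(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

#' Classify domain introns into the nine structural patterns a-i
#'
#' Applies a top-down decision table over the introns located inside the
#' bZIP domain:
#' \describe{
#'   \item{i}{no intron in the domain (the \code{"table"} scheme labels
#'     this case \emph{h}, matching the printed family table)}
#'   \item{b}{two phase-0 introns, one in the basic region, one in the
#'     hinge}
#'   \item{g}{a single phase-1 intron in the basic region}
#'   \item{c/d/e}{a phase-2 intron in the basic region plus a phase-0
#'     intron in the leucine zipper, split by the zipper intron's frame
#'     position against \code{breakpoints} (defaults: first, second, third
#'     heptad)}
#'   \item{f}{a phase-2 intron in the basic region and none in the zipper}
#'   \item{a}{a single phase-0 zipper intron inserted between Gln and Ala}
#'   \item{h}{a single phase-0 zipper intron with other flanking residues}
#' }
#' Anything else returns \code{"unclassified"} with a diagnostic attribute.
#'
#' @param domain_introns \code{data.frame} from
#'   \code{\link{locate_domain_introns}} (possibly empty).
#' @param scheme \code{"text"} (default) or \code{"table"}; the two differ
#'   only in the letter given to the intron-less case.
#' @param breakpoints Zipper frame positions splitting patterns c/d/e
#'   (default \code{c(1, 8, 15)}).
#' @return Single pattern letter.
#' @export
classify_intron_pattern <- function(domain_introns,
                                    scheme = c("text", "table"),
                                    breakpoints = c(1L, 8L, 15L)) {
  scheme <- match.arg(scheme)
  di <- domain_introns
  n <- nrow(di)
  if (n == 0L) return(if (scheme == "text") "i" else "h")
  if (n == 2L && all(di$phase == 0L) &&
      setequal(di$subregion, c("basic", "hinge"))) {
    return("b")
  }
  if (n == 1L && di$phase == 1L && di$subregion == "basic") return("g")
  basic_p2 <- di$phase == 2L & di$subregion == "basic"
  zipper_p0 <- di$phase == 0L & di$subregion == "zipper"
  if (any(basic_p2)) {
    if (any(zipper_p0)) {
      fp <- di$frame_position[zipper_p0][1]
      if (fp < breakpoints[2]) return("c")
      if (fp < breakpoints[3]) return("d")
      return("e")
    }
    if (!any(di$subregion == "zipper")) return("f")
  }
  if (n == 1L && di$phase == 0L && di$subregion == "zipper") {
    if (di$aa_before == "Q" && di$aa_after == "A") return("a")
    return("h")
  }
  structure("unclassified",
            diagnostic = sprintf(
              "%d domain intron(s): %s",
              n, paste(sprintf("(%s,P%d,%+d)", di$subregion, di$phase,
                               di$frame_position), collapse = " ")))
}

#' Summarize gene structures for a set of annotated genes
#'
#' @param models Named list of \code{gene_model} objects.
#' @param annotations Named list of \code{bzip_annotation} objects (names
#'   are gene ids).
#' @param proteins Named character vector or \code{AAStringSet} of protein
#'   sequences.
#' @param scheme Pattern lettering scheme, see
#'   \code{\link{classify_intron_pattern}}.
#' @return \code{data.frame} with one row per annotation: \code{gene_id},
#'   \code{intron_count} (introns in the full CDS), \code{pattern}, and
#'   \code{flagged} (\code{TRUE} when the gene model is missing, in which
#'   case counts are \code{NA} rather than the gene being dropped).
#' @export
summarize_gene_structures <- function(models, annotations, proteins,
                                      scheme = c("text", "table")) {
  scheme <- match.arg(scheme)
  rows <- lapply(names(annotations), function(g) {
    if (is.null(models[[g]])) {
      return(data.frame(gene_id = g, intron_count = NA_integer_,
                        pattern = NA_character_, flagged = TRUE,
                        stringsAsFactors = FALSE))
    }
    model <- models[[g]]
    di <- locate_domain_introns(model, annotations[[g]],
                                as.character(proteins[g]))
    data.frame(
      gene_id = g,
      intron_count = max(0L, nrow(model$cds) - 1L),
      pattern = classify_intron_pattern(di, scheme),
      flagged = FALSE,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}
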