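# Gene models and GFF3 I/O.
#
# Internal convention: all coordinates are 0-based half-open; the 1-based
# closed GFF3 convention is converted exactly once, at the I/O boundary.
# Exon and CDS intervals are stored in transcription order (5'->3' on the
# transcript), i.e. descending genomic position on the minus strand.

#' Construct a gene model
#'
#' @param gene_id Gene identifier.
#' @param chromosome Chromosome / contig name.
#' @param strand \code{"+"} or \code{"-"}.
#' @param exons Two-column matrix of exon intervals (start, end), 0-based
#'   half-open, in transcription order.
#' @param cds Two-column matrix of CDS intervals, same convention; defaults
#'   to \code{exons}.
#' @return A \code{gene_model} object. When the total CDS length is not
#'   divisible by 3 the model is returned with \code{cds_incomplete = TRUE}
#'   and a warning.
#' @export
gene_model <- function(gene_id, chromosome, strand, exons, cds = exons) {
  stopifnot(strand %in% c("+", "-"))
  exons <- .as_interval_matrix(exons, gene_id, "exon")
  cds <- .as_interval_matrix(cds, gene_id, "CDS")
  .check_transcription_order(exons, strand, gene_id)
  .check_transcription_order(cds, strand, gene_id)
  cds_len <- sum(cds[, 2] - cds[, 1])
  incomplete <- cds_len %% 3L != 0L
  if (incomplete) {
    warning("CDS length of ", gene_id, " (", cds_len,
            " nt) is not divisible by 3; model flagged")
  }
  structure(list(
    gene_id = gene_id,
    chromosome = as.character(chromosome),
    strand = strand,
    exons = exons,
    cds = cds,
    cds_incomplete = incomplete
  ), class = "gene_model")
}

.as_interval_matrix <- function(x, gene_id, what) {
  x <- matrix(as.numeric(x), ncol = 2,
              dimnames = list(NULL, c("start", "end")))
  if (any(x[, 2] <= x[, 1])) {
    stop(gene_id, ": ", what, " intervals must have end > start")
  }
  storage.mode(x) <- "integer"
  x
}

.check_transcription_order <- function(iv, strand, gene_id) {
  if (nrow(iv) < 2L) return(invisible())
  ok <- if (strand == "+") {
    all(diff(iv[, 1]) > 0) && all(iv[-1, 1] >= iv[-nrow(iv), 2])
  } else {
    all(diff(iv[, 1]) < 0) && all(iv[-nrow(iv), 1] >= iv[-1, 2])
  }
  if (!ok) {
    stop(gene_id, ": intervals must be non-overlapping and sorted in ",
         "transcription order")
  }
  invisible()
}

#' Total CDS length of a gene model in nucleotides
#' @param model A \code{gene_model}.
#' @return Integer length.
#' @export
cds_length <- function(model) {
  sum(model$cds[, 2] - model$cds[, 1])
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("gene_model %s  %s:%d-%d (%s)  %d exon(s), CDS %d nt\n",
              x$gene_id, x$chromosome, min(x$exons[, 1]), max(x$exons[, 2]),
              x$strand, nrow(x$exons), cds_length(x)))
  invisible(x)
}

#' Read gene models from a GFF3 file
#'
#' Expects gene/mRNA/CDS features (exon features are used when present,
#' otherwise CDS intervals stand in for exons). One mRNA per gene is the
#' normal case; for multi-isoform genes the isoform with the longest total
#' CDS is taken as the representative.
#'
#' @param path Path to a GFF3 file.
#' @return Named list of \code{gene_model} objects.
#' @export
read_gff3 <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  gr <- rtracklayer::import(path, format = "gff3")
  type <- as.character(gr$type)
  ids <- gr$ID
  parents <- vapply(as.list(gr$Parent), function(p) {
    if (length(p) == 0L) NA_character_ else p[[1]]
  }, character(1))

  gene_ids <- ids[type == "gene"]
  mrna <- which(type == "mRNA")
  if (length(mrna) == 0L) stop("GFF3 has no mRNA features: ", path)
  mrna_parent <- parents[mrna]
  if (any(is.na(mrna_parent)) || !all(mrna_parent %in% gene_ids)) {
    stop("mRNA feature(s) with missing or unknown gene parent in ", path)
  }
  feat <- which(type %in% c("CDS", "exon"))
  feat_parent <- parents[feat]
  if (any(is.na(feat_parent)) || !all(feat_parent %in% ids[mrna])) {
    stop("CDS/exon feature(s) with missing or unknown mRNA parent in ", path)
  }

  models <- lapply(unique(mrna_parent), function(g) {
    tx <- ids[mrna][mrna_parent == g]
    pick <- tx[1]
    if (length(tx) > 1L) {
      lens <- vapply(tx, function(t) {
        i <- feat[feat_parent == t & type[feat] == "CDS"]
        sum(GenomicRanges::width(gr[i]))
      }, numeric(1))
      pick <- tx[which.max(lens)]
    }
    idx_cds <- feat[feat_parent == pick & type[feat] == "CDS"]
    idx_ex <- feat[feat_parent == pick & type[feat] == "exon"]
    if (length(idx_ex) == 0L) idx_ex <- idx_cds
    strand <- as.character(GenomicRanges::strand(gr[idx_cds[1]]))
    to_internal <- function(i) {
      m <- cbind(GenomicRanges::start(gr[i]) - 1L, GenomicRanges::end(gr[i]))
      m[order(m[, 1], decreasing = (strand == "-")), , drop = FALSE]
    }
    gene_model(
      gene_id = g,
      chromosome = as.character(GenomicRanges::seqnames(gr[idx_cds[1]])),
      strand = strand,
      exons = to_internal(idx_ex),
      cds = to_internal(idx_cds)
    )
  })
  names(models) <- unique(mrna_parent)
  models
}

#' Write gene models to a GFF3 file
#'
#' @param models A \code{gene_model} or list of them.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_gff3 <- function(models, path) {
  if (inherits(models, "gene_model")) models <- list(models)
  rows <- lapply(models, function(m) {
    span <- c(min(m$exons[, 1]), max(m$exons[, 2]))
    mrna_id <- paste0(m$gene_id, ".t1")
    ex <- m$exons[order(m$exons[, 1]), , drop = FALSE]
    # GFF3 phase: bases to skip to reach a codon start, per CDS piece in
    # transcription order
    lens <- m$cds[, 2] - m$cds[, 1]
    tx_phase <- (3L - c(0L, cumsum(lens)[-length(lens)]) %% 3L) %% 3L
    ord <- order(m$cds[, 1])
    cds <- m$cds[ord, , drop = FALSE]
    cds_phase <- tx_phase[ord]
    data.frame(
      seqnames = m$chromosome,
      start = c(span[1], span[1], ex[, 1], cds[, 1]) + 1L,
      end = c(span[2], span[2], ex[, 2], cds[, 2]),
      strand = m$strand,
      type = c("gene", "mRNA", rep("exon", nrow(ex)), rep("CDS", nrow(cds))),
      phase = c(NA, NA, rep(NA, nrow(ex)), cds_phase),
      ID = c(m$gene_id, mrna_id,
             paste0(mrna_id, ".exon", seq_len(nrow(ex))),
             paste0(mrna_id, ".cds", seq_len(nrow(cds)))),
      Parent = c(NA, m$gene_id, rep(mrna_id, nrow(ex) + nrow(cds))),
      stringsAsFactors = FALSE
    )
  })
  df <- do.call(rbind, rows)
  gr <- GenomicRanges::GRanges(
    seqnames = df$seqnames,
    ranges = IRanges::IRanges(df$start, df$end),
    strand = df$strand,
    type = df$type,
    phase = df$phase,
    ID = df$ID
  )
  gr$Parent <- IRanges::CharacterList(
    lapply(df$Parent, function(p) if (is.na(p)) character(0) else p))
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Extract the spliced CDS sequence of a gene model from its contig
#'
#' Walks the CDS intervals in transcription order; on the minus strand each
#' piece is reverse-complemented.
#'
#' @param model A \code{gene_model}.
#' @param contig Nucleotide sequence of the chromosome/contig
#'   (\code{DNAString} or character).
#' @return A \code{DNAString} of the spliced CDS.
#' @export
spliced_cds_sequence <- function(model, contig) {
  contig <- Biostrings::DNAString(as.character(contig))
  pieces <- lapply(seq_len(nrow(model$cds)), function(i) {
    s <- Biostrings::subseq(contig, model$cds[i, 1] + 1L, model$cds[i, 2])
    if (model$strand == "-") Biostrings::reverseComplement(s) else s
  })
  do.call(Biostrings::xscat, pieces)
}

#' Translate a gene model's CDS
#'
#' @inheritParams spliced_cds_sequence
#' @return Single-letter amino-acid string (stop codon, if present at the
#'   end, removed).
#' @export
translate_cds <- function(model, contig) {
  nt <- spliced_cds_sequence(model, contig)
  aa <- as.character(Biostrings::translate(nt, no.init.codon = TRUE))
  sub("\\*$", "", aa)
}
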