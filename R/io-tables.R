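# Tabular I/O: expression matrices, qPCR Ct tables, family tables and
# MCScanX-format collinearity files.

#' Read a genes x samples expression matrix from TSV
#'
#' First column holds gene ids, the header row sample ids. Values are
#' log2 fluorescence intensities unless \code{log2_transform} is set, in
#' which case the (linear) values are log2-transformed on read.
#'
#' @param path Path to a TSV file.
#' @param log2_transform Apply \code{log2} to the values (default
#'   \code{FALSE}: the input is assumed pre-logged).
#' @return Numeric matrix with gene ids as row names and sample ids as
#'   column names.
#' @export
read_expression_matrix <- function(path, log2_transform = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path)
  nfields <- utils::count.fields(path, sep = "\t", quote = "")
  if (length(unique(nfields)) != 1L) {
    stop("ragged rows in ", path, ": rows have ",
         paste(unique(nfields), collapse = ", "), " fields")
  }
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, colClasses = "character")
  if (any(is.na(colnames(df))) || any(colnames(df)[-1] == "")) {
    stop("missing sample id in header of ", path)
  }
  gene_ids <- df[[1]]
  if (anyDuplicated(gene_ids)) {
    stop("duplicate gene id(s): ",
         paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "))
  }
  vals <- as.matrix(df[, -1, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(vals), nrow = nrow(vals)))
  if (any(is.na(num) & !is.na(vals))) {
    bad <- which(is.na(num) & !is.na(vals), arr.ind = TRUE)[1, ]
    stop("non-numeric value at row ", bad[1], " (", gene_ids[bad[1]],
         "), column ", bad[2] + 1L, " of ", path)
  }
  dimnames(num) <- list(gene_ids, colnames(df)[-1])
  if (log2_transform) num <- log2(num)
  num
}

#' Write an expression matrix to TSV
#'
#' @param m Numeric matrix with gene row names and sample column names.
#' @param path Output path.
#' @param digits Significant digits written (default 10, enough for a
#'   read/write round trip within 1e-9).
#' @return \code{path}, invisibly.
#' @export
write_expression_matrix <- function(m, path, digits = 10) {
  stopifnot(is.matrix(m), !is.null(rownames(m)), !is.null(colnames(m)))
  df <- data.frame(gene_id = rownames(m),
                   signif(m, digits),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a qRT-PCR Ct table from TSV
#'
#' Expected columns: \code{gene_id}, \code{condition}, \code{bio_rep},
#' \code{tech_rep}, \code{ct_target}, \code{ct_reference} (reference gene
#' cycles, e.g. actin, measured alongside the target).
#'
#' @param path Path to a TSV file.
#' @return \code{data.frame} of Ct records.
#' @export
read_ct_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  needed <- c("gene_id", "condition", "bio_rep", "tech_rep",
              "ct_target", "ct_reference")
  missing <- setdiff(needed, colnames(df))
  if (length(missing) > 0L) {
    stop("Ct table lacks column(s): ", paste(missing, collapse = ", "))
  }
  ct <- c(df$ct_target, df$ct_reference)
  if (any(!is.finite(ct)) || any(ct <= 0)) {
    stop("Ct values must be positive and finite")
  }
  df
}

#' Write a Ct table to TSV
#' @param df Ct records as returned by \code{\link{read_ct_table}}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_ct_table <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.FAMILY_GROUPS <- c(LETTERS[1:10], "UC")
.PATTERN_LETTERS <- letters[1:9]

#' Validate a family table
#'
#' One record per family member: gene id, phylogenetic group (A-J or UC),
#' chromosome, locus interval, strand, protein length, intron count and
#' intron/exon structural pattern letter.
#'
#' @param table \code{data.frame} with at least columns \code{gene_id},
#'   \code{group}, \code{chromosome}, \code{start}, \code{end},
#'   \code{strand}, \code{protein_length}, \code{intron_count},
#'   \code{pattern}.
#' @return The table, invisibly, when valid.
#' @export
validate_family_table <- function(table) {
  needed <- c("gene_id", "group", "chromosome", "start", "end", "strand",
              "protein_length", "intron_count", "pattern")
  missing <- setdiff(needed, colnames(table))
  if (length(missing) > 0L) {
    stop("family table lacks column(s): ", paste(missing, collapse = ", "))
  }
  if (anyDuplicated(table$gene_id)) {
    stop("duplicate gene id(s): ",
         paste(unique(table$gene_id[duplicated(table$gene_id)]),
               collapse = ", "))
  }
  if (!all(table$group %in% .FAMILY_GROUPS)) {
    stop("group labels must be A..J or UC")
  }
  if (!all(table$pattern %in% .PATTERN_LETTERS)) {
    stop("pattern letters must be a..i")
  }
  if (!all(table$start < table$end)) stop("locus start must be < end")
  invisible(table)
}

#' Read a family table from TSV
#' @param path Path to a TSV file.
#' @return Validated \code{data.frame}.
#' @export
read_family_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE,
                          colClasses = c(chromosome = "character"))
  validate_family_table(df)
  df
}

#' Write a family table to TSV
#' @param table Validated family table.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_family_table <- function(table, path) {
  validate_family_table(table)
  utils::write.table(table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' The packaged grapevine bZIP family table (55 genes)
#'
#' Returns the family table of the 55 grapevine (Vitis vinifera) bZIP
#' genes: id, CRIBI 12X V1 accession, phylogenetic group, chromosome,
#' locus, strand, protein length, intron count, intron/exon pattern and
#' Arabidopsis ortholog list. Two pattern columns are provided:
#' \code{pattern} carries the letters as printed in the original family
#' table (which labels every domain-intron-less gene \emph{h}), and
#' \code{pattern_text} the letters under the rule-based scheme used by
#' \code{\link{classify_intron_pattern}} (domain-intron-less genes are
#' \emph{i}).
#'
#' @return Validated family table \code{data.frame} with 55 rows.
#' @export
table1_fixture <- function() {
  path <- system.file("extdata", "vvbzip_table1.tsv", package = "bzipkit",
                      mustWork = TRUE)
  read_family_table(path)
}

#' Read an MCScanX-format collinearity file
#'
#' Parses the textual MCScanX \code{.collinearity} dialect: block headers
#' \code{## Alignment <id>: ... <chrA>&<chrB> ...} followed by anchor lines
#' \code{<block>-<k>: geneA geneB e-value}.
#'
#' @param path Path to a \code{.collinearity} file.
#' @return List with \code{blocks} (\code{data.frame}: block_id, chrom_a,
#'   chrom_b) and \code{anchors} (\code{data.frame}: block_id, gene_a,
#'   gene_b).
#' @export
read_collinearity <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  blocks <- list(); anchors <- list()
  current <- NA_character_
  for (ln in lines) {
    if (grepl("^##\\s*Alignment", ln)) {
      id <- sub("^##\\s*Alignment\\s+(\\S+?):?\\s.*$", "\\1", ln)
      current <- sub(":$", "", id)
      chrs <- regmatches(ln, regexpr("\\S+&\\S+", ln))
      pair <- if (length(chrs) == 1L) strsplit(chrs, "&")[[1]] else
        c(NA_character_, NA_character_)
      blocks[[length(blocks) + 1L]] <-
        data.frame(block_id = current, chrom_a = pair[1], chrom_b = pair[2],
                   stringsAsFactors = FALSE)
    } else if (grepl("^#", ln) || !nzchar(trimws(ln))) {
      next
    } else {
      if (is.na(current)) stop("anchor line before any block header: ", ln)
      # "<block>-<k>: geneA geneB e-value" -- genes follow the first colon
      parts <- strsplit(ln, ":", fixed = TRUE)[[1]]
      if (length(parts) < 2L) next
      fields <- strsplit(trimws(paste(parts[-1], collapse = ":")),
                         "\\s+")[[1]]
      if (length(fields) < 2L) next
      anchors[[length(anchors) + 1L]] <-
        data.frame(block_id = current, gene_a = fields[1],
                   gene_b = fields[2], stringsAsFactors = FALSE)
    }
  }
  list(
    blocks = if (length(blocks)) do.call(rbind, blocks) else
      data.frame(block_id = character(), chrom_a = character(),
                 chrom_b = character(), stringsAsFactors = FALSE),
    anchors = if (length(anchors)) do.call(rbind, anchors) else
      data.frame(block_id = character(), gene_a = character(),
                 gene_b = character(), stringsAsFactors = FALSE)
  )
}
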