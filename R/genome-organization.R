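# Genome organization: chromosome distribution, tandem arrangement and
# family-restricted collinearity summaries.

#' Chromosome distribution of a gene family
#'
#' Counts family genes per chromosome. Genes on chromosomes outside the
#' supplied universe (e.g. "Un" or "18_random") count as unmapped;
#' percentages are computed over mapped genes only, as is conventional for
#' family distribution tables.
#'
#' @param table Validated family table.
#' @param chromosomes Chromosome universe (default \code{"1"}..\code{"19"},
#'   the grapevine karyotype).
#' @return List: \code{counts} (\code{data.frame} chromosome/count/pct over
#'   the universe plus any literal unmapped labels), \code{n_genes},
#'   \code{n_mapped}, \code{n_unmapped}, \code{occupied_chromosomes},
#'   \code{empty_chromosomes}.
#' @export
chromosome_distribution <- function(table,
                                    chromosomes = as.character(1:19)) {
  validate_family_table(table)
  chrom <- as.character(table$chromosome)
  mapped <- chrom %in% chromosomes
  unknown <- unique(chrom[!mapped])
  odd <- unknown[!grepl("random|un", unknown, ignore.case = TRUE)]
  if (length(odd) > 0L) {
    warning("unrecognized chromosome label(s) counted as unmapped: ",
            paste(odd, collapse = ", "))
  }
  n_mapped <- sum(mapped)
  count_for <- function(lbl) sum(chrom == lbl)
  labels <- c(chromosomes, unknown)
  counts <- data.frame(
    chromosome = labels,
    count = vapply(labels, count_for, integer(1)),
    mapped = labels %in% chromosomes,
    stringsAsFactors = FALSE
  )
  counts$pct <- ifelse(counts$mapped & n_mapped > 0,
                       round(100 * counts$count / n_mapped, 2), NA_real_)
  occupied <- chromosomes[chromosomes %in% chrom]
  list(
    counts = counts,
    n_genes = nrow(table),
    n_mapped = n_mapped,
    n_unmapped = nrow(table) - n_mapped,
    occupied_chromosomes = occupied,
    empty_chromosomes = setdiff(chromosomes, chrom)
  )
}

.components_from_pairs <- function(pairs, vertices = NULL) {
  verts <- unique(c(vertices, pairs$gene_a, pairs$gene_b))
  if (length(verts) == 0L) return(list())
  edges <- data.frame(from = pairs$gene_a, to = pairs$gene_b,
                      stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = verts)
  comp <- igraph::components(g)
  unname(split(names(comp$membership), comp$membership))
}

#' Detect tandem arrays of homologous family genes
#'
#' Two homologs on the same chromosome whose combined footprint (outermost
#' start to outermost end) is within \code{max_span}, with at most
#' \code{max_intervening} other family genes between them, are merged into
#' an array; arrays are maximal under this relation.
#'
#' @param table Validated family table.
#' @param homolog_pairs \code{data.frame} with columns \code{gene_a},
#'   \code{gene_b}, a symmetric homology relation over table gene ids.
#' @param max_span Maximum pair footprint in bp (default 1e5). The default
#'   criterion is distance-based only; \code{max_intervening} defaults to
#'   unlimited because intervening non-family genes are unknowable from the
#'   family table alone.
#' @param max_intervening Maximum number of other family genes with a start
#'   position strictly between the pair's starts (default \code{Inf}).
#' @return List of tandem arrays (character vectors of gene ids, each of
#'   size >= 2), ordered by first gene id; empty list when none.
#' @export
detect_tandem <- function(table, homolog_pairs, max_span = 1e5,
                          max_intervening = Inf) {
  validate_family_table(table)
  unknown <- setdiff(unique(c(homolog_pairs$gene_a, homolog_pairs$gene_b)),
                     table$gene_id)
  if (length(unknown) > 0L) {
    stop("homolog pair(s) reference unknown gene(s): ",
         paste(unknown, collapse = ", "))
  }
  rownames(table) <- table$gene_id
  qualifies <- function(a, b) {
    ta <- table[a, ]; tb <- table[b, ]
    if (ta$chromosome != tb$chromosome) return(FALSE)
    span <- max(ta$end, tb$end) - min(ta$start, tb$start)
    if (span > max_span) return(FALSE)
    between <- table$chromosome == ta$chromosome &
      table$start > min(ta$start, tb$start) &
      table$start < max(ta$start, tb$start) &
      !(table$gene_id %in% c(a, b))
    sum(between) <= max_intervening
  }
  keep <- vapply(seq_len(nrow(homolog_pairs)), function(i) {
    qualifies(homolog_pairs$gene_a[i], homolog_pairs$gene_b[i])
  }, logical(1))
  pairs <- homolog_pairs[keep, , drop = FALSE]
  if (nrow(pairs) == 0L) return(list())
  comps <- .components_from_pairs(pairs)
  comps <- lapply(comps, sort)
  comps[order(vapply(comps, `[`, character(1), 1))]
}

#' Summarize collinearity restricted to family genes
#'
#' Restricts the anchors of an MCScanX-format collinearity file to pairs in
#' which both genes belong to the family, counts blocks containing at least
#' one such anchor, and computes the connected components of the
#' family homology graph (duplicate pairs, triplets, ...).
#'
#' @param coll Parsed collinearity file from
#'   \code{\link{read_collinearity}}.
#' @param table Validated family table; anchors are matched against
#'   \code{gene_id} and, when present, \code{gene_accession}.
#' @return List: \code{family_anchors} (\code{data.frame} block_id /
#'   gene_a / gene_b in family ids), \code{n_blocks}, \code{block_ids},
#'   \code{components} (list of character vectors), and \code{triplets}
#'   (components of size exactly 3).
#' @export
summarize_collinearity <- function(coll, table) {
  validate_family_table(table)
  id_map <- stats::setNames(table$gene_id, table$gene_id)
  if ("gene_accession" %in% colnames(table)) {
    id_map <- c(id_map, stats::setNames(table$gene_id,
                                        table$gene_accession))
  }
  a <- id_map[coll$anchors$gene_a]
  b <- id_map[coll$anchors$gene_b]
  keep <- !is.na(a) & !is.na(b)
  fam <- data.frame(block_id = coll$anchors$block_id[keep],
                    gene_a = unname(a[keep]), gene_b = unname(b[keep]),
                    stringsAsFactors = FALSE)
  comps <- .components_from_pairs(fam)
  comps <- lapply(comps, sort)
  comps <- comps[lengths(comps) >= 2L]
  comps <- comps[order(vapply(comps, `[`, character(1), 1))]
  list(
    family_anchors = fam,
    n_blocks = length(unique(fam$block_id)),
    block_ids = sort(unique(fam$block_id)),
    components = comps,
    triplets = comps[lengths(comps) == 3L]
  )
}
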