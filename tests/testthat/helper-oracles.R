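# Independent brute-force oracles used to cross-check the implementation.
# Each is written from the definition, not by calling the package path it
# checks.

# Pearson correlation straight from the covariance formula
oracle_pcc <- function(x, y) {
  n <- length(x)
  sxy <- sum(x * y) - n * mean(x) * mean(y)
  sxx <- sum(x^2) - n * mean(x)^2
  syy <- sum(y^2) - n * mean(y)^2
  sxy / sqrt(sxx * syy)
}

# classic union-find over gene-pair edges
oracle_components <- function(pairs) {
  verts <- sort(unique(c(pairs$gene_a, pairs$gene_b)))
  parent <- stats::setNames(verts, verts)
  find <- function(x) {
    while (parent[[x]] != x) x <- parent[[x]]
    x
  }
  for (i in seq_len(nrow(pairs))) {
    ra <- find(pairs$gene_a[i]); rb <- find(pairs$gene_b[i])
    if (ra != rb) parent[[ra]] <- rb
  }
  roots <- vapply(verts, find, character(1))
  unname(lapply(split(verts, roots), sort))
}

# per-nucleotide codon walk: CDS coordinate t -> genomic coordinate
oracle_cds_to_genomic <- function(model) {
  out <- integer(0)
  for (k in seq_len(nrow(model$cds))) {
    s <- model$cds[k, 1]; e <- model$cds[k, 2]
    g <- if (model$strand == "+") seq(s, e - 1L) else seq(e - 1L, s)
    out <- c(out, g)
  }
  out
}

# O(n^2) tandem scan with iterated merging until fixed point
oracle_tandem <- function(table, pairs, max_span) {
  rownames(table) <- table$gene_id
  edges <- list()
  for (i in seq_len(nrow(pairs))) {
    a <- pairs$gene_a[i]; b <- pairs$gene_b[i]
    if (table[a, "chromosome"] != table[b, "chromosome"]) next
    span <- max(table[a, "end"], table[b, "end"]) -
      min(table[a, "start"], table[b, "start"])
    if (span <= max_span) edges[[length(edges) + 1L]] <- c(a, b)
  }
  if (length(edges) == 0L) return(list())
  ed <- do.call(rbind, edges)
  comps <- oracle_components(data.frame(gene_a = ed[, 1], gene_b = ed[, 2],
                                        stringsAsFactors = FALSE))
  comps[order(vapply(comps, `[`, character(1), 1))]
}

# independently written rule table for the nine structural patterns
# (text lettering); cases described as data frames with subregion, phase,
# frame_position, aa_before, aa_after
oracle_pattern_text <- function(di) {
  n <- nrow(di)
  if (n == 0L) return("i")
  has <- function(sub, ph) any(di$subregion == sub & di$phase == ph)
  if (n == 2L && has("basic", 0L) && has("hinge", 0L)) return("b")
  if (n == 1L && has("basic", 1L)) return("g")
  if (has("basic", 2L)) {
    zp <- di[di$subregion == "zipper" & di$phase == 0L, , drop = FALSE]
    if (nrow(zp) > 0L) {
      fp <- zp$frame_position[1]
      return(if (fp < 8) "c" else if (fp < 15) "d" else "e")
    }
    if (!any(di$subregion == "zipper")) return("f")
  }
  if (n == 1L && has("zipper", 0L)) {
    if (di$aa_before == "Q" && di$aa_after == "A") return("a") else
      return("h")
  }
  "unclassified"
}

# build a set of annotated synthetic proteins for alignment tests
make_annotated_set <- function(heptad_counts, seeds = seq_along(heptad_counts)) {
  prots <- Map(function(h, s) gen_bzip_protein(heptads = h, seed = s),
               heptad_counts, seeds)
  seqs <- stats::setNames(vapply(prots, function(p) p$sequence, ""),
                          vapply(prots, function(p) p$id, ""))
  anns <- stats::setNames(
    lapply(names(seqs), function(id) annotate_bzip_domain(seqs[[id]], id = id)),
    names(seqs))
  list(proteins = prots, seqs = seqs, anns = anns)
}

# random additive distance matrix from a random unrooted tree; returns both
random_additive <- function(n_taxa, seed) {
  set.seed(seed)
  tr <- ape::unroot(ape::rtree(n_taxa,
                               br = function(n) stats::runif(n, 0.05, 1)))
  D <- stats::cophenetic(tr)
  ord <- sort(rownames(D))
  list(tree = tr, d = D[ord, ord])
}
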