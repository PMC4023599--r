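# Frame-anchored domain alignment, p-distances, neighbor-joining tree
# construction (Saitou-Nei Q criterion, implemented here) and
# nearest-reference group assignment.

#' Align bZIP domains by their shared numbering frame
#'
#' Exploits the fixed -18/-10/+1 frame of the domain grammar: every residue
#' is placed in the column of its frame position, so no progressive
#' alignment is needed. Positions absent from a sequence (shorter zippers)
#' become gaps.
#'
#' @param annotations Named list of \code{bzip_annotation} objects.
#' @param proteins Named character vector or \code{AAStringSet} of the
#'   corresponding sequences.
#' @param trim_to_common Restrict columns to frame positions present in
#'   every sequence (default \code{FALSE}: columns span the union of
#'   frames, shorter rows gap-padded on the right).
#' @return A \code{domain_alignment}: list with \code{ids}, \code{frames}
#'   (column frame positions) and \code{matrix} (character matrix, gap
#'   \code{"-"}).
#' @export
anchored_domain_alignment <- function(annotations, proteins,
                                      trim_to_common = FALSE) {
  ids <- names(annotations)
  stopifnot(length(ids) > 0L, all(ids %in% names(proteins)))
  per_seq <- lapply(ids, function(id) {
    ann <- annotations[[id]]
    chars <- strsplit(as.character(proteins[[id]]), "", fixed = TRUE)[[1]]
    idx <- seq(ann$asn_index, ann$spans$zipper[2] - 1L)
    list(frames = index_to_frame(idx, ann$asn_index),
         residues = chars[idx + 1L])
  })
  names(per_seq) <- ids
  ends <- vapply(per_seq, function(s) max(s$frames), integer(1))
  max_frame <- if (trim_to_common) min(ends) else max(ends)
  frames <- setdiff(seq(-18L, max_frame), 0L)
  m <- matrix("-", nrow = length(ids), ncol = length(frames),
              dimnames = list(ids, as.character(frames)))
  for (id in ids) {
    s <- per_seq[[id]]
    keep <- s$frames %in% frames
    m[id, as.character(s$frames[keep])] <- s$residues[keep]
  }
  structure(list(ids = ids, frames = frames, matrix = m),
            class = "domain_alignment")
}

#' Uncorrected p-distances over an alignment
#'
#' d(i, j) = mismatches / compared columns with pairwise deletion of gap
#' positions. A pair with no comparable column gets distance 1 with a
#' warning.
#'
#' @param aln A \code{domain_alignment} (or a character matrix of aligned
#'   residues with row names).
#' @return Symmetric numeric distance matrix with zero diagonal.
#' @export
p_distance <- function(aln) {
  m <- if (inherits(aln, "domain_alignment")) aln$matrix else aln
  stopifnot(is.matrix(m), nrow(m) >= 2L)
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      ok <- m[i, ] != "-" & m[j, ] != "-"
      if (!any(ok)) {
        warning("no comparable columns between ", rownames(m)[i], " and ",
                rownames(m)[j], "; distance set to 1")
        d[i, j] <- d[j, i] <- 1
      } else {
        d[i, j] <- d[j, i] <- sum(m[i, ok] != m[j, ok]) / sum(ok)
      }
    }
  }
  d
}

## Active-node label = lexicographically smallest leaf below it; pair ties
## on the Q criterion are broken by the sorted label pair.
.nj_pick_pair <- function(Q, labels) {
  n <- nrow(Q)
  best <- NULL; best_q <- Inf
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      key <- sort(c(labels[i], labels[j]))
      if (Q[i, j] < best_q - 1e-12 ||
          (abs(Q[i, j] - best_q) <= 1e-12 && !is.null(best) &&
           paste(key, collapse = "\r") <
             paste(sort(c(labels[best[1]], labels[best[2]])),
                   collapse = "\r"))) {
        best <- c(i, j); best_q <- Q[i, j]
      }
    }
  }
  best
}

.clamp_pair <- function(b) {
  # negative branch length: clamp to 0, excess moved to the sister branch
  if (b[1] < 0) { b[2] <- b[2] + b[1]; b[1] <- 0 }
  if (b[2] < 0) { b[1] <- max(0, b[1] + b[2]); b[2] <- 0 }
  b
}

.fmt_len <- function(x) sprintf("%.12g", max(0, x))

#' Build an unrooted neighbor-joining tree
#'
#' Standard Saitou-Nei agglomeration: iteratively joins the pair
#' minimizing Q(i, j) = (n-2) d(i, j) - r_i - r_j, with the usual branch
#' length formulas. Negative branch lengths are clamped to zero with the
#' excess transferred to the sister branch; Q ties are broken by the
#' lexicographically smallest pair of subtree labels, making the result
#' deterministic.
#'
#' @param d Symmetric distance matrix with row/column names and zero
#'   diagonal; at least 3 taxa.
#' @return An \code{ape} \code{phylo} object (unrooted).
#' @export
build_nj_tree <- function(d) {
  stopifnot(is.matrix(d), nrow(d) == ncol(d))
  if (nrow(d) < 3L) stop("neighbor joining needs at least 3 taxa")
  if (is.null(rownames(d))) stop("distance matrix must carry taxon names")
  if (max(abs(d - t(d))) > 1e-12) stop("distance matrix is not symmetric")

  labels <- rownames(d)          # lexicographic tie-break key per node
  newick <- rownames(d)          # growing subtree strings
  D <- d
  while (nrow(D) > 3L) {
    n <- nrow(D)
    r <- rowSums(D)
    Q <- (n - 2) * D - outer(r, r, `+`)
    diag(Q) <- Inf
    pick <- .nj_pick_pair(Q, labels)
    i <- pick[1]; j <- pick[2]
    bi <- 0.5 * D[i, j] + (r[i] - r[j]) / (2 * (n - 2))
    b <- .clamp_pair(c(bi, D[i, j] - bi))
    new_nwk <- sprintf("(%s:%s,%s:%s)", newick[i], .fmt_len(b[1]),
                       newick[j], .fmt_len(b[2]))
    new_lab <- min(labels[i], labels[j])
    du <- 0.5 * (D[i, ] + D[j, ] - D[i, j])
    keep <- setdiff(seq_len(n), c(i, j))
    D2 <- rbind(cbind(D[keep, keep, drop = FALSE], du[keep]),
                c(du[keep], 0))
    rownames(D2) <- colnames(D2) <- c(rownames(D)[keep], new_lab)
    D <- D2
    newick <- c(newick[keep], new_nwk)
    labels <- c(labels[keep], new_lab)
  }
  # final trivalent join: closed-form three-point branch lengths
  b1 <- max(0, (D[1, 2] + D[1, 3] - D[2, 3]) / 2)
  b2 <- max(0, (D[1, 2] + D[2, 3] - D[1, 3]) / 2)
  b3 <- max(0, (D[1, 3] + D[2, 3] - D[1, 2]) / 2)
  txt <- sprintf("(%s:%s,%s:%s,%s:%s);",
                 newick[1], .fmt_len(b1), newick[2], .fmt_len(b2),
                 newick[3], .fmt_len(b3))
  ape::read.tree(text = txt)
}

#' Assign family groups by nearest labeled reference
#'
#' Each query takes the group of its nearest reference, by patristic
#' (tree path-length) distance when a tree is supplied, otherwise by the
#' raw distance matrix. A query whose two nearest references carry
#' different labels with a distance margin below \code{tie_margin} is
#' labeled \code{"UC"} (unclassified).
#'
#' @param d Symmetric distance matrix over queries and references.
#' @param reference_labels Named character vector: reference id -> group
#'   (A..J, or UC for reference members of unclassified clades).
#' @param tree Optional \code{phylo} tree over the same taxa; when given,
#'   path-length distances are used.
#' @param tie_margin Margin (substitutions/site) below which conflicting
#'   nearest references yield UC (default 0.02).
#' @return \code{data.frame}: \code{gene_id}, \code{group},
#'   \code{support} (distance to the nearest reference).
#' @export
assign_groups <- function(d, reference_labels, tree = NULL,
                          tie_margin = 0.02) {
  refs <- names(reference_labels)
  if (is.null(refs) || any(is.na(reference_labels)) ||
      any(reference_labels == "")) {
    stop("every reference must carry a non-empty group label")
  }
  if (!all(reference_labels %in% .FAMILY_GROUPS)) {
    stop("reference labels must be A..J or UC")
  }
  if (!is.null(tree)) {
    d <- stats::cophenetic(tree)
  }
  stopifnot(all(refs %in% rownames(d)))
  queries <- rownames(d)
  out <- lapply(queries, function(q) {
    dd <- d[q, refs]
    ord <- order(dd, refs)       # deterministic on distance ties
    lab <- unname(reference_labels[refs[ord[1]]])
    support <- dd[ord[1]]
    if (length(refs) > 1L) {
      lab2 <- unname(reference_labels[refs[ord[2]]])
      if (lab2 != lab && (dd[ord[2]] - dd[ord[1]]) < tie_margin &&
          support > 0) {
        lab <- "UC"
      }
    }
    data.frame(gene_id = q, group = lab, support = unname(support),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Bootstrap support for a neighbor-joining domain tree
#'
#' Resamples alignment columns with replacement, rebuilds the NJ tree per
#' replicate and reports, for each internal edge of the reference tree,
#' the proportion of replicates containing the same bipartition.
#'
#' @param aln A \code{domain_alignment}.
#' @param n_replicates Number of bootstrap replicates (default 100).
#' @param seed Random seed.
#' @return List with the reference \code{tree} and \code{support}
#'   (proportions in [0, 1], ordered as \code{ape::prop.clades} over the
#'   reference tree's internal nodes).
#' @export
bootstrap_nj <- function(aln, n_replicates = 100L, seed = 1L) {
  stopifnot(inherits(aln, "domain_alignment"))
  ref <- build_nj_tree(p_distance(aln))
  set.seed(seed)
  reps <- lapply(seq_len(n_replicates), function(i) {
    cols <- sample(ncol(aln$matrix), replace = TRUE)
    build_nj_tree(p_distance(aln$matrix[, cols, drop = FALSE]))
  })
  counts <- ape::prop.clades(ref, reps, rooted = FALSE)
  counts[is.na(counts)] <- 0
  list(tree = ref, support = counts / n_replicates)
}
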