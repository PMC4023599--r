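# Expression analyses: thresholded Pearson co-expression, 2^-ddCt
# relative quantification, stress-responder calling, correlation-based
# clustering, and qPCR-vs-atlas agreement.

.pcc_p_value <- function(r, n) {
  # two-tailed p from the t transform, n-2 degrees of freedom
  r <- pmin(1, pmax(-1, r))
  t <- abs(r) * sqrt((n - 2) / pmax(.Machine$double.eps, 1 - r^2))
  p <- 2 * stats::pt(-t, df = n - 2)
  p[abs(r) >= 1] <- 0
  p
}

#' Classify all gene pairs by Pearson co-expression
#'
#' Computes the product-moment correlation of every unordered gene pair
#' across samples, its two-tailed p-value from the t transform
#' t = r sqrt((n-2)/(1-r^2)), and classifies pairs by the conventional
#' thresholds: significant-positive (p < alpha and r >= pos),
#' significant-negative (p < alpha and r <= neg), strong-positive
#' (significant-positive with r > strong), otherwise not-significant.
#' Boundary values count (r = pos with p < alpha is significant-positive).
#'
#' @param m Genes x samples numeric matrix (log2 intensities).
#' @param alpha Significance level (default 0.01, two-tailed).
#' @param pos,neg,strong Correlation thresholds (defaults 0.35, -0.35,
#'   0.9).
#' @return \code{data.frame}: \code{gene_a}, \code{gene_b}, \code{pcc},
#'   \code{p_value}, \code{class}. Zero-variance rows are excluded with a
#'   warning; fewer than 3 samples is an error.
#' @export
pairwise_pcc <- function(m, alpha = 0.01, pos = 0.35, neg = -0.35,
                         strong = 0.9) {
  stopifnot(is.matrix(m), !is.null(rownames(m)))
  n <- ncol(m)
  if (n < 3L) stop("need at least 3 samples to test correlations")
  v <- apply(m, 1, stats::var)
  if (any(v == 0)) {
    warning("zero-variance gene(s) excluded: ",
            paste(rownames(m)[v == 0], collapse = ", "))
    m <- m[v > 0, , drop = FALSE]
  }
  g <- nrow(m)
  if (g < 2L) {
    return(data.frame(gene_a = character(), gene_b = character(),
                      pcc = numeric(), p_value = numeric(),
                      class = character(), stringsAsFactors = FALSE))
  }
  r <- stats::cor(t(m))
  pair <- which(upper.tri(r), arr.ind = TRUE)
  pcc <- r[pair]
  p <- .pcc_p_value(pcc, n)
  sig_pos <- p < alpha & pcc >= pos
  sig_neg <- p < alpha & pcc <= neg
  cls <- rep("not-significant", length(pcc))
  cls[sig_pos] <- "significant-positive"
  cls[sig_pos & pcc > strong] <- "strong-positive"
  cls[sig_neg] <- "significant-negative"
  data.frame(
    gene_a = rownames(m)[pair[, 1]],
    gene_b = rownames(m)[pair[, 2]],
    pcc = pcc,
    p_value = p,
    class = cls,
    stringsAsFactors = FALSE
  )
}

#' Relative expression by the 2^-ddCt method
#'
#' ddCt = (Ct_target - Ct_reference)_treatment - (Ct_target -
#' Ct_reference)_control; fold = 2^-ddCt. Technical replicates are
#' averaged at the Ct level within each biological replicate; ddCt is
#' formed per biological replicate against its own control (falling back
#' to the mean control dCt when a replicate lacks a control measurement),
#' and folds are averaged across biological replicates.
#'
#' @param records Ct table as from \code{\link{read_ct_table}}: columns
#'   \code{gene_id}, \code{condition}, \code{bio_rep}, \code{tech_rep},
#'   \code{ct_target}, \code{ct_reference}.
#' @param control_condition Name of the control/calibrator condition; its
#'   folds are exactly 1.
#' @return \code{data.frame}: \code{gene_id}, \code{condition},
#'   \code{fold}, \code{n_bio}.
#' @export
ddct_relative_expression <- function(records, control_condition) {
  needed <- c("gene_id", "condition", "bio_rep", "ct_target",
              "ct_reference")
  stopifnot(all(needed %in% colnames(records)))
  if (any(is.na(records$ct_reference))) {
    bad <- records[is.na(records$ct_reference), ][1, ]
    stop("missing reference-gene Ct for ", bad$gene_id, " in condition ",
         bad$condition)
  }
  if (!control_condition %in% records$condition) {
    stop("no records for control condition ", control_condition)
  }
  # technical replicates -> one dCt per gene x condition x biological rep
  key <- interaction(records$gene_id, records$condition, records$bio_rep,
                     drop = TRUE)
  dct <- do.call(rbind, lapply(split(records, key), function(df) {
    data.frame(gene_id = df$gene_id[1], condition = df$condition[1],
               bio_rep = df$bio_rep[1],
               dct = mean(df$ct_target) - mean(df$ct_reference),
               stringsAsFactors = FALSE)
  }))
  out <- lapply(split(dct, dct$gene_id), function(df) {
    ctrl <- df[df$condition == control_condition, ]
    if (nrow(ctrl) == 0L) {
      stop("no control records for gene ", df$gene_id[1])
    }
    ctrl_by_rep <- stats::setNames(ctrl$dct, ctrl$bio_rep)
    folds_by_cond <- lapply(split(df, df$condition), function(cd) {
      ref <- ctrl_by_rep[as.character(cd$bio_rep)]
      ref[is.na(ref)] <- mean(ctrl$dct)
      mean(2^(-(cd$dct - ref)))
    })
    data.frame(gene_id = df$gene_id[1],
               condition = names(folds_by_cond),
               fold = unlist(folds_by_cond, use.names = FALSE),
               n_bio = vapply(split(df, df$condition), nrow, integer(1)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Call stress responders from fold changes
#'
#' A gene is up-regulated when any condition reaches
#' \code{fold >= threshold} (the boundary counts: "at least two fold" is
#' inclusive) and down-regulated when any reaches
#' \code{fold <= 1/threshold}; both can hold at once.
#'
#' @param folds \code{data.frame} with columns \code{gene_id},
#'   \code{condition}, \code{fold} (positive), e.g. from
#'   \code{\link{ddct_relative_expression}}.
#' @param threshold Fold-change threshold (default 2).
#' @param exclude_conditions Conditions ignored for calling (e.g. the
#'   control itself); default none.
#' @return \code{data.frame}: \code{gene_id}, \code{direction} (\code{up},
#'   \code{down}, \code{both} or \code{none}), \code{max_fold},
#'   \code{min_fold}.
#' @export
classify_responders <- function(folds, threshold = 2,
                                exclude_conditions = character()) {
  stopifnot(all(c("gene_id", "condition", "fold") %in% colnames(folds)),
            all(folds$fold > 0))
  folds <- folds[!folds$condition %in% exclude_conditions, , drop = FALSE]
  out <- lapply(split(folds, folds$gene_id), function(df) {
    up <- any(df$fold >= threshold)
    down <- any(df$fold <= 1 / threshold)
    data.frame(
      gene_id = df$gene_id[1],
      direction = if (up && down) "both" else if (up) "up"
      else if (down) "down" else "none",
      max_fold = max(df$fold),
      min_fold = min(df$fold),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Cluster expression profiles by correlation distance
#'
#' Agglomerative clustering with average linkage on distance 1 - PCC, cut
#' at k clusters. Constant rows cannot enter a correlation distance; they
#' are assigned afterwards to the cluster with the nearest mean profile in
#' Euclidean distance, with a warning.
#'
#' @param m Genes x samples numeric matrix.
#' @param k Number of clusters (default 4); must not exceed the number of
#'   genes.
#' @return Named integer vector of cluster labels (1..k).
#' @export
cluster_expression <- function(m, k = 4L) {
  stopifnot(is.matrix(m), !is.null(rownames(m)))
  if (k > nrow(m)) stop("k exceeds the number of genes")
  v <- apply(m, 1, stats::var)
  constant <- rownames(m)[v == 0]
  mv <- m[v > 0, , drop = FALSE]
  if (length(constant) > 0L) {
    warning("constant row(s) assigned by Euclidean fallback: ",
            paste(constant, collapse = ", "))
  }
  k_eff <- min(k, nrow(mv))
  d <- stats::as.dist(1 - stats::cor(t(mv)))
  hc <- stats::hclust(d, method = "average")
  labels <- stats::cutree(hc, k = k_eff)
  if (length(constant) > 0L) {
    centers <- t(vapply(seq_len(k_eff), function(cl) {
      colMeans(mv[labels == cl, , drop = FALSE])
    }, numeric(ncol(m))))
    extra <- vapply(constant, function(g) {
      which.min(rowSums((centers - matrix(m[g, ], k_eff, ncol(m),
                                          byrow = TRUE))^2))
    }, integer(1))
    labels <- c(labels, extra)
  }
  labels[rownames(m)]
}

#' Agreement between qPCR and atlas expression profiles
#'
#' For each gene measured on both platforms, computes the Pearson
#' correlation across matched samples and flags agreement at the
#' two-tailed \code{alpha} level.
#'
#' @param qpcr Genes x samples matrix of qPCR relative expression.
#' @param atlas Genes x samples matrix of atlas values.
#' @param sample_pairs \code{data.frame} with columns \code{qpcr_sample},
#'   \code{atlas_sample} giving the matched tissues.
#' @param alpha Significance level (default 0.01).
#' @return \code{data.frame}: \code{gene_id}, \code{pcc}, \code{p_value},
#'   \code{agreement}, \code{n}. Genes with fewer than 3 matched samples
#'   are skipped with a warning.
#' @export
compare_qpcr_vs_atlas <- function(qpcr, atlas, sample_pairs,
                                  alpha = 0.01) {
  stopifnot(all(c("qpcr_sample", "atlas_sample") %in%
                  colnames(sample_pairs)))
  qs <- sample_pairs$qpcr_sample
  as_ <- sample_pairs$atlas_sample
  stopifnot(all(qs %in% colnames(qpcr)), all(as_ %in% colnames(atlas)))
  genes <- intersect(rownames(qpcr), rownames(atlas))
  rows <- lapply(genes, function(g) {
    x <- qpcr[g, qs]; y <- atlas[g, as_]
    ok <- is.finite(x) & is.finite(y)
    if (sum(ok) < 3L) {
      warning("gene ", g, " skipped: fewer than 3 matched samples")
      return(NULL)
    }
    r <- stats::cor(x[ok], y[ok])
    p <- .pcc_p_value(r, sum(ok))
    data.frame(gene_id = g, pcc = r, p_value = p,
               agreement = p < alpha, n = sum(ok),
               stringsAsFactors = FALSE)
  })
  rows <- Filter(Negate(is.null), rows)
  if (length(rows) == 0L) {
    return(data.frame(gene_id = character(), pcc = numeric(),
                      p_value = numeric(), agreement = logical(),
                      n = integer(), stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}
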