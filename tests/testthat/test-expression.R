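test_that("pairwise PCC hits the exact endpoints and classes", {
  set.seed(2)
  base <- rnorm(54)
  m <- rbind(g1 = base,
             g2 = 2 * base + 5,     # exact positive affine copy
             g3 = -base)            # exact negation
  pc <- pairwise_pcc(m)
  r12 <- pc[pc$gene_a == "g1" & pc$gene_b == "g2", ]
  expect_equal(r12$pcc, 1)
  expect_equal(r12$class, "strong-positive")
  r13 <- pc[pc$gene_a == "g1" & pc$gene_b == "g3", ]
  expect_equal(r13$pcc, -1)
  expect_equal(r13$class, "significant-negative")
  expect_error(pairwise_pcc(m[, 1:2]), "3 samples")
  m2 <- rbind(m, g4 = rep(1, 54))
  expect_warning(pc2 <- pairwise_pcc(m2), "zero-variance")
  expect_false("g4" %in% c(pc2$gene_a, pc2$gene_b))
})

test_that("PCC values match the covariance-formula oracle to 1e-12", {
  set.seed(31)
  m <- matrix(rnorm(10 * 54), 10, 54,
              dimnames = list(sprintf("g%02d", 1:10), NULL))
  pc <- pairwise_pcc(m)
  expect_equal(nrow(pc), choose(10, 2))
  for (i in seq_len(nrow(pc))) {
    r_oracle <- oracle_pcc(m[pc$gene_a[i], ], m[pc$gene_b[i], ])
    expect_equal(pc$pcc[i], r_oracle, tolerance = 1e-12)
    # class must follow the thresholds applied to the oracle value
    p_oracle <- 2 * pt(-abs(r_oracle) * sqrt(52 / (1 - r_oracle^2)), 52)
    want <- if (p_oracle < 0.01 && r_oracle >= 0.35) {
      if (r_oracle > 0.9) "strong-positive" else "significant-positive"
    } else if (p_oracle < 0.01 && r_oracle <= -0.35) {
      "significant-negative"
    } else "not-significant"
    expect_equal(pc$class[i], want)
  }
})

test_that("classification boundaries are honored at r = 0.35 and r = 0.9", {
  # construct pairs with sample correlation within 1e-12 of the target
  set.seed(7)
  n <- 54
  x <- as.vector(scale(rnorm(n)))
  z <- residuals(lm(rnorm(n) ~ x)); z <- as.vector(scale(z))
  mk <- function(r) r * x + sqrt(1 - r^2) * z
  for (case in list(list(0.351, "significant-positive"),
                    list(0.349, "not-significant"),
                    list(0.9005, "strong-positive"),
                    list(0.8995, "significant-positive"),
                    list(-0.351, "significant-negative"),
                    list(-0.349, "not-significant"))) {
    m <- rbind(a = x, b = mk(case[[1]]))
    pc <- pairwise_pcc(m)
    expect_equal(pc$pcc, case[[1]], tolerance = 1e-9)
    expect_equal(pc$class, case[[2]])
  }
})

test_that("ddCt folds follow the definition and its invariances", {
  rec <- expand.grid(gene_id = "g1", condition = c("ctrl", "trt"),
                     bio_rep = 1:3, tech_rep = 1:3,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  rec$ct_reference <- 18
  rec$ct_target <- ifelse(rec$condition == "ctrl", 23, 22)  # dCt 5 vs 4
  f <- ddct_relative_expression(rec, "ctrl")
  expect_equal(f$fold[f$condition == "ctrl"], 1)
  expect_equal(f$fold[f$condition == "trt"], 2)

  # equal Cts in treatment and control -> fold 1
  rec2 <- rec; rec2$ct_target <- 23
  f2 <- ddct_relative_expression(rec2, "ctrl")
  expect_equal(f2$fold, c(1, 1))

  # adding a constant to target AND reference of one condition is neutral
  rec3 <- rec
  shift <- rec3$condition == "trt"
  rec3$ct_target[shift] <- rec3$ct_target[shift] + 3.7
  rec3$ct_reference[shift] <- rec3$ct_reference[shift] + 3.7
  f3 <- ddct_relative_expression(rec3, "ctrl")
  expect_equal(f3$fold, f$fold)

  rec4 <- rec; rec4$ct_reference[1] <- NA
  expect_error(ddct_relative_expression(rec4, "ctrl"), "reference")
  expect_error(ddct_relative_expression(rec, "0d"), "control")
})

test_that("responder calls use the inclusive two-fold boundary", {
  folds <- data.frame(gene_id = rep(c("flat", "edge", "dn", "both"),
                                    each = 2),
                      condition = rep(c("t1", "t2"), 4),
                      fold = c(1, 1, 1.1, 2.0, 0.5, 0.9, 2.5, 0.4))
  calls <- classify_responders(folds)
  calls <- calls[match(c("flat", "edge", "dn", "both"), calls$gene_id), ]
  expect_equal(calls$direction, c("none", "up", "down", "both"))
  expect_equal(calls$max_fold[2], 2.0)

  # monotone: raising the threshold never adds responders
  set.seed(5)
  rnd <- data.frame(gene_id = rep(sprintf("g%02d", 1:30), each = 4),
                    condition = rep(paste0("t", 1:4), 30),
                    fold = 2^runif(120, -3, 3))
  up2 <- classify_responders(rnd, threshold = 2)
  up3 <- classify_responders(rnd, threshold = 3)
  responders <- function(x) x$gene_id[x$direction != "none"]
  expect_true(all(responders(up3) %in% responders(up2)))
  # brute-force agreement
  for (g in unique(rnd$gene_id)) {
    fg <- rnd$fold[rnd$gene_id == g]
    want_up <- any(fg >= 2); want_dn <- any(fg <= 0.5)
    got <- up2$direction[up2$gene_id == g]
    expect_equal(got, if (want_up && want_dn) "both" else
      if (want_up) "up" else if (want_dn) "down" else "none")
  }
})

test_that("correlation clustering recovers planted blocks and invariances", {
  sim <- gen_expression_matrix(12, n_samples = 40,
                               blocks = list(1:6, 7:12), r_target = 0.95,
                               seed = 13)
  labels <- cluster_expression(sim$matrix, k = 2)
  expect_equal(length(unique(labels[1:6])), 1L)
  expect_equal(length(unique(labels[7:12])), 1L)
  expect_false(labels[1] == labels[7])

  # k = n -> singletons
  expect_equal(sort(unname(cluster_expression(sim$matrix[1:5, ], k = 5))),
               1:5)
  # permutation of genes -> identical partition up to renaming
  perm <- sample(12)
  lp <- cluster_expression(sim$matrix[perm, ], k = 2)[rownames(sim$matrix)]
  expect_equal(length(unique(paste(labels, lp))), 2L)
  expect_error(cluster_expression(sim$matrix, k = 13), "exceeds")
  # constant row falls back to Euclidean assignment with a warning
  m2 <- rbind(sim$matrix, flatgene = rep(sim$matrix[1, 1], 40))
  expect_warning(l2 <- cluster_expression(m2, k = 2), "flatgene")
  expect_true(l2["flatgene"] %in% 1:2)
})

test_that("qPCR-vs-atlas agreement flags follow the exact t test", {
  qp <- rbind(gA = c(1, 2, 3, 4), gB = c(1, -1, 1, -1))
  at <- rbind(gA = c(2, 4, 6, 8), gB = c(-1, -1, 1, 1))
  pairs <- data.frame(qpcr_sample = as.character(1:4),
                      atlas_sample = paste0("s", 1:4))
  colnames(qp) <- pairs$qpcr_sample
  colnames(at) <- pairs$atlas_sample
  cmp <- compare_qpcr_vs_atlas(qp, at, pairs)
  expect_equal(cmp$pcc[cmp$gene_id == "gA"], 1)
  expect_true(cmp$agreement[cmp$gene_id == "gA"])
  expect_equal(cmp$pcc[cmp$gene_id == "gB"], 0)
  expect_false(cmp$agreement[cmp$gene_id == "gB"])

  qp2 <- qp; qp2["gB", 2:4] <- NA
  expect_warning(cmp2 <- compare_qpcr_vs_atlas(qp2, at, pairs), "skipped")
  expect_false("gB" %in% cmp2$gene_id)

  # flag behavior matches the exact t quantile at alpha = 0.01
  set.seed(41)
  for (rep in 1:20) {
    x <- rnorm(5); y <- 0.99 * scale(x)[, 1] + 0.1 * rnorm(5)
    qp3 <- rbind(g = x); at3 <- rbind(g = y)
    colnames(qp3) <- colnames(at3) <- paste0("s", 1:5)
    p5 <- data.frame(qpcr_sample = paste0("s", 1:5),
                     atlas_sample = paste0("s", 1:5))
    got <- compare_qpcr_vs_atlas(qp3, at3, p5)
    r <- cor(x, y)
    p <- 2 * pt(-abs(r) * sqrt(3 / (1 - r^2)), 3)
    expect_equal(got$agreement, p < 0.01)
  }
})
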