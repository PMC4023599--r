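test_that("intron phases follow cumulative CDS length mod 3", {
  mk <- function(len1, len2) {
    gene_model("g", "chr1", "+",
               exons = rbind(c(0L, len1), c(len1 + 100L, len1 + 100L + len2)))
  }
  expect_equal(compute_intron_phases(mk(30L, 30L))$phase, 0L)
  expect_equal(compute_intron_phases(mk(31L, 29L))$phase, 1L)
  expect_equal(compute_intron_phases(mk(32L, 28L))$phase, 2L)
  # zero-intron gene: empty, not an error
  single <- gene_model("g", "chr1", "+", matrix(c(0L, 30L), 1))
  expect_equal(nrow(compute_intron_phases(single)), 0L)
})

test_that("phases telescope across exons and mirror across strands", {
  for (seed in 1:10) {
    set.seed(seed)
    plan <- data.frame(
      subregion = c("basic", "zipper"),
      frame_position = c(-12, 4),
      phase = sample(0:2, 2, replace = TRUE)
    )
    p <- gen_bzip_protein(heptads = 4, seed = seed)
    fwd <- gen_bzip_gene(p, plan, strand = "+", seed = seed)
    rev <- gen_bzip_gene(p, plan, strand = "-", seed = seed)
    ph_f <- compute_intron_phases(fwd$model)
    ph_r <- compute_intron_phases(rev$model)
    expect_equal(ph_f$phase, plan$phase)  # plan is already 5'->3'
    expect_equal(ph_f$phase, ph_r$phase)
    expect_equal(ph_f$codon_offset, ph_r$codon_offset)
    # telescoping: phase_k = (phase_{k-1} + exon_k length) mod 3
    lens <- fwd$model$cds[, 2] - fwd$model$cds[, 1]
    expect_equal(ph_f$phase,
                 cumsum(lens)[-length(lens)] %% 3L)
  }
})

test_that("domain-to-genome mapping matches a per-nucleotide codon walk", {
  # single-exon plus-strand gene: residue 0 -> [start, start + 3)
  p <- gen_bzip_protein(heptads = 3, seed = 31)
  g0 <- gen_bzip_gene(p, NULL, strand = "+", seed = 31)
  ann0 <- annotate_bzip_domain(p$sequence, id = p$id)
  start <- g0$model$cds[1, 1]
  iv <- map_domain_to_genome(g0$model, ann0)
  expect_equal(iv$basic[1, 1], start + 3L * ann0$asn_index)

  for (strand in c("+", "-")) {
    plan <- data.frame(subregion = c("basic", "hinge", "downstream"),
                       frame_position = c(-12, -5, 2),
                       phase = c(2, 0, 1))
    g <- gen_bzip_gene(p, plan, strand = strand, seed = 32)
    ann <- annotate_bzip_domain(translate_cds(g$model, g$contig), id = p$id)
    walk <- oracle_cds_to_genomic(g$model)  # CDS coord -> genomic coord
    spans <- map_domain_to_genome(g$model, ann)
    for (sub in names(spans)) {
      res <- seq(ann$spans[[sub]][1], ann$spans[[sub]][2] - 1L)
      nts <- unlist(lapply(res, function(r) walk[(3L * r):(3L * r + 2L) + 1L]))
      covered <- sort(unique(unlist(
        lapply(seq_len(nrow(spans[[sub]])), function(k) {
          seq(spans[[sub]][k, 1], spans[[sub]][k, 2] - 1L)
        }))))
      expect_equal(covered, sort(nts))
    }
  }
})

test_that("domain introns are located with subregion, frame and flanks", {
  p <- gen_bzip_protein(heptads = 4, seed = 41)
  plan <- data.frame(subregion = c("hinge", "downstream"),
                     frame_position = c(-4, 3), phase = c(0, 0))
  g <- gen_bzip_gene(p, plan, strand = "+", seed = 41)
  ann <- annotate_bzip_domain(p$sequence, id = p$id)
  di <- locate_domain_introns(g$model, ann, p$sequence)
  expect_equal(nrow(di), 1L)            # downstream intron excluded
  expect_equal(di$subregion, "hinge")
  expect_equal(di$frame_position, -4L)
  expect_equal(di$phase, 0L)

  # gene with introns overall but none in the domain -> empty
  plan2 <- data.frame(subregion = "downstream", frame_position = c(1, 5),
                      phase = c(0, 2))
  g2 <- gen_bzip_gene(p, plan2, strand = "+", seed = 42)
  expect_equal(nrow(locate_domain_introns(g2$model, ann, p$sequence)), 0L)
})

test_that("planted (subregion, phase) combinations are recovered in bulk", {
  subregions <- c("basic", "hinge", "zipper")
  frames <- list(basic = c(-16, -12), hinge = c(-7, -3), zipper = c(3, 10))
  n_ok <- 0L; n_all <- 0L
  for (seed in 1:50) {
    set.seed(seed + 900)
    sub <- sample(subregions, 1)
    fp <- sample(frames[[sub]], 1)
    ph <- sample(0:2, 1)
    strand <- sample(c("+", "-"), 1)
    p <- gen_bzip_protein(heptads = 4, seed = seed + 900)
    g <- gen_bzip_gene(p, data.frame(subregion = sub, frame_position = fp,
                                     phase = ph),
                       strand = strand, seed = seed)
    ann <- annotate_bzip_domain(p$sequence, id = p$id)
    di <- locate_domain_introns(g$model, ann, p$sequence)
    n_all <- n_all + 1L
    if (nrow(di) == 1L && di$subregion == sub && di$phase == ph &&
        di$frame_position == fp) {
      n_ok <- n_ok + 1L
    }
  }
  expect_equal(n_ok, n_all)
})

test_that("pattern classifier reproduces the published rule table", {
  di <- function(...) {
    d <- data.frame(..., stringsAsFactors = FALSE)
    if (is.null(d$aa_before)) d$aa_before <- rep("G", nrow(d))
    if (is.null(d$aa_after)) d$aa_after <- rep("G", nrow(d))
    d
  }
  # two P0 introns in basic + hinge (the VvbZIP23-style configuration)
  expect_equal(classify_intron_pattern(
    di(subregion = c("basic", "hinge"), phase = c(0L, 0L),
       frame_position = c(-14L, -5L))), "b")
  # single P1 intron in the basic region (VvbZIP53-style)
  expect_equal(classify_intron_pattern(
    di(subregion = "basic", phase = 1L, frame_position = -14L)), "g")
  # empty: i under the text scheme, h under the table scheme
  empty <- di(subregion = character(0), phase = integer(0),
              frame_position = integer(0))
  expect_equal(classify_intron_pattern(empty, scheme = "text"), "i")
  expect_equal(classify_intron_pattern(empty, scheme = "table"), "h")
  # c/d/e split by the zipper intron position
  for (case in list(list(4L, "c"), list(11L, "d"), list(16L, "e"))) {
    expect_equal(classify_intron_pattern(
      di(subregion = c("basic", "zipper"), phase = c(2L, 0L),
         frame_position = c(-12L, case[[1]]))), case[[2]])
  }
  # Gln|Ala flanks separate a from h
  expect_equal(classify_intron_pattern(
    di(subregion = "zipper", phase = 0L, frame_position = 4L,
       aa_before = "Q", aa_after = "A")), "a")
  expect_equal(classify_intron_pattern(
    di(subregion = "zipper", phase = 0L, frame_position = 4L,
       aa_before = "S", aa_after = "T")), "h")
})

test_that("classifier agrees with an independent rule oracle on all cases", {
  subregions <- c("basic", "hinge", "zipper")
  single <- expand.grid(subregion = subregions, phase = 0:2,
                        frame_position = c(-14, -5, 4, 11, 16),
                        flankQA = c(TRUE, FALSE), stringsAsFactors = FALSE)
  valid_frame <- function(sub, fp) {
    (sub == "basic" & fp <= -10) | (sub == "hinge" & fp > -10 & fp < 0) |
      (sub == "zipper" & fp > 0)
  }
  single <- single[valid_frame(single$subregion, single$frame_position), ]
  as_di <- function(rows) {
    data.frame(subregion = rows$subregion, phase = as.integer(rows$phase),
               frame_position = as.integer(rows$frame_position),
               aa_before = ifelse(rows$flankQA, "Q", "S"),
               aa_after = ifelse(rows$flankQA, "A", "T"),
               stringsAsFactors = FALSE)
  }
  letter <- function(x) as.character(x)  # drop the diagnostic attribute
  # all single-intron cases
  for (i in seq_len(nrow(single))) {
    d <- as_di(single[i, ])
    expect_equal(letter(classify_intron_pattern(d)),
                 letter(oracle_pattern_text(d)),
                 info = paste(unlist(single[i, ]), collapse = "/"))
  }
  # all ordered two-intron combinations
  idx <- expand.grid(i = seq_len(nrow(single)), j = seq_len(nrow(single)))
  idx <- idx[idx$i != idx$j, ]
  for (k in seq_len(nrow(idx))) {
    d <- as_di(single[c(idx$i[k], idx$j[k]), ])
    expect_equal(letter(classify_intron_pattern(d)),
                 letter(oracle_pattern_text(d)))
  }
})

test_that("all nine structural patterns are planted and recovered, both strands", {
  for (strand in c("+", "-")) {
    for (pat in letters[1:9]) {
      g <- gen_pattern_example(pat, strand = strand, seed = 60)
      prot <- translate_cds(g$model, g$contig)
      expect_identical(prot, g$protein$sequence)
      ann <- annotate_bzip_domain(prot, id = g$model$gene_id)
      di <- locate_domain_introns(g$model, ann, prot)
      expect_equal(classify_intron_pattern(di), pat,
                   info = paste(pat, strand))
    }
  }
})

test_that("gene-structure summary reports counts, patterns and flags", {
  genes <- lapply(1:6, function(i) {
    gen_pattern_example(letters[i], strand = "+", seed = 70 + i)
  })
  models <- stats::setNames(lapply(genes, `[[`, "model"),
                            vapply(genes, function(g) g$model$gene_id, ""))
  seqs <- stats::setNames(
    vapply(genes, function(g) g$protein$sequence, ""), names(models))
  anns <- stats::setNames(
    lapply(names(models), function(id) annotate_bzip_domain(seqs[[id]],
                                                            id = id)),
    names(models))
  out <- summarize_gene_structures(models, anns, seqs)
  expect_equal(out$pattern, letters[1:6])
  expect_equal(out$intron_count,
               vapply(models, function(m) nrow(m$cds) - 1L, integer(1),
                      USE.NAMES = FALSE))
  # a missing model flags the gene instead of dropping it
  out2 <- summarize_gene_structures(models[-1], anns, seqs)
  expect_true(out2$flagged[out2$gene_id == names(models)[1]])
  expect_equal(nrow(out2), 6L)
})

test_that("two planted introns in one codon are refused", {
  p <- gen_bzip_protein(heptads = 3, seed = 80)
  plan <- data.frame(subregion = c("basic", "basic"),
                     frame_position = c(-12, -12), phase = c(1, 2))
  expect_error(gen_bzip_gene(p, plan), "one codon")
})
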