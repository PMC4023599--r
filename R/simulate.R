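# Synthetic-data generators. Every generator is deterministic given
# (configuration, seed) and returns its planted ground truth alongside the
# data, so that a zero-noise run of the full pipeline can be checked
# against the truth exactly.

# Residues that never carry grammar meaning: no Asn/Arg/Lys (anchor
# residues) and no Leu/Ile/Val/Phe/Met (heptad residues). Filler drawn
# from this alphabet can neither seed a spurious anchor nor extend a
# zipper, which makes the planted annotation provably unique.
.FILLER_AA <- c("A", "C", "D", "E", "G", "H", "P", "Q", "S", "T", "W", "Y")

#' Generate a protein obeying the bZIP domain grammar
#'
#' Plants an Asn at frame -18, Arg (or a requested substitution) at -10
#' and Leu at each heptad position; every other residue is filler drawn
#' from the non-grammar alphabet (no N/R/K/L/I/V/F/M), so the planted
#' anchor and heptad count are the unique best annotation.
#'
#' @param heptads Number of heptad units (3..11).
#' @param substitutions Named character vector of planted residues by frame
#'   position, e.g. \code{c("-10" = "K", "+8" = "M")}. Replacing the
#'   invariant Asn at -18 is refused while \code{strict} is \code{TRUE}.
#' @param seed Random seed.
#' @param id Protein id (default derived from the seed).
#' @param group Optional group label carried into the truth.
#' @param n_tail,c_tail Flanking tail lengths (defaults 12 and 15).
#' @param strict Refuse substitutions that break the grammar itself
#'   (default \code{TRUE}).
#' @return List: \code{id}, \code{sequence}, \code{truth} (list with
#'   \code{asn_index}, \code{heptads}, \code{substitutions}, \code{group},
#'   \code{gradient}).
#' @export
gen_bzip_protein <- function(heptads, substitutions = NULL, seed = 1L,
                             id = NULL, group = NA_character_,
                             n_tail = 12L, c_tail = 15L, strict = TRUE) {
  stopifnot(heptads >= 3L, heptads <= 11L)
  if (strict && "-18" %in% names(substitutions)) {
    stop("replacing the invariant Asn at -18 breaks the grammar")
  }
  set.seed(seed)
  if (is.null(id)) id <- sprintf("synbzip%05d", seed)
  filler <- function(n) sample(.FILLER_AA, n, replace = TRUE)
  asn_index <- n_tail
  zipper <- character(7L * heptads - 6L)
  zipper[] <- filler(length(zipper))
  zipper[1L + 7L * (seq_len(heptads) - 1L)] <- "L"
  chars <- c(filler(n_tail),
             "N", filler(7L), "R", filler(9L),
             zipper,
             filler(c_tail))
  for (fp in names(substitutions)) {
    idx <- frame_to_index(as.integer(fp), asn_index)
    if (idx < 0L || idx >= length(chars)) {
      stop("substitution at frame ", fp, " falls outside the sequence")
    }
    chars[idx + 1L] <- substitutions[[fp]]
  }
  list(
    id = id,
    sequence = paste(chars, collapse = ""),
    truth = list(
      asn_index = asn_index,
      heptads = heptads,
      substitutions = substitutions,
      group = group,
      gradient = as.character(utils::as.roman(heptads - 2L))
    )
  )
}

.CODON_FOR_AA <- c(
  A = "GCT", C = "TGT", D = "GAT", E = "GAA", F = "TTT", G = "GGT",
  H = "CAT", I = "ATT", K = "AAA", L = "CTG", M = "ATG", N = "AAT",
  P = "CCT", Q = "CAA", R = "CGT", S = "TCT", T = "ACT", V = "GTT",
  W = "TGG", Y = "TAT"
)

#' Generate a gene model with planted introns inside the bZIP domain
#'
#' Reverse-translates a generated protein into a CDS, cuts it at the
#' requested codon boundaries/offsets so each planted intron lands in the
#' requested subregion with the requested phase, and assembles a contig
#' (with GT..AG introns and random flanks). On the minus strand the
#' reverse-complemented contig is emitted with mirrored coordinates.
#'
#' @param protein A list from \code{\link{gen_bzip_protein}}.
#' @param intron_plan \code{data.frame} with columns \code{subregion}
#'   (\code{basic}/\code{hinge}/\code{zipper}/\code{downstream}),
#'   \code{frame_position} (domain frame; for \code{downstream} introns a
#'   0-based codon offset past the domain instead) and \code{phase}
#'   (0/1/2). May have zero rows.
#' @param strand \code{"+"} or \code{"-"}.
#' @param seed Random seed (intron and flank sequence).
#' @param intron_length,flank Intron and flank lengths in bp.
#' @param chromosome Contig name.
#' @return List: \code{model} (a \code{gene_model}), \code{contig}
#'   (\code{DNAString}), \code{protein} (the input), \code{truth} (the
#'   plan plus the planted CDS cut offsets).
#' @export
gen_bzip_gene <- function(protein, intron_plan = NULL, strand = "+",
                          seed = 1L, intron_length = 90L, flank = 150L,
                          chromosome = "chrSim") {
  set.seed(seed)
  aa <- strsplit(protein$sequence, "", fixed = TRUE)[[1]]
  cds <- paste(.CODON_FOR_AA[aa], collapse = "")
  cds <- paste0(cds, "TAA")
  cds_len <- nchar(cds)
  asn <- protein$truth$asn_index

  if (is.null(intron_plan) || nrow(intron_plan) == 0L) {
    cuts <- integer(0)
  } else {
    stopifnot(all(intron_plan$phase %in% 0:2))
    codon <- mapply(function(sub, fp) {
      if (sub == "downstream") {
        # first codon past the zipper span (last heptad + 7), then fp more
        zip_span_end <- asn + 18L + 7L * (protein$truth$heptads - 1L) + 7L
        zip_span_end + fp
      } else {
        frame_to_index(as.integer(fp), asn)
      }
    }, intron_plan$subregion, intron_plan$frame_position)
    cuts <- as.integer(3L * codon + intron_plan$phase)
    if (anyDuplicated(codon)) stop("two introns in one codon")
    if (any(cuts <= 0L) || any(cuts >= cds_len)) {
      stop("intron plan positions must lie strictly inside the CDS")
    }
    ord <- order(cuts)
    cuts <- cuts[ord]
  }

  rand_nt <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                      replace = TRUE), collapse = "")
  bounds <- c(0L, cuts, cds_len)
  exon_seqs <- substring(cds, bounds[-length(bounds)] + 1L, bounds[-1])
  introns <- vapply(seq_along(cuts), function(k) {
    paste0("GT", rand_nt(intron_length - 4L), "AG")
  }, character(1))
  pieces <- character(0)
  sense_exons <- matrix(integer(0), ncol = 2)
  pos <- flank
  for (k in seq_along(exon_seqs)) {
    sense_exons <- rbind(sense_exons,
                         c(pos, pos + nchar(exon_seqs[k])))
    pieces <- c(pieces, exon_seqs[k])
    pos <- pos + nchar(exon_seqs[k])
    if (k <= length(introns)) {
      pieces <- c(pieces, introns[k])
      pos <- pos + nchar(introns[k])
    }
  }
  contig <- paste0(rand_nt(flank), paste(pieces, collapse = ""),
                   rand_nt(flank))
  L <- nchar(contig)

  if (strand == "-") {
    contig <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(contig)))
    exons <- cbind(L - sense_exons[, 2], L - sense_exons[, 1])
  } else {
    exons <- sense_exons
  }
  model <- gene_model(
    gene_id = protein$id, chromosome = chromosome, strand = strand,
    exons = exons
  )
  list(
    model = model,
    contig = Biostrings::DNAString(contig),
    protein = protein,
    truth = list(plan = intron_plan, cds_cuts = cuts)
  )
}

#' Construct a synthetic example gene for each structural pattern
#'
#' Builds a protein and gene model whose domain introns classify, under
#' the text scheme, to the requested pattern letter a-i.
#'
#' @param pattern One of letters a..i.
#' @param strand \code{"+"} or \code{"-"}.
#' @param seed Random seed.
#' @return As \code{\link{gen_bzip_gene}}; \code{truth$pattern} holds the
#'   planted letter.
#' @export
gen_pattern_example <- function(pattern = letters[1:9], strand = "+",
                                seed = 1L) {
  pattern <- match.arg(pattern)
  plan <- function(...) {
    df <- data.frame(...)
    df[, c("subregion", "frame_position", "phase")]
  }
  subs <- NULL
  ip <- switch(pattern,
    a = {
      subs <- c("+3" = "Q", "+4" = "A")
      plan(subregion = "zipper", frame_position = 4, phase = 0)
    },
    b = plan(subregion = c("basic", "hinge"),
             frame_position = c(-14, -5), phase = c(0, 0)),
    c = plan(subregion = c("basic", "zipper"),
             frame_position = c(-12, 4), phase = c(2, 0)),
    d = plan(subregion = c("basic", "zipper"),
             frame_position = c(-12, 11), phase = c(2, 0)),
    e = plan(subregion = c("basic", "zipper"),
             frame_position = c(-12, 16), phase = c(2, 0)),
    f = plan(subregion = "basic", frame_position = -12, phase = 2),
    g = plan(subregion = "basic", frame_position = -14, phase = 1),
    h = {
      subs <- c("+3" = "S", "+4" = "T")
      plan(subregion = "zipper", frame_position = 4, phase = 0)
    },
    i = plan(subregion = character(0), frame_position = numeric(0),
             phase = numeric(0))
  )
  prot <- gen_bzip_protein(heptads = 4L, substitutions = subs, seed = seed,
                           id = sprintf("pat_%s_%s_%d", pattern, strand,
                                        seed))
  g <- gen_bzip_gene(prot, intron_plan = ip, strand = strand,
                     seed = seed + 7L)
  g$truth$pattern <- pattern
  g
}

#' Generate an expression matrix with planted correlated blocks
#'
#' Block members share a latent per-sample profile: member values are
#' mu_g + sqrt(r) z + sqrt(1-r) * noise_sd * e, so that with the default
#' \code{noise_sd = 1} the population within-block correlation is exactly
#' \code{r_target} (and exactly 1 when \code{r_target = 1}, independent of
#' the noise). Background genes are independent.
#'
#' @param n_genes Number of genes.
#' @param n_samples Number of samples (default 54, a typical organ/tissue
#'   atlas size; at n = 54 the critical |r| at p = 0.01 is about 0.35).
#' @param blocks List of integer vectors of gene indices (disjoint).
#' @param r_target Population within-block correlation, in [0, 1).
#'   \code{r_target = 1} is allowed and gives identical profiles up to the
#'   gene baseline.
#' @param noise_sd Scale of the independent component (default 1, which
#'   preserves the calibration; must be >= 0).
#' @param baseline_mean Mean log2-intensity baseline (default 8).
#' @param seed Random seed.
#' @return List: \code{matrix} (genes x samples, dimnames set),
#'   \code{truth} (blocks, r_target).
#' @export
gen_expression_matrix <- function(n_genes, n_samples = 54L,
                                  blocks = list(), r_target = 0.9,
                                  noise_sd = 1, baseline_mean = 8,
                                  seed = 1L) {
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  stopifnot(r_target >= 0, r_target <= 1)
  if (length(blocks) > 1L && anyDuplicated(unlist(blocks))) {
    stop("blocks must be disjoint")
  }
  set.seed(seed)
  gene_ids <- sprintf("gene%03d", seq_len(n_genes))
  sample_ids <- sprintf("sample%02d", seq_len(n_samples))
  mu <- stats::rnorm(n_genes, baseline_mean, 1)
  m <- matrix(stats::rnorm(n_genes * n_samples, sd = max(noise_sd, 0)),
              n_genes, n_samples, dimnames = list(gene_ids, sample_ids))
  for (b in blocks) {
    z <- stats::rnorm(n_samples)
    for (g in b) {
      m[g, ] <- sqrt(r_target) * z +
        sqrt(1 - r_target) * noise_sd * stats::rnorm(n_samples)
    }
  }
  m <- m + mu
  list(matrix = m,
       truth = list(blocks = lapply(blocks, function(b) gene_ids[b]),
                    r_target = r_target))
}

#' Generate a qRT-PCR Ct table with planted fold changes
#'
#' Inverts the 2^-ddCt model: Ct_target = baseline_g - log2(fold) + noise,
#' with the reference-gene Ct constant within each condition, so that at
#' zero noise \code{\link{ddct_relative_expression}} recovers the planted
#' folds exactly.
#'
#' @param planted_folds Genes x conditions numeric matrix of fold changes
#'   (all > 0); the control column must be 1.
#' @param control_condition Control column name (default the first
#'   column).
#' @param n_bio,n_tech Biological / technical replicates (defaults 3, 3).
#' @param ct_noise_sd Normal noise on target Ct cycles (default 0).
#' @param baseline_ct Mean target Ct at fold 1 (default 25 cycles).
#' @param reference_ct Reference-gene Ct (default 18 cycles).
#' @param seed Random seed.
#' @return List: \code{records} (Ct table \code{data.frame}),
#'   \code{truth} (the planted fold matrix).
#' @export
gen_qpcr <- function(planted_folds,
                     control_condition = colnames(planted_folds)[1],
                     n_bio = 3L, n_tech = 3L, ct_noise_sd = 0,
                     baseline_ct = 25, reference_ct = 18, seed = 1L) {
  stopifnot(is.matrix(planted_folds), all(planted_folds > 0),
            !is.null(rownames(planted_folds)),
            !is.null(colnames(planted_folds)))
  if (any(planted_folds[, control_condition] != 1)) {
    stop("control-condition folds must be planted as 1")
  }
  set.seed(seed)
  genes <- rownames(planted_folds)
  conds <- colnames(planted_folds)
  grid <- expand.grid(gene_id = genes, condition = conds,
                      bio_rep = seq_len(n_bio), tech_rep = seq_len(n_tech),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  base_g <- stats::setNames(baseline_ct + stats::runif(length(genes), -2, 2),
                            genes)
  fold <- planted_folds[cbind(grid$gene_id, grid$condition)]
  grid$ct_target <- base_g[grid$gene_id] - log2(fold) +
    stats::rnorm(nrow(grid), sd = ct_noise_sd)
  grid$ct_reference <- reference_ct
  grid <- grid[, c("gene_id", "condition", "bio_rep", "tech_rep",
                   "ct_target", "ct_reference")]
  list(records = grid, truth = list(folds = planted_folds))
}
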