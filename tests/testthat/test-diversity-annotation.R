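# Distance matrices, UPGMA, PCA and variant functional annotation, each
# checked against an independent brute-force oracle.

test_that("mismatch distance matches a double-loop oracle", {
  vt <- random_vt(n = 100, samples = paste0("S", 1:5), seed = 3)
  d <- genotype_distance(vt)
  expect_equal(diag(d), setNames(rep(0, 5), paste0("S", 1:5)))
  expect_equal(d, t(d))
  gt <- as.matrix(vt[paste0("S", 1:5)])
  for (i in 1:4) for (j in (i + 1):5) {
    num <- 0; den <- 0
    for (k in seq_len(nrow(gt))) {
      if (!is.na(gt[k, i]) && !is.na(gt[k, j])) {
        den <- den + 1
        if (gt[k, i] != gt[k, j]) num <- num + 1
      }
    }
    expect_equal(d[i, j], num / den)
  }
  # identical and fully discordant pairs hit the bounds
  vt2 <- make_vt("1", 1:10, rep("A", 10), rep("T", 10),
                 list(X = rep("0/0", 10), Y = rep("0/0", 10),
                      Z = rep("1/1", 10)))
  d2 <- genotype_distance(vt2)
  expect_equal(d2["X", "Y"], 0)
  expect_equal(d2["X", "Z"], 1)
})

# independent UPGMA oracle: recompute every merge's distance from the
# ORIGINAL matrix as the mean over all leaf pairs (no incremental update)
upgma_oracle_heights <- function(d) {
  labs <- rownames(d)
  clusters <- as.list(labs)
  heights <- c()
  while (length(clusters) > 1) {
    best <- NULL; bestd <- Inf
    for (i in seq_along(clusters)) for (j in seq_along(clusters)) {
      if (i < j) {
        dd <- mean(d[clusters[[i]], clusters[[j]]])
        if (dd < bestd - 1e-12) { bestd <- dd; best <- c(i, j) }
      }
    }
    heights <- c(heights, bestd / 2)
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  sort(heights)
}

test_that("UPGMA agglomerates the worked example and simple cases", {
  d <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tree <- upgma(d)
  want <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
  expect_true(ape::all.equal.phylo(tree, want, use.edge.length = TRUE))
  # two taxa: a cherry at half the distance
  d2 <- matrix(c(0, 3, 3, 0), 2, 2, dimnames = list(c("x", "y"),
                                                    c("x", "y")))
  expect_true(ape::all.equal.phylo(
    upgma(d2), ape::read.tree(text = "(x:1.5,y:1.5);"),
    use.edge.length = TRUE))
  expect_match(write_newick(upgma(d2)), "x:1.5")
})

test_that("UPGMA trees are ultrametric and match brute force on <= 5 taxa", {
  withr::with_seed(23, {
    for (rep in 1:12) {
      n <- sample(3:5, 1)
      m <- matrix(0, n, n)
      m[upper.tri(m)] <- sample(10:1000, n * (n - 1) / 2)
      m <- m + t(m)
      dimnames(m) <- list(letters[1:n], letters[1:n])
      tree <- upgma(m)
      # ultrametric: all root-to-tip path lengths equal
      depths <- ape::node.depth.edgelength(tree)[seq_len(n)]
      expect_lt(max(depths) - min(depths), 1e-9)
      # merge heights match the all-pairs re-averaging oracle
      node_h <- ape::branching.times(tree)
      expect_equal(sort(unname(node_h)), upgma_oracle_heights(m),
                   tolerance = 1e-9)
      # and the tree topology agrees with average-linkage hclust
      hc <- stats::hclust(stats::as.dist(m), method = "average")
      ht <- ape::as.phylo(hc)
      expect_equal(ape::dist.topo(ape::unroot(tree), ape::unroot(ht)), 0,
                   ignore_attr = TRUE)
    }
  })
})

test_that("two-group parents cluster into two monophyletic groups", {
  hits <- 0L
  for (s in 1:10) {
    cfg <- simulation_config(seed = 100 + s)
    ref <- generate_reference(cfg)
    parents <- generate_parents(cfg, ref)
    d <- genotype_distance(parents)
    tree <- upgma(d)
    donor_like <- c(cfg$donors, "MTU1010")
    rec_like <- setdiff(cfg$recipients, "MTU1010")
    tree_u <- ape::unroot(tree)
    ok <- ape::is.monophyletic(tree, donor_like) &&
      ape::is.monophyletic(tree, rec_like)
    hits <- hits + ok
  }
  expect_gte(hits, 9L)  # >= 95%-style recovery at this sample of runs
})

test_that("PCA coordinates match an SVD oracle", {
  vt <- random_vt(n = 20, samples = paste0("S", 1:5), seed = 17,
                  het_rate = 0.2, missing_rate = 0)
  p <- pca_coordinates(vt, n_components = 3)
  expect_true(sum(p$explained_variance) <= 1 + 1e-12)
  # oracle: centred dosage matrix decomposed directly
  gt <- as.matrix(vt[paste0("S", 1:5)])
  x <- t(matrix(c(0, 1, 2)[match(gt, c("0/0", "0/1", "1/1"))],
                nrow = nrow(gt)))
  x <- x[, apply(x, 2, var) > 0, drop = FALSE]
  xc <- scale(x, center = TRUE, scale = FALSE)
  sv <- svd(xc)
  scores <- sv$u %*% diag(sv$d)
  for (k in 1:3) {
    expect_equal(abs(p$scores[[paste0("PC", k)]]), abs(scores[, k]),
                 tolerance = 1e-6, ignore_attr = TRUE)
  }
  # mirror-image pair: symmetric PC1 scores
  vt3 <- make_vt("1", 1:6, rep("A", 6), rep("T", 6),
                 list(M = rep("0/0", 6), W = rep("1/1", 6)))
  p3 <- pca_coordinates(vt3, 1)
  expect_equal(sum(p3$scores$PC1), 0, tolerance = 1e-12)
})

make_models <- function() {
  # gene g1 on +: exons 101-200 and 301-400; CDS 151-200 + 301-351 (UTRs
  # flanking); gene g2 on -: single exon 601-700 fully coding except UTRs
  tibble::tribble(
    ~gene_id, ~chromosome, ~strand, ~feature, ~start, ~end,
    "g1", "1", "+", "gene", 101L, 400L,
    "g1", "1", "+", "exon", 101L, 200L,
    "g1", "1", "+", "exon", 301L, 400L,
    "g1", "1", "+", "UTR", 101L, 150L,
    "g1", "1", "+", "CDS", 151L, 200L,
    "g1", "1", "+", "CDS", 301L, 351L,
    "g1", "1", "+", "UTR", 352L, 400L
  )
}

test_that("variant context classification respects feature precedence", {
  gm <- make_models()
  v <- tibble::tibble(chromosome = "1",
                      position_bp = c(50L, 120L, 160L, 250L, 360L, 500L))
  out <- classify_variant_context(v, gm)
  expect_equal(out$context,
               c("intergenic", "UTR", "CDS", "intron", "UTR", "intergenic"))
  # brute-force interval oracle over random positions
  withr::with_seed(5, {
    pos <- sample(1:800, 1000, replace = TRUE)
  })
  out2 <- classify_variant_context(
    tibble::tibble(chromosome = "1", position_bp = pos), gm)
  oracle <- vapply(pos, function(p) {
    inside <- function(f) any(gm$feature == f & gm$start <= p & gm$end >= p)
    if (inside("CDS")) "CDS" else if (inside("UTR")) "UTR"
    else if (inside("gene")) "intron" else "intergenic"
  }, character(1))
  expect_identical(out2$context, oracle)
  # exactly one label per variant, always
  expect_true(all(out2$context %in% c("CDS", "UTR", "intron",
                                      "intergenic")))
})

test_that("coding effects translate codons with strand handling", {
  # plus-strand single-codon gene: GCA at 11..13
  seqs <- paste0(strrep("T", 10), "GCAATG", strrep("T", 10))
  ref <- ref_from_seq(seqs)
  gm <- tibble::tibble(gene_id = "g", chromosome = "1", strand = "+",
                       feature = "CDS", start = c(11L, 14L),
                       end = c(13L, 16L))
  # GCA -> GCG at codon position 3: synonymous (Ala)
  eff <- coding_effect(tibble::tibble(chromosome = "1", position_bp = 13L,
                                      ref_allele = "A", alt_allele = "G"),
                       gm, ref)
  expect_equal(eff$effect, "synonymous")
  expect_equal(eff$ref_aa, "A")
  # ATG -> ACG at its second base: missense (Met -> Thr)
  eff2 <- coding_effect(tibble::tibble(chromosome = "1", position_bp = 15L,
                                       ref_allele = "T", alt_allele = "C"),
                        gm, ref)
  expect_equal(eff2$effect, "missense")
  expect_equal(c(eff2$ref_aa, eff2$alt_aa), c("M", "T"))
  # a CDS whose length is not a codon multiple is an error
  gm_bad <- dplyr::mutate(gm, end = c(13L, 15L))
  expect_error(coding_effect(tibble::tibble(chromosome = "1",
                                            position_bp = 12L,
                                            ref_allele = "C",
                                            alt_allele = "T"),
                             gm_bad, ref),
               class = "kaspanel_validation_error")
})

test_that("all single-base codon edits agree with exhaustive translation", {
  code <- Biostrings::GENETIC_CODE
  withr::with_seed(41, {
    codons <- replicate(50, paste(sample(c("A", "C", "G", "T"), 3,
                                         replace = TRUE), collapse = ""))
  })
  for (codon in codons) {
    ref <- ref_from_seq(paste0("TTTT", codon, "TTTT"))
    gm <- tibble::tibble(gene_id = "g", chromosome = "1", strand = "+",
                         feature = "CDS", start = 5L, end = 7L)
    for (p in 1:3) {
      for (alt in setdiff(c("A", "C", "G", "T"),
                          substr(codon, p, p))) {
        eff <- coding_effect(
          tibble::tibble(chromosome = "1", position_bp = 4L + p,
                         alt_allele = alt), gm, ref)
        alt_codon <- codon
        substr(alt_codon, p, p) <- alt
        aa1 <- code[[codon]]; aa2 <- code[[alt_codon]]
        want <- if (aa1 == "*" || aa2 == "*") "other"
                else if (aa1 == aa2) "synonymous" else "missense"
        expect_equal(eff$effect, want)
      }
    }
  }
})

test_that("coding effects are strand-consistent under mirroring", {
  withr::with_seed(8, {
    cds <- paste(sample(c("A", "C", "G", "T"), 30, replace = TRUE),
                 collapse = "")
  })
  seqs <- paste0("AAAA", cds, "AAAA")
  ref_plus <- ref_from_seq(seqs)
  gm_plus <- tibble::tibble(gene_id = "g", chromosome = "1", strand = "+",
                            feature = "CDS", start = 5L, end = 34L)
  # mirrored chromosome: reverse complement, gene on the minus strand
  seqs_rc <- as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(seqs)))
  ref_minus <- ref_from_seq(seqs_rc)
  L <- nchar(seqs)
  gm_minus <- tibble::tibble(gene_id = "g", chromosome = "1", strand = "-",
                             feature = "CDS", start = L - 34L + 1L,
                             end = L - 5L + 1L)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  for (off in c(0L, 7L, 16L, 29L)) {
    pos <- 5L + off
    base <- substr(seqs, pos, pos)
    alt <- setdiff(c("A", "C", "G", "T"), base)[1]
    e1 <- coding_effect(tibble::tibble(chromosome = "1", position_bp = pos,
                                       alt_allele = alt), gm_plus, ref_plus)
    pos_rc <- L - pos + 1L
    e2 <- coding_effect(tibble::tibble(chromosome = "1",
                                       position_bp = pos_rc,
                                       alt_allele = unname(comp[alt])),
                        gm_minus, ref_minus)
    expect_equal(e2$effect, e1$effect)
    expect_equal(c(e2$ref_aa, e2$alt_aa), c(e1$ref_aa, e1$alt_aa))
  }
})

test_that("GFF3 gene models load through the standard importer", {
  skip_if_not_installed("rtracklayer")
  gff <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "1\ttest\tgene\t101\t400\t.\t+\t.\tID=g1",
    "1\ttest\tmRNA\t101\t400\t.\t+\t.\tID=g1.1;Parent=g1",
    "1\ttest\texon\t101\t200\t.\t+\t.\tParent=g1.1",
    "1\ttest\tfive_prime_UTR\t101\t150\t.\t+\t.\tParent=g1.1",
    "1\ttest\tCDS\t151\t200\t.\t+\t0\tParent=g1.1"
  ), gff)
  gm <- read_gene_models(gff)
  expect_setequal_chr(unique(gm$feature), c("gene", "exon", "UTR", "CDS"))
  expect_true(all(gm$gene_id == "g1"))
  out <- classify_variant_context(
    tibble::tibble(chromosome = "1", position_bp = c(120L, 160L, 300L)),
    gm)
  expect_equal(out$context, c("UTR", "CDS", "intron"))
})
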