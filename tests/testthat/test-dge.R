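test_that("size factors: identity, scaling and the median-of-ratios oracle", {
  m <- matrix(rpois(300, 50), 50, 6,
              dimnames = list(sprintf("g%02d", 1:50), sprintf("s%d", 1:6)))
  expect_equal(unname(size_factors(m[, c(1, 1, 1)])), rep(1, 3))

  two <- cbind(a = m[, 1], b = 2 * m[, 1])
  sf2 <- size_factors(two)
  expect_equal(unname(sf2[2] / sf2[1]), 2)

  # independent brute-force oracle on a random NB matrix
  set.seed(33)
  big <- matrix(rnbinom(3000, mu = rlnorm(500, 4, 1), size = 10), 500, 6,
                dimnames = list(sprintf("g%03d", 1:500), sprintf("s%d", 1:6)))
  keep <- apply(big > 0, 1, all)
  ref <- exp(rowMeans(log(big[keep, ])))
  oracle <- apply(big[keep, ] / ref, 2, median)
  oracle <- oracle / exp(mean(log(oracle)))
  expect_equal(unname(size_factors(big)), unname(oracle), tolerance = 1e-12)

  # invariant to gene permutation, equivariant to column scaling
  expect_equal(size_factors(big[sample(nrow(big)), ]), size_factors(big))
  sc <- size_factors(sweep(big, 2, c(1, 2, 1, 1, 1, 1), "*") |> round())
  expect_gt(sc[2] / sc[1], 1.9)
})

test_that("size factors error without an all-expressed gene unless fallback", {
  m <- rbind(g1 = c(0, 5, 5), g2 = c(5, 0, 5), g3 = c(5, 5, 0))
  colnames(m) <- c("a", "b", "c")
  expect_error(size_factors(m), "fallback")
  expect_length(size_factors(m, fallback = TRUE), 3)
})

test_that("BH adjustment matches an independent step-up oracle", {
  expect_equal(bh_adjust(0.02), 0.02)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")

  step_up <- function(p) {  # textbook BH with explicit monotonicity pass
    n <- length(p)
    o <- order(p)
    adj <- p[o] * n / seq_len(n)
    adj <- rev(cummin(rev(adj)))
    pmin(1, adj)[order(o)]
  }
  set.seed(7)
  for (i in 1:25) {
    p <- runif(sample(1:40, 1))
    expect_equal(bh_adjust(p), step_up(p))
  }
})

test_that("coverage estimate implements reads x length / transcriptome", {
  expect_equal(coverage_estimate(760000, 100, 76e6), 1)
  expect_equal(coverage_estimate(2 * 760000, 100, 76e6), 2)
  expect_equal(coverage_estimate(9120000, 100, 76e6), 12)
  expect_error(coverage_estimate(0, 100, 76e6), "positive")
})

test_that("identical count vectors in both groups give LFC 0 and p near 1", {
  mu <- matrix(c(80, 80, 40, 60), 2, 2,
               dimnames = list(c("flat", "moving"), NULL))
  cm <- make_counts(mu, data.frame(genotype = "WT",
                                   age_group = c("2-6", "9-16")),
                    n_reps = 3, dispersion = NULL)
  # perturb replicate columns identically in both groups for the flat gene
  cm$counts["flat", ] <- rep(c(70, 80, 90), 2)
  deg <- nb_test(cm, list(age_group = "2-6"), list(age_group = "9-16"),
                 sf = setNames(rep(1, 6), cm$samples$sample))
  i <- which(deg$gene == "flat")
  expect_equal(deg$log2FC[i], 0, tolerance = 1e-6)
  expect_equal(deg$pvalue[i], 1, tolerance = 1e-6)
})

test_that("all-zero genes are reported flat and excluded from the FDR family", {
  set.seed(5)
  mu <- cbind(rep(100, 40), rep(100, 40))
  rownames(mu) <- sprintf("g%02d", 1:40)
  cm <- make_counts(mu, data.frame(genotype = "WT",
                                   age_group = c("2-6", "9-16")),
                    n_reps = 3, dispersion = 0.1, seed = 6)
  cm$counts["g01", ] <- 0
  deg <- nb_test(cm, list(age_group = "2-6"), list(age_group = "9-16"))
  i <- which(deg$gene == "g01")
  expect_equal(deg$log2FC[i], 0)
  expect_equal(deg$pvalue[i], 1)
  expect_false(deg$significant[i])
  # BH family excludes the all-zero gene: recompute over the rest
  expect_equal(deg$padj[-i], bh_adjust(deg$pvalue[-i]))
})

test_that("DEG table invariants hold on simulated data", {
  sim <- small_sim()
  deg <- nb_test(sim$counts, list(genotype = "WT", age_group = "2-6"),
                 list(genotype = "WT", age_group = "30-36"))
  expect_true(all(deg$padj >= deg$pvalue - 1e-12, na.rm = TRUE))
  nz <- deg$log2FC != 0
  expect_identical(deg$direction[nz],
                   ifelse(deg$log2FC[nz] > 0, "up", "down"))
  expect_identical(deg$significant, !is.na(deg$padj) & deg$padj < 0.05 &
                     abs(deg$log2FC) >= 0)
  expect_error(nb_test(sim$counts, list(genotype = "WT", age_group = "2-6"),
                       list(genotype = "none")), "no samples")
})

test_that("power rises with effect size and replicate number", {
  pwr <- function(lfc, n_reps, seed) {
    set.seed(seed)
    G <- 150
    mu0 <- rlnorm(G, log(150), 0.8)
    mu <- cbind(mu0, mu0 * 2^c(rep(lfc, 30), rep(0, G - 30)))
    rownames(mu) <- sprintf("g%03d", 1:G)
    cm <- make_counts(mu, data.frame(genotype = "WT",
                                     age_group = c("2-6", "9-16")),
                      n_reps = n_reps, dispersion = 0.1, seed = seed)
    deg <- nb_test(cm, list(age_group = "2-6"), list(age_group = "9-16"))
    mean(deg$significant[1:30])
  }
  p_small <- mean(sapply(1:3, pwr, lfc = 0.5, n_reps = 3))
  p_mid <- mean(sapply(1:3, pwr, lfc = 2, n_reps = 3))
  p_big <- mean(sapply(1:3, pwr, lfc = 2, n_reps = 8))
  expect_lte(p_small, p_mid)
  expect_lte(p_mid, p_big + 0.02)
  expect_gt(p_big, 0.9)
})

test_that("log2 fold changes agree with an established NB GLM implementation", {
  suppressPackageStartupMessages(requireNamespace("DESeq2"))
  set.seed(14)
  G <- 250
  mu0 <- rlnorm(G, log(120), 1)
  lfc <- c(rnorm(50, 0, 1.5), rep(0, G - 50))
  mu <- cbind(mu0, mu0 * 2^lfc)
  rownames(mu) <- sprintf("g%03d", 1:G)
  cm <- make_counts(mu, data.frame(genotype = "WT",
                                   age_group = c("2-6", "9-16")),
                    n_reps = 4, dispersion = 0.05, seed = 14)
  deg <- nb_test(cm, list(age_group = "2-6"), list(age_group = "9-16"))

  coldata <- cm$samples
  coldata$age_group <- factor(as.character(coldata$age_group))
  dds <- DESeq2::DESeqDataSetFromMatrix(
    countData = matrix(as.integer(cm$counts), nrow(cm$counts),
                       dimnames = dimnames(cm$counts)),
    colData = coldata, design = ~age_group)
  dds <- suppressMessages(DESeq2::DESeq(dds, quiet = TRUE))
  res <- DESeq2::results(dds, contrast = c("age_group", "9-16", "2-6"))
  keep <- deg$baseMean > 20
  expect_gt(cor(deg$log2FC[keep], res$log2FoldChange[keep]), 0.98)
  # significance calls mostly agree too
  agree <- mean((deg$padj < 0.05) == (res$padj < 0.05), na.rm = TRUE)
  expect_gt(agree, 0.9)
})
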