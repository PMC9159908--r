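test_that("relative abundances are per-sample proportions", {
  counts <- matrix(c(5, 0, 0, 2, 2, 2), nrow = 3,
                   dimnames = list(paste0("t", 1:3), c("s1", "s2")))
  rel <- relativeAbundance(counts)
  expect_equal(rel[, "s1"], c(t1 = 1, t2 = 0, t3 = 0))
  expect_equal(rel[, "s2"], rep(1 / 3, 3), ignore_attr = TRUE)
  set.seed(7)
  r <- relativeAbundance(matrix(rpois(40, 5) + 1, nrow = 8,
                                dimnames = list(paste0("t", 1:8),
                                                paste0("s", 1:5))))
  expect_equal(colSums(r), rep(1, 5), ignore_attr = TRUE)
  empty <- counts; empty[, 2] <- 0
  expect_error(relativeAbundance(empty), class = "msipValidationError")
})

test_that("alpha diversity matches closed forms and hand computation", {
  S <- 12
  expect_equal(shannonIndex(rep(1 / S, S)), log(S))
  expect_equal(simpsonIndex(rep(1 / S, S))$D, 1 / S)
  expect_equal(shannonIndex(c(1, 0, 0)), 0)
  expect_equal(simpsonIndex(c(1, 0, 0))$D, 1)
  p <- c(0.5, 0.25, 0.25)
  expect_equal(shannonIndex(p), 1.0397, tolerance = 1e-4)
  expect_equal(simpsonIndex(p)$D, 0.375)
  expect_equal(simpsonIndex(p)$one_minus_D, 0.625)
})

test_that("shannon is maximized by the uniform distribution", {
  set.seed(8)
  S <- 20
  hUnif <- shannonIndex(rep(1 / S, S))
  for (i in 1:30) {
    p <- as.vector(stats::rgamma(S, 1))
    p <- p / sum(p)
    expect_lte(shannonIndex(p), hUnif + 1e-12)
  }
})

test_that("fold change reproduces the printed ratios and is reciprocal", {
  expect_equal(round(foldChange(14.3, 1.7)$fold, 1), 8.4)
  expect_equal(foldChange(3, 3)$fold, 1)
  expect_equal(foldChange(1.7, 0.004)$fold, 425)
  set.seed(9)
  a <- runif(10, 0.01, 1); b <- runif(10, 0.01, 1)
  expect_equal(foldChange(a, b)$fold * foldChange(b, a)$fold, rep(1, 10))
  expect_equal(foldChange(4, 2)$log2_fold, 1)
  # pseudocount keeps zero-abundance taxa finite
  expect_true(is.finite(foldChange(1, 0, pseudocount = 0.001)$fold))
})

test_that("the default pseudocount is half the smallest nonzero abundance", {
  expect_equal(defaultPseudocount(c(0, 0.004, 0.1)), 0.002)
  expect_equal(defaultPseudocount(c(0, 0)), 0)
})

test_that("two-group test matches the pooled t-test and handles degeneracy", {
  expect_equal(taxonTest(c(1, 1, 1), c(1, 1, 1)), 1)
  expect_equal(taxonTest(c(0, 0, 0), c(10, 10, 10)), 0)
  set.seed(10)
  x <- rnorm(5); y <- rnorm(5, 1)
  expect_equal(taxonTest(x, y),
               stats::t.test(x, y, var.equal = TRUE)$p.value)
  jitter <- c(0, 1e-9, -1e-9)
  expect_lt(taxonTest(jitter, 10 + jitter), 1e-6)
  expect_error(taxonTest(1, c(1, 2)), class = "msipValidationError")
})

test_that("LSD pairwise comparisons hold their nominal type-I error", {
  set.seed(11)
  hits <- replicate(1000, {
    y <- stats::rnorm(9)
    g <- gl(3, 3)
    r <- lsdTest(y, g)
    r$anova_p < 0.05 && any(r$pairwise$p < 0.05)
  })
  expect_gt(mean(hits), 0.02)
  expect_lt(mean(hits), 0.08)
})

test_that("volcano classes are exhaustive, exclusive, and threshold-true", {
  expect_equal(volcanoClassify(2, 0.01), "enriched")
  expect_equal(volcanoClassify(-1, 0.01), "depleted")
  expect_equal(volcanoClassify(2, 0.2), "unchanged")
  expect_equal(volcanoClassify(0, 0.001), "unchanged")
  set.seed(12)
  lfc <- rnorm(200); p <- runif(200)
  cls <- volcanoClassify(lfc, p)
  expect_true(all(cls %in% c("enriched", "depleted", "unchanged")))
  expect_equal(cls == "enriched", p < 0.05 & lfc > 0)
  expect_equal(cls == "depleted", p < 0.05 & lfc < 0)
  expect_error(volcanoClassify(1, 2), class = "msipValidationError")
})

test_that("volcano analysis flags a planted responder as enriched", {
  o <- simulateOtuTable(seed = 5, nReplicates = 10,
                        groups = c("NoCH4", "13CH4"),
                        nBackgroundTaxa = 60, dispersion = 100,
                        libSize = 5e4)
  v <- volcanoAnalysis(o$se, "13CH4", "NoCH4")
  hit <- v[v$taxon == "Otu0001", ]
  expect_equal(hit$class, "enriched")
  expect_lt(abs(log(hit$fold / 8.4)), log(1.4))
})

test_that("alpha diversity and taxonomy survive the OTU container", {
  o <- simulateOtuTable(seed = 6)
  ad <- alphaDiversity(o$se)
  expect_equal(nrow(ad), ncol(SummarizedExperiment::assay(o$se, "counts")))
  expect_true(all(ad$shannon > 0))
  expect_true(all(ad$simpson_D >= 0 & ad$simpson_D <= 1))
  expect_equal(ad$simpson_D + ad$simpson_1mD, rep(1, nrow(ad)))
})
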