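test_that("Hill numbers hit the closed-form cases", {
  expect_equal(hillDiversity(c(25, 25, 25, 25)), 4)
  expect_equal(hillDiversity(c(10)), 1)
  # (75, 25): Shannon = 0.5623 by hand, then exponentiate
  H <- -(0.75 * log(0.75) + 0.25 * log(0.25))
  expect_equal(hillDiversity(c(75, 25)), exp(H))
  expect_equal(hillDiversity(c(75, 25)), 1.7548, tolerance = 1e-4)
  expect_equal(hillDiversity(c(75, 25), q = 0), 2)
  # zero-count taxa are ignored
  expect_equal(hillDiversity(c(75, 25, 0, 0)), hillDiversity(c(75, 25)))
  expect_error(hillDiversity(c(0, 0)), "empty sample")

  # 1D <= 0D with equality only when uniform
  set.seed(1)
  for (i in 1:10) {
    x <- rpois(8, 30) + 1
    expect_lte(hillDiversity(x, 1), hillDiversity(x, 0) + 1e-9)
  }
  # agreement with the standard Shannon implementation
  m <- matrix(rpois(40, 20) + 1, nrow = 4)
  expect_equal(unname(hillDiversity(m)), exp(vegan::diversity(m, "shannon")),
               ignore_attr = TRUE)
})

test_that("Hill evenness is the 1D/0D ratio", {
  expect_equal(hillEvenness(rep(7, 5)), 1)
  expect_equal(hillEvenness(c(100)), 1)
  expect_equal(hillEvenness(c(75, 25)), hillDiversity(c(75, 25)) / 2)
})

test_that("Hellinger rows are unit-norm square-root proportions", {
  m <- rbind(c(1, 4), c(3, 3))
  h <- hellingerTransform(m)
  expect_equal(h[1, ], c(sqrt(0.2), sqrt(0.8)), ignore_attr = TRUE)
  expect_equal(unname(rowSums(h^2)), c(1, 1))
  hs <- hellingerTransform(matrix(5, 3, 4))
  expect_equal(unique(as.vector(hs)), 1 / sqrt(4))
  expect_error(hellingerTransform(rbind(c(1, 2), c(0, 0))), "zero-sum")
})

test_that("Bray-Curtis has its textbook values and bounds", {
  m <- rbind(a = c(1, 1), b = c(0, 2), c = c(1, 1), d = c(2, 0))
  d <- as.matrix(brayCurtis(m))
  expect_equal(d["a", "c"], 0)
  expect_equal(d["b", "d"], 1)       # disjoint
  expect_equal(d["a", "b"], 0.5)     # (1 + 1) / 4
  expect_true(all(d >= 0 & d <= 1))
  expect_equal(d, t(d))
  expect_error(brayCurtis(rbind(c(0, 0), c(0, 0), c(1, 2))), "all-zero")
})

test_that("NMDS recovers a planted 2-D configuration and is deterministic", {
  set.seed(42)
  conf <- matrix(rnorm(20 * 2), ncol = 2)
  d <- dist(conf)
  ord <- nmdsOrdination(d, seed = 3)
  expect_lt(ord@stress, 1e-3)
  expect_true(ord@converged)
  # Procrustes alignment recovers the planted configuration
  pro <- vegan::procrustes(conf, ord@coordinates, symmetric = TRUE)
  expect_lt(pro$ss, 1e-4)
  # coordinates are centred
  expect_equal(unname(colMeans(ord@coordinates)), c(0, 0))
  # determinism under a fixed seed
  ord2 <- nmdsOrdination(d, seed = 3)
  expect_identical(ord@coordinates, ord2@coordinates)
  # an equilateral triple embeds exactly
  eq <- matrix(1, 3, 3) - diag(3)
  expect_lt(nmdsOrdination(eq, restarts = 5, seed = 1)@stress, 1e-3)
  expect_error(nmdsOrdination(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric")
})

test_that("k-means separates planted clouds and keeps duplicates together", {
  x <- makeBlobs(sd = 0.2)
  lab <- kmeansCluster(x, 3, seed = 1)
  truth <- rep(1:3, each = 20)
  expect_equal(length(unique(paste(lab, truth))), 3)  # perfect refinement
  # duplicated points co-cluster
  xd <- rbind(x, x[1, ], x[1, ])
  labd <- kmeansCluster(xd, 3, seed = 1)
  expect_equal(labd[61], labd[62])
  expect_equal(labd[61], labd[1])
  # determinism
  expect_identical(kmeansCluster(x, 3, seed = 9), kmeansCluster(x, 3, seed = 9))
  expect_error(kmeansCluster(x, 1, seed = 1), "k")
})

test_that("Calinski-Harabasz matches hand computation and vegan", {
  # {0, 0.1} vs {10, 10.1}: B = 100, W = 0.01, CH = (100/1)/(0.01/2)
  x <- matrix(c(0, 0.1, 10, 10.1), ncol = 1)
  lab <- c(1, 1, 2, 2)
  expect_equal(calinskiHarabasz(x, lab), (100 / 1) / (0.01 / 2))
  # scale invariance
  expect_equal(calinskiHarabasz(x * 37, lab), calinskiHarabasz(x, lab))
  # singleton-only clustering flagged as infinite
  expect_equal(calinskiHarabasz(matrix(c(0, 10), ncol = 1), c(1, 2)), Inf)
  # cross-check against vegan::cascadeKM on the blob data
  blobs <- makeBlobs()
  lab3 <- kmeansCluster(blobs, 3, seed = 1)
  ck <- vegan::cascadeKM(blobs, 3, 3)
  expect_equal(calinskiHarabasz(blobs, lab3),
               unname(ck$results["calinski", ]), tolerance = 1e-8)
  # random labels on one blob give CH near 1 on average
  set.seed(8)
  one <- matrix(rnorm(200), ncol = 2)
  chs <- replicate(30, calinskiHarabasz(one, sample(rep(1:2, 50))))
  expect_lt(abs(mean(chs) - 1), 0.5)
})

test_that("model-order selection finds planted k and flags weak structure", {
  r3 <- chooseK(makeBlobs(), kMax = 6, seed = 1)
  expect_equal(r3@k, 3L)
  expect_false(r3@weakStructure)
  set.seed(10)
  r1 <- chooseK(matrix(rnorm(120), ncol = 2), kMax = 6, seed = 1)
  expect_true(r1@weakStructure)
  expect_equal(r1@k, 2L)
  expect_s3_class(r1@dendrogram, "hclust")
  # determinism
  r3b <- chooseK(makeBlobs(), kMax = 6, seed = 1)
  expect_identical(r3@labels, r3b@labels)
})

test_that("indicator values follow the Dufrene-Legendre identities", {
  # a perfect indicator: present in every sample of one cluster only
  m <- cbind(perfect = c(5, 8, 6, 7, 5, 0, 0, 0, 0, 0),
             even = rep(4, 10))
  lab <- rep(1:2, each = 5)
  iv <- indicatorValue(m, lab, nPerm = 199, seed = 2)
  perf <- iv@pValues[iv@pValues$taxon == "perfect", ]
  expect_equal(perf$indval, 100)
  # only a label permutation reproducing the exact partition can tie the
  # observed value, so p sits at the combinatorial floor
  expect_lt(perf$p, 0.05)
  # equal mean abundance and full occupancy in both clusters -> 50
  evenRow <- iv@table[iv@table$taxon == "even", ]
  expect_equal(evenRow$indval, c(50, 50))
  # specificity sums to one over clusters for any non-empty genus
  sums <- tapply(iv@table$A, iv@table$taxon, sum)
  expect_equal(as.vector(sums), rep(1, length(sums)))
  expect_true(all(iv@table$indval >= 0 & iv@table$indval <= 100))
  expect_error(indicatorValue(m, rep(1, 6)), "2 clusters")
})

test_that("permutation p-values are uniform under exchanged labels", {
  set.seed(9)
  m <- matrix(rpois(24 * 80, 20), nrow = 24)
  lab <- sample(rep(1:2, each = 12))
  iv <- indicatorValue(m, lab, nPerm = 499, seed = 11)
  p <- iv@pValues$p
  ks <- suppressWarnings(stats::ks.test(p, "punif"))
  expect_gt(ks$p.value, 0.01)
  # validity: P(p <= alpha) <= alpha within Monte-Carlo error
  for (a in c(0.05, 0.1, 0.25))
    expect_lte(mean(p <= a), a + 2 * sqrt(a * (1 - a) / length(p)))
})

test_that("rank aggregation pools sub-floor taxa", {
  counts <- rbind(asv1 = c(980, 985), asv2 = c(15, 10), asv3 = c(5, 5))
  tax <- c("Bacteria;F1;C1;O1;Fam1;GenA", "Bacteria;F1;C1;O1;Fam1;GenB",
           "Bacteria;F2;C2;O2;Fam2;GenC")
  meta <- data.frame(sample = c("s1", "s2"), reactor = "R", day = c(1, 2))
  colnames(counts) <- meta$sample
  asv <- asvExperiment(counts, taxonomy = tax, metadata = meta)

  agg <- aggregateTaxa(asv, rank = "genus", floor = 0.01)
  expect_true("<1% abundance" %in% rownames(agg$counts))   # GenC pooled
  expect_true("GenB" %in% rownames(agg$counts))            # 1.5 % kept
  expect_equal(unname(colSums(agg$proportions)), c(1, 1))
  expect_error(aggregateTaxa(asv, rank = "variety"), "unknown taxonomy rank")

  solo <- asvExperiment(counts[1, , drop = FALSE], taxonomy = tax[1],
                        metadata = meta)
  aggS <- aggregateTaxa(solo, rank = "genus")
  expect_equal(as.vector(aggS$proportions), c(1, 1))
})

test_that("cluster ANOVA reproduces the classical F statistic", {
  res <- clusterAnova(c(1, 2, 3, 4, 5, 6), rep(1:2, each = 3))
  expect_equal(res$F, 13.5)
  expect_equal(res$p, 1 - pf(13.5, 1, 4))
  # identical groups: F = 0
  expect_equal(clusterAnova(rep(c(1, 2, 3), 2), rep(1:2, each = 3))$F, 0)
  # shift invariance
  res2 <- clusterAnova(c(1, 2, 3, 4, 5, 6) + 100, rep(1:2, each = 3))
  expect_equal(res2$F, res$F)
  # degenerate: zero variance, equal means
  deg <- clusterAnova(rep(5, 6), rep(1:2, each = 3))
  expect_true(deg$degenerate)
  expect_equal(deg$F, 0)
})
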