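## Longitudinal community statistics on ASV count tables: Hill diversity and
## evenness, Hellinger standardisation, Bray-Curtis dissimilarity, NMDS,
## k-means with Calinski-Harabasz model-order selection, indicator-value
## analysis and cluster-parameter ANOVA.

# Community matrix convention: samples as rows (vegan's). ASVExperiment
# stores taxa as rows, so it is transposed on the way in.
.communityMatrix <- function(x) {
  if (is(x, "ASVExperiment"))
    return(t(SummarizedExperiment::assay(x, "counts")))
  m <- as.matrix(x)
  storage.mode(m) <- "double"
  m
}

#' Hill diversity number of order q
#'
#' Effective number of taxa: \eqn{^qD = (\sum_i p_i^q)^{1/(1-q)}}; at q = 0
#' this is richness, at q = 1 the limit \eqn{\exp(-\sum_i p_i \ln p_i)}
#' (the exponential of Shannon entropy). Zero-count taxa are ignored.
#'
#' @param x counts: a vector (one sample), a samples x taxa matrix, or an
#'   [ASVExperiment-class].
#' @param q diversity order (default 1).
#' @return effective number of taxa, per sample.
#' @examples
#' hillDiversity(c(25, 25, 25, 25))       # 4
#' hillDiversity(c(75, 25))               # exp(0.5623) ~ 1.755
#' @export
hillDiversity <- function(x, q = 1) {
  if (is.null(dim(x)) && !is(x, "ASVExperiment")) {
    if (sum(x) <= 0) stop("empty sample: row sum must be positive")
    p <- x[x > 0] / sum(x)
    if (q == 1) return(exp(-sum(p * log(p))))
    if (q == 0) return(length(p))
    return(sum(p^q)^(1 / (1 - q)))
  }
  m <- .communityMatrix(x)
  apply(m, 1, hillDiversity, q = q)
}

#' First-order Hill evenness
#'
#' The ratio form \eqn{^1E = ^1D / ^0D}: first-order diversity divided by
#' richness, in \eqn{(0, 1]} with 1 for a perfectly even community.
#'
#' @inheritParams hillDiversity
#' @return evenness per sample.
#' @export
hillEvenness <- function(x) {
  hillDiversity(x, q = 1) / hillDiversity(x, q = 0)
}

#' Hellinger standardisation
#'
#' Per-sample square root of relative abundances (each transformed row has
#' unit Euclidean norm). Delegates to [vegan::decostand()].
#'
#' @param x samples x taxa counts (or an [ASVExperiment-class]).
#' @return transformed matrix, samples x taxa.
#' @export
hellingerTransform <- function(x) {
  m <- .communityMatrix(x)
  if (any(rowSums(m) <= 0)) stop("zero-sum sample row(s); cannot standardise")
  as.matrix(vegan::decostand(m, method = "hellinger"))
}

#' Bray-Curtis dissimilarity
#'
#' \eqn{d(x, y) = \sum_i |x_i - y_i| / \sum_i (x_i + y_i)}; symmetric with
#' zero diagonal. Delegates to [vegan::vegdist()]. Pairs of all-zero rows
#' have no defined dissimilarity and raise an error.
#'
#' @param x samples x taxa matrix (or an [ASVExperiment-class]).
#' @return a `dist` object.
#' @export
brayCurtis <- function(x) {
  m <- .communityMatrix(x)
  if (sum(rowSums(m) == 0) >= 2)
    stop("two or more all-zero samples: Bray-Curtis undefined for such pairs")
  vegan::vegdist(m, method = "bray")
}

#' Non-metric multidimensional scaling
#'
#' Kruskal stress-1 NMDS by iterative majorisation with monotone (isotonic)
#' regression of configuration distances on the input dissimilarities,
#' via [vegan::metaMDS()] (engine `monoMDS`, primary tie treatment), keeping
#' the best of `restarts` seeded random starts. Identical seed and input
#' give an identical embedding.
#'
#' @param dissim a `dist` or symmetric dissimilarity matrix.
#' @param dims embedding dimension (default 2).
#' @param restarts random restarts (default 20).
#' @param maxIter maximum iterations per start.
#' @param seed integer RNG seed.
#' @return an [OrdinationResult-class]; `stress` is a fraction in [0, 1].
#' @export
nmdsOrdination <- function(dissim, dims = 2, restarts = 20, maxIter = 500,
                           seed = 1L) {
  if (!inherits(dissim, "dist")) {
    m <- as.matrix(dissim)
    if (!isSymmetric(unname(m), tol = 1e-8)) stop("dissimilarity matrix must be symmetric")
    dissim <- stats::as.dist(m)
  }
  if (attr(dissim, "Size") < 3) stop("need at least 3 samples")
  set.seed(seed)
  fit <- withCallingHandlers(
    vegan::metaMDS(dissim, k = dims, trymax = restarts, maxit = maxIter,
                   trace = FALSE, autotransform = FALSE, wascores = FALSE),
    warning = function(w) {
      # a perfect embedding is a success, not a warning, here
      if (grepl("stress is (nearly) zero", conditionMessage(w), fixed = TRUE))
        invokeRestart("muffleWarning")
    })
  coords <- scale(vegan::scores(fit, display = "sites"), scale = FALSE)
  new("OrdinationResult", coordinates = unclass(coords), stress = fit$stress,
      converged = isTRUE(fit$converged) || fit$stress < 1e-3,
      seed = as.integer(seed))
}

#' Seeded k-means clustering
#'
#' Standard Lloyd/Hartigan-Wong k-means (stats::kmeans) with `nstart`
#' seeded restarts, keeping the lowest within-cluster sum of squares.
#'
#' @param x numeric matrix, samples x features (typically
#'   Hellinger-standardised counts).
#' @param k number of clusters, \eqn{2 \le k \le n - 1}.
#' @param seed integer RNG seed.
#' @param nstart restarts (default 10).
#' @return integer vector of labels in 1..k.
#' @export
kmeansCluster <- function(x, k, seed = 1L, nstart = 10) {
  m <- as.matrix(x)
  if (k < 2 || k > nrow(m) - 1) stop("'k' must lie in [2, n - 1]")
  set.seed(seed)
  km <- stats::kmeans(m, centers = k, nstart = nstart, iter.max = 100)
  as.integer(km$cluster)
}

#' Calinski-Harabasz statistic
#'
#' \eqn{CH = (B/(k-1)) / (W/(n-k))} with B and W the between- and
#' within-cluster sums of squares. Scale-invariant; singleton-only
#' clusterings with W = 0 return `Inf`.
#'
#' @param x numeric matrix, samples x features.
#' @param labels cluster labels (k >= 2, all clusters non-empty).
#' @return the CH statistic.
#' @export
calinskiHarabasz <- function(x, labels) {
  m <- as.matrix(x)
  labels <- as.integer(factor(labels))
  k <- max(labels)
  n <- nrow(m)
  if (k < 2) stop("need at least 2 clusters")
  if (any(tabulate(labels, k) == 0)) stop("empty cluster")
  centre <- colMeans(m)
  W <- 0; B <- 0
  for (g in seq_len(k)) {
    mg <- m[labels == g, , drop = FALSE]
    cg <- colMeans(mg)
    W <- W + sum(sweep(mg, 2, cg)^2)
    B <- B + nrow(mg) * sum((cg - centre)^2)
  }
  if (W == 0) return(Inf)
  (B / (k - 1)) / (W / (n - k))
}

#' Choose the number of clusters by the Calinski-Harabasz criterion
#'
#' Runs seeded k-means for k = 2..kMax, computes the CH statistic for each,
#' and selects the argmax. When the CH curve shows no pronounced optimum
#' (max/min ratio below `weakRatio`) the structure is flagged weak and k = 2
#' is reported for inspection only. A Bray-Curtis average-linkage dendrogram
#' is attached as a side artifact for visual comparison, not as a decision
#' criterion.
#'
#' @param x numeric matrix, samples x features (Hellinger-standardised
#'   counts for community data).
#' @param kMax largest candidate k (default `min(8, n - 1)`).
#' @param seed integer RNG seed.
#' @param weakRatio CH max/min ratio below which structure is called weak.
#' @param dissim optional dissimilarity for the side dendrogram; defaults to
#'   Euclidean distances of `x`.
#' @return a [ClusterResult-class].
#' @export
chooseK <- function(x, kMax = NULL, seed = 1L, weakRatio = 2,
                    dissim = NULL) {
  m <- as.matrix(x)
  n <- nrow(m)
  if (is.null(kMax)) kMax <- min(8L, n - 1L)
  if (kMax < 2) stop("'kMax' must be at least 2")
  ks <- 2:kMax
  labs <- lapply(ks, function(k) kmeansCluster(m, k, seed = seed))
  ch <- vapply(seq_along(ks), function(i) calinskiHarabasz(m, labs[[i]]),
               numeric(1))
  names(ch) <- ks
  finite <- is.finite(ch)
  weak <- all(finite) && max(ch) / min(ch) < weakRatio
  if (weak) {
    kChosen <- 2L
    rule <- "weak structure; defaulting to k = 2"
  } else {
    kChosen <- ks[which.max(ch)]
    rule <- "argmax Calinski-Harabasz over k = 2..kMax"
  }
  if (is.null(dissim)) dissim <- stats::dist(m)
  dend <- stats::hclust(stats::as.dist(dissim), method = "average")
  new("ClusterResult", k = as.integer(kChosen),
      labels = labs[[match(kChosen, ks)]], chIndex = ch, chosenKRule = rule,
      weakStructure = weak, dendrogram = dend)
}

#' Indicator value analysis (Dufrene-Legendre)
#'
#' For genus g and cluster c: specificity \eqn{A_{gc}} is the mean abundance
#' of g in c divided by the sum over clusters of its mean abundances;
#' fidelity \eqn{B_{gc}} is the fraction of samples of c in which g occurs;
#' \eqn{IndVal_{gc} = 100 A_{gc} B_{gc}}. Each genus' observed statistic is
#' its maximum over clusters; significance is assessed by permuting the
#' cluster labels: \eqn{p = (1 + \#\{IndVal^{perm} \ge IndVal^{obs}\}) /
#' (n_{perm} + 1)}.
#'
#' @param x genus-aggregated counts, samples x genera (or an
#'   [ASVExperiment-class] already aggregated).
#' @param labels cluster labels, at least 2 non-empty clusters.
#' @param nPerm number of permutations (default 999).
#' @param seed integer RNG seed.
#' @return an [IndValResult-class].
#' @export
indicatorValue <- function(x, labels, nPerm = 999, seed = 1L) {
  m <- .communityMatrix(x)
  labels <- as.integer(factor(labels))
  k <- max(labels)
  if (k < 2) stop("need at least 2 clusters")
  if (any(tabulate(labels, k) == 0)) stop("cluster with zero samples")

  statMatrix <- function(lab) {
    sizes <- tabulate(lab, k)
    meanAb <- rowsum(m, lab) / sizes            # k x G mean abundance
    occ <- rowsum((m > 0) + 0, lab) / sizes     # k x G occurrence fraction
    colTot <- colSums(meanAb)
    A <- sweep(meanAb, 2, ifelse(colTot > 0, colTot, 1), "/")
    list(A = A, B = occ, indval = 100 * A * occ)
  }

  obs <- statMatrix(labels)
  G <- ncol(m)
  genus <- colnames(m)
  if (is.null(genus)) genus <- paste0("taxon", seq_len(G))
  tab <- data.frame(
    taxon = rep(genus, each = k),
    cluster = rep(seq_len(k), G),
    A = as.vector(obs$A), B = as.vector(obs$B),
    indval = as.vector(obs$indval)
  )
  obsMax <- apply(obs$indval, 2, max)
  obsArg <- apply(obs$indval, 2, which.max)

  set.seed(seed)
  count <- integer(G)
  for (b in seq_len(nPerm)) {
    permMax <- apply(statMatrix(sample(labels))$indval, 2, max)
    count <- count + (permMax >= obsMax - 1e-12)
  }
  p <- (1 + count) / (nPerm + 1)
  pv <- data.frame(taxon = genus, cluster = as.integer(obsArg),
                   indval = obsMax, p = p)
  new("IndValResult", table = tab, pValues = pv,
      nPerm = as.integer(nPerm), seed = as.integer(seed))
}

#' Aggregate counts at a taxonomic rank with a relative-abundance floor
#'
#' Sums counts by the value of `rank`, converts to per-sample proportions,
#' and pools every taxon whose relative abundance stays below `floor` in all
#' samples into a single `"<1% abundance"` group (threshold adjustable).
#'
#' @param x an [ASVExperiment-class].
#' @param rank taxonomy rank to aggregate at (default "genus").
#' @param floor pooling threshold as a proportion (default 0.01).
#' @return list with `counts` (aggregated counts, groups x samples) and
#'   `proportions` (same shape, columns summing to 1).
#' @export
aggregateTaxa <- function(x, rank = "genus", floor = 0.01) {
  stopifnot(is(x, "ASVExperiment"))
  rd <- SummarizedExperiment::rowData(x)
  if (!rank %in% colnames(rd)) stop("unknown taxonomy rank '", rank, "'")
  groups <- as.character(rd[[rank]])
  groups[is.na(groups) | groups == ""] <- "unclassified"
  counts <- rowsum(SummarizedExperiment::assay(x, "counts"), groups)
  prop <- sweep(counts, 2, colSums(counts), "/")
  rare <- apply(prop, 1, max) < floor
  if (any(rare)) {
    pooledCounts <- colSums(counts[rare, , drop = FALSE])
    counts <- rbind(counts[!rare, , drop = FALSE],
                    `<1% abundance` = pooledCounts)
    prop <- sweep(counts, 2, colSums(counts), "/")
  }
  list(counts = counts, proportions = prop)
}

#' One-way ANOVA of a process parameter across clusters
#'
#' Classical one-way F test (equal-variance) of whether clusters differ in
#' an associated process parameter, via [stats::oneway.test()]. Groups with
#' zero within-group variance and equal means are flagged degenerate.
#'
#' @param values numeric parameter values, one per sample.
#' @param labels cluster labels.
#' @return list with `F`, `p`, `df` (numerator, denominator) and
#'   `degenerate`.
#' @examples
#' clusterAnova(c(1, 2, 3, 4, 5, 6), rep(1:2, each = 3))$F  # 13.5
#' @export
clusterAnova <- function(values, labels) {
  labels <- factor(labels)
  if (nlevels(labels) < 2) stop("need at least 2 groups")
  if (length(values) - nlevels(labels) < 2) stop("need at least 2 residual df")
  groupVar <- tapply(values, labels, stats::var)
  groupMean <- tapply(values, labels, mean)
  if (all(groupVar == 0, na.rm = TRUE) && stats::var(groupMean) == 0)
    return(list(F = 0, p = 1, df = c(nlevels(labels) - 1,
                length(values) - nlevels(labels)), degenerate = TRUE))
  fit <- stats::oneway.test(values ~ labels, var.equal = TRUE)
  list(F = unname(fit$statistic), p = fit$p.value,
       df = unname(fit$parameter), degenerate = FALSE)
}
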