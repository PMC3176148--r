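# Enzyme classification by mol% composition: Euclidean distances, Ward
# agglomeration, multiscale bootstrap AU p-values, and a k-class cut.

#' Euclidean distances between specificity profiles
#'
#' @param profiles List of `specificity_profile`s, or a numeric matrix of
#'   mol% compositions (enzymes in rows).
#' @return Symmetric distance matrix with zero diagonal.
#' @export
euclidean_distances <- function(profiles) {
  X <- if (is.matrix(profiles)) profiles else profiles_matrix(profiles)
  if (nrow(X) < 2L) stop("need at least 2 profiles")
  as.matrix(dist(X, method = "euclidean"))
}

#' Ward agglomerative clustering
#'
#' Classical minimum-variance Ward clustering: Lance-Williams updates on
#' squared Euclidean distances (`stats::hclust`, method `"ward.D"` on
#' `d^2`). Heights are the merge-criterion values on the squared-distance
#' scale.
#'
#' @param D Symmetric distance matrix (unsquared), e.g. from
#'   [euclidean_distances()].
#' @return An `hclust` object.
#' @export
ward_cluster <- function(D) {
  M <- as.matrix(D)
  hclust(as.dist(M^2), method = "ward.D")
}

# Numeric subset keys (sum of 2^(obs-1), exact for n <= 53 observations)
# for each internal node of an hclust merge sequence; observation indices
# refer to the original row order.
hclust_node_keys <- function(merge) {
  nn <- nrow(merge)
  keys <- numeric(nn)
  for (i in seq_len(nn)) {
    a <- merge[i, 1]; b <- merge[i, 2]
    ka <- if (a < 0) 2^(-a - 1) else keys[a]
    kb <- if (b < 0) 2^(-b - 1) else keys[b]
    keys[i] <- ka + kb
  }
  keys
}

# member sets (canonical sorted-label strings) for each internal node of an
# hclust merge sequence, in merge order
hclust_node_sets <- function(hc) {
  labs <- hc$labels
  n <- length(labs)
  sets <- vector("list", n - 1L)
  keys <- character(n - 1L)
  for (i in seq_len(n - 1L)) {
    members <- c(
      if (hc$merge[i, 1] < 0) labs[-hc$merge[i, 1]] else sets[[hc$merge[i, 1]]],
      if (hc$merge[i, 2] < 0) labs[-hc$merge[i, 2]] else sets[[hc$merge[i, 2]]])
    sets[[i]] <- members
    keys[i] <- paste(sort(members), collapse = "\r")
  }
  list(sets = lapply(sets, sort), keys = keys)
}

#' Multiscale bootstrap support for Ward clusters
#'
#' Resamples the species (feature) columns of the mol% matrix at several
#' sample-size scales `r` (drawing `ceiling(r * m)` of the `m` columns with
#' replacement), reclusters each replicate, and records the per-node
#' presence frequency `BP(r)`. The approximately-unbiased (AU) p-value per
#' node comes from weighted probit regression of `qnorm(1 - BP(r))` on
#' `{sqrt(r), 1/sqrt(r)}`: with `v` the signed-distance coefficient on
#' `sqrt(r)` and `c` the curvature coefficient on `1/sqrt(r)`,
#' `AU = 1 - pnorm(v - c)`. BP values are clipped to `[1/(B+1), B/(B+1)]`
#' before the probit transform.
#'
#' With few feature columns (typically ~14 fatty-acid species) AU accuracy
#' is limited; reports carry both AU and the plain `BP` at scale 1.
#'
#' @param profiles List of `specificity_profile`s or a mol% matrix.
#' @param replicates Bootstrap replicates per scale (default 1000).
#' @param scales Numeric vector of resampling scales (default 0.5-1.4).
#' @param seed Integer seed (results are bit-reproducible given a seed).
#' @return Object of class `class_dendrogram`: the `hclust` fit, per-node
#'   member `sets`, `bp` matrix (nodes x scales), `bp1` (scale closest
#'   to 1), `au` vector, plus the resampling settings.
#' @export
multiscale_bootstrap <- function(profiles, replicates = 1000L,
                                 scales = seq(0.5, 1.4, by = 0.1),
                                 seed = 1L) {
  X <- if (is.matrix(profiles)) profiles else profiles_matrix(profiles)
  if (nrow(X) < 3L) stop("need at least 3 profiles")
  if (ncol(X) < 2L) stop("need at least 2 species columns")
  if (replicates < 1L) stop("replicates must be >= 1")
  hc <- ward_cluster(euclidean_distances(X))
  nodes <- hclust_node_sets(hc)
  ref_keys <- hclust_node_keys(hc$merge)
  m <- ncol(X)
  n <- nrow(X)
  if (n > 53L) stop("multiscale bootstrap supports up to 53 profiles")
  nnode <- length(nodes$keys)
  bp <- matrix(0, nnode, length(scales),
               dimnames = list(NULL, paste0("r", scales)))
  set.seed(seed)
  for (si in seq_along(scales)) {
    msub <- max(2L, ceiling(scales[si] * m))
    counts <- rep(0L, nnode)
    for (b in seq_len(replicates)) {
      redraws <- 0L
      repeat {
        cols <- sample.int(m, msub, replace = TRUE)
        Xb <- X[, cols, drop = FALSE]
        Db <- dist(Xb)
        if (any(Db > 0)) break
        redraws <- redraws + 1L
        if (redraws > 10L)
          stop("degenerate resample (zero-variance matrix) at scale ",
               scales[si], ", replicate ", b)
      }
      hb <- hclust(Db^2, method = "ward.D")
      hit <- match(hclust_node_keys(hb$merge), ref_keys)
      hit <- hit[!is.na(hit)]
      counts[hit] <- counts[hit] + 1L
    }
    bp[, si] <- counts / replicates
  }
  au <- au_from_bp(bp, scales, replicates)
  structure(list(hclust = hc, sets = nodes$sets, keys = nodes$keys,
                 bp = bp, bp1 = bp[, which.min(abs(scales - 1))],
                 au = au, scales = scales, replicates = replicates,
                 seed = seed),
            class = "class_dendrogram")
}

#' AU p-values from multiscale bootstrap probabilities
#'
#' Weighted least-squares probit regression, one fit per node (row of
#' `bp`): `qnorm(1 - BP(r)) ~ v * sqrt(r) + c / sqrt(r)` with inverse
#' delta-method variance weights `replicates * dnorm(z)^2 / (BP (1 - BP))`,
#' then `AU = 1 - pnorm(v - c)`. Rows are clipped to `[1/(B+1), B/(B+1)]`
#' first; a node present in every replicate at every scale reports AU 1,
#' one never recovered reports AU 0.
#'
#' @param bp Matrix of bootstrap probabilities (nodes x scales).
#' @param scales Scale vector matching `bp` columns.
#' @param replicates Bootstrap replicates per scale.
#' @return Numeric AU vector, one per node.
#' @export
au_from_bp <- function(bp, scales, replicates) {
  bpc <- pmin(pmax(bp, 1 / (replicates + 1)), replicates / (replicates + 1))
  vapply(seq_len(nrow(bp)), function(i) {
    p0 <- bp[i, ]
    if (all(p0 >= 1)) return(1)   # unanimous at every scale
    if (all(p0 <= 0)) return(0)   # never recovered at any scale
    p <- bpc[i, ]
    z <- qnorm(1 - p)
    w <- replicates * dnorm(z)^2 / (p * (1 - p))
    Xd <- cbind(sqrt_r = sqrt(scales), inv_sqrt_r = 1 / sqrt(scales))
    fit <- lm.fit(Xd * sqrt(w), z * sqrt(w))
    v <- fit$coefficients["sqrt_r"]
    c_ <- fit$coefficients["inv_sqrt_r"]
    unname(1 - pnorm(v - c_))
  }, numeric(1))
}

#' @export
print.class_dendrogram <- function(x, ...) {
  cat("Class dendrogram: ", length(x$hclust$labels), " enzymes, ",
      x$replicates, " bootstrap replicates x ", length(x$scales),
      " scales\n", sep = "")
  invisible(x)
}

#' Cut a dendrogram into k substrate-specificity classes
#'
#' Class labels are ordered by decreasing cluster size, ties broken by the
#' lexicographically smallest member id.
#'
#' @param hc An `hclust`, or a `class_dendrogram`.
#' @param k Number of classes (default 3).
#' @return Named integer vector enzyme -> class (1..k).
#' @export
cut_classes <- function(hc, k = 3L) {
  if (inherits(hc, "class_dendrogram")) hc <- hc$hclust
  n <- length(hc$labels)
  if (k < 1L || k > n) stop("k must be between 1 and the number of profiles")
  raw <- cutree(hc, k = k)
  sizes <- table(raw)
  minmem <- vapply(names(sizes), function(cl)
    min(names(raw)[raw == as.integer(cl)]), character(1))
  ord <- order(-as.integer(sizes), minmem)
  relabel <- setNames(seq_len(k), names(sizes)[ord])
  setNames(as.integer(relabel[as.character(raw)]), names(raw))
}

#' Mean silhouette widths for a range of class counts
#'
#' Diagnostic for choosing k: average silhouette width of the Ward cut at
#' each k.
#'
#' @param hc An `hclust` or `class_dendrogram`.
#' @param D Distance matrix used for the clustering (unsquared).
#' @param ks Integer vector of class counts to evaluate.
#' @return Named numeric vector of mean silhouette widths.
#' @export
silhouette_diagnostics <- function(hc, D, ks = 2:6) {
  if (inherits(hc, "class_dendrogram")) hc <- hc$hclust
  M <- as.matrix(D)
  ks <- ks[ks >= 2 & ks < nrow(M)]
  vapply(ks, function(k) {
    cl <- cutree(hc, k = k)
    mean(cluster::silhouette(cl, dmatrix = M)[, "sil_width"])
  }, numeric(1)) |> setNames(paste0("k", ks))
}

#' Write a class dendrogram with AU/BP annotations as Newick
#'
#' Internal node labels carry `au:bp` (percent) annotations; leaf order and
#' topology follow the Ward merge sequence; heights are merge-criterion
#' values.
#'
#' @param cd A `class_dendrogram`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_class_dendrogram <- function(cd, path) {
  phy <- ape::as.phylo(cd$hclust)
  # ape orders internal nodes by merge traversal; map node sets to labels
  nlab <- character(phy$Nnode)
  tips <- phy$tip.label
  for (i in seq_len(phy$Nnode)) {
    node <- length(tips) + i
    desc <- tips[unlist(phangorn::Descendants(phy, node, type = "tips"))]
    key <- paste(sort(desc), collapse = "\r")
    j <- match(key, cd$keys)
    nlab[i] <- if (is.na(j)) "" else
      sprintf("au%.0f_bp%.0f", 100 * cd$au[j], 100 * cd$bp1[j])
  }
  phy$node.label <- nlab
  ape::write.tree(phy, file = path)
  invisible(path)
}
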