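# Distance-based tree construction: NJ (deterministic tie-break), OLS branch
# lengths, minimum-evolution NNI hill climbing, bootstrap supports, rooting.

format_bl <- function(x) sprintf("%.17g", x)

#' Neighbor-joining tree from a distance matrix
#'
#' Standard NJ with the Q criterion. Ties in the Q minimum are broken by the
#' smallest (row, column) index pair of the current matrix, so the result is
#' invariant to input row order up to relabeling. Negative branch-length
#' estimates are clamped to zero.
#'
#' @param D An `evodist` or a symmetric numeric matrix with dimnames.
#' @return An unrooted `phylo` tree (class from \pkg{ape}).
#' @export
neighbor_joining <- function(D) {
  if (inherits(D, "evodist")) {
    ids <- D$ids; M <- D$d
  } else {
    M <- as.matrix(D); ids <- rownames(M)
  }
  n <- length(ids)
  if (n < 3L) stop("neighbor joining needs at least 3 sequences")
  # each active cluster is a Newick fragment
  labs <- ids
  frag <- ids
  while (length(frag) > 3L) {
    r <- nrow(M)
    rs <- rowSums(M)
    Q <- (r - 2) * M - outer(rs, rs, "+")
    diag(Q) <- Inf
    qmin <- min(Q)
    hits <- which(Q - qmin <= 0, arr.ind = TRUE)
    hits <- hits[hits[, 1] < hits[, 2], , drop = FALSE]
    hits <- hits[order(hits[, 1], hits[, 2]), , drop = FALSE]
    i <- hits[1, 1]; j <- hits[1, 2]
    li <- M[i, j] / 2 + (rs[i] - rs[j]) / (2 * (r - 2))
    lj <- M[i, j] - li
    li <- max(li, 0); lj <- max(lj, 0)
    newfrag <- paste0("(", frag[i], ":", format_bl(li), ",",
                      frag[j], ":", format_bl(lj), ")")
    dnew <- (M[i, ] + M[j, ] - M[i, j]) / 2
    keep <- setdiff(seq_len(r), c(i, j))
    M2 <- rbind(cbind(M[keep, keep, drop = FALSE], dnew[keep]),
                c(dnew[keep], 0))
    frag <- c(frag[keep], newfrag)
    M <- M2
  }
  d12 <- M[1, 2]; d13 <- M[1, 3]; d23 <- M[2, 3]
  l1 <- max((d12 + d13 - d23) / 2, 0)
  l2 <- max((d12 + d23 - d13) / 2, 0)
  l3 <- max((d13 + d23 - d12) / 2, 0)
  nwk <- paste0("(", frag[1], ":", format_bl(l1), ",",
                frag[2], ":", format_bl(l2), ",",
                frag[3], ":", format_bl(l3), ");")
  ape::read.tree(text = nwk)
}

# ---- OLS branch lengths ---------------------------------------------------

# pairs x edges incidence matrix for an unrooted binary phylo
path_design_matrix <- function(tree) {
  n <- length(tree$tip.label)
  ne <- nrow(tree$edge)
  nn <- max(tree$edge)
  parent_edge <- integer(nn)      # edge index leading to each node (rooted view)
  parent_node <- integer(nn)
  for (e in seq_len(ne)) {
    parent_edge[tree$edge[e, 2]] <- e
    parent_node[tree$edge[e, 2]] <- tree$edge[e, 1]
  }
  root <- setdiff(unique(tree$edge[, 1]), tree$edge[, 2])
  rootpath <- matrix(FALSE, n, ne)
  for (tip in seq_len(n)) {
    v <- tip
    while (v != root) {
      rootpath[tip, parent_edge[v]] <- TRUE
      v <- parent_node[v]
    }
  }
  pairs <- combn(n, 2L)
  A <- matrix(0, ncol(pairs), ne)
  for (p in seq_len(ncol(pairs))) {
    A[p, ] <- xor(rootpath[pairs[1, p], ], rootpath[pairs[2, p], ])
  }
  list(A = A, pairs = pairs)
}

# OLS-fit branch lengths; returns fitted lengths (edge order of tree$edge)
# and the ME criterion (sum of fitted lengths, unclamped)
ols_branch_lengths <- function(tree, M) {
  pd <- path_design_matrix(tree)
  tips <- tree$tip.label
  dvec <- M[cbind(tips[pd$pairs[1, ]], tips[pd$pairs[2, ]])]
  fit <- lm.fit(pd$A, dvec)
  b <- fit$coefficients
  b[is.na(b)] <- 0
  list(lengths = b, tree_length = sum(b))
}

#' Total OLS tree length (minimum-evolution criterion)
#'
#' @param tree Unrooted binary `phylo`.
#' @param D An `evodist` or distance matrix.
#' @return Sum of OLS-fitted branch lengths.
#' @export
ols_tree_length <- function(tree, D) {
  M <- if (inherits(D, "evodist")) D$d else as.matrix(D)
  ols_branch_lengths(tree, M)$tree_length
}

#' Minimum-evolution refinement by greedy NNI
#'
#' Re-fits ordinary-least-squares branch lengths and hill-climbs over
#' nearest-neighbor-interchange rearrangements, accepting a move only while
#' the total OLS tree length strictly decreases (tolerance 1e-10). The
#' returned tree carries OLS branch lengths with negatives clamped to zero.
#'
#' @param tree Unrooted binary `phylo` over the ids of `D`.
#' @param D An `evodist` or distance matrix.
#' @return Refined `phylo`; attribute `tree_length` holds the final ME
#'   criterion value.
#' @export
minimum_evolution_refine <- function(tree, D) {
  M <- if (inherits(D, "evodist")) D$d else as.matrix(D)
  if (!ape::is.binary(tree)) stop("minimum-evolution refinement requires a binary unrooted tree")
  if (!setequal(tree$tip.label, rownames(M)))
    stop("tree tips do not match distance-matrix ids")
  cur <- tree
  fit <- ols_branch_lengths(cur, M)
  cur_len <- fit$tree_length
  repeat {
    cands <- phangorn::nni(cur)
    lens <- vapply(cands, function(tr) ols_branch_lengths(tr, M)$tree_length,
                   numeric(1))
    best <- which.min(lens)
    if (lens[best] < cur_len - 1e-10) {
      cur <- cands[[best]]
      cur_len <- lens[best]
    } else break
  }
  fit <- ols_branch_lengths(cur, M)
  cur$edge.length <- pmax(fit$lengths, 0)
  attr(cur, "tree_length") <- fit$tree_length
  cur
}

# ---- bipartitions and bootstrap supports ----------------------------------

`%||%` <- function(a, b) if (is.null(a)) b else a

# Canonical bipartition string per internal node (n+1, n+2, ...): the split
# side NOT containing the alphabetically smallest tip, members sorted and
# collapsed. NA for trivial splits (root, pendant edges).
node_bipartitions <- function(tree) {
  tips <- tree$tip.label
  n <- length(tips)
  anchor <- min(tips)
  pp <- ape::prop.part(tree)  # clades indexed by internal node n+1, n+2, ...
  vapply(seq_along(pp), function(k) {
    set <- tips[pp[[k]]]
    if (length(set) >= n) return(NA_character_)
    side <- if (anchor %in% set) setdiff(tips, set) else set
    if (length(side) < 2L || length(side) > n - 2L) return(NA_character_)
    paste(sort(side), collapse = "\r")
  }, character(1))
}

#' Bootstrap supports for a distance tree
#'
#' Resamples alignment columns with replacement (seeded), recomputes the
#' distance matrix (with the replicate's own pairwise-deletion masks) and a
#' neighbor-joining tree per replicate, and annotates each internal edge of
#' the point-estimate tree with the percentage of replicates containing the
#' same bipartition.
#'
#' @param aln An [aligned_protein_set()] with >= 4 sequences.
#' @param model A `substitution_model`.
#' @param replicates Number of bootstrap replicates (default 1000).
#' @param seed Integer seed; supports are bit-reproducible given a seed.
#' @param tree Optional point-estimate tree; computed from the full
#'   alignment (NJ, then ME refinement if `refine = TRUE`) when `NULL`.
#' @param refine Apply minimum-evolution NNI refinement to the point tree
#'   and each replicate tree (default `FALSE`: plain NJ per replicate).
#' @param keep_replicates Attach the replicate trees as attribute
#'   `"replicate_trees"` (default `FALSE`).
#' @return The point-estimate `phylo` with `node.label` containing support
#'   percentages (0-100; `NA` for the root/trivial splits).
#' @export
bootstrap_supports <- function(aln, model = jtt_model(), replicates = 1000L,
                               seed = 1L, tree = NULL, refine = FALSE,
                               keep_replicates = FALSE) {
  stopifnot(inherits(aln, "aligned_protein_set"))
  if (length(aln$ids) < 4L) stop("bootstrap supports need at least 4 sequences")
  if (replicates < 1L) stop("replicates must be >= 1")
  enc <- aln_encode(aln)
  map <- aln_to_model_index()
  n <- nrow(enc); L <- ncol(enc)
  # per-pair site patterns, reused across replicates
  pairs <- combn(n, 2L)
  np <- ncol(pairs)
  pat <- matrix(NA_integer_, np, L)
  for (p in seq_len(np)) {
    a <- enc[pairs[1, p], ]; b <- enc[pairs[2, p], ]
    ok <- !is.na(a) & !is.na(b)
    pat[p, ok] <- (map[a[ok]] - 1L) * 20L + map[b[ok]]
  }
  tgrid <- dist_t_grid()
  logP <- log_p_grid(model, tgrid)

  if (is.null(tree)) {
    D0 <- distance_matrix(aln, model)
    tree <- neighbor_joining(D0)
    if (refine) tree <- minimum_evolution_refine(tree, D0)
  }
  point_bip <- node_bipartitions(tree)

  set.seed(seed)
  tally <- new.env(hash = TRUE, parent = emptyenv())
  rep_trees <- if (keep_replicates) vector("list", replicates) else NULL
  for (b in seq_len(replicates)) {
    redraws <- 0L
    repeat {
      cols <- sample.int(L, L, replace = TRUE)
      patb <- pat[, cols, drop = FALSE]
      keep <- !is.na(patb)
      pidx <- row(patb)[keep]
      vals <- patb[keep]
      # pattern counts per pair, one tabulate over pair-major blocks of 400
      cnt <- tabulate((pidx - 1L) * 400L + vals, nbins = np * 400L)
      counts <- matrix(cnt, nrow = 400L)
      if (all(colSums(counts) > 0L)) break
      redraws <- redraws + 1L
      if (redraws > 10L)
        stop("bootstrap replicate ", b, ": >10 redraws with an all-gap pair")
      warning("bootstrap replicate ", b, " produced an all-gap pair; redrawn")
    }
    gridL <- crossprod(logP, counts)
    qr_ <- quad_refine(gridL, tgrid)
    Mb <- matrix(0, n, n, dimnames = list(aln$ids, aln$ids))
    Mb[cbind(pairs[1, ], pairs[2, ])] <- qr_$t
    Mb <- Mb + t(Mb)
    trb <- neighbor_joining(Mb)
    if (refine) trb <- minimum_evolution_refine(trb, Mb)
    if (keep_replicates) rep_trees[[b]] <- trb
    for (s in node_bipartitions(trb)) {
      if (is.na(s)) next
      tally[[s]] <- (tally[[s]] %||% 0L) + 1L
    }
  }
  sup <- vapply(point_bip, function(s) {
    if (is.na(s)) return(NA_real_)
    100 * (tally[[s]] %||% 0L) / replicates
  }, numeric(1), USE.NAMES = FALSE)
  tree$node.label <- ifelse(is.na(sup), "", format(sup, trim = TRUE))
  attr(tree, "supports") <- sup
  if (keep_replicates) {
    class(rep_trees) <- "multiPhylo"
    attr(tree, "replicate_trees") <- rep_trees
  }
  tree
}

#' Root a tree with an outgroup
#'
#' Checks that the outgroup is monophyletic in the unrooted tree, then
#' places the root on the edge subtending the outgroup clade, splitting
#' that edge at its midpoint.
#'
#' @param tree Unrooted `phylo`.
#' @param outgroup_ids Character vector of outgroup tip labels.
#' @return Rooted `phylo`.
#' @export
root_with_outgroup <- function(tree, outgroup_ids) {
  tips <- tree$tip.label
  if (!all(outgroup_ids %in% tips))
    stop("outgroup id(s) not in tree: ",
         paste(setdiff(outgroup_ids, tips), collapse = ", "))
  if (length(outgroup_ids) < length(tips) - 1L &&
      length(outgroup_ids) > 1L) {
    key <- paste(sort(as.character(outgroup_ids)), collapse = "\r")
    # accept either side of a bipartition
    bips <- node_bipartitions(tree)
    comp <- paste(sort(setdiff(tips, outgroup_ids)), collapse = "\r")
    if (!(key %in% bips) && !(comp %in% bips)) {
      mono <- ape::is.monophyletic(tree, outgroup_ids)
      if (!mono)
        stop("outgroup is not monophyletic: ",
             paste(sort(outgroup_ids), collapse = ", "))
    }
  }
  rooted <- ape::root(tree, outgroup = outgroup_ids, resolve.root = TRUE)
  # split the subtending edge at its midpoint
  rootnode <- length(rooted$tip.label) + 1L
  kids <- which(rooted$edge[, 1] == rootnode)
  if (length(kids) == 2L) {
    tot <- sum(rooted$edge.length[kids])
    rooted$edge.length[kids] <- tot / 2
  }
  rooted
}

#' Majority-rule consensus of bootstrap replicate trees
#'
#' @param trees A `multiPhylo` (e.g. attribute `"replicate_trees"` from
#'   [bootstrap_supports()] with `keep_replicates = TRUE`).
#' @param p Majority threshold passed to [ape::consensus()] (default 0.5).
#' @return Consensus `phylo`.
#' @export
majority_consensus <- function(trees, p = 0.5) {
  ape::consensus(trees, p = p)
}

#' Write a tree to Newick
#'
#' Supports are written as internal node labels; branch lengths with 10
#' significant digits.
#'
#' @param tree A `phylo`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path, digits = 10)
  invisible(path)
}
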