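# helper: compare two unrooted trees: same topology (RF = 0) and matched
# branch lengths per bipartition
expect_same_unrooted_tree <- function(t1, t2, tol = 1e-9) {
  expect_equal(ape::dist.topo(ape::unroot(t1), ape::unroot(t2)), 0,
               ignore_attr = TRUE)
  d1 <- ape::cophenetic.phylo(t1)
  d2 <- ape::cophenetic.phylo(t2)
  ids <- rownames(d1)
  expect_equal(d1[ids, ids], d2[ids, ids], tolerance = tol)
}

test_that("NJ recovers the generating 4-taxon additive tree exactly", {
  fx <- four_taxon_fixture()
  tr <- neighbor_joining(as_evodist(fx$D))
  expect_same_unrooted_tree(tr, fx$tree, tol = 1e-9)
  # oracle: OLS residual over all three resolved topologies is minimal at
  # the generating split AB|CD
  topos <- c("((A,B),C,D);", "((A,C),B,D);", "((A,D),B,C);")
  rss <- vapply(topos, function(nwk) {
    tt <- ape::read.tree(text = nwk)
    tt$edge.length <- rep(1, nrow(tt$edge))
    pd <- acylTE:::path_design_matrix(tt)
    dv <- fx$D[cbind(tt$tip.label[pd$pairs[1, ]], tt$tip.label[pd$pairs[2, ]])]
    sum(lm.fit(pd$A, dv)$residuals^2)
  }, numeric(1))
  expect_equal(unname(which.min(rss)), 1L)
  expect_lt(rss[1], 1e-18)
})

test_that("three taxa use the closed-form branch lengths", {
  M <- matrix(c(0, 0.3, 0.5, 0.3, 0, 0.6, 0.5, 0.6, 0), 3, 3,
              dimnames = list(c("x", "y", "z"), c("x", "y", "z")))
  tr <- neighbor_joining(as_evodist(M))
  bl <- setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(bl[["x"]], (0.3 + 0.5 - 0.6) / 2, tolerance = 1e-12)
  expect_equal(bl[["y"]], (0.3 + 0.6 - 0.5) / 2, tolerance = 1e-12)
  expect_equal(bl[["z"]], (0.5 + 0.6 - 0.3) / 2, tolerance = 1e-12)
  expect_error(neighbor_joining(as_evodist(M[1:2, 1:2])), "at least 3")
})

test_that("NJ is invariant to input row order", {
  set.seed(5)
  tree <- ape::rtree(8, br = function(n) runif(n, 0.05, 0.5))
  D <- additive_matrix(tree)
  t1 <- neighbor_joining(as_evodist(D))
  perm <- sample(rownames(D))
  t2 <- neighbor_joining(as_evodist(D[perm, perm]))
  expect_same_unrooted_tree(t1, t2, tol = 1e-9)
})

test_that("NJ + OLS reproduces random additive instances to 1e-9", {
  for (seed in 1:6) {
    set.seed(seed)
    n <- sample(4:8, 1)
    tree <- ape::rtree(n, br = function(k) runif(k, 0.05, 0.6))
    D <- additive_matrix(tree)
    tr <- neighbor_joining(as_evodist(D))
    expect_same_unrooted_tree(tr, tree, tol = 1e-9)
    # cross-check against ape's NJ
    expect_equal(ape::dist.topo(ape::unroot(tr), ape::unroot(ape::nj(D))), 0,
                 ignore_attr = TRUE)
    # additive matrices are an ME fixed point
    ref <- minimum_evolution_refine(tr, as_evodist(D))
    expect_equal(ape::dist.topo(ape::unroot(ref), ape::unroot(tree)), 0,
                 ignore_attr = TRUE)
  }
})

test_that("ME refinement restores an NNI-perturbed topology and never
           increases tree length", {
  set.seed(77)
  tree <- ape::rtree(5, br = function(k) runif(k, 0.1, 0.6))
  D <- as_evodist(additive_matrix(tree))
  true_len <- ols_tree_length(tree, D)
  pert <- phangorn::nni(ape::unroot(tree))[[1]]
  pert_len <- ols_tree_length(pert, D)
  ref <- minimum_evolution_refine(pert, D)
  expect_lte(attr(ref, "tree_length"), pert_len + 1e-12)
  expect_equal(ape::dist.topo(ape::unroot(ref), ape::unroot(tree)), 0,
               ignore_attr = TRUE)
  expect_equal(attr(ref, "tree_length"), true_len, tolerance = 1e-9)
  star_like <- ape::read.tree(text = "(A:1,B:1,C:1,D:1);")
  expect_error(minimum_evolution_refine(star_like, D), "binary")
})

test_that("bootstrap supports are deterministic and match a hand tally", {
  st <- simulate_tree(k = 2, m = 4, intra_depth = 0.15, stem_length = 1,
                      seed = 12)
  aln <- simulate_alignment(st$tree, sites = 250, seed = 13,
                            species = st$species)
  bt1 <- bootstrap_supports(aln, replicates = 20, seed = 99,
                            keep_replicates = TRUE)
  bt2 <- bootstrap_supports(aln, replicates = 20, seed = 99)
  expect_identical(attr(bt1, "supports"), attr(bt2, "supports"))
  # independent tally via ape::prop.clades over the saved replicate trees
  reps <- attr(bt1, "replicate_trees")
  ref <- ape::prop.clades(bt1, reps, rooted = FALSE)
  sup <- attr(bt1, "supports")
  comparable <- !is.na(sup) & !is.na(ref)
  expect_true(any(comparable))
  expect_equal(sup[comparable], 100 * ref[comparable] / 20,
               tolerance = 1e-12)
  # the two clades are separated by a long stem: support must be 100
  key_clades <- c(paste(sort(st$partition$groups$S1), collapse = "\r"),
                  paste(sort(st$partition$groups$S2), collapse = "\r"))
  bips <- acylTE:::node_bipartitions(bt1)
  stem_nodes <- which(bips %in% key_clades)
  expect_true(all(sup[stem_nodes] == 100))
})

test_that("outgroup rooting places the root on the subtending edge", {
  tr <- ape::read.tree(text = "((a:1,b:1):0.6,(c:1,d:1):0.4,(e:1,f:1):0.2);")
  r1 <- root_with_outgroup(tr, c("a", "b"))
  expect_true(ape::is.rooted(r1))
  kids <- which(r1$edge[, 1] == length(r1$tip.label) + 1L)
  # the 0.6 subtending edge is split at its midpoint
  expect_equal(unname(r1$edge.length[kids]), c(0.3, 0.3), tolerance = 1e-9)
  # complement side gives the same root split
  r2 <- root_with_outgroup(tr, c("c", "d", "e", "f"))
  root_split <- function(r) {
    kids <- r$edge[r$edge[, 1] == length(r$tip.label) + 1L, 2]
    sets <- lapply(kids, function(k) {
      if (k <= length(r$tip.label)) r$tip.label[k]
      else sort(ape::extract.clade(r, k)$tip.label)
    })
    sets[[order(vapply(sets, function(s) s[1], character(1)))[1]]]
  }
  expect_identical(root_split(r1), root_split(r2))
  # bipartition set invariant under root + unroot
  expect_equal(ape::dist.topo(ape::unroot(r1), tr), 0, ignore_attr = TRUE)
  # single-tip outgroup roots on its pendant edge
  r3 <- root_with_outgroup(tr, "a")
  expect_true(ape::is.rooted(r3))
  expect_error(root_with_outgroup(tr, c("a", "c")), "monophyletic")
})
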