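test_that("pair statistics match direct arithmetic on the 4+4 toy matrix", {
  D <- two_group_toy()
  A <- paste0("a", 1:4); B <- paste0("b", 1:4)
  rec <- pair_statistics(D, A, B)
  # independent enumeration of the pairs
  intra_a <- c(); intra_b <- c(); inter <- c()
  for (i in 1:3) for (j in (i + 1):4) {
    intra_a <- c(intra_a, D$d[paste0("a", i), paste0("a", j)])
    intra_b <- c(intra_b, D$d[paste0("b", i), paste0("b", j)])
  }
  for (i in 1:4) for (j in 1:4) inter <- c(inter, D$d[paste0("a", i), paste0("b", j)])
  expect_equal(rec$d_inter, mean(inter), tolerance = 1e-15)
  expect_equal(rec$d_ii, mean(intra_a), tolerance = 1e-15)
  expect_equal(rec$d_jj, mean(intra_b), tolerance = 1e-15)
  expect_equal(rec$d_intra_pooled, mean(c(intra_a, intra_b)), tolerance = 1e-15)
  expect_equal(rec$var_inter, pop_var(inter), tolerance = 1e-15)
  expect_equal(rec$var_intra_pooled,
               (6 * pop_var(intra_a) + 6 * pop_var(intra_b)) / 12,
               tolerance = 1e-15)
  expect_identical(rec$n_ij, 16L)
  expect_identical(rec$n_ii, 6L)
  expect_identical(rec$n_jj, 6L)
  # z equals the hand-computed statistic to 1e-12
  z_hand <- (mean(inter) - mean(c(intra_a, intra_b))) /
    sqrt(pop_var(inter) / 16 +
           (6 * pop_var(intra_a) + 6 * pop_var(intra_b)) / 12 / 12)
  expect_equal(z_value(rec), z_hand, tolerance = 1e-12)
  # symmetry up to label swap
  rec_ba <- pair_statistics(D, B, A)
  expect_equal(z_value(rec_ba), z_value(rec), tolerance = 1e-15)
  expect_equal(rec_ba$d_inter, rec$d_inter)
  expect_equal(rec_ba$d_ii, rec$d_jj)
})

test_that("taxa count convention uses sequence counts in the denominators", {
  D <- two_group_toy()
  rec <- pair_statistics(D, paste0("a", 1:4), paste0("b", 1:4), counts = "taxa")
  expect_identical(rec$n_ij, 8L)
  expect_identical(rec$n_ii, 4L)
  expect_identical(rec$n_jj, 4L)
  z_taxa <- (rec$d_inter - rec$d_intra_pooled) /
    sqrt(rec$var_inter / 8 + rec$var_intra_pooled / 8)
  expect_equal(z_value(rec), z_taxa, tolerance = 1e-12)
})

test_that("z edge cases: null, degenerate separation, variance scaling", {
  D <- two_group_toy()
  rec <- pair_statistics(D, paste0("a", 1:4), paste0("b", 1:4))
  # null: equal means -> z = 0
  rec0 <- rec; rec0$d_inter <- rec0$d_intra_pooled
  expect_identical(z_value(rec0), 0)
  # degenerate: zero variances with separation -> +Inf, flagged
  recd <- rec; recd$var_inter <- 0; recd$var_intra_pooled <- 0
  zd <- z_value(recd)
  expect_identical(as.numeric(zd), Inf)
  expect_true(attr(zd, "degenerate"))
  recd$d_inter <- recd$d_intra_pooled
  expect_identical(z_value(recd), 0)
  # doubling both variances shrinks z by 1/sqrt(2)
  rec2 <- rec; rec2$var_inter <- 2 * rec$var_inter
  rec2$var_intra_pooled <- 2 * rec$var_intra_pooled
  expect_equal(z_value(rec2), z_value(rec) / sqrt(2), tolerance = 1e-12)
  # contract errors
  expect_error(pair_statistics(D, c("a1", "a2"), c("a2", "b1")), "overlap")
  expect_error(pair_statistics(D, "a1", paste0("b", 1:4)), "at least 2")
})

test_that("constant-separated groups validate with a degenerate pass", {
  ids <- c(paste0("a", 1:5), paste0("b", 1:5))
  M <- matrix(0.9, 10, 10, dimnames = list(ids, ids))
  M[1:5, 1:5] <- 0.1; M[6:10, 6:10] <- 0.1; diag(M) <- 0
  D <- as_evodist(M)
  part <- subfamily_partition(list(A = ids[1:5], B = ids[6:10]))
  rec <- pair_statistics(D, ids[1:5], ids[6:10])
  expect_equal(rec$d_inter, 0.9)
  expect_equal(rec$d_intra_pooled, 0.1)
  expect_equal(rec$var_inter, 0)
  v <- validate_partition(D, part)
  expect_true(v$pass)
  expect_true(v$degenerate)
  expect_identical(v$z_min, Inf)
})

test_that("membership rule: undersized or species-poor groups fail", {
  ids <- c(paste0("a", 1:4), paste0("b", 1:6))
  M <- matrix(0.9, 10, 10, dimnames = list(ids, ids))
  M[1:4, 1:4] <- 0.1; M[5:10, 5:10] <- 0.1; diag(M) <- 0
  D <- as_evodist(M)
  part <- subfamily_partition(list(A = ids[1:4], B = ids[5:10]))
  v <- validate_partition(D, part, min_size = 5)
  expect_false(v$pass)
  expect_match(v$violations, "membership", all = FALSE)
  # same sizes but all group-B members from one species
  species <- setNames(c(paste0("sp", 1:4), rep("spX", 6)), ids)
  part2 <- subfamily_partition(list(B = ids[5:10]), non_grouped = ids[1:4])
  v2 <- validate_partition(D, part2, min_size = 5, species = species)
  expect_false(v2$pass)
})

test_that("proposal takes outermost qualifying clades and leaves the rest", {
  # 16-tip fixture: a supported clade of 7 (t1-t7) contains a supported
  # clade of 5 (t1-t5); all other splits are below the support threshold
  ladder <- paste0("(t9:.1,(t10:.1,(t11:.1,(t12:.1,(t13:.1,(t14:.1,",
                   "(t15:.1,t16:.1):.1):.1):.1):.1):.1):.1):.5")
  clade7 <- paste0("((((t1:.1,t2:.1):.1,(t3:.1,t4:.1):.1):.1,t5:.1):.2,",
                   "(t6:.1,t7:.1):.1):.8")
  tr <- ape::read.tree(text = paste0("(", clade7, ",t8:.1,", ladder, ");"))
  pp <- ape::prop.part(tr)
  keyset <- function(v) paste(sort(paste0("t", v)), collapse = ",")
  sup <- rep(40, tr$Nnode)
  for (k in seq_along(pp)) {
    got <- paste(sort(tr$tip.label[pp[[k]]]), collapse = ",")
    if (got %in% c(keyset(1:5), keyset(1:7))) sup[k] <- 100
  }
  sup[1] <- NA  # root
  attr(tr, "supports") <- sup
  part <- propose_initial_partition(tr, support_min = 70, min_size = 5,
                                    min_species = 1)
  expect_length(part$groups, 1L)
  expect_setequal(part$groups[[1]], paste0("t", 1:7))
  expect_setequal(part$non_grouped, paste0("t", 8:16))
  # star tree: nothing qualifies
  star <- ape::read.tree(text = "(a:1,b:1,c:1,d:1,e:1,f:1);")
  attr(star, "supports") <- NA_real_  # lone internal node is the root
  expect_warning(p0 <- propose_initial_partition(star, min_size = 2,
                                                 min_species = 1),
                 "non-grouped")
  expect_length(p0$groups, 0)
  expect_setequal(p0$non_grouped, star$tip.label)
})

test_that("perfect two-clade tree proposes exactly those clades", {
  st <- simulate_tree(k = 2, m = 5, intra_depth = 0.1, stem_length = 1,
                      seed = 41)
  aln <- simulate_alignment(st$tree, sites = 300, seed = 42,
                            species = st$species)
  bt <- bootstrap_supports(aln, replicates = 30, seed = 43)
  part <- propose_initial_partition(bt, min_size = 5, min_species = 5,
                                    species = setNames(aln$species, aln$ids))
  expect_length(part$groups, 2L)
  got <- lapply(part$groups, sort)
  truth <- lapply(st$partition$groups, sort)
  expect_setequal(unname(vapply(got, paste, character(1), collapse = ",")),
                  unname(vapply(truth, paste, character(1), collapse = ",")))
})

test_that("refinement merges artificially split clades and ejects rogues", {
  st <- simulate_tree(k = 3, m = 6, intra_depth = 0.1, stem_length = 1,
                      seed = 51)
  aln <- simulate_alignment(st$tree, sites = 300, seed = 52,
                            species = st$species)
  D <- distance_matrix(aln)
  bt <- bootstrap_supports(aln, replicates = 30, seed = 53)
  sp <- setNames(aln$species, aln$ids)
  truth <- lapply(st$partition$groups, sort)
  # split S1 into two halves
  g1 <- truth$S1
  init <- subfamily_partition(
    c(list(S1a = g1[1:3], S1b = g1[4:6]),
      truth[c("S2", "S3")]))
  res <- refine_partition(D, bt, init, min_size = 5, min_species = 5,
                          species = sp)
  got <- lapply(res$partition$groups, sort)
  expect_setequal(unname(vapply(got, paste, character(1), collapse = ",")),
                  unname(vapply(truth, paste, character(1), collapse = ",")))
  expect_true(any(res$log$action == "merge"))
  expect_true(res$validation$pass)
  # already-valid partition is a fixed point with an empty log
  res2 <- refine_partition(D, bt, res$partition, min_size = 5,
                           min_species = 5, species = sp)
  expect_identical(lapply(res2$partition$groups, sort),
                   lapply(res$partition$groups, sort))
  expect_identical(nrow(res2$log), 0L)
})

test_that("a rogue long-branch sequence is ejected to non-grouped", {
  # crafted matrix: two tight groups plus one rogue parked inside group A;
  # the rogue inflates the pooled intra variance until z fails, and no
  # merge is possible (the union would be the whole tip set)
  ids <- c(paste0("a", 1:5), "rogue", paste0("b", 1:5))
  n <- length(ids)
  M <- matrix(0, n, n, dimnames = list(ids, ids))
  jit <- function(i, j) 0.002 * ((i * 7 + j * 3) %% 5)
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    gi <- substr(ids[i], 1, 1); gj <- substr(ids[j], 1, 1)
    base <- if (ids[i] == "rogue" || ids[j] == "rogue") 1.5
            else if (gi == gj) 0.10 else 0.20
    M[i, j] <- M[j, i] <- base + jit(i, j)
  }
  D <- as_evodist(M)
  tree <- neighbor_joining(D)
  A <- c(paste0("a", 1:5), "rogue"); B <- paste0("b", 1:5)
  expect_lt(z_value(pair_statistics(D, A, B)), 3.3)
  init <- subfamily_partition(list(A = A, B = B))
  res <- refine_partition(D, tree, init, min_size = 5, min_species = 5)
  expect_true(res$validation$pass)
  expect_identical(res$partition$non_grouped, "rogue")
  expect_setequal(res$partition$groups$A, paste0("a", 1:5))
  expect_setequal(res$partition$groups$B, B)
  expect_true(any(res$log$action == "eject"))
})

test_that("partition reports serialize to JSON and TSV", {
  D <- two_group_toy()
  part <- subfamily_partition(list(A = paste0("a", 1:4), B = paste0("b", 1:4)))
  v <- validate_partition(D, part, min_size = 4)
  res <- list(partition = part, validation = v,
              log = data.frame(iteration = integer(0), action = character(0),
                               detail = character(0)))
  js <- withr::local_tempfile(fileext = ".json")
  write_partition_report(res, js)
  obj <- jsonlite::read_json(js)
  expect_true(obj$pass)
  expect_named(obj$groups, c("A", "B"))
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_partition_tsv(part, tsv)
  tab <- read.delim(tsv)
  expect_identical(nrow(tab), 8L)
})
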