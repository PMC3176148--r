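# Shared fixtures and independent oracles used across the test files.

# tiny alignment with species metadata
toy_alignment <- function() {
  aligned_protein_set(
    ids = c("seq1", "seq2", "seq3"),
    species = c("Cocos nucifera", "Cuphea viscosissima", "Elaeis guineensis"),
    sequences = c("MKALCDEFGHIK", "MKALCDEFGHIR", "MKTLCDEFGH-K"))
}

# additive distance matrix from a tree, via path-length arithmetic done
# independently of the package (ape cophenetic)
additive_matrix <- function(tree) ape::cophenetic.phylo(tree)

# the classic 4-taxon additive fixture: pendant branches 0.1/0.2/0.3/0.4,
# internal branch 0.5
four_taxon_fixture <- function() {
  tree <- ape::read.tree(text = "((A:0.1,B:0.2):0.5,C:0.3,D:0.4);")
  list(tree = tree, D = additive_matrix(tree))
}

# 8x8 two-group toy distance matrix: intra values cycle over
# {0.08, 0.10, 0.12}, inter values cycle over {0.85, 0.90, 0.95}
two_group_toy <- function() {
  ids <- c(paste0("a", 1:4), paste0("b", 1:4))
  M <- matrix(0, 8, 8, dimnames = list(ids, ids))
  intra_vals <- c(0.08, 0.10, 0.12)
  inter_vals <- c(0.85, 0.90, 0.95)
  ki <- 0; ke <- 0
  for (i in 1:7) for (j in (i + 1):8) {
    same <- (i <= 4) == (j <= 4)
    if (same) {
      ki <- ki + 1
      M[i, j] <- M[j, i] <- intra_vals[(ki - 1) %% 3 + 1]
    } else {
      ke <- ke + 1
      M[i, j] <- M[j, i] <- inter_vals[(ke - 1) %% 3 + 1]
    }
  }
  structure(list(ids = ids, d = M,
                 shared_sites = matrix(100L, 8, 8, dimnames = dimnames(M)),
                 flags = matrix("ok", 8, 8, dimnames = dimnames(M))),
            class = "evodist")
}

# wrap a plain matrix as an evodist
as_evodist <- function(M) {
  structure(list(ids = rownames(M), d = M,
                 shared_sites = matrix(1000L, nrow(M), ncol(M),
                                       dimnames = dimnames(M)),
                 flags = matrix("ok", nrow(M), ncol(M),
                                dimnames = dimnames(M))),
            class = "evodist")
}

# population variance (independent arithmetic)
pop_var <- function(x) sum((x - mean(x))^2) / length(x)

# Exhaustive grid-search likelihood oracle for the pairwise ML distance:
# evaluates sum(counts * log(pi_a P_ab(t))) over a fine t grid for several
# count vectors at once. Independent spectral arithmetic (base eigen on Q).
grid_search_distances <- function(count_mat, model, step = 1e-4) {
  eg <- eigen(model$Q)
  V <- eg$vectors; Vi <- solve(V); lam <- Re(eg$values)
  # W[ab, k] so that P_flat(t) = W %*% exp(lam * t)
  W <- matrix(0, 400, 20)
  for (k in 1:20) W[, k] <- as.vector(Re(outer(V[, k], Vi[k, ])))
  tg <- seq(1e-4, 10, by = step)
  npair <- ncol(count_mat)
  best_ll <- rep(-Inf, npair)
  best_t <- rep(NA_real_, npair)
  # column-major flattening: index a + 20*(b-1) holds P[a, b]
  logpi_flat <- rep(log(model$pi), times = 20)
  chunk <- 2000L
  for (s in seq(1, length(tg), by = chunk)) {
    tt <- tg[s:min(s + chunk - 1L, length(tg))]
    E <- exp(outer(lam, tt))
    Pf <- W %*% E
    Pf[Pf < 1e-300] <- 1e-300
    ll <- crossprod(count_mat, log(Pf) + logpi_flat)  # npair x length(tt)
    mx <- apply(ll, 1, max)
    am <- apply(ll, 1, which.max)
    upd <- mx > best_ll
    best_ll[upd] <- mx[upd]
    best_t[upd] <- tt[am[upd]]
  }
  list(t = best_t, loglik = best_ll)
}

# pattern-count vector for two residue strings (independent tabulation)
oracle_pair_counts <- function(sa, sb, order = c("A", "R", "N", "D", "C",
                                                 "Q", "E", "G", "H", "I",
                                                 "L", "K", "M", "F", "P",
                                                 "S", "T", "W", "Y", "V")) {
  a <- match(strsplit(sa, "")[[1]], order)
  b <- match(strsplit(sb, "")[[1]], order)
  keep <- !is.na(a) & !is.na(b)
  counts <- numeric(400)
  for (i in which(keep)) {
    idx <- a[i] + 20 * (b[i] - 1)
    counts[idx] <- counts[idx] + 1
  }
  counts
}

# random aligned pair at true divergence t_true under the model
simulate_pair <- function(t_true, sites, model, seed) {
  set.seed(seed)
  ord <- rownames(model$S)
  anc <- sample(ord, sites, replace = TRUE, prob = model$pi)
  P <- transition_matrix(model, t_true)
  der <- vapply(anc, function(a) sample(ord, 1L, prob = P[a, ]), character(1))
  list(a = paste(anc, collapse = ""), b = paste(der, collapse = ""))
}

# Brute-force Ward agglomeration oracle on raw coordinates: at each step
# merge the two clusters whose union minimizes the increase in total
# within-cluster sum of squares. Returns merged member sets (sorted labels)
# and the SSE increase of each merge.
ward_oracle <- function(X) {
  clusters <- lapply(rownames(X), function(r) r)
  sse <- function(members) {
    M <- X[members, , drop = FALSE]
    sum(sweep(M, 2, colMeans(M))^2)
  }
  merges <- list(); costs <- numeric(0)
  while (length(clusters) > 1L) {
    best <- NULL; best_cost <- Inf
    for (i in seq_along(clusters)) for (j in seq_along(clusters)) {
      if (i >= j) next
      un <- c(clusters[[i]], clusters[[j]])
      cost <- sse(un) - sse(clusters[[i]]) - sse(clusters[[j]])
      if (cost < best_cost - 1e-12) { best_cost <- cost; best <- c(i, j) }
    }
    un <- sort(c(clusters[[best[1]]], clusters[[best[2]]]))
    merges[[length(merges) + 1L]] <- un
    costs <- c(costs, best_cost)
    clusters <- c(clusters[-best], list(un))
  }
  list(sets = merges, delta_sse = costs)
}

# profile list from a mol% matrix (for clustering tests)
profiles_from_matrix <- function(X) {
  lapply(rownames(X), function(r) compose_profile(X[r, ], r))
}
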