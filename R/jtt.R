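# Jones-Taylor-Thornton (1992) empirical amino-acid model: exchangeability
# counts (lower triangle, column-major, ARNDCQEGHILKMFPSTWYV order) and
# equilibrium frequencies, as distributed with standard phylogenetics software.
JTT_EXCHANGE <- c(
  58, 54, 81, 56, 57, 105, 179, 27, 36, 30, 35, 54, 15, 194, 378, 475, 9,
  11, 298, 45, 16, 113, 310, 29, 137, 328, 22, 38, 646, 44, 5, 74, 101, 64,
  126, 20, 17, 528, 34, 86, 58, 81, 391, 47, 12, 263, 30, 10, 15, 503, 232,
  8, 70, 16, 10, 49, 767, 130, 112, 11, 7, 26, 15, 4, 15, 59, 38, 4, 46,
  31, 9, 5, 59, 69, 17, 23, 7, 31, 78, 14, 223, 42, 115, 209, 62, 323, 26,
  597, 9, 72, 292, 43, 4, 164, 53, 51, 18, 24, 20, 119, 26, 12, 9, 181, 18,
  5, 18, 30, 32, 10, 7, 45, 23, 6, 6, 27, 14, 5, 24, 201, 33, 55, 8, 47,
  16, 56, 45, 33, 40, 115, 73, 46, 8, 573, 11, 229, 21, 479, 89, 10, 40,
  245, 9, 32, 961, 14, 388, 248, 102, 59, 25, 52, 24, 180, 65, 4, 21, 47,
  103, 10, 8, 14, 43, 16, 29, 226, 24, 18, 323, 17, 92, 12, 53, 536, 62,
  285, 118, 6, 10, 23, 477, 35, 63, 38, 12, 21, 112, 71, 25, 16)

JTT_FREQS <- c(
  A = 0.0767479232520768, R = 0.0516909483090517, N = 0.0426449573550427,
  D = 0.0515439484560515, C = 0.0198029801970198, Q = 0.0407519592480408,
  E = 0.0618299381700618, G = 0.0731519268480732, H = 0.0229439770560229,
  I = 0.0537609462390538, L = 0.0919039080960919, K = 0.0586759413240587,
  M = 0.0238259761740238, F = 0.0401259598740401, P = 0.0509009490990509,
  S = 0.0687649312350688, T = 0.0585649414350586, W = 0.0142609857390143,
  Y = 0.0321019678980321, V = 0.0660049339950660)

# Residue order used by the model matrices (differs from alphabetical
# AMINO_ACIDS order used by the alignment encoder).
JTT_ORDER <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
               "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

#' Construct a reversible amino-acid substitution model
#'
#' Builds the rate generator Q from symmetric exchangeabilities S and
#' equilibrium frequencies pi: `Q[a,b] = S[a,b] * pi[b]` for `a != b`, rows
#' summing to zero, scaled so the expected rate `-sum(pi * diag(Q))` is one
#' substitution per site. The spectral decomposition of the symmetrized
#' generator is precomputed for fast transition matrices.
#'
#' @param S Symmetric nonnegative 20x20 exchangeability matrix (diagonal
#'   ignored), with dimnames giving the residue order.
#' @param pi Equilibrium frequency vector (positive, sums to 1 after
#'   normalization), names matching `S`.
#' @param name Model name.
#' @return Object of class `substitution_model` with elements `name`,
#'   `S`, `pi`, `Q`, and the eigendecomposition used by
#'   [transition_matrix()].
#' @export
substitution_model <- function(S, pi, name = "custom") {
  stopifnot(is.matrix(S), nrow(S) == 20L, ncol(S) == 20L, length(pi) == 20L)
  if (any(pi <= 0)) stop("all equilibrium frequencies must be > 0")
  if (max(abs(S - t(S))) > 1e-12) stop("exchangeability matrix must be symmetric")
  pi <- pi / sum(pi)
  ord <- rownames(S)
  Q <- S * rep(pi, each = 20L)
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  mu <- -sum(pi * diag(Q))
  Q <- Q / mu
  # symmetrized generator B = D^{1/2} Q D^{-1/2} has real spectrum
  sq <- sqrt(pi)
  B <- Q * (sq %o% (1 / sq))
  B <- (B + t(B)) / 2
  eig <- eigen(B, symmetric = TRUE)
  structure(list(name = name, S = S, pi = setNames(pi, ord), Q = Q,
                 eigenvalues = eig$values,
                 U = eig$vectors, sq = sq),
            class = "substitution_model")
}

#' The JTT amino-acid substitution model
#'
#' @return A `substitution_model` with the embedded JTT-1992
#'   exchangeabilities and frequencies.
#' @export
jtt_model <- function() {
  S <- matrix(0, 20, 20, dimnames = list(JTT_ORDER, JTT_ORDER))
  S[lower.tri(S)] <- JTT_EXCHANGE
  S <- S + t(S)
  substitution_model(S, JTT_FREQS, name = "JTT")
}

#' @export
print.substitution_model <- function(x, ...) {
  cat("Substitution model:", x$name,
      "(20 states, mean rate 1 substitution/site)\n")
  invisible(x)
}

#' Transition probability matrix P(t) = exp(Qt)
#'
#' @param model A `substitution_model`.
#' @param t Branch length in expected substitutions per site (>= 0).
#' @return 20x20 row-stochastic matrix in the model's residue order; tiny
#'   negative entries from round-off are clamped to zero.
#' @export
transition_matrix <- function(model, t) {
  stopifnot(inherits(model, "substitution_model"), length(t) == 1L)
  if (!is.finite(t) || t < 0) stop("branch length t must be >= 0")
  U <- model$U
  P <- (U %*% (exp(model$eigenvalues * t) * t(U))) *
    ((1 / model$sq) %o% model$sq)
  if (min(P) < -1e-12)
    stop("transition matrix entry below -1e-12; eigendecomposition unstable")
  P[P < 0] <- 0
  dimnames(P) <- dimnames(model$S)
  P
}

# ---- internal machinery for pairwise ML distances -------------------------

DIST_TMIN <- 1e-6
DIST_TMAX <- 10
SATURATION_MARGIN <- 1e-3
LOW_COVERAGE_SITES <- 20L

# fixed coarse search grid (log-spaced); shared by all distance routines
dist_t_grid <- function(n = 121L) exp(seq(log(DIST_TMIN), log(DIST_TMAX), length.out = n))

# map alignment-encoding indices (alphabetical) to JTT model order
aln_to_model_index <- function() match(AMINO_ACIDS, JTT_ORDER)

# 400-vector of site-pattern counts (model order) for one pair of
# integer-encoded rows; NA entries (gap/ambiguity) are pairwise-deleted.
pair_pattern_counts <- function(a, b, map) {
  keep <- !is.na(a) & !is.na(b)
  if (!any(keep)) return(integer(400))
  idx <- (map[a[keep]] - 1L) * 20L + map[b[keep]]
  tabulate(idx, nbins = 400L)
}

# log P(t) flattened column of length 400 for each grid t: 400 x G matrix
log_p_grid <- function(model, tgrid) {
  vapply(tgrid, function(t) {
    P <- transition_matrix(model, t)
    log(pmax(P, 1e-300))
  }, numeric(400L))
}

# Brent refinement of the ML distance given counts and a bracketing interval.
# The objective includes the stationary prior pi_a (constant in t; kept for
# interpretability of the reported log-likelihood).
ml_refine_brent <- function(counts, model, lower, upper, tol = 1e-8) {
  nz <- which(counts > 0L)
  cnz <- counts[nz]
  logpi <- log(model$pi)[((nz - 1L) %/% 20L) + 1L]
  const <- sum(cnz * logpi)
  f <- function(t) {
    P <- transition_matrix(model, t)
    const + sum(cnz * log(pmax(P[nz], 1e-300)))
  }
  opt <- optimize(f, lower = lower, upper = upper, maximum = TRUE, tol = tol)
  list(t = opt$maximum, loglik = opt$objective)
}

# shared core: counts -> (distance, flag) using grid bracket + Brent
ml_dist_from_counts <- function(counts, model, gridL = NULL, tgrid = dist_t_grid(),
                                logP = NULL, tol = 1e-8) {
  n_shared <- sum(counts)
  if (n_shared == 0L) stop("zero shared sites")
  if (is.null(gridL)) {
    if (is.null(logP)) logP <- log_p_grid(model, tgrid)
    gridL <- as.numeric(crossprod(counts, logP))
  }
  i <- which.max(gridL)
  lower <- tgrid[max(i - 1L, 1L)]
  upper <- tgrid[min(i + 1L, length(tgrid))]
  ref <- ml_refine_brent(counts, model, lower, upper, tol = tol)
  d <- ref$t
  flag <- "ok"
  if (d >= DIST_TMAX - SATURATION_MARGIN) {
    d <- DIST_TMAX
    flag <- "saturated"
  } else if (n_shared < LOW_COVERAGE_SITES) {
    flag <- "low_coverage"
  }
  list(distance = d, shared_sites = as.integer(n_shared), flag = flag)
}

#' Pairwise maximum-likelihood distance between two aligned sequences
#'
#' Estimates the evolutionary distance t maximizing the independent-sites
#' log-likelihood `sum(log(pi_a * P_ab(t)))` over the shared sites (columns
#' where both sequences carry a canonical residue; gaps and ambiguity codes
#' are pairwise-deleted). The optimum is located by bounded scalar
#' maximization on \[1e-6, 10\] to tolerance 1e-8 (a fixed coarse grid
#' brackets the optimum first).
#'
#' @param seqA,seqB Aligned sequences (equal-length strings) or equal-length
#'   character vectors of residues.
#' @param model A `substitution_model`, e.g. [jtt_model()].
#' @return List with `distance` (substitutions/site), `shared_sites`, and
#'   `flag` (`"ok"`, `"saturated"` if the optimum hit the upper bound, or
#'   `"low_coverage"` if fewer than 20 shared sites).
#' @export
pairwise_ml_distance <- function(seqA, seqB, model = jtt_model()) {
  if (is.character(seqA) && length(seqA) == 1L) seqA <- strsplit(toupper(seqA), "")[[1]]
  if (is.character(seqB) && length(seqB) == 1L) seqB <- strsplit(toupper(seqB), "")[[1]]
  if (length(seqA) != length(seqB)) stop("sequences must have equal aligned length")
  a <- match(seqA, AMINO_ACIDS)
  b <- match(seqB, AMINO_ACIDS)
  map <- aln_to_model_index()
  counts <- pair_pattern_counts(a, b, map)
  ml_dist_from_counts(counts, model)
}

# all-pairs pattern-count matrix: 400 x npairs; pairs in combn order
all_pair_counts <- function(enc, map) {
  n <- nrow(enc)
  pairs <- combn(n, 2L)
  np <- ncol(pairs)
  L <- ncol(enc)
  cnt <- matrix(0L, nrow = 400L, ncol = np)
  for (p in seq_len(np)) {
    cnt[, p] <- pair_pattern_counts(enc[pairs[1L, p], ], enc[pairs[2L, p], ], map)
  }
  list(pairs = pairs, counts = cnt)
}

# vectorized quadratic (in log t) refinement from the coarse grid; used by
# bootstrap replicates where per-pair Brent polishing is unnecessary
quad_refine <- function(gridL, tgrid) {
  G <- length(tgrid)
  x <- log(tgrid)
  i <- max.col(t(gridL), ties.method = "first")  # gridL: G x npairs
  ti <- numeric(ncol(gridL))
  sat <- i == G
  lowhit <- i == 1L
  ti[lowhit] <- tgrid[1L]
  ti[sat] <- DIST_TMAX
  mid <- which(!sat & !lowhit)
  if (length(mid)) {
    im <- i[mid]
    y1 <- gridL[cbind(im - 1L, mid)]
    y2 <- gridL[cbind(im, mid)]
    y3 <- gridL[cbind(im + 1L, mid)]
    x1 <- x[im - 1L]; x2 <- x[im]; x3 <- x[im + 1L]
    # three-point parabola vertex in x = log(t)
    denom <- (x2 - x1) * (y2 - y3) - (x2 - x3) * (y2 - y1)
    num <- (x2 - x1)^2 * (y2 - y3) - (x2 - x3)^2 * (y2 - y1)
    xs <- ifelse(abs(denom) < 1e-30, x2, x2 - 0.5 * num / denom)
    xs <- pmin(pmax(xs, x1), x3)
    ti[mid] <- exp(xs)
  }
  list(t = pmin(pmax(ti, DIST_TMIN), DIST_TMAX), sat = sat)
}

#' All-pairs evolutionary distance matrix
#'
#' Computes the j x j symmetric matrix of pairwise ML distances under the
#' given substitution model with pairwise deletion of gaps/ambiguities,
#' together with per-pair shared-site counts and quality flags.
#'
#' @param aln An [aligned_protein_set()] with at least two sequences.
#' @param model A `substitution_model`.
#' @param refine `"brent"` (default; identical to element-wise
#'   [pairwise_ml_distance()]) or `"grid"` (coarse-grid + quadratic
#'   interpolation; used internally for bootstrap replicates).
#' @return Object of class `evodist`: `ids`, `d` (matrix), `shared_sites`
#'   (integer matrix), `flags` (character matrix).
#' @export
distance_matrix <- function(aln, model = jtt_model(),
                            refine = c("brent", "grid")) {
  stopifnot(inherits(aln, "aligned_protein_set"))
  refine <- match.arg(refine)
  n <- length(aln$ids)
  if (n < 2L) stop("need at least 2 sequences")
  enc <- aln_encode(aln)
  map <- aln_to_model_index()
  pc <- all_pair_counts(enc, map)
  zero <- colSums(pc$counts) == 0L
  if (any(zero)) {
    p <- which(zero)[1L]
    stop("zero shared sites for pair ", aln$ids[pc$pairs[1L, p]], " / ",
         aln$ids[pc$pairs[2L, p]])
  }
  tgrid <- dist_t_grid()
  logP <- log_p_grid(model, tgrid)
  gridL <- crossprod(logP, pc$counts)   # G x npairs
  np <- ncol(pc$counts)
  d <- matrix(0, n, n, dimnames = list(aln$ids, aln$ids))
  ss <- matrix(ncol(enc), n, n, dimnames = dimnames(d))
  fl <- matrix("ok", n, n, dimnames = dimnames(d))
  shared <- colSums(pc$counts)
  if (refine == "brent") {
    dv <- numeric(np); fv <- character(np)
    for (p in seq_len(np)) {
      r <- ml_dist_from_counts(pc$counts[, p], model, gridL = gridL[, p],
                               tgrid = tgrid)
      dv[p] <- r$distance; fv[p] <- r$flag
    }
  } else {
    qr_ <- quad_refine(gridL, tgrid)
    dv <- qr_$t
    fv <- ifelse(qr_$sat, "saturated",
                 ifelse(shared < LOW_COVERAGE_SITES, "low_coverage", "ok"))
    dv[qr_$sat] <- DIST_TMAX
  }
  for (p in seq_len(np)) {
    i <- pc$pairs[1L, p]; j <- pc$pairs[2L, p]
    d[i, j] <- d[j, i] <- dv[p]
    ss[i, j] <- ss[j, i] <- shared[p]
    fl[i, j] <- fl[j, i] <- fv[p]
  }
  diag(ss) <- as.integer(colSums(!is.na(t(enc))))
  structure(list(ids = aln$ids, d = d, shared_sites = ss, flags = fl),
            class = "evodist")
}

#' @export
print.evodist <- function(x, ...) {
  cat("Evolutionary distance matrix: ", length(x$ids), " sequences; ",
      sum(x$flags[upper.tri(x$flags)] != "ok"), " flagged pair(s)\n", sep = "")
  invisible(x)
}

#' Write a distance matrix as TSV (ids as header row and column)
#'
#' @param D An `evodist`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_distance_tsv <- function(D, path) {
  df <- data.frame(id = D$ids, D$d, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a distance matrix in PHYLIP square format
#'
#' @param D An `evodist`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_distance_phylip <- function(D, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%5d", length(D$ids)), con)
  for (i in seq_along(D$ids)) {
    writeLines(paste(formatC(D$ids[i], width = -10),
                     paste(sprintf("%.6f", D$d[i, ]), collapse = " ")), con)
  }
  invisible(path)
}
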