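# Subfamily delineation: inter/intra-subfamily distance statistics, the
# pairwise z acceptance test (z > 3.3 <=> p < 0.001, one-sided), and
# iterative partition refinement against a bootstrapped tree.

#' Construct a subfamily partition
#'
#' @param groups Named list mapping group label to character vector of
#'   sequence ids; groups must be pairwise disjoint.
#' @param non_grouped Character vector of ids outside any subfamily.
#' @return Object of class `subfamily_partition`.
#' @export
subfamily_partition <- function(groups = list(), non_grouped = character(0)) {
  if (length(groups) && is.null(names(groups)))
    names(groups) <- paste0("S", seq_along(groups))
  all_ids <- c(unlist(groups, use.names = FALSE), non_grouped)
  if (anyDuplicated(all_ids))
    stop("partition ids overlap: ",
         paste(unique(all_ids[duplicated(all_ids)]), collapse = ", "))
  structure(list(groups = lapply(groups, as.character),
                 non_grouped = as.character(non_grouped)),
            class = "subfamily_partition")
}

#' @export
print.subfamily_partition <- function(x, ...) {
  cat("Subfamily partition: ", length(x$groups), " group(s), ",
      length(x$non_grouped), " non-grouped\n", sep = "")
  for (g in names(x$groups))
    cat("  ", g, ": ", length(x$groups[[g]]), " sequences\n", sep = "")
  invisible(x)
}

partition_ids <- function(partition)
  c(unlist(partition$groups, use.names = FALSE), partition$non_grouped)

# population (denominator n) or sample (n-1) variance
vec_var <- function(x, denominator = c("n", "n-1")) {
  denominator <- match.arg(denominator)
  n <- length(x)
  if (n == 0L) return(NA_real_)
  v <- sum((x - mean(x))^2)
  if (denominator == "n") v / n else if (n > 1L) v / (n - 1L) else 0
}

#' Inter/intra-subfamily distance statistics for a pair of groups
#'
#' Computes the mean inter-group distance over all cross pairs, the two
#' within-group means over unordered pairs, the pair-count-weighted pooled
#' intra mean and variance, and the counts entering the z denominator under
#' the configured convention.
#'
#' @param D An `evodist`.
#' @param A,B Disjoint character vectors of ids (each >= 2 members in `D`).
#' @param counts Count convention for the z denominators: `"pairs"`
#'   (default; number of distance pairs contributing to each mean) or
#'   `"taxa"` (number of sequences).
#' @param var_denominator `"n"` (population pooling, default) or `"n-1"`.
#' @return A list of class `z_test_record` (z unset; see [z_value()]).
#' @export
pair_statistics <- function(D, A, B, counts = c("pairs", "taxa"),
                            var_denominator = c("n", "n-1")) {
  counts <- match.arg(counts)
  var_denominator <- match.arg(var_denominator)
  A <- as.character(A); B <- as.character(B)
  if (length(intersect(A, B))) stop("groups overlap")
  if (length(A) < 2L || length(B) < 2L)
    stop("each group needs at least 2 members")
  miss <- setdiff(c(A, B), D$ids)
  if (length(miss)) stop("ids not in distance matrix: ", paste(miss, collapse = ", "))
  cross <- as.vector(D$d[A, B])
  dAA <- D$d[A, A][upper.tri(diag(length(A)))]
  dBB <- D$d[B, B][upper.tri(diag(length(B)))]
  pA <- length(dAA); pB <- length(dBB)
  mA <- mean(dAA); mB <- mean(dBB)
  vA <- vec_var(dAA, var_denominator); vB <- vec_var(dBB, var_denominator)
  d_intra_pooled <- (pA * mA + pB * mB) / (pA + pB)
  var_intra_pooled <- (pA * vA + pB * vB) / (pA + pB)
  if (counts == "pairs") {
    n_ij <- length(cross); n_ii <- pA; n_jj <- pB
  } else {
    n_ij <- length(A) + length(B); n_ii <- length(A); n_jj <- length(B)
  }
  structure(list(
    group_i = attr(A, "label") %||% "A", group_j = attr(B, "label") %||% "B",
    members_i = A, members_j = B,
    d_inter = mean(cross), d_ii = mA, d_jj = mB,
    d_intra_pooled = d_intra_pooled,
    var_inter = vec_var(cross, var_denominator),
    var_intra_pooled = var_intra_pooled,
    n_ij = n_ij, n_ii = n_ii, n_jj = n_jj,
    counts = counts),
    class = "z_test_record")
}

#' The subfamily-separation z statistic
#'
#' `z = (d_inter - d_intra_pooled) / sqrt(var_inter/N_inter +
#' var_intra_pooled/N_intra)` where `N_inter = n_ij` and
#' `N_intra = n_ii + n_jj` under the record's count convention. `z > 0`
#' iff the two groups are more separated than cohesive; `z > 3.3`
#' corresponds to p < 0.001 (one-sided standard-normal tail).
#'
#' Degenerate records (both variances zero) return `Inf` with attribute
#' `degenerate = TRUE` when the inter mean exceeds the pooled intra mean,
#' `0` when they are equal, and `-Inf` otherwise.
#'
#' @param rec A `z_test_record` from [pair_statistics()].
#' @return Numeric z value.
#' @export
z_value <- function(rec) {
  stopifnot(inherits(rec, "z_test_record"))
  denom2 <- rec$var_inter / rec$n_ij +
    rec$var_intra_pooled / (rec$n_ii + rec$n_jj)
  delta <- rec$d_inter - rec$d_intra_pooled
  if (denom2 <= 0) {
    if (delta > 0) return(structure(Inf, degenerate = TRUE))
    if (delta < 0) return(structure(-Inf, degenerate = TRUE))
    return(0)
  }
  delta / sqrt(denom2)
}

membership_ok <- function(members, species, min_size, min_species) {
  if (length(members) < min_size) return(FALSE)
  sp <- if (is.null(species)) members else species[members]
  length(unique(sp)) >= min_species
}

all_pair_records <- function(D, partition, counts, var_denominator) {
  labs <- names(partition$groups)
  recs <- list()
  zs <- numeric(0)
  if (length(labs) >= 2L) {
    cmb <- combn(labs, 2L)
    for (k in seq_len(ncol(cmb))) {
      gi <- cmb[1, k]; gj <- cmb[2, k]
      rec <- pair_statistics(D, partition$groups[[gi]], partition$groups[[gj]],
                             counts = counts, var_denominator = var_denominator)
      rec$group_i <- gi; rec$group_j <- gj
      rec$z <- z_value(rec)
      recs[[paste(gi, gj, sep = " / ")]] <- rec
      zs <- c(zs, rec$z)
    }
  }
  list(records = recs, z = zs)
}

records_table <- function(recs) {
  if (!length(recs))
    return(data.frame(group_i = character(0), group_j = character(0),
                      d_inter = numeric(0), d_intra_pooled = numeric(0),
                      var_inter = numeric(0), var_intra_pooled = numeric(0),
                      n_ij = integer(0), n_ii = integer(0), n_jj = integer(0),
                      z = numeric(0)))
  do.call(rbind, lapply(recs, function(r)
    data.frame(group_i = r$group_i, group_j = r$group_j,
               d_inter = r$d_inter, d_intra_pooled = r$d_intra_pooled,
               var_inter = r$var_inter, var_intra_pooled = r$var_intra_pooled,
               n_ij = r$n_ij, n_ii = r$n_ii, n_jj = r$n_jj,
               z = as.numeric(r$z), row.names = NULL)))
}

#' Validate a subfamily partition
#'
#' A partition passes iff every pairwise z exceeds the threshold AND every
#' group meets the membership rule (at least `min_size` sequences from at
#' least `min_species` distinct species).
#'
#' @param D An `evodist`.
#' @param partition A `subfamily_partition` covering `D`'s ids.
#' @param z_threshold z acceptance threshold (default 3.3, i.e. p < 0.001).
#' @param min_size Minimum sequences per subfamily (default 5).
#' @param min_species Minimum distinct species per subfamily (default
#'   `min_size`); ignored when `species` is `NULL`.
#' @param species Optional named vector mapping id to species.
#' @param counts,var_denominator Passed to [pair_statistics()].
#' @return List: `pass` (logical), `records` (data frame of all pairwise
#'   `z_test_record`s), `violations` (character), `z_min`.
#' @export
validate_partition <- function(D, partition, z_threshold = 3.3, min_size = 5L,
                               min_species = min_size, species = NULL,
                               counts = "pairs", var_denominator = "n") {
  stopifnot(inherits(partition, "subfamily_partition"))
  miss <- setdiff(partition_ids(partition), D$ids)
  if (length(miss)) stop("partition ids not in D: ", paste(miss, collapse = ", "))
  violations <- character(0)
  for (g in names(partition$groups)) {
    mem <- partition$groups[[g]]
    if (!membership_ok(mem, species, min_size, min_species))
      violations <- c(violations, paste0(
        "group ", g, " violates membership rule (", length(mem),
        " sequences, ",
        length(unique(if (is.null(species)) mem else species[mem])),
        " species)"))
  }
  ap <- all_pair_records(D, partition,
                         counts = counts, var_denominator = var_denominator)
  for (nm in names(ap$records)) {
    if (ap$records[[nm]]$z <= z_threshold)
      violations <- c(violations,
                      paste0("z(", nm, ") = ",
                             format(ap$records[[nm]]$z, digits = 4),
                             " <= ", z_threshold))
  }
  degenerate <- any(vapply(ap$records,
                           function(r) isTRUE(attr(r$z, "degenerate")),
                           logical(1)))
  list(pass = length(violations) == 0L,
       records = records_table(ap$records),
       violations = violations,
       z_min = if (length(ap$z)) min(ap$z) else NA_real_,
       degenerate = degenerate)
}

# ---- propose / refine -----------------------------------------------------

# Candidate clades from supported bipartitions: the smaller side of each
# split (a subfamily is in practice a minority clade; the far side is the
# union of everything else), or both sides when the split is balanced.
supported_clades <- function(tree, support_min) {
  sup <- attr(tree, "supports")
  if (is.null(sup)) {
    sup <- suppressWarnings(as.numeric(tree$node.label))
  }
  if (is.null(sup) || !length(sup)) stop("tree has no bootstrap supports")
  tips <- tree$tip.label
  pp <- ape::prop.part(tree)
  out <- list()
  for (k in seq_along(pp)) {
    if (k > length(sup) || is.na(sup[k]) || sup[k] < support_min) next
    set <- tips[pp[[k]]]
    if (length(set) >= length(tips)) next
    comp <- setdiff(tips, set)
    sides <- if (length(set) < length(comp)) list(set)
             else if (length(comp) < length(set)) list(comp)
             else list(set, comp)
    for (cand in sides) {
      if (length(cand) < 2L) next
      cand <- sort(cand)
      out[[paste(cand, collapse = "\r")]] <- cand
    }
  }
  out
}


#' Propose an initial subfamily partition from a bootstrapped tree
#'
#' Automated surrogate for breaking a bootstrapped tree into apparent
#' subfamilies by eye: candidate groups are the smaller sides of
#' well-supported bipartitions (both sides when the split is balanced)
#' that meet the membership rule; the final proposal greedily selects
#' disjoint candidates largest-first, so nested supported clades resolve
#' to the outermost qualifying one.
#'
#' @param tree `phylo` with bootstrap supports (see [bootstrap_supports()]).
#' @param support_min Minimum support percentage (default 70).
#' @param min_size,min_species,species Membership rule, as in
#'   [validate_partition()].
#' @return A `subfamily_partition`; all-tips-non-grouped with a warning if
#'   no clade qualifies.
#' @export
propose_initial_partition <- function(tree, support_min = 70, min_size = 5L,
                                      min_species = min_size, species = NULL) {
  tips <- tree$tip.label
  cands <- supported_clades(tree, support_min)
  cands <- Filter(function(m) membership_ok(m, species, min_size, min_species),
                  cands)
  if (!length(cands)) {
    warning("no supported clade meets the membership rule; all sequences non-grouped")
    return(subfamily_partition(list(), non_grouped = sort(tips)))
  }
  ord <- order(-vapply(cands, length, integer(1)),
               vapply(cands, function(m) paste(m, collapse = "\r"), character(1)))
  cands <- cands[ord]
  chosen <- list()
  used <- character(0)
  for (m in cands) {
    if (!length(intersect(m, used))) {
      chosen[[length(chosen) + 1L]] <- m
      used <- c(used, m)
    }
  }
  names(chosen) <- paste0("S", seq_along(chosen))
  subfamily_partition(chosen, non_grouped = sort(setdiff(tips, used)))
}

# does a set of tips form one side of a bipartition of the tree?
is_tree_clade <- function(tree, members) {
  tips <- tree$tip.label
  members <- sort(members)
  if (length(members) <= 1L || length(members) >= length(tips)) return(FALSE)
  anchor <- min(tips)
  side <- if (anchor %in% members) sort(setdiff(tips, members)) else members
  key <- paste(side, collapse = "\r")
  key %in% node_bipartitions(tree)
}

#' Iteratively refine a subfamily partition until all z exceed the threshold
#'
#' Deterministic greedy loop mirroring manual curation: while validation
#' fails, (1) for the worst (lowest-z) pair, merge the two groups if their
#' union is a clade in the tree, (2) otherwise eject to non-grouped the
#' single sequence whose removal maximally increases the minimum pairwise z
#' (ties broken by the lexicographically smallest id); once all z pass,
#' (3) groups still violating the membership rule dissolve to non-grouped.
#' z failures are resolved first so that artificially split fragments of
#' one clade merge back rather than dissolving for being undersized.
#' Capped at `10 * j` iterations.
#'
#' @param D An `evodist`.
#' @param tree The bootstrapped `phylo` used for the clade test.
#' @param initial A `subfamily_partition` covering `D`'s ids.
#' @param z_threshold,min_size,min_species,species,counts,var_denominator
#'   As in [validate_partition()].
#' @return List: `partition` (final, passing), `log` (data frame audit
#'   trail), `validation` (final [validate_partition()] report). Errors if
#'   the iteration cap is reached, carrying the best partition found in the
#'   condition's `best_partition` field.
#' @export
refine_partition <- function(D, tree, initial, z_threshold = 3.3,
                             min_size = 5L, min_species = min_size,
                             species = NULL, counts = "pairs",
                             var_denominator = "n") {
  stopifnot(inherits(initial, "subfamily_partition"))
  cur <- initial
  j <- length(D$ids)
  log <- data.frame(iteration = integer(0), action = character(0),
                    detail = character(0))
  note <- function(it, action, detail) {
    log[nrow(log) + 1L, ] <<- list(it, action, detail)
  }
  best <- NULL; best_zmin <- -Inf
  validate <- function(p) validate_partition(
    D, p, z_threshold = z_threshold, min_size = min_size,
    min_species = min_species, species = species, counts = counts,
    var_denominator = var_denominator)
  for (it in seq_len(10L * j)) {
    # groups too small to carry distance statistics can never be repaired
    tiny <- Filter(function(g) length(cur$groups[[g]]) < 2L,
                   names(cur$groups))
    for (g in tiny) {
      note(it, "dissolve", paste0(g, " (", length(cur$groups[[g]]),
                                  " sequence) -> non-grouped"))
      cur <- subfamily_partition(cur$groups[setdiff(names(cur$groups), g)],
                                 c(cur$non_grouped, cur$groups[[g]]))
    }
    v <- validate(cur)
    if (!is.na(v$z_min) && v$z_min > best_zmin) {
      best <- cur; best_zmin <- v$z_min
    }
    if (v$pass) {
      return(list(partition = cur, log = log, validation = v))
    }
    tab <- v$records
    tab <- tab[order(tab$z, tab$group_i, tab$group_j), , drop = FALSE]
    if (nrow(tab) == 0L || tab$z[1L] > z_threshold) {
      # all pairwise z pass: remaining failures are membership violations
      bad <- Filter(function(g) !membership_ok(cur$groups[[g]], species,
                                               min_size, min_species),
                    names(cur$groups))
      for (g in bad) {
        note(it, "dissolve", paste0(g, " (", length(cur$groups[[g]]),
                                    " sequences) -> non-grouped"))
        cur <- subfamily_partition(cur$groups[setdiff(names(cur$groups), g)],
                                   c(cur$non_grouped, cur$groups[[g]]))
      }
      next
    }
    worst <- tab[1L, ]
    gi <- worst$group_i; gj <- worst$group_j
    union_members <- c(cur$groups[[gi]], cur$groups[[gj]])
    if (is_tree_clade(tree, union_members)) {
      lab <- paste(sort(c(gi, gj)), collapse = "+")
      note(it, "merge", paste0(gi, " + ", gj, " (z = ",
                               format(worst$z, digits = 4), ") -> ", lab))
      gs <- cur$groups[setdiff(names(cur$groups), c(gi, gj))]
      gs[[lab]] <- sort(union_members)
      cur <- subfamily_partition(gs, cur$non_grouped)
    } else {
      cand_ids <- sort(unlist(cur$groups, use.names = FALSE))
      best_id <- NA_character_; best_min <- -Inf
      for (id in cand_ids) {
        gs <- lapply(cur$groups, function(m) setdiff(m, id))
        gs <- gs[vapply(gs, length, integer(1)) >= 2L]
        if (length(gs) < 2L) next
        trial <- subfamily_partition(gs, character(0))
        ap <- all_pair_records(D, trial, counts, var_denominator)
        zmin <- min(ap$z)
        if (zmin > best_min) { best_min <- zmin; best_id <- id }
      }
      if (is.na(best_id))
        stop("refinement stalled: no ejection improves the partition")
      note(it, "eject", paste0(best_id, " -> non-grouped (min z ",
                               format(worst$z, digits = 4), " -> ",
                               format(best_min, digits = 4), ")"))
      gs <- lapply(cur$groups, function(m) setdiff(m, best_id))
      cur <- subfamily_partition(gs, c(cur$non_grouped, best_id))
    }
  }
  cond <- simpleError(paste0("refinement iteration cap (", 10L * j,
                             ") reached without a valid partition"))
  cond$best_partition <- best
  stop(cond)
}

#' Write a partition-validation report as JSON
#'
#' @param result Output of [refine_partition()] (or a compatible list with
#'   `partition`, `validation`, `log`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_partition_report <- function(result, path) {
  obj <- list(
    groups = result$partition$groups,
    non_grouped = result$partition$non_grouped,
    pass = result$validation$pass,
    z_min = result$validation$z_min,
    records = result$validation$records,
    violations = result$validation$violations,
    audit_log = result$log)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Write a partition as a two-column TSV (id, group or NA)
#'
#' @param partition A `subfamily_partition`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_partition_tsv <- function(partition, path) {
  rows <- rbind(
    do.call(rbind, lapply(names(partition$groups), function(g)
      data.frame(id = partition$groups[[g]], group = g))),
    if (length(partition$non_grouped))
      data.frame(id = partition$non_grouped, group = NA_character_))
  rows <- rows[order(rows$id), , drop = FALSE]
  write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
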