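# Seeded generators emulating the statistical structure the analysis
# assumes: subfamily-structured amino-acid divergence under the JTT process,
# and class-structured fatty-acid composition vectors with Dirichlet noise,
# control-strain background, and internal-standard peak tables.

#' Simulate a subfamily-structured phylogeny
#'
#' Generates `k` clades of `m` tips each; every clade is a random
#' coalescent-shaped subtree whose tip depth is drawn uniformly from
#' `[0.5, 1] * intra_depth`, and clades are joined at a central node by
#' stems of length `stem_length`. Tip labels are `t01, t02, ...`; the true
#' partition assigns each clade to one subfamily. Deterministic given
#' `seed`.
#'
#' @param k Number of subfamilies (>= 1).
#' @param m Tips per subfamily (>= 2).
#' @param intra_depth Expected within-clade tip depth (substitutions/site).
#' @param stem_length Subfamily stem length (substitutions/site).
#' @param seed Integer seed.
#' @return List: `tree` (`phylo`), `partition` (the generating
#'   `subfamily_partition`), `species` (named vector, one distinct species
#'   per tip).
#' @export
simulate_tree <- function(k = 3L, m = 10L, intra_depth = 0.1,
                          stem_length = 1.0, seed = 1L) {
  stopifnot(k >= 1L, m >= 2L, intra_depth >= 0, stem_length >= 0)
  set.seed(seed)
  ntip <- k * m
  width <- max(2L, nchar(as.character(ntip)))
  tips <- sprintf(paste0("t%0", width, "d"), seq_len(ntip))
  groups <- split(tips, rep(seq_len(k), each = m))
  frags <- character(k)
  for (ci in seq_len(k)) {
    depth <- runif(1, 0.5, 1) * intra_depth
    frags[ci] <- random_clade_scaled(groups[[ci]], depth)
  }
  nwk <- if (k == 1L) paste0(frags[1], ";") else
    paste0("(", paste0(frags, ":", format_bl(stem_length), collapse = ","), ");")
  tree <- ape::read.tree(text = nwk)
  partition <- subfamily_partition(
    setNames(groups, paste0("S", seq_len(k))))
  species <- setNames(paste0("sp", seq_len(ntip)), tips)
  list(tree = tree, partition = partition, species = species)
}

# coalescent subtree with exact numeric depth rescaling
random_clade_scaled <- function(tips, depth) {
  m <- length(tips)
  if (m == 1L) return(paste0(tips, ":", format_bl(depth)))
  height <- setNames(rep(0, m), tips)
  frag <- setNames(tips, tips)
  t_now <- 0
  events <- list()
  active <- tips
  # first pass: record join order and times
  while (length(active) > 1L) {
    kk <- length(active)
    t_now <- t_now + stats::rexp(1, rate = kk * (kk - 1) / 2)
    pick <- sort(sample(length(active), 2L))
    events[[length(events) + 1L]] <- list(a = active[pick[1]],
                                          b = active[pick[2]], t = t_now)
    active <- c(setdiff(active, c(active[pick[1]], active[pick[2]])),
                active[pick[1]])
  }
  s <- if (t_now > 0) depth / t_now else 0
  for (ev in events) {
    a <- ev$a; b <- ev$b; t_sc <- ev$t * s
    newfrag <- paste0("(", frag[a], ":", format_bl(t_sc - height[a]), ",",
                      frag[b], ":", format_bl(t_sc - height[b]), ")")
    frag <- frag[setdiff(names(frag), c(a, b))]
    height <- height[setdiff(names(height), c(a, b))]
    frag[a] <- newfrag
    height[a] <- t_sc
  }
  frag[[1]]
}

#' Simulate an alignment along a tree under a substitution model
#'
#' Root states are drawn from the model's stationary frequencies; each
#' branch of length `b` transforms states site-wise by sampling from the
#' rows of `transition_matrix(model, b)`. No indels; species names default
#' to one distinct species per tip.
#'
#' @param tree A `phylo` with finite branch lengths.
#' @param sites Number of alignment columns.
#' @param model A `substitution_model`.
#' @param seed Integer seed.
#' @param species Optional named species vector (tip -> species).
#' @return An [aligned_protein_set()].
#' @export
simulate_alignment <- function(tree, sites, model = jtt_model(), seed = 1L,
                               species = NULL) {
  stopifnot(inherits(tree, "phylo"), sites >= 1L)
  if (any(!is.finite(tree$edge.length)))
    stop("branch lengths must be finite")
  set.seed(seed)
  ntip <- length(tree$tip.label)
  nn <- max(tree$edge)
  root <- setdiff(unique(tree$edge[, 1]), tree$edge[, 2])
  states <- matrix(NA_integer_, nn, sites)
  states[root, ] <- sample.int(20L, sites, replace = TRUE, prob = model$pi)
  # cladewise edge order guarantees parent states exist before children
  tree <- ape::reorder.phylo(tree, "cladewise")
  edges <- tree$edge
  lens <- tree$edge.length
  for (e in seq_len(nrow(edges))) {
    par <- edges[e, 1]; child <- edges[e, 2]
    P <- transition_matrix(model, lens[e])
    ps <- states[par, ]
    cs <- integer(sites)
    for (a in unique(ps)) {
      idx <- which(ps == a)
      cs[idx] <- sample.int(20L, length(idx), replace = TRUE, prob = P[a, ])
    }
    states[child, ] <- cs
  }
  # model order -> letters
  seqs <- apply(states[seq_len(ntip), , drop = FALSE], 1L,
                function(row) paste(JTT_ORDER[row], collapse = ""))
  ids <- tree$tip.label
  if (is.null(species)) species <- setNames(paste0("sp", seq_len(ntip)), ids)
  aligned_protein_set(ids, unname(species[ids]), seqs)
}

#' Default substrate-specificity class archetypes
#'
#' Three mol% archetypes over a standard fatty-acid panel: Class I
#' (C14/C16-dominant), Class II (bimodal C8 + C14), Class III
#' (C8-dominant). The remainder of each archetype is spread uniformly over
#' the rest of the panel so every vector sums to 100.
#'
#' @return Named list of named numeric vectors (mol%, each summing to 100).
#' @export
class_archetypes <- function() {
  panel <- c("4:0", "6:0", "8:0", "10:0", "12:0", "14:0", "14:1",
             "16:0", "16:1", "18:0", "18:1")
  spread <- function(major, rest_total) {
    v <- setNames(rep(0, length(panel)), panel)
    v[names(major)] <- major
    others <- setdiff(panel, names(major))
    v[others] <- rest_total / length(others)
    v
  }
  list(
    I   = spread(c("14:0" = 45, "16:0" = 20, "16:1" = 30), 5),
    II  = spread(c("8:0" = 35, "14:0" = 30, "12:0" = 15), 20),
    III = spread(c("8:0" = 80, "6:0" = 10), 10))
}

#' Control-strain background fatty-acid concentrations
#'
#' Defaults to the three most abundant fatty acids produced by the
#' control strain: 8:0 at 2.0, 14:0 at 3.5 and 16:0 at 3.1 nmol/mL.
#'
#' @return Named numeric vector (nmol/mL).
#' @export
control_background <- function() c("8:0" = 2.0, "14:0" = 3.5, "16:0" = 3.1)

#' Simulate class-structured specificity profiles and their peak tables
#'
#' Per enzyme, the mol% vector is drawn from a Dirichlet distribution
#' centred on its class archetype (`concentration * archetype / 100`), the
#' fatty-acid total from a lognormal, net concentrations as
#' `mol% * total / 100`, and raw concentrations as net plus the control
#' background. Peak tables are emitted by inverting the internal-standard
#' quantitation arithmetic (fixed standard areas), so the full
#' quantify/subtract/compose pipeline is exercised end-to-end.
#'
#' @param archetypes Named list of mol% archetype vectors (default
#'   [class_archetypes()]).
#' @param profiles_per_class Enzymes per class (default 8).
#' @param concentration Dirichlet concentration (default 200; `Inf`
#'   disables composition noise).
#' @param total_meanlog,total_sdlog Lognormal parameters of the fatty-acid
#'   total in nmol/mL (defaults `log(100)` and 0.5; `total_sdlog = 0`
#'   disables total noise).
#' @param background Control background vector (default
#'   [control_background()]).
#' @param standards An [internal_standard_set()].
#' @param seed Integer seed.
#' @return List: `labels` (named class vector), `molpct` (true mol%
#'   matrix), `peaks` (data frame: enzyme, species, area), `control`
#'   (data frame: species, nmol_per_mL), `standards`.
#' @export
simulate_profiles <- function(archetypes = class_archetypes(),
                              profiles_per_class = 8L,
                              concentration = 200,
                              total_meanlog = log(100), total_sdlog = 0.5,
                              background = control_background(),
                              standards = internal_standard_set(),
                              seed = 1L) {
  stopifnot(concentration > 0, profiles_per_class >= 1L)
  for (a in archetypes)
    if (abs(sum(a) - 100) > 1e-6) stop("archetype vectors must sum to 100")
  set.seed(seed)
  classes <- names(archetypes)
  enzymes <- character(0); labels <- character(0)
  molpct <- NULL
  is_area <- 1e5  # fixed detector response for every internal standard peak
  peak_rows <- list()
  panel <- sort(unique(unlist(lapply(archetypes, names))))
  for (cl in classes) {
    arch <- setNames(rep(0, length(panel)), panel)
    arch[names(archetypes[[cl]])] <- archetypes[[cl]]
    for (i in seq_len(profiles_per_class)) {
      enz <- sprintf("%s_%02d", cl, i)
      if (is.infinite(concentration)) {
        p <- arch / 100
      } else {
        g <- rgamma(length(arch), shape = concentration * arch / 100)
        if (sum(g) == 0) g[] <- arch / 100
        p <- g / sum(g)
      }
      total <- if (total_sdlog == 0) exp(total_meanlog) else
        rlnorm(1, total_meanlog, total_sdlog)
      net <- p * total  # nmol/mL per species
      bg <- setNames(rep(0, length(panel)), panel)
      bg[names(background)] <- background
      raw <- net + bg
      # invert quantify(): area = conc / conc_IS * area_IS (unit RF)
      std <- assign_standard(carbon_number(panel))
      area <- raw / standards$conc_nmol_ml[std] * is_area
      peak_rows[[enz]] <- data.frame(
        enzyme = enz,
        species = c(panel, standards$species),
        area = c(as.numeric(area), rep(is_area, length(standards$species))))
      enzymes <- c(enzymes, enz); labels <- c(labels, cl)
      molpct <- rbind(molpct, 100 * p)
    }
  }
  rownames(molpct) <- enzymes
  colnames(molpct) <- panel
  ctl <- setNames(rep(0, length(panel)), panel)
  ctl[names(background)] <- background
  list(labels = setNames(labels, enzymes),
       molpct = molpct,
       peaks = do.call(rbind, c(peak_rows, list(make.row.names = FALSE))),
       control = data.frame(species = panel, nmol_per_mL = as.numeric(ctl)),
       standards = standards)
}
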