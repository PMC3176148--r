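# End-to-end orchestration of the two analysis arms with machine-readable
# artifacts and a reproducibility manifest.

#' Pipeline configuration
#'
#' Collects paths and parameters for [run_phylo()] and [run_specificity()].
#' Defaults mirror the study parameters: z threshold 3.3 (p < 0.001),
#' subfamily membership of at least five sequences from five species, and
#' 1000 bootstrap replicates for both tree supports and cluster p-values.
#'
#' @param msa Path to an aligned protein FASTA.
#' @param peaks Path to a peak-table CSV (`enzyme, species, area`).
#' @param control Path to a control-profile CSV (`species, nmol_per_mL`).
#' @param z_threshold Subfamily acceptance threshold (default 3.3).
#' @param min_size,min_species Membership rule (default 5 and 5).
#' @param bootstrap_replicates Tree bootstrap replicates (default 1000).
#' @param clustering_replicates Multiscale-bootstrap replicates (default 1000).
#' @param k Number of specificity classes to cut (default 3).
#' @param seed Integer seed used for all resampling.
#' @param support_min Minimum bootstrap support for proposed clades.
#' @param counts z-denominator count convention (`"pairs"` or `"taxa"`).
#' @param out_dir Optional directory for artifacts; created if needed.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(msa = NULL, peaks = NULL, control = NULL,
                            z_threshold = 3.3, min_size = 5L,
                            min_species = 5L, bootstrap_replicates = 1000L,
                            clustering_replicates = 1000L, k = 3L,
                            seed = 1L, support_min = 70,
                            counts = "pairs", out_dir = NULL) {
  stopifnot(z_threshold > 0, bootstrap_replicates >= 1L,
            clustering_replicates >= 1L)
  structure(list(msa = msa, peaks = peaks, control = control,
                 z_threshold = z_threshold, min_size = min_size,
                 min_species = min_species,
                 bootstrap_replicates = bootstrap_replicates,
                 clustering_replicates = clustering_replicates, k = k,
                 seed = seed, support_min = support_min, counts = counts,
                 out_dir = out_dir),
            class = "pipeline_config")
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("stage '", name, "': ", conditionMessage(e), call. = FALSE))
}

write_manifest <- function(config, path, extra = list()) {
  cfg <- lapply(unclass(config), function(x) {
    if (is.null(x) || (is.atomic(x) && length(x) <= 100L)) x
    else sprintf("<in-memory %s>", class(x)[1])
  })
  cfg$out_dir <- NULL  # machine-specific; keep manifests reproducible
  obj <- c(list(package = "acylTE",
                version = as.character(utils::packageVersion("acylTE")),
                config = cfg), extra)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' Run the phylogeny / subfamily-delineation arm
#'
#' Distances -> NJ + minimum-evolution tree -> bootstrap supports ->
#' proposed partition -> z-driven refinement -> validated partition.
#' Artifacts (distance TSV, Newick tree, partition TSV, JSON report,
#' manifest) are written when `config$out_dir` is set.
#'
#' @param config A [pipeline_config()] with `msa` set (or an
#'   `aligned_protein_set` passed directly as `config$msa`).
#' @return List: `distances`, `tree`, `partition`, `validation`, `log`.
#' @export
run_phylo <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  aln <- stage("read_msa", {
    if (inherits(config$msa, "aligned_protein_set")) config$msa
    else read_msa(config$msa)
  })
  model <- jtt_model()
  D <- stage("distances", distance_matrix(aln, model))
  tree <- stage("tree", {
    tr <- neighbor_joining(D)
    minimum_evolution_refine(tr, D)
  })
  tree <- stage("bootstrap", bootstrap_supports(
    aln, model, replicates = config$bootstrap_replicates,
    seed = config$seed, tree = tree))
  species <- setNames(aln$species, aln$ids)
  init <- stage("propose", propose_initial_partition(
    tree, support_min = config$support_min, min_size = config$min_size,
    min_species = config$min_species, species = species))
  res <- stage("refine", refine_partition(
    D, tree, init, z_threshold = config$z_threshold,
    min_size = config$min_size, min_species = config$min_species,
    species = species, counts = config$counts))
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    write_distance_tsv(D, file.path(config$out_dir, "distances.tsv"))
    write_newick(tree, file.path(config$out_dir, "tree.nwk"))
    write_partition_tsv(res$partition, file.path(config$out_dir, "partition.tsv"))
    write_partition_report(res, file.path(config$out_dir, "subfamilies.json"))
    write_manifest(config, file.path(config$out_dir, "manifest_phylo.json"),
                   extra = list(n_sequences = length(aln$ids),
                                alignment_columns = aln$length))
  }
  list(distances = D, tree = tree, partition = res$partition,
       validation = res$validation, log = res$log)
}

#' Run the specificity-classification arm
#'
#' Quantify peak tables -> subtract control background -> compose mol%
#' profiles -> Ward clustering with multiscale-bootstrap AU p-values ->
#' k-class cut. Artifacts (profile CSV, dendrogram Newick, class TSV, JSON
#' diagnostics, manifest) are written when `config$out_dir` is set.
#'
#' @param config A [pipeline_config()] with `peaks` and `control` set
#'   (paths, or data frames passed directly).
#' @return List: `profiles`, `dendrogram` (`class_dendrogram`; `NULL` when
#'   `k == 1` or fewer than 3 profiles), `classes`, `silhouette`.
#' @export
run_specificity <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  peaks <- stage("read_peaks", {
    if (is.data.frame(config$peaks)) config$peaks else read.csv(config$peaks)
  })
  if (nrow(peaks) == 0L) stop("stage 'read_peaks': empty peak table")
  ctl_df <- stage("read_control", {
    if (is.data.frame(config$control)) config$control
    else read.csv(config$control)
  })
  control <- setNames(ctl_df$nmol_per_mL, ctl_df$species)
  standards <- internal_standard_set()
  profiles <- stage("quantify", {
    lapply(split(peaks, peaks$enzyme), function(tab) {
      conc <- quantify(tab[, c("species", "area")], standards)
      net <- background_subtract(conc, control)
      compose_profile(net, tab$enzyme[1])
    })
  })
  profiles <- profiles[order(names(profiles))]
  X <- profiles_matrix(profiles)
  dend <- NULL
  if (config$k > 1L && nrow(X) >= 3L) {
    dend <- stage("cluster", multiscale_bootstrap(
      X, replicates = config$clustering_replicates, seed = config$seed))
    classes <- stage("cut", cut_classes(dend, k = config$k))
    sil <- silhouette_diagnostics(dend, euclidean_distances(X))
  } else {
    classes <- setNames(rep(1L, nrow(X)), rownames(X))
    sil <- NULL
  }
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    write_profiles_csv(profiles, file.path(config$out_dir, "profiles.csv"),
                       file.path(config$out_dir, "totals.csv"))
    if (!is.null(dend))
      write_class_dendrogram(dend, file.path(config$out_dir, "dendrogram.nwk"))
    write.table(data.frame(enzyme = names(classes), class = classes),
                file.path(config$out_dir, "classes.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    diag <- list(k = config$k,
                 silhouette = as.list(sil),
                 au = if (!is.null(dend)) dend$au else NULL,
                 bp = if (!is.null(dend)) dend$bp1 else NULL)
    jsonlite::write_json(diag, file.path(config$out_dir, "class_diagnostics.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
    write_manifest(config, file.path(config$out_dir, "manifest_specificity.json"),
                   extra = list(n_enzymes = nrow(X)))
  }
  list(profiles = profiles, dendrogram = dend, classes = classes,
       silhouette = sil)
}
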