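# In vivo activity quantitation: internal-standard concentration assignment,
# control-strain background subtraction, totals, and mol% composition.

# 2-alkanone methylketone names -> carbon count
MK_CARBONS <- c(
  "2-nonanone" = 9, "2-decanone" = 10, "2-undecanone" = 11,
  "2-dodecanone" = 12, "2-tridecanone" = 13, "2-tetradecanone" = 14,
  "2-pentadecanone" = 15, "2-hexadecanone" = 16, "2-heptadecanone" = 17)

is_fatty_acid <- function(species) grepl("^\\d+:\\d+$", species)

#' Carbon number of an analyte species
#'
#' Fatty acids are written `carbons:double-bonds` (e.g. `"8:0"`, `"16:1"`);
#' methylketones by their 2-alkanone name (e.g. `"2-tridecanone"`).
#'
#' @param species Character vector of analyte names.
#' @return Integer vector of carbon counts.
#' @export
carbon_number <- function(species) {
  out <- rep(NA_integer_, length(species))
  fa <- is_fatty_acid(species)
  out[fa] <- as.integer(sub(":.*$", "", species[fa]))
  mk <- match(tolower(species), names(MK_CARBONS))
  out[!fa & !is.na(mk)] <- as.integer(MK_CARBONS[mk[!fa & !is.na(mk)]])
  if (anyNA(out))
    stop("unparseable analyte species: ",
         paste(species[is.na(out)], collapse = ", "))
  out
}

#' Internal standard set for fatty-acid quantitation
#'
#' Defaults follow the assay: 10 ug heptanoic acid (7:0), 10 ug undecanoic
#' acid (11:0) and 20 ug heptadecanoic acid (17:0) spiked into 2 mL of
#' culture supernatant. Concentrations are derived as
#' `mass / MW * 1000 / volume` nmol/mL.
#'
#' @param mass_ug Named vector of spiked masses (ug) per standard species.
#' @param mw Named vector of molecular weights (g/mol).
#' @param volume_ml Sample volume (mL).
#' @return Object of class `internal_standard_set` with derived
#'   `conc_nmol_ml`.
#' @export
internal_standard_set <- function(
    mass_ug = c("7:0" = 10, "11:0" = 10, "17:0" = 20),
    mw = c("7:0" = 130.185, "11:0" = 186.291, "17:0" = 270.451),
    volume_ml = 2) {
  stopifnot(all(mass_ug > 0), all(mw > 0), volume_ml > 0,
            setequal(names(mass_ug), names(mw)))
  mw <- mw[names(mass_ug)]
  conc <- mass_ug / mw * 1000 / volume_ml  # ug / (g/mol) = umol; *1000 = nmol
  structure(list(species = names(mass_ug), mass_ug = mass_ug, mw = mw,
                 volume_ml = volume_ml, conc_nmol_ml = conc),
            class = "internal_standard_set")
}

# chain-length -> internal standard species. C4-C9 -> 7:0, C10-C12 -> 11:0,
# >= C13 -> 17:0 (C9, unassigned by the assay's stated ranges, maps to 7:0).
assign_standard <- function(carbons) {
  ifelse(carbons <= 9, "7:0", ifelse(carbons <= 12, "11:0", "17:0"))
}

#' Quantify analyte peaks against internal standards
#'
#' Each analyte concentration is
#' `area_analyte / area_IS * response_factor * conc_IS` where the internal
#' standard is assigned by carbon number (<= 9 -> 7:0, 10-12 -> 11:0,
#' >= 13 -> 17:0; methylketones by their carbon count). The standards'
#' own peaks are consumed as references and excluded from the output.
#'
#' @param peaks Data frame with columns `species` and `area` (detector
#'   response, >= 0).
#' @param standards An [internal_standard_set()].
#' @param response_factors Optional named vector of per-species molar
#'   response factors (default 1 for all).
#' @return Named numeric vector: species -> nmol/mL.
#' @export
quantify <- function(peaks, standards = internal_standard_set(),
                     response_factors = NULL) {
  stopifnot(is.data.frame(peaks), all(c("species", "area") %in% names(peaks)))
  if (any(peaks$area < 0)) stop("peak areas must be >= 0")
  is_rows <- match(standards$species, peaks$species)
  if (anyNA(is_rows))
    stop("missing internal standard peak(s): ",
         paste(standards$species[is.na(is_rows)], collapse = ", "))
  is_area <- setNames(peaks$area[is_rows], standards$species)
  if (any(is_area == 0))
    stop("zero internal standard area: ",
         paste(standards$species[is_area == 0], collapse = ", "))
  analytes <- peaks[!(peaks$species %in% standards$species), , drop = FALSE]
  if (nrow(analytes) == 0L) return(setNames(numeric(0), character(0)))
  rf <- rep(1, nrow(analytes))
  if (!is.null(response_factors)) {
    hit <- match(analytes$species, names(response_factors))
    rf[!is.na(hit)] <- response_factors[hit[!is.na(hit)]]
  }
  std <- assign_standard(carbon_number(analytes$species))
  conc <- analytes$area / is_area[std] * rf * standards$conc_nmol_ml[std]
  setNames(as.numeric(conc), analytes$species)
}

#' Subtract control-strain background
#'
#' Net production is `max(sample - control, 0)` per species over the union
#' of the two species universes (missing = 0). Species clamped at zero are
#' recorded in attribute `"clamped"`.
#'
#' @param sample,control Named numeric vectors (species -> nmol/mL).
#' @return Named numeric net vector with attribute `clamped`.
#' @export
background_subtract <- function(sample, control) {
  universe <- union(names(sample), names(control))
  s <- setNames(rep(0, length(universe)), universe)
  s[names(sample)] <- sample
  ctl <- setNames(rep(0, length(universe)), universe)
  ctl[names(control)] <- control
  raw <- s - ctl
  net <- pmax(raw, 0)
  attr(net, "clamped") <- universe[raw < 0]
  net
}

#' Compose a substrate-specificity profile
#'
#' Fatty-acid mol% is the net concentration of each fatty-acid species as a
#' percentage of the total fatty acids produced; methylketone production is
#' likewise expressed relative to the fatty-acid total (excluded from the
#' mol% denominator).
#'
#' @param net Named numeric vector of net concentrations (nmol/mL).
#' @param enzyme Enzyme identifier.
#' @return Object of class `specificity_profile`: `enzyme`,
#'   `net_concentration`, `mol_percent` (fatty acids; sums to 100),
#'   `total_fa` (nmol/mL), `methylketone_molpct`.
#' @export
compose_profile <- function(net, enzyme) {
  fa <- is_fatty_acid(names(net))
  total_fa <- sum(net[fa])
  if (total_fa <= 0) stop("no activity above background for ", enzyme)
  molpct <- 100 * net[fa] / total_fa
  mk <- 100 * net[!fa] / total_fa
  sort_by_name <- function(x) {
    if (!length(x)) return(setNames(numeric(0), character(0)))
    x[order(names(x))]
  }
  net_plain <- setNames(as.numeric(net), names(net))
  structure(list(enzyme = enzyme,
                 net_concentration = sort_by_name(net_plain),
                 mol_percent = sort_by_name(molpct),
                 total_fa = total_fa,
                 methylketone_molpct = sort_by_name(mk)),
            class = "specificity_profile")
}

#' @export
print.specificity_profile <- function(x, ...) {
  cat("Specificity profile for ", x$enzyme, ": total FA ",
      format(x$total_fa, digits = 4), " nmol/mL\n", sep = "")
  top <- sort(x$mol_percent, decreasing = TRUE)
  top <- top[top >= 1]
  cat("  mol%:", paste(sprintf("%s %.1f", names(top), top), collapse = ", "),
      "\n")
  invisible(x)
}

#' Matrix of mol% compositions across profiles
#'
#' @param profiles List of `specificity_profile`s.
#' @return Numeric matrix, enzymes in rows, fatty-acid species in columns
#'   (union universe; missing = 0).
#' @export
profiles_matrix <- function(profiles) {
  stopifnot(length(profiles) >= 1L)
  sp <- sort(unique(unlist(lapply(profiles, function(p) names(p$mol_percent)))))
  m <- t(vapply(profiles, function(p) {
    v <- setNames(rep(0, length(sp)), sp)
    v[names(p$mol_percent)] <- p$mol_percent
    v
  }, numeric(length(sp))))
  rownames(m) <- vapply(profiles, function(p) p$enzyme, character(1))
  m
}

#' Write specificity profiles to CSV
#'
#' Long format: `enzyme, species, net_nmol_per_mL, mol_pct` (mol_pct `NA`
#' for methylketones).
#'
#' @param profiles List of `specificity_profile`s.
#' @param path Output path.
#' @param totals_path Optional path for a per-enzyme totals CSV.
#' @return `path`, invisibly.
#' @export
write_profiles_csv <- function(profiles, path, totals_path = NULL) {
  rows <- do.call(rbind, lapply(profiles, function(p) {
    sp <- names(p$net_concentration)
    data.frame(enzyme = p$enzyme, species = sp,
               net_nmol_per_mL = as.numeric(p$net_concentration),
               mol_pct = ifelse(is_fatty_acid(sp),
                                100 * p$net_concentration /
                                  p$total_fa, NA_real_))
  }))
  write.table(rows, path, sep = ",", quote = FALSE, row.names = FALSE)
  if (!is.null(totals_path)) {
    tot <- data.frame(
      enzyme = vapply(profiles, function(p) p$enzyme, character(1)),
      total_fa_nmol_per_mL = vapply(profiles, function(p) p$total_fa, numeric(1)))
    write.table(tot, totals_path, sep = ",", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
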