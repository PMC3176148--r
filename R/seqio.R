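AMINO_ACIDS <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                 "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

# Ambiguity/unknown codes retained on read, treated as missing downstream
# (consistent with pairwise deletion of gaps).
AA_MISSING <- c("-", ".", "B", "Z", "X", "J", "U", "O", "*")

#' Construct an aligned protein set
#'
#' Container for a protein multiple sequence alignment plus per-sequence
#' species metadata. All downstream evolutionary distances are computed over
#' this universe of sequences.
#'
#' @param ids Character vector of unique sequence identifiers.
#' @param species Character vector of species/taxon labels, same length.
#' @param sequences Character vector of aligned sequences (equal lengths;
#'   the 20 amino-acid letters plus gap `-` and ambiguity codes).
#' @return An object of class `aligned_protein_set` with elements `ids`,
#'   `species`, `sequences` and `length` (alignment columns).
#' @export
aligned_protein_set <- function(ids, species, sequences) {
  ids <- as.character(ids)
  species <- as.character(species)
  sequences <- toupper(as.character(sequences))
  if (length(ids) == 0L) stop("alignment is empty")
  if (length(species) != length(ids) || length(sequences) != length(ids))
    stop("ids, species and sequences must have equal length")
  if (anyDuplicated(ids))
    stop("duplicate sequence id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  widths <- nchar(sequences)
  if (widths[1] < 1L) stop("alignment length must be >= 1")
  if (length(unique(widths)) != 1L) {
    bad <- ids[widths != widths[1]]
    stop("ragged alignment: sequence(s) ", paste(bad, collapse = ", "),
         " differ in length from ", ids[1])
  }
  known <- c(AMINO_ACIDS, AA_MISSING)
  letters_used <- unique(strsplit(paste(sequences, collapse = ""), "")[[1]])
  unknown <- setdiff(letters_used, known)
  if (length(unknown))
    stop("unknown alignment character(s): ", paste(unknown, collapse = ", "))
  structure(list(ids = ids, species = species, sequences = sequences,
                 length = widths[1]),
            class = "aligned_protein_set")
}

#' @export
print.aligned_protein_set <- function(x, ...) {
  cat("Aligned protein set: ", length(x$ids), " sequences, ",
      x$length, " columns\n", sep = "")
  invisible(x)
}

#' @export
length.aligned_protein_set <- function(x) length(x$ids)

#' Convert an alignment to a character matrix
#'
#' @param x An `aligned_protein_set`.
#' @param ... Unused.
#' @return Character matrix (sequences in rows, columns are alignment sites),
#'   rownames are sequence ids.
#' @method as.matrix aligned_protein_set
#' @export
as.matrix.aligned_protein_set <- function(x, ...) {
  m <- do.call(rbind, strsplit(x$sequences, ""))
  rownames(m) <- x$ids
  m
}

# Integer encoding: 1..20 for canonical residues, NA for gap/ambiguity.
aln_encode <- function(aln) {
  m <- as.matrix(aln)
  enc <- match(m, AMINO_ACIDS)
  dim(enc) <- dim(m)
  rownames(enc) <- rownames(m)
  enc
}

#' Read a protein multiple sequence alignment from FASTA
#'
#' Species labels are parsed from the FASTA header: text after the first
#' `|` separator (default) or, if absent, the whole header is used as both
#' id and species.
#'
#' @param path Path to a FASTA file.
#' @param species_sep Header token separating id from species (default `"|"`).
#' @return An [aligned_protein_set()].
#' @export
read_msa <- function(path, species_sep = "|") {
  ss <- Biostrings::readAAStringSet(path)
  if (length(ss) == 0L) stop("empty FASTA file: ", path)
  headers <- trimws(names(ss))
  parts <- strsplit(headers, species_sep, fixed = TRUE)
  ids <- vapply(parts, function(p) trimws(p[1]), character(1))
  species <- vapply(parts, function(p) {
    if (length(p) >= 2L) trimws(paste(p[-1], collapse = species_sep)) else trimws(p[1])
  }, character(1))
  aligned_protein_set(ids, species, as.character(ss))
}

#' Write an alignment to FASTA
#'
#' Headers are written as `id|species` so that [read_msa()] round-trips
#' losslessly (when `species == id` only the id is written).
#'
#' @param aln An `aligned_protein_set`.
#' @param path Output file path.
#' @param species_sep Separator used in headers.
#' @return `path`, invisibly.
#' @export
write_msa <- function(aln, path, species_sep = "|") {
  hdr <- ifelse(aln$species == aln$ids, aln$ids,
                paste(aln$ids, aln$species, sep = species_sep))
  ss <- Biostrings::AAStringSet(aln$sequences)
  names(ss) <- hdr
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Cleave a plastid transit peptide at a conserved motif
#'
#' Plant acyl-ACP thioesterases carry an N-terminal plastid-targeting
#' extension; the mature protein is inferred to start at the conserved
#' `LPDW` motif (the motif's leucine is the putative mature N-terminus).
#' The suffix starting at the first occurrence of the motif is returned.
#'
#' @param sequence Protein sequence (single string).
#' @param motif Cleavage anchor motif (default `"LPDW"`).
#' @return The mature protein string, or `NA_character_` with attribute
#'   `reason = "no cleavage site"` when the motif is absent (never a silent
#'   truncation).
#' @export
cleave_transit_peptide <- function(sequence, motif = "LPDW") {
  stopifnot(is.character(sequence), length(sequence) == 1L, nchar(sequence) > 0L)
  pos <- regexpr(motif, sequence, fixed = TRUE)
  if (pos < 0L)
    return(structure(NA_character_, reason = "no cleavage site"))
  substring(sequence, pos)
}

# Average and monoisotopic residue masses (Da); water added once per chain.
AA_MASS_AVERAGE <- c(
  A = 71.0788, R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  Q = 128.1307, E = 129.1155, G = 57.0519, H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
  S = 87.0782, T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326)
AA_MASS_MONO <- c(
  A = 71.03711, R = 156.10111, N = 114.04293, D = 115.02694, C = 103.00919,
  Q = 128.05858, E = 129.04259, G = 57.02146, H = 137.05891, I = 113.08406,
  L = 113.08406, K = 128.09496, M = 131.04049, F = 147.06841, P = 97.05276,
  S = 87.03203, T = 101.04768, W = 186.07931, Y = 163.06333, V = 99.06841)
WATER_AVERAGE <- 18.0153
WATER_MONO <- 18.010565

#' Bjellqvist pKa set
#'
#' Default ionizable-group pKa values used for theoretical pI calculation.
#' Entries `Cterm`/`Nterm` are the chain termini; the remainder are side
#' chains. Any named list/vector with the same names can be substituted.
#'
#' @return Named numeric vector of pKa values.
#' @export
pka_bjellqvist <- function() {
  c(Cterm = 3.55, Nterm = 7.50,
    D = 4.05, E = 4.45, H = 5.98, C = 9.00, Y = 10.00, K = 10.00, R = 12.00)
}

# Net charge of a protein at a given pH under the Henderson-Hasselbalch model.
protein_net_charge <- function(counts, pka, pH) {
  pos_groups <- c(Nterm = 1, counts[c("K", "R", "H")])
  names(pos_groups) <- c("Nterm", "K", "R", "H")
  neg_groups <- c(Cterm = 1, counts[c("D", "E", "C", "Y")])
  names(neg_groups) <- c("Cterm", "D", "E", "C", "Y")
  pos <- sum(pos_groups / (1 + 10^(pH - pka[names(pos_groups)])))
  neg <- sum(neg_groups / (1 + 10^(pka[names(neg_groups)] - pH)))
  pos - neg
}

#' Molecular weight and theoretical isoelectric point of a protein
#'
#' MW is the sum of residue masses (average by default, monoisotopic
#' optionally) plus one water. pI is the pH at which the net charge of the
#' Henderson-Hasselbalch charge model crosses zero, solved by bisection on
#' \[0, 14\] to 1e-4 pH units.
#'
#' @param sequence Protein sequence over the 20 canonical residues.
#' @param pka_set Named pKa vector, default [pka_bjellqvist()].
#' @param mass One of `"average"` (default) or `"monoisotopic"`.
#' @return A list of class `protein_properties`: `length` (residues),
#'   `molecular_weight` (Da) and `isoelectric_point` (pH units).
#' @export
protein_properties <- function(sequence, pka_set = pka_bjellqvist(),
                               mass = c("average", "monoisotopic")) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  if (nchar(sequence) == 0L) stop("empty sequence")
  mass <- match.arg(mass)
  res <- strsplit(toupper(sequence), "")[[1]]
  bad <- setdiff(unique(res), AMINO_ACIDS)
  if (length(bad))
    stop("non-canonical residue(s): ", paste(bad, collapse = ", "))
  tab <- if (mass == "average") AA_MASS_AVERAGE else AA_MASS_MONO
  water <- if (mass == "average") WATER_AVERAGE else WATER_MONO
  mw <- sum(tab[res]) + water
  counts <- vapply(AMINO_ACIDS, function(a) sum(res == a), numeric(1))
  lo <- 0; hi <- 14
  f_lo <- protein_net_charge(counts, pka_set, lo)
  f_hi <- protein_net_charge(counts, pka_set, hi)
  if (f_lo <= 0) {
    pi_val <- 0
  } else if (f_hi >= 0) {
    pi_val <- 14
  } else {
    while (hi - lo > 1e-4) {
      mid <- (lo + hi) / 2
      if (protein_net_charge(counts, pka_set, mid) > 0) lo <- mid else hi <- mid
    }
    pi_val <- (lo + hi) / 2
  }
  structure(list(length = length(res), molecular_weight = unname(mw),
                 isoelectric_point = pi_val),
            class = "protein_properties")
}

#' @export
print.protein_properties <- function(x, ...) {
  cat(sprintf("Protein: %d residues, MW %.2f Da, pI %.2f\n",
              x$length, x$molecular_weight, x$isoelectric_point))
  invisible(x)
}
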