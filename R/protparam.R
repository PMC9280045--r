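# Protein physicochemical profile: molecular weight, theoretical pI,
# instability index, aliphatic index and GRAVY, computed the way the
# ExPASy-style protein parameter tools define them.

.check_protein <- function(seq, allow_x = FALSE) {
  seq <- toupper(as.character(seq))
  if (length(seq) != 1L || !nzchar(seq)) stop("empty protein sequence")
  chars <- strsplit(seq, "")[[1]]
  allowed <- names(.residue_mass)
  if (allow_x) allowed <- c(allowed, "X")
  bad <- setdiff(unique(chars), allowed)
  if (length(bad)) stop("non-standard residue: ", bad[1L])
  chars
}

#' Default pKa set for charge and pI calculations
#'
#' A Bjellqvist-style set (as used in the ExPASy lineage of pI tools):
#' terminal and side-chain pKa values for D, E, C, Y, H, K, R. Cysteine is
#' treated as ionizable (reduced form).
#'
#' @return A list with `name`, `n_terminus`, `c_terminus` and `side_chains`.
#' @export
default_pka <- function() .default_pka

#' Protein molecular weight
#'
#' Sum of average residue masses plus one water (18.01524 Da).
#'
#' @param protein A protein sequence (standard 20 residues).
#' @return Molecular weight in Da.
#' @export
molecular_weight <- function(protein) {
  chars <- .check_protein(protein)
  sum(.residue_mass[chars]) + .water_mass
}

#' Net charge of a protein at a given pH
#'
#' Henderson-Hasselbalch sum: positive groups (N-terminus, H, K, R)
#' contribute 1/(1+10^(pH-pKa)); negative groups (C-terminus, D, E, C, Y)
#' contribute -1/(1+10^(pKa-pH)). Strictly decreasing in pH.
#'
#' @param protein A protein sequence.
#' @param pH pH value in [0, 14].
#' @param pka A pKa set (see [default_pka()]).
#' @return Signed net charge.
#' @export
net_charge <- function(protein, pH, pka = default_pka()) {
  chars <- .check_protein(protein, allow_x = TRUE)
  counts <- table(factor(chars, levels = c("D", "E", "C", "Y", "H", "K", "R")))
  pos_pka <- c(pka$n_terminus,
               rep(pka$side_chains[["H"]], counts[["H"]]),
               rep(pka$side_chains[["K"]], counts[["K"]]),
               rep(pka$side_chains[["R"]], counts[["R"]]))
  neg_pka <- c(pka$c_terminus,
               rep(pka$side_chains[["D"]], counts[["D"]]),
               rep(pka$side_chains[["E"]], counts[["E"]]),
               rep(pka$side_chains[["C"]], counts[["C"]]),
               rep(pka$side_chains[["Y"]], counts[["Y"]]))
  sum(1 / (1 + 10^(pH - pos_pka))) - sum(1 / (1 + 10^(neg_pka - pH)))
}

#' Theoretical isoelectric point
#'
#' Bisection root of [net_charge()] on [0, 14]; the root exists and is
#' unique because the net charge is strictly decreasing in pH with a sign
#' change over the interval.
#'
#' @param protein A protein sequence.
#' @param pka A pKa set.
#' @param tol Bisection tolerance in pH units.
#' @return The pI.
#' @export
isoelectric_point <- function(protein, pka = default_pka(), tol = 1e-3) {
  lo <- 0
  hi <- 14
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (net_charge(protein, mid, pka) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Instability index
#'
#' Guruprasad dipeptide-weight statistic: II = (10/L) * sum of DIWV over
#' consecutive residue pairs. Proteins with II < 40 are classed stable;
#' the boundary value 40 is unstable.
#'
#' @param protein A protein sequence of length >= 2.
#' @param diwv 20x20 dipeptide weight matrix (rows: first residue).
#' @return II, with the stability class in attribute `"class"`.
#' @export
instability_index <- function(protein, diwv = .diwv) {
  chars <- .check_protein(protein)
  L <- length(chars)
  if (L < 2L) stop("instability index requires length >= 2")
  ii <- 10 / L * sum(diwv[cbind(chars[-L], chars[-1L])])
  attr(ii, "class") <- if (ii < 40) "stable" else "unstable"
  ii
}

#' Aliphatic index
#'
#' AI = X_Ala + 2.9 X_Val + 3.9 (X_Ile + X_Leu) with X in mole percent.
#'
#' @param protein A protein sequence.
#' @return The aliphatic index.
#' @export
aliphatic_index <- function(protein) {
  chars <- .check_protein(protein)
  x <- 100 * table(factor(chars, levels = c("A", "V", "I", "L"))) /
    length(chars)
  unname(x[["A"]] + 2.9 * x[["V"]] + 3.9 * (x[["I"]] + x[["L"]]))
}

#' Grand average of hydropathy (GRAVY)
#'
#' Arithmetic mean of per-residue Kyte-Doolittle hydropathy values;
#' negative values indicate hydrophilic proteins.
#'
#' @param protein A protein sequence.
#' @param kd_table Named hydropathy values for the 20 residues.
#' @return Mean hydropathy.
#' @export
gravy <- function(protein, kd_table = .kyte_doolittle) {
  chars <- .check_protein(protein)
  mean(kd_table[chars])
}

#' Full physicochemical profile of one protein
#'
#' @param protein A protein sequence.
#' @param pka A pKa set for the pI.
#' @return A one-row data frame: `length`, `mw`, `pi`, `instability`,
#'   `stability_class`, `aliphatic`, `gravy`.
#' @export
phys_chem_profile <- function(protein, pka = default_pka()) {
  ii <- instability_index(protein)
  data.frame(length = length(.check_protein(protein)),
             mw = molecular_weight(protein),
             pi = isoelectric_point(protein, pka),
             instability = as.numeric(ii),
             stability_class = attr(ii, "class"),
             aliphatic = aliphatic_index(protein),
             gravy = gravy(protein),
             stringsAsFactors = FALSE)
}

#' Physicochemical profiles for a protein family
#'
#' @param records A `seq_records` (protein) object.
#' @param pka A pKa set.
#' @return A data frame with one row per record, id column first.
#' @export
phys_chem_profiles <- function(records, pka = default_pka()) {
  rows <- lapply(seq_len(nrow(records)), function(i)
    cbind(data.frame(id = records$id[i], stringsAsFactors = FALSE),
          phys_chem_profile(records$residues[i], pka)))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
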