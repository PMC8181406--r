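# Residue dictionaries, radii and property tables.
# All tables are package constants; user-facing functions take them as
# arguments so any entry can be overridden.

PROTEIN_3TO1 <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
  GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
  LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
  SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V")

PROTEIN_1TO3 <- structure(names(PROTEIN_3TO1), names = unname(PROTEIN_3TO1))

# residue names treated as protein but outside the standard 20
NONSTANDARD_PROTEIN <- c("MSE", "SEC", "PYL", "UNK")

RNA_RESIDUES <- c("A", "C", "G", "U", "I", "N")

#' Classify a residue name as protein, RNA or other
#'
#' @param resid character vector of 3-letter amino-acid or nucleotide codes.
#' @return character vector over `"protein"`, `"rna"`, `"other"`.
#' @export
residueKind <- function(resid) {
  r <- toupper(trimws(resid))
  out <- rep("other", length(r))
  out[r %in% c(names(PROTEIN_3TO1), NONSTANDARD_PROTEIN)] <- "protein"
  out[r %in% RNA_RESIDUES] <- "rna"
  out
}

#' Van der Waals radii by element (Angstrom)
#'
#' Bondi-style element radii used by the Shrake-Rupley SASA computation.
#' @return named numeric vector.
#' @export
vdwRadii <- function() {
  c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80,
    P = 1.80, SE = 1.90, F = 1.47, CL = 1.75, BR = 1.85,
    I = 1.98, MG = 1.73, ZN = 1.39, FE = 1.40, K = 2.75, "NA" = 2.27)
}

#' Maximum per-residue SASA in an extended Gly-X-Gly context (Angstrom^2)
#'
#' Theoretical maxima of Tien et al. (2013), used to normalise residue SASA
#' into relative SASA (rSASA).
#' @return named numeric vector over one-letter amino-acid codes.
#' @export
maxSasaTable <- function() {
  c(A = 129.0, R = 274.0, N = 195.0, D = 193.0, C = 167.0,
    Q = 225.0, E = 223.0, G = 104.0, H = 224.0, I = 197.0,
    L = 201.0, K = 236.0, M = 224.0, F = 240.0, P = 159.0,
    S = 155.0, T = 172.0, W = 285.0, Y = 263.0, V = 174.0)
}

BLOSUM62_AA <- strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]

BLOSUM62_MATRIX <- matrix(as.integer(c(
  4, -1, -2, -2, 0, -1, -1, 0, -2, -1, -1, -1, -1, -2, -1, 1, 0, -3, -2, 0,
  -1, 5, 0, -2, -3, 1, 0, -2, 0, -3, -2, 2, -1, -3, -2, -1, -1, -3, -2, -3,
  -2, 0, 6, 1, -3, 0, 0, 0, 1, -3, -3, 0, -2, -3, -2, 1, 0, -4, -2, -3,
  -2, -2, 1, 6, -3, 0, 2, -1, -1, -3, -4, -1, -3, -3, -1, 0, -1, -4, -3, -3,
  0, -3, -3, -3, 9, -3, -4, -3, -3, -1, -1, -3, -1, -2, -3, -1, -1, -2, -2, -1,
  -1, 1, 0, 0, -3, 5, 2, -2, 0, -3, -2, 1, 0, -3, -1, 0, -1, -2, -1, -2,
  -1, 0, 0, 2, -4, 2, 5, -2, 0, -3, -3, 1, -2, -3, -1, 0, -1, -3, -2, -2,
  0, -2, 0, -1, -3, -2, -2, 6, -2, -4, -4, -2, -3, -3, -2, 0, -2, -2, -3, -3,
  -2, 0, 1, -1, -3, 0, 0, -2, 8, -3, -3, -1, -2, -1, -2, -1, -2, -2, 2, -3,
  -1, -3, -3, -3, -1, -3, -3, -4, -3, 4, 2, -3, 1, 0, -3, -2, -1, -3, -1, 3,
  -1, -2, -3, -4, -1, -2, -3, -4, -3, 2, 4, -2, 2, 0, -3, -2, -1, -2, -1, 1,
  -1, 2, 0, -1, -3, 1, 1, -2, -1, -3, -2, 5, -1, -3, -1, 0, -1, -3, -2, -2,
  -1, -1, -2, -3, -1, 0, -2, -3, -2, 1, 2, -1, 5, 0, -2, -1, -1, -1, -1, 1,
  -2, -3, -3, -3, -2, -3, -3, -3, -1, 0, 0, -3, 0, 6, -4, -2, -2, 1, 3, -1,
  -1, -2, -2, -1, -3, -1, -1, -2, -2, -3, -3, -1, -2, -4, 7, -1, -1, -4, -3, -2,
  1, -1, 1, 0, -1, 0, 0, 0, -1, -2, -2, 0, -1, -2, -1, 4, 1, -3, -2, -2,
  0, -1, 0, -1, -1, -1, -1, -2, -2, -1, -1, -1, -1, -2, -1, 1, 5, -2, -2, 0,
  -3, -3, -4, -4, -2, -2, -3, -2, -2, -3, -2, -3, -1, 1, -4, -3, -2, 11, 2, -3,
  -2, -2, -2, -3, -2, -1, -2, -3, 2, -1, -1, -2, -1, 3, -3, -2, -2, 2, 7, -1,
  0, -3, -3, -3, -1, -2, -2, -3, -3, 3, 1, -2, 1, -1, -2, -2, 0, -3, -1, 4)),
  nrow = 20, byrow = TRUE, dimnames = list(BLOSUM62_AA, BLOSUM62_AA))

#' Residue property tables
#'
#' All per-residue scales used by the delta features and the rule engine:
#' * `volume`: Zamyatnin residue volumes (Angstrom^3; Gly 60.1, Arg 173.4,
#'   Glu 138.4, ...).
#' * `hydrophobicity`: Kyte-Doolittle scale (configurable; replace the
#'   vector to use another scale).
#' * `formal_charge`: side-chain formal charge at neutral pH
#'   (K/R +1, D/E -1, His `his_charge`, default +0.5, else 0).
#' * `helix_propensity`: Pace-Scholtz helix propensities (kcal/mol; lower
#'   means stronger helix former; Pro 3.16 is the helix breaker).
#' * `disorder_propensity`: TOP-IDP-style disorder propensities (higher
#'   means more disorder-promoting).
#' * `blosum62`: the standard 20x20 BLOSUM62 substitution matrix.
#'
#' @param his_charge formal charge assigned to histidine (default 0.5).
#' @return named list of tables.
#' @export
propertyTables <- function(his_charge = 0.5) {
  volume <- c(A = 88.6, R = 173.4, N = 114.1, D = 111.1, C = 108.5,
              Q = 143.8, E = 138.4, G = 60.1, H = 153.2, I = 166.7,
              L = 166.7, K = 168.6, M = 162.9, F = 189.9, P = 112.7,
              S = 89.0, T = 116.1, W = 227.8, Y = 193.6, V = 140.0)
  hydrophobicity <- c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5,
                      Q = -3.5, E = -3.5, G = -0.4, H = -3.2, I = 4.5,
                      L = 3.8, K = -3.9, M = 1.9, F = 2.8, P = -1.6,
                      S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2)
  formal_charge <- c(A = 0, R = 1, N = 0, D = -1, C = 0,
                     Q = 0, E = -1, G = 0, H = his_charge, I = 0,
                     L = 0, K = 1, M = 0, F = 0, P = 0,
                     S = 0, T = 0, W = 0, Y = 0, V = 0)
  helix_propensity <- c(A = 0.00, L = 0.21, R = 0.21, M = 0.24, K = 0.26,
                        Q = 0.39, E = 0.40, I = 0.41, W = 0.49, S = 0.50,
                        Y = 0.53, F = 0.54, H = 0.61, V = 0.61, N = 0.65,
                        T = 0.66, C = 0.68, D = 0.69, G = 1.00, P = 3.16)
  disorder_propensity <- c(W = -0.884, F = -0.697, Y = -0.510, I = -0.486,
                           M = -0.397, L = -0.326, V = -0.121, N = 0.007,
                           C = 0.020, T = 0.059, A = 0.060, G = 0.166,
                           R = 0.180, D = 0.192, H = 0.303, Q = 0.318,
                           S = 0.341, K = 0.586, E = 0.736, P = 0.987)
  list(volume = volume,
       hydrophobicity = hydrophobicity,
       formal_charge = formal_charge,
       helix_propensity = helix_propensity[BLOSUM62_AA],
       disorder_propensity = disorder_propensity[BLOSUM62_AA],
       blosum62 = BLOSUM62_MATRIX)
}

# ---- hydrogen-bond donor/acceptor typing (heavy atoms) -------------------

# per residue: named character vectors of side-chain atom roles;
# backbone handled generically (N donor, O/OXT acceptor for protein;
# phosphate/ribose oxygens for RNA).
HB_PROTEIN_SIDECHAIN <- list(
  SER = c(OG = "both"), THR = c(OG1 = "both"), TYR = c(OH = "both"),
  CYS = c(SG = "donor"),
  LYS = c(NZ = "donor"),
  ARG = c(NE = "donor", NH1 = "donor", NH2 = "donor"),
  HIS = c(ND1 = "both", NE2 = "both"),
  ASN = c(ND2 = "donor", OD1 = "acceptor"),
  GLN = c(NE2 = "donor", OE1 = "acceptor"),
  ASP = c(OD1 = "acceptor", OD2 = "acceptor"),
  GLU = c(OE1 = "acceptor", OE2 = "acceptor"),
  TRP = c(NE1 = "donor"),
  MET = c(SD = "acceptor"))

HB_RNA_COMMON <- c(OP1 = "acceptor", OP2 = "acceptor", O1P = "acceptor",
                   O2P = "acceptor", "O5'" = "acceptor", "O3'" = "acceptor",
                   "O4'" = "acceptor", "O2'" = "both")

HB_RNA_BASE <- list(
  A = c(N6 = "donor", N1 = "acceptor", N3 = "acceptor", N7 = "acceptor"),
  G = c(N1 = "donor", N2 = "donor", O6 = "acceptor", N3 = "acceptor",
        N7 = "acceptor"),
  C = c(N4 = "donor", O2 = "acceptor", N3 = "acceptor"),
  U = c(N3 = "donor", O2 = "acceptor", O4 = "acceptor"))

#' Hydrogen-bond roles for the heavy atoms of one residue type
#'
#' Standard donor/acceptor typing for protein and RNA residues; backbone
#' amide N is a donor and carbonyl O/OXT acceptors, phosphate and ribose
#' oxygens are acceptors with the 2'-OH both donor and acceptor.
#'
#' @param resid 3-letter residue (or 1-letter nucleotide) code.
#' @return named character vector atom name -> `"donor"`, `"acceptor"` or
#'   `"both"`; `NULL` for unknown residue names.
#' @export
hbondRoles <- function(resid) {
  r <- toupper(trimws(resid))
  if (r %in% c(names(PROTEIN_3TO1), NONSTANDARD_PROTEIN)) {
    roles <- c(N = "donor", O = "acceptor", OXT = "acceptor")
    sc <- HB_PROTEIN_SIDECHAIN[[r]]
    return(c(roles, sc))
  }
  if (r %in% names(HB_RNA_BASE)) {
    return(c(HB_RNA_COMMON, HB_RNA_BASE[[r]]))
  }
  NULL
}

# ---- interface patch definitions ----------------------------------------

#' Conserved interface patch definitions
#'
#' The five conserved, positively charged surface patches of RPS19 that
#' contact secondary-structure elements of 18S rRNA, as author-numbered
#' residue sets plus the contacted rRNA element and its nucleotide ranges.
#'
#' @return named list (I..V); each entry has `protein_residues` (integer
#'   vector), `rna_element` (character) and `rna_ranges` (2-column matrix of
#'   closed nucleotide intervals).
#' @export
patchDefinitions <- function() {
  list(
    I = list(protein_residues = c(37L, 38L, 39L, 43L, 44L, 45L),
             rna_element = "h42",
             rna_ranges = rbind(c(1603L, 1607L), c(1626L, 1629L))),
    II = list(protein_residues = c(47L, 52L, 55L, 56L, 59L, 62L, 63L, 67L,
                                   79L, 80L),
              rna_element = "h41",
              rna_ranges = rbind(c(1537L, 1543L), c(1583L, 1596L))),
    III = list(protein_residues = c(84L, 85L, 86L, 89L, 91L, 92L),
               rna_element = "h42+h43",
               rna_ranges = rbind(c(1653L, 1656L), c(1664L, 1666L))),
    IV = list(protein_residues = c(71L, 72L, 94L, 96L, 97L, 98L, 101L,
                                   102L, 105L, 120L, 121L),
              rna_element = "h41es10",
              rna_ranges = rbind(c(1561L, 1571L))),
    V = list(protein_residues = c(2L:9L, 65L, 129L, 132L, 135L),
             rna_element = "h39es9",
             rna_ranges = rbind(c(1414L, 1430L))))
}
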