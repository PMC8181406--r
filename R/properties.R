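# one-letter code normalisation shared by the delta operations
aa1 <- function(x) {
  x <- toupper(x)
  x[nchar(x) == 3] <- PROTEIN_3TO1[x[nchar(x) == 3]]
  if (anyNA(x) || !all(x %in% BLOSUM62_AA))
    stop("unknown amino acid: ", paste(unique(x[is.na(x) |
                                                !(x %in% BLOSUM62_AA)]),
                                       collapse = ", "))
  x
}

#' Signed percent volume change of a substitution
#'
#' `100 * (V_mut - V_wt) / V_wt` on the Zamyatnin residue volumes, e.g.
#' Gly (60.1 A^3) to Arg (173.4 A^3) is +188.52%.
#'
#' @param wt,mut wild-type and mutant residues (1- or 3-letter codes).
#' @param tables property tables from [propertyTables()].
#' @return signed percent (vectorised).
#' @export
volumeChangePct <- function(wt, mut, tables = propertyTables()) {
  v <- tables$volume
  unname(100 * (v[aa1(mut)] - v[aa1(wt)]) / v[aa1(wt)])
}

#' Signed percent hydrophobicity change of a substitution
#'
#' Percent change on the configured hydrophobicity scale (Kyte-Doolittle by
#' default).  The scale crosses zero, so the percent is taken against the
#' wild-type magnitude: `100 * (h_mut - h_wt) / |h_wt|`; a negative value
#' means the site gets less hydrophobic.
#'
#' @inheritParams volumeChangePct
#' @return signed percent (vectorised).
#' @export
hydrophobicityChangePct <- function(wt, mut, tables = propertyTables()) {
  h <- tables$hydrophobicity
  unname(100 * (h[aa1(mut)] - h[aa1(wt)]) / abs(h[aa1(wt)]))
}

#' Formal side-chain charge change of a substitution
#'
#' @inheritParams volumeChangePct
#' @return `formal_charge(mut) - formal_charge(wt)` (vectorised).
#' @export
chargeChange <- function(wt, mut, tables = propertyTables()) {
  q <- tables$formal_charge
  unname(q[aa1(mut)] - q[aa1(wt)])
}

#' Helix-propensity change of a substitution
#'
#' Difference on the Pace-Scholtz scale (kcal/mol; positive means the
#' mutant is a poorer helix former, with Pro the extreme).
#'
#' @inheritParams volumeChangePct
#' @export
helixPropensityChange <- function(wt, mut, tables = propertyTables()) {
  p <- tables$helix_propensity
  unname(p[aa1(mut)] - p[aa1(wt)])
}

#' Disorder-propensity change of a substitution
#'
#' Difference on a TOP-IDP-style scale (positive means more
#' disorder-promoting).
#'
#' @inheritParams volumeChangePct
#' @export
disorderPropensityChange <- function(wt, mut, tables = propertyTables()) {
  p <- tables$disorder_propensity
  unname(p[aa1(mut)] - p[aa1(wt)])
}

#' BLOSUM62 substitution score
#'
#' @inheritParams volumeChangePct
#' @return integer matrix lookup (symmetric in its arguments).
#' @export
blosumScore <- function(wt, mut, tables = propertyTables()) {
  m <- tables$blosum62
  unname(m[cbind(aa1(wt), aa1(mut))])
}
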