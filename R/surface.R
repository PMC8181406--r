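#' Deterministic golden-spiral points on the unit sphere
#'
#' @param n number of points.
#' @return n x 3 matrix of unit vectors.
#' @export
spherePoints <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  phi <- (seq_len(n) - 1) * pi * (3 - sqrt(5))
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(x = r * cos(phi), y = r * sin(phi), z = z)
}

#' Shrake-Rupley solvent-accessible surface area
#'
#' Rolls a spherical probe over each atom's van der Waals sphere using a
#' fixed, deterministic golden-spiral point set: per atom,
#' `SASA = (exposed points / n) * 4 * pi * (r_vdw + probe)^2`.
#'
#' @param model a [StructureModel-class].
#' @param probe probe radius in Angstrom (water, 1.4).
#' @param nPoints number of test points per atom (960 by default).
#' @param radii named vdW radius table, element symbol -> Angstrom.
#' @param unknownElement `"error"` to fail on an element missing from
#'   `radii`, `"default"` to use `defaultRadius` with a warning.
#' @param defaultRadius fallback radius (Angstrom).
#' @return a [SasaResult-class].
#' @examples
#' m <- makeToyComplex(nResidues = 5)
#' shrakeRupley(m)
#' @export
shrakeRupley <- function(model, probe = 1.4, nPoints = 960,
                         radii = vdwRadii(),
                         unknownElement = c("error", "default"),
                         defaultRadius = 1.70) {
  stopifnot(is(model, "StructureModel"), probe >= 0, nPoints >= 12)
  unknownElement <- match.arg(unknownElement)
  a <- model@atoms
  el <- toupper(a$elesy)
  r <- unname(radii[el])
  if (anyNA(r)) {
    missing <- unique(el[is.na(r)])
    if (unknownElement == "error")
      stop("no vdW radius for element(s): ", paste(missing, collapse = ", "))
    warning("using default radius ", defaultRadius, " A for element(s): ",
            paste(missing, collapse = ", "))
    r[is.na(r)] <- defaultRadius
  }
  xyz <- coords(model)
  n <- nrow(xyz)
  R <- r + probe                      # expanded radii
  pts <- spherePoints(nPoints)
  sasa <- numeric(n)
  maxR <- max(R)
  for (i in seq_len(n)) {
    d2 <- (xyz[, 1] - xyz[i, 1])^2 + (xyz[, 2] - xyz[i, 2])^2 +
          (xyz[, 3] - xyz[i, 3])^2
    nb <- which(d2 < (R[i] + maxR)^2 & d2 > 0)
    nb <- nb[d2[nb] < (R[i] + R[nb])^2]
    if (length(nb) == 0L) {
      sasa[i] <- 4 * pi * R[i]^2
      next
    }
    p <- pts * R[i]
    p[, 1] <- p[, 1] + xyz[i, 1]
    p[, 2] <- p[, 2] + xyz[i, 2]
    p[, 3] <- p[, 3] + xyz[i, 3]
    free <- rep(TRUE, nPoints)
    for (j in nb) {
      if (!any(free)) break
      dj2 <- (p[free, 1] - xyz[j, 1])^2 + (p[free, 2] - xyz[j, 2])^2 +
             (p[free, 3] - xyz[j, 3])^2
      keep <- dj2 > R[j]^2
      free[free] <- keep
    }
    sasa[i] <- sum(free) / nPoints * 4 * pi * R[i]^2
  }
  key <- paste(a$chain, a$resno, a$insert, sep = "\r")
  perRes <- rowsum(sasa, key, reorder = FALSE)
  idx <- !duplicated(key)
  perResidue <- data.frame(chain = a$chain[idx], resno = a$resno[idx],
                           insert = a$insert[idx], resid = a$resid[idx],
                           sasa = perRes[, 1], stringsAsFactors = FALSE)
  rownames(perResidue) <- NULL
  new("SasaResult", perAtom = sasa, perResidue = perResidue,
      probeRadius = probe, nSpherePoints = as.integer(nPoints))
}

#' Relative solvent-accessible surface area
#'
#' Divides a residue SASA by the residue's maximum SASA in an extended
#' Gly-X-Gly context.  Values slightly above 1 can occur and are kept
#' unless `clamp = TRUE`.
#'
#' @param residueSasa SASA in Angstrom^2 (vectorised).
#' @param residueName 1- or 3-letter amino-acid code (vectorised).
#' @param table named max-SASA table over one-letter codes.
#' @param clamp clamp results into [0, 1]?
#' @return unitless fraction(s).
#' @export
relativeSasa <- function(residueSasa, residueName, table = maxSasaTable(),
                         clamp = FALSE) {
  one <- toupper(residueName)
  long <- nchar(one) == 3
  one[long] <- PROTEIN_3TO1[one[long]]
  mx <- table[one]
  if (anyNA(mx))
    stop("no max-SASA entry for residue(s): ",
         paste(unique(residueName[is.na(mx)]), collapse = ", "))
  out <- unname(residueSasa / mx)
  if (clamp) out <- pmin(1, pmax(0, out))
  out
}

#' Per-residue rSASA profile of the protein residues of a model
#'
#' Convenience wrapper running [shrakeRupley()] and normalising each
#' standard protein residue by [relativeSasa()].
#'
#' @param model a [StructureModel-class] (typically a complex; rSASA is then
#'   in the packed context).
#' @param chainId restrict the report to this chain (SASA is still computed
#'   in the context of the whole `model`).
#' @param ... passed to [shrakeRupley()].
#' @return data.frame with columns chain, resno, insert, resid, sasa, rsasa.
#' @export
rsasaProfile <- function(model, chainId = NULL, ...) {
  s <- shrakeRupley(model, ...)
  pr <- s@perResidue
  pr <- pr[pr$resid %in% names(PROTEIN_3TO1), , drop = FALSE]
  if (!is.null(chainId)) pr <- pr[pr$chain == chainId, , drop = FALSE]
  pr$rsasa <- relativeSasa(pr$sasa, pr$resid)
  rownames(pr) <- NULL
  pr
}
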