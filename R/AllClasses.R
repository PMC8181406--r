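#' @import methods
NULL

#' StructureModel: a single-model macromolecular structure
#'
#' A uniform chain/residue/atom container for protein-RNA complexes.  Atoms
#' are stored as a data.frame in file order with author chain identifiers and
#' author residue numbering, one row per atom.
#'
#' @slot atoms data.frame with columns `chain` (character), `resno`
#'   (integer, author numbering), `insert` (character, `""` when absent),
#'   `resid` (character, 3-letter residue or nucleotide code), `elety`
#'   (character, atom name), `elesy` (character, element symbol), `x`, `y`,
#'   `z` (numeric, Angstrom), `kind` (character: `"protein"`, `"rna"` or
#'   `"other"`, inferred from residue-name dictionaries).
#' @slot modelId integer model number (1 for single-model files).
#'
#' @seealso [readStructure()], [extractChain()], [sequenceOf()]
#' @export
setClass("StructureModel",
  representation(atoms = "data.frame", modelId = "integer"),
  prototype(modelId = 1L)
)

setValidity("StructureModel", function(object) {
  a <- object@atoms
  need <- c("chain", "resno", "insert", "resid", "elety", "elesy",
            "x", "y", "z", "kind")
  if (!all(need %in% names(a)))
    return(paste("atoms must contain columns:", paste(need, collapse = ", ")))
  if (nrow(a) == 0L)
    return("empty structure: no polymer atoms")
  if (!all(is.finite(a$x) & is.finite(a$y) & is.finite(a$z)))
    return("non-finite atom coordinates")
  if (any(!nzchar(a$elesy)))
    return("atoms with empty element symbol")
  TRUE
})

#' StructureEnsemble: multiple conformations of one topology
#'
#' Holds the models of a multi-model coordinate file (e.g. an MD snapshot
#' ensemble written as multi-model PDB).  All models must share identical
#' residue and atom naming and order.
#'
#' @slot models list of [StructureModel-class] objects.
#' @export
setClass("StructureEnsemble", representation(models = "list"))

setValidity("StructureEnsemble", function(object) {
  if (length(object@models) < 1L) return("ensemble has no models")
  if (!all(vapply(object@models, is, logical(1), "StructureModel")))
    return("models must all be StructureModel objects")
  ref <- object@models[[1]]@atoms
  key <- function(a) paste(a$chain, a$resno, a$insert, a$resid, a$elety)
  k0 <- key(ref)
  for (m in object@models[-1]) {
    if (nrow(m@atoms) != nrow(ref) || !identical(key(m@atoms), k0))
      return("models differ in residue/atom topology")
  }
  TRUE
})

#' SasaResult: solvent-accessible surface areas
#'
#' @slot perAtom numeric vector, one SASA value (A^2) per atom of the model
#'   the result was computed from.
#' @slot perResidue data.frame with columns `chain`, `resno`, `insert`,
#'   `resid`, `sasa` (A^2 summed over the residue's atoms).
#' @slot probeRadius numeric, probe radius in Angstrom.
#' @slot nSpherePoints integer, number of test points per atom.
#' @export
setClass("SasaResult",
  representation(perAtom = "numeric", perResidue = "data.frame",
                 probeRadius = "numeric", nSpherePoints = "integer"))

setValidity("SasaResult", function(object) {
  if (any(object@perAtom < -1e-9)) return("negative per-atom SASA")
  if (any(object@perResidue$sasa < -1e-9)) return("negative per-residue SASA")
  if (abs(sum(object@perAtom) - sum(object@perResidue$sasa)) >
      1e-6 * max(1, sum(object@perAtom)))
    return("per-residue SASA does not sum to per-atom SASA")
  TRUE
})

#' FlexibilityProfile: per-residue backbone RMSF
#'
#' @slot rmsf numeric vector of per-residue backbone RMSF values (Angstrom).
#' @slot resno integer vector of author residue numbers, parallel to `rmsf`.
#' @slot reference matrix of the average-conformation backbone coordinates
#'   used as superposition reference (one row per backbone atom, columns
#'   x/y/z).
#' @export
setClass("FlexibilityProfile",
  representation(rmsf = "numeric", resno = "integer", reference = "matrix"))

setValidity("FlexibilityProfile", function(object) {
  if (length(object@rmsf) != length(object@resno))
    return("rmsf and resno lengths differ")
  if (any(object@rmsf < 0)) return("negative RMSF")
  TRUE
})

#' TrainedModel: a fitted pathogenicity predictor
#'
#' RBF-kernel SVM refit on the full training table with the selected feature
#' subset and hyper-parameters, plus the feature scaler and a
#' sigmoid score calibration mapping decision values onto [0, 1].
#'
#' @slot features character vector of selected feature names.
#' @slot cost,gamma numeric SVM hyper-parameters (cost is the SVM C).
#' @slot fit the underlying [e1071::svm] fit.
#' @slot center,scale named numeric vectors of the z-score scaler fitted on
#'   the training table.
#' @slot calibration numeric length-2 vector `c(A, B)` of the sigmoid
#'   score map `1 / (1 + exp(A * f + B))` on decision values `f`.
#' @slot cvMcc numeric, the cross-validation MCC achieved during selection
#'   (NA when trained directly).
#' @export
setClass("TrainedModel",
  representation(features = "character", cost = "numeric", gamma = "numeric",
                 fit = "ANY", center = "numeric", scale = "numeric",
                 calibration = "numeric", cvMcc = "numeric"))

setValidity("TrainedModel", function(object) {
  if (length(object@features) < 1L) return("no features")
  if (length(object@calibration) != 2L) return("calibration must be c(A, B)")
  TRUE
})

setMethod("show", "StructureModel", function(object) {
  a <- object@atoms
  res <- unique(paste(a$chain, a$resno, a$insert))
  cat("StructureModel (model", object@modelId, "):",
      nrow(a), "atoms,", length(res), "residues,",
      length(unique(a$chain)), "chain(s):",
      paste(unique(a$chain), collapse = " "), "\n")
})

setMethod("show", "StructureEnsemble", function(object) {
  cat("StructureEnsemble:", length(object@models), "models of",
      nrow(object@models[[1]]@atoms), "atoms\n")
})

setMethod("show", "SasaResult", function(object) {
  cat("SasaResult:", length(object@perAtom), "atoms, total",
      sprintf("%.1f", sum(object@perAtom)), "A^2 (probe",
      object@probeRadius, "A,", object@nSpherePoints, "points)\n")
})

setMethod("show", "TrainedModel", function(object) {
  cat("TrainedModel: RBF SVM, C =", object@cost, ", gamma =", object@gamma,
      "\n  features:", paste(object@features, collapse = ", "),
      "\n  cv MCC:", object@cvMcc, "\n")
})

#' @describeIn StructureModel-class number of atoms
#' @param x a StructureModel
#' @export
nAtoms <- function(x) nrow(x@atoms)

#' Residue table of a model
#'
#' One row per residue, in atom order.
#'
#' @param x a [StructureModel-class]
#' @return data.frame with columns chain, resno, insert, resid, kind.
#' @export
residueTable <- function(x) {
  a <- x@atoms
  key <- paste(a$chain, a$resno, a$insert, sep = "\r")
  idx <- !duplicated(key)
  data.frame(chain = a$chain[idx], resno = a$resno[idx],
             insert = a$insert[idx], resid = a$resid[idx],
             kind = a$kind[idx], stringsAsFactors = FALSE)
}

#' @rdname residueTable
#' @export
nResidues <- function(x) nrow(residueTable(x))

#' Atom coordinate matrix
#'
#' @param x a [StructureModel-class]
#' @return numeric matrix with one row per atom, columns x, y, z.
#' @export
coords <- function(x) {
  as.matrix(x@atoms[, c("x", "y", "z")])
}
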