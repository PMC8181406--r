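#' Read a macromolecular structure (PDB or mmCIF)
#'
#' Parses coordinates into the package's uniform chain/residue/atom model.
#' Polymer ATOM records (and HETATM records bearing polymer residue names
#' such as MSE) are kept; waters, ions and ligands are dropped.  Alternate
#' locations are reduced to the highest-occupancy conformer.  Multi-model
#' files yield a [StructureEnsemble-class].
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"pdb"` or `"cif"`.
#' @return a [StructureModel-class], or a [StructureEnsemble-class] for
#'   multi-model files.
#' @examples
#' pdb <- tempfile(fileext = ".pdb")
#' writeStructure(makeToyComplex(nResidues = 6), pdb)
#' readStructure(pdb)
#' @export
readStructure <- function(path, format = c("auto", "pdb", "cif")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.(cif|mmcif)(\\.gz)?$", path, ignore.case = TRUE))
      "cif" else "pdb"
  }
  pdb <- tryCatch(
    if (format == "cif") bio3d::read.cif(path, verbose = FALSE)
    else bio3d::read.pdb(path, multi = TRUE, verbose = FALSE),
    error = function(e) stop("failed to parse ", path, " as ", format, ": ",
                             conditionMessage(e), call. = FALSE))
  atomsFromBio3d(pdb)
}

# convert a bio3d pdb object into StructureModel / StructureEnsemble
atomsFromBio3d <- function(pdb) {
  a <- pdb$atom
  a$chain[is.na(a$chain)] <- " "
  a$insert[is.na(a$insert)] <- ""
  elesy <- a$elesy
  if (is.null(elesy)) elesy <- rep(NA_character_, nrow(a))
  guess <- toupper(substr(gsub("[0-9']", "", a$elety), 1, 1))
  elesy <- ifelse(is.na(elesy) | !nzchar(trimws(elesy)), guess,
                  toupper(trimws(elesy)))
  kind <- residueKind(a$resid)
  keep <- (a$type == "ATOM" & kind != "other") |
          (a$type == "HETATM" & kind == "protein")
  # highest-occupancy altloc conformer
  occ <- a$o
  occ[is.na(occ)] <- 1
  alt <- a$alt
  alt[is.na(alt)] <- ""
  ord <- order(-occ)
  akey <- paste(a$chain, a$resno, a$insert, a$elety, sep = "\r")
  first <- ord[!duplicated(akey[ord])]
  keepAlt <- logical(nrow(a))
  keepAlt[first] <- TRUE
  keep <- keep & keepAlt

  buildModel <- function(xyz, modelId) {
    m <- matrix(xyz, ncol = 3, byrow = TRUE)
    df <- data.frame(chain = a$chain, resno = as.integer(a$resno),
                     insert = a$insert, resid = toupper(trimws(a$resid)),
                     elety = a$elety, elesy = elesy,
                     x = m[, 1], y = m[, 2], z = m[, 3],
                     kind = kind, stringsAsFactors = FALSE)
    df <- df[keep, , drop = FALSE]
    rownames(df) <- NULL
    if (nrow(df) == 0L)
      stop("empty structure: no polymer atoms found", call. = FALSE)
    new("StructureModel", atoms = df, modelId = as.integer(modelId))
  }

  xyz <- pdb$xyz
  if (is.matrix(xyz) && nrow(xyz) > 1L) {
    models <- lapply(seq_len(nrow(xyz)), function(i) buildModel(xyz[i, ], i))
    new("StructureEnsemble", models = models)
  } else {
    buildModel(as.numeric(xyz), 1L)
  }
}

#' Write a structure (or ensemble) as PDB
#'
#' Fixed-width PDB v3.3 output; ensembles are written as multi-model files
#' with MODEL/ENDMDL records.
#'
#' @param x a [StructureModel-class] or [StructureEnsemble-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeStructure <- function(x, path) {
  if (is(x, "StructureEnsemble")) {
    con <- file(path, "w")
    on.exit(close(con))
    for (i in seq_along(x@models)) {
      writeLines(sprintf("MODEL     %4d", i), con)
      writeLines(pdbLines(x@models[[i]]), con)
      writeLines("ENDMDL", con)
    }
    writeLines("END", con)
  } else {
    writeLines(c(pdbLines(x), "END"), path)
  }
  invisible(path)
}

pdbLines <- function(model) {
  a <- model@atoms
  name <- ifelse(nchar(a$elety) < 4 & nchar(a$elesy) == 1,
                 sprintf(" %-3s", a$elety), sprintf("%-4s", a$elety))
  sprintf("ATOM  %5d %s %-3s%2s%4d%-1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          seq_len(nrow(a)) %% 100000L, name, a$resid,
          substr(paste0(a$chain, " "), 1, 1), a$resno,
          substr(paste0(a$insert, " "), 1, 1),
          a$x, a$y, a$z, 1.0, 0.0, a$elesy)
}

#' Extract one chain from a model
#'
#' @param model a [StructureModel-class].
#' @param chainId chain identifier.
#' @return a [StructureModel-class] containing exactly that chain, with
#'   coordinates unchanged.
#' @export
extractChain <- function(model, chainId) {
  stopifnot(is(model, "StructureModel"))
  sel <- model@atoms$chain == chainId
  if (!any(sel)) stop("chain not found: '", chainId, "'")
  out <- model@atoms[sel, , drop = FALSE]
  rownames(out) <- NULL
  new("StructureModel", atoms = out, modelId = model@modelId)
}

#' One-letter sequence of a protein chain
#'
#' @param model a [StructureModel-class].
#' @param chainId chain identifier; may be omitted for single-chain models.
#' @return one-letter string; nonstandard protein residues appear as `"X"`.
#' @export
sequenceOf <- function(model, chainId = NULL) {
  stopifnot(is(model, "StructureModel"))
  if (!is.null(chainId)) model <- extractChain(model, chainId)
  rt <- residueTable(model)
  if (!all(rt$kind == "protein"))
    stop("sequenceOf requires a protein chain; found kinds: ",
         paste(unique(rt$kind), collapse = ", "))
  one <- PROTEIN_3TO1[rt$resid]
  one[is.na(one)] <- "X"
  paste(one, collapse = "")
}
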