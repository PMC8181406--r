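#' Load a per-mutation stability-change (ddG) table
#'
#' Reads either the package's own TSV (header with columns `position`,
#' `mut`, optional `wt`, and `ddg`) or a PositionScan-style two-column file
#' whose first column is a mutation code (`GLY127ARG`, `GLYA127R`,
#' `GA127R` or `G127R`; an optional chain letter is ignored) and whose
#' second column is the ddG in kcal/mol.  Duplicate (position, mutant)
#' entries keep the last value with a warning.
#'
#' @param path file path.
#' @return data.frame of class `ddg_table` with columns `position`, `mut`,
#'   `ddg`.
#' @export
loadDdgTable <- function(path) {
  firstLine <- readLines(path, n = 1L)
  if (grepl("position", firstLine, ignore.case = TRUE)) {
    d <- utils::read.delim(path, stringsAsFactors = FALSE)
    names(d) <- tolower(names(d))
    if (!all(c("position", "mut", "ddg") %in% names(d)))
      stop("ddG TSV must have columns position, mut, ddg")
    out <- data.frame(position = as.integer(d$position),
                      mut = toupper(d$mut), ddg = as.numeric(d$ddg),
                      stringsAsFactors = FALSE)
  } else {
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines))]
    out <- data.frame(position = integer(0), mut = character(0),
                      ddg = numeric(0))
    for (i in seq_along(lines)) {
      f <- strsplit(trimws(lines[i]), "[\t ]+")[[1]]
      if (length(f) < 2L)
        stop("malformed ddG row at line ", i, ": '", lines[i], "'")
      code <- toupper(f[1])
      m <- regmatches(code,
        regexec("^([A-Z]{3}|[A-Z])([A-Z]?)([0-9]+)([A-Z])$", code))[[1]]
      if (length(m) != 5L)
        stop("malformed mutation code at line ", i, ": '", f[1], "'")
      wt3 <- m[2]
      val <- suppressWarnings(as.numeric(f[2]))
      if (is.na(val))
        stop("malformed ddG value at line ", i, ": '", f[2], "'")
      out <- rbind(out, data.frame(position = as.integer(m[4]),
                                   mut = m[5], ddg = val,
                                   stringsAsFactors = FALSE))
    }
  }
  key <- paste0(out$position, out$mut)
  if (anyDuplicated(key)) {
    warning("duplicate ddG entries; keeping the last value")
    out <- out[!duplicated(key, fromLast = TRUE), , drop = FALSE]
  }
  rownames(out) <- NULL
  class(out) <- c("ddg_table", "data.frame")
  out
}

#' Look up a ddG value
#'
#' @param ddg a `ddg_table` from [loadDdgTable()] (or a data.frame with the
#'   same columns).
#' @param position,mut the mutation.
#' @return ddG in kcal/mol, or NA when absent.
#' @export
ddgOf <- function(ddg, position, mut) {
  if (is.null(ddg)) return(NA_real_)
  hit <- ddg$position == position & ddg$mut == toupper(mut)
  if (!any(hit)) return(NA_real_)
  ddg$ddg[which(hit)[1]]
}

#' The candidate feature registry
#'
#' The 8 core features used by the published predictor come first (BSA,
#' rBSA, HB_Num, delta-charge, ddG, delta-helix, BLOSUM62, delta-disorder),
#' followed by 10 additional structural/conservation candidates filling the
#' 18-feature pool over which selection is run.
#'
#' @return character vector of 18 feature names.
#' @export
featureRegistry <- function() {
  c("bsa", "rbsa", "hb_num", "d_charge", "ddg", "d_helix", "blosum62",
    "d_disorder",
    "rsasa", "d_volume_pct", "d_hydrophobicity_pct", "conservation",
    "in_patch", "is_proline_sub", "wt_volume", "mut_volume",
    "wt_hydrophobicity", "mut_hydrophobicity")
}

#' Extract the feature vector of one mutation
#'
#' Pure function of its inputs: interface/H-bond features are read from the
#' wild-type residue's interface record (zero when the residue is not
#' interfacial), deltas from the property tables, and ddG/conservation from
#' the supplied external tables (NA when missing -- never silently zero).
#'
#' @param mutation list with `position`, `wt`, `mut`
#'   (see [parseProteinMutation()]).
#' @param interface data.frame from [interfaceResidues()] covering the
#'   subject chain; when supplied, the mutated position must resolve to a
#'   structure residue.
#' @param hbondCounts named vector from [hbondsPerResidue()].
#' @param rsasa named numeric vector, residue number -> relative SASA in the
#'   packed context (see [rsasaProfile()]).
#' @param tables property tables from [propertyTables()].
#' @param ddg optional `ddg_table`.
#' @param conservation optional named numeric vector, position -> normalised
#'   conservation score.
#' @param patches patch definitions for the `in_patch` flag.
#' @return named numeric vector over [featureRegistry()].
#' @export
extractFeatures <- function(mutation, interface = NULL,
                            hbondCounts = integer(0), rsasa = NULL,
                            tables = propertyTables(), ddg = NULL,
                            conservation = NULL,
                            patches = patchDefinitions()) {
  pos <- mutation$position
  wt <- aa1(mutation$wt)
  mut <- aa1(mutation$mut)

  bsa <- rbsa <- 0
  if (!is.null(interface)) {
    hit <- which(interface$resno == pos)
    if (!length(hit))
      stop("position ", pos, " (", wt, ") not resolvable to a structure ",
           "residue of the interface table")
    rec <- interface[hit[1], ]
    if (rec$resid %in% names(PROTEIN_3TO1) &&
        PROTEIN_3TO1[rec$resid] != wt)
      stop("wild-type mismatch at position ", pos, ": structure has ",
           rec$resid, ", mutation says ", wt)
    if (isTRUE(rec$is_interface)) {
      bsa <- rec$bsa
      rbsa <- rec$rbsa
    }
  }
  hb <- 0
  if (length(hbondCounts)) {
    v <- hbondCounts[as.character(pos)]
    if (!is.na(v)) hb <- as.numeric(v)
  }
  if (!is.null(interface) &&
      !isTRUE(interface$is_interface[match(pos, interface$resno)]))
    hb <- 0

  rs <- NA_real_
  if (!is.null(rsasa)) {
    v <- rsasa[as.character(pos)]
    if (!is.na(v)) rs <- as.numeric(v)
  }
  cons <- NA_real_
  if (!is.null(conservation)) {
    v <- conservation[as.character(pos)]
    if (!is.na(v)) cons <- as.numeric(v)
  }
  c(bsa = bsa, rbsa = rbsa, hb_num = hb,
    d_charge = chargeChange(wt, mut, tables),
    ddg = ddgOf(ddg, pos, mut),
    d_helix = helixPropensityChange(wt, mut, tables),
    blosum62 = blosumScore(wt, mut, tables),
    d_disorder = disorderPropensityChange(wt, mut, tables),
    rsasa = rs,
    d_volume_pct = volumeChangePct(wt, mut, tables),
    d_hydrophobicity_pct = hydrophobicityChangePct(wt, mut, tables),
    conservation = cons,
    in_patch = as.numeric(!is.na(assignPatch(pos, patches))),
    is_proline_sub = as.numeric(mut == "P"),
    wt_volume = unname(tables$volume[wt]),
    mut_volume = unname(tables$volume[mut]),
    wt_hydrophobicity = unname(tables$hydrophobicity[wt]),
    mut_hydrophobicity = unname(tables$hydrophobicity[mut]))
}

#' Extract a feature table for a set of mutations
#'
#' @param mutations data.frame with columns `position`, `wt`, `mut` and
#'   optionally `label`.
#' @param ... passed to [extractFeatures()].
#' @return data.frame: position, wt, mut, the [featureRegistry()] columns,
#'   and `label` when present.
#' @export
extractFeatureTable <- function(mutations, ...) {
  rows <- lapply(seq_len(nrow(mutations)), function(i) {
    extractFeatures(list(position = mutations$position[i],
                         wt = mutations$wt[i], mut = mutations$mut[i]), ...)
  })
  out <- cbind(mutations[, c("position", "wt", "mut")],
               as.data.frame(do.call(rbind, rows)))
  if (!is.null(mutations$label)) out$label <- mutations$label
  rownames(out) <- NULL
  out
}

#' Synthetic surrogate stability-change estimator
#'
#' A deliberately simple, clearly non-physical stand-in used only to make
#' synthetic pipelines runnable end-to-end without an external force-field
#' estimator: burial-weighted hydrophobicity loss plus a volume-clash term,
#' `ddg = (1 - rsasa) * (0.5 * max(0, h_wt - h_mut)
#'        + 1.5 * max(0, (V_mut - V_wt) / 60))`.
#' Do not interpret its output as a physical free energy.
#'
#' @param wt,mut residues (1- or 3-letter codes).
#' @param rsasa relative SASA of the site in [0, 1].
#' @param tables property tables.
#' @return surrogate ddG-like value (kcal/mol-scaled, >= 0).
#' @export
surrogateDdg <- function(wt, mut, rsasa, tables = propertyTables()) {
  wt <- aa1(wt)
  mut <- aa1(mut)
  burial <- pmax(0, 1 - pmin(1, rsasa))
  hloss <- pmax(0, tables$hydrophobicity[wt] - tables$hydrophobicity[mut])
  vclash <- pmax(0, (tables$volume[mut] - tables$volume[wt]) / 60)
  unname(burial * (0.5 * hloss + 1.5 * vclash))
}
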