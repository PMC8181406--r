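# helper: one ideal-helix protein backbone (rise 1.5 A, 100 deg/residue,
# CA radius 2.3 A); returns the atom data.frame rows for residues 1..n
helixBackbone <- function(n, resid = rep("GLY", n), chain = "A",
                          cbOut = NULL) {
  rows <- list()
  for (i in seq_len(n)) {
    th <- (i - 1) * 100 * pi / 180
    u <- c(cos(th), sin(th), 0)          # outward radial unit
    tg <- c(-sin(th), cos(th), 0)        # tangent
    ca <- 2.3 * u + c(0, 0, 1.5 * (i - 1))
    at <- rbind(N = ca - 1.0 * tg - c(0, 0, 0.9),
                CA = ca,
                C = ca + 1.0 * tg + c(0, 0, 0.9),
                O = ca + 1.0 * tg + c(0, 0, 2.1))
    el <- c("N", "C", "C", "O")
    nm <- c("N", "CA", "C", "O")
    if (!is.null(cbOut) && !is.na(cbOut[i])) {
      at <- rbind(at, CB = ca + cbOut[i] * u)
      el <- c(el, if (resid[i] == "SER") "O" else "C")
      nm <- c(nm, if (resid[i] == "SER") "OG" else "CB")
    }
    rows[[i]] <- data.frame(chain = chain, resno = as.integer(i),
                            insert = "",
                            resid = resid[i], elety = nm, elesy = el,
                            x = at[, 1], y = at[, 2], z = at[, 3],
                            kind = "protein", stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Build a toy protein-RNA complex with planted contacts
#'
#' An ideal alpha-helix protein chain (`A`) plus a pseudo-RNA chain (`B`)
#' of reduced nucleotides (P, OP1, OP2, O5', C1' heavy atoms, sufficient
#' for donor/acceptor typing).  At each contact position a nucleotide is
#' placed against the residue's side chain; at hydrogen-bond positions the
#' phosphate OP1 acceptor sits 2.9 +/- 0.1 A from the serine OG donor, at
#' contact-only positions the closest RNA atom is the (non-bonding) C1'
#' carbon with all acceptors beyond the H-bond cutoff.  All other protein
#' residues stay about 8 A or more from any RNA atom.  A remote nucleotide
#' 60 A away guarantees an RNA chain is always present.
#'
#' @param nResidues protein length.
#' @param contactPositions residue indices placed against the RNA chain.
#' @param hbondPositions subset of `contactPositions` given a planted
#'   hydrogen bond.
#' @param seed RNG seed (the only randomness is the +/- 0.1 A bond-length
#'   jitter).
#' @return a [StructureModel-class] with chains A (protein) and B (RNA).
#' @export
makeToyComplex <- function(nResidues = 20, contactPositions = integer(0),
                           hbondPositions = contactPositions, seed = 1) {
  stopifnot(all(contactPositions %in% seq_len(nResidues)),
            all(hbondPositions %in% contactPositions))
  resid <- rep("ALA", nResidues)
  resid[contactPositions] <- "SER"
  cb <- rep(1.5, nResidues)
  cb[contactPositions] <- 3.0            # serine OG reaching outward
  prot <- helixBackbone(nResidues, resid, "A", cbOut = cb)

  nuc <- function(origin, u, tg, resno) {
    # origin = the RNA atom closest to the protein; build outward from it
    p <- origin + 1.5 * u
    data.frame(chain = "B", resno = as.integer(resno), insert = "",
               resid = "U",
               elety = c("P", "OP1", "OP2", "O5'", "C1'"),
               elesy = c("P", "O", "O", "O", "C"),
               x = c(p[1], origin[1], (p + 1.5 * tg)[1],
                     (p + c(0, 0, 1.5))[1], (p + 1.2 * u)[1]),
               y = c(p[2], origin[2], (p + 1.5 * tg)[2],
                     (p + c(0, 0, 1.5))[2], (p + 1.2 * u)[2]),
               z = c(p[3], origin[3], (p + 1.5 * tg)[3],
                     (p + c(0, 0, 1.5))[3], (p + 1.2 * u)[3]),
               kind = "rna", stringsAsFactors = FALSE)
  }

  rna <- list()
  withSeed(seed, {
    for (i in contactPositions) {
      th <- (i - 1) * 100 * pi / 180
      u <- c(cos(th), sin(th), 0)
      tg <- c(-sin(th), cos(th), 0)
      og <- 2.3 * u + c(0, 0, 1.5 * (i - 1)) + 3.0 * u
      if (i %in% hbondPositions) {
        d <- 2.9 + stats::runif(1, -0.1, 0.1)
        rna[[length(rna) + 1L]] <- nuc(og + d * u, u, tg, 1000L + i)
      } else {
        # closest atom is C1' (carbon, no H-bond); acceptors kept past 4 A
        n <- nuc(og + 4.2 * u, u, tg, 1000L + i)
        c1 <- og + 2.9 * u
        n[n$elety == "C1'", c("x", "y", "z")] <- as.list(c1)
        rna[[length(rna) + 1L]] <- n
      }
    }
  })
  rna[[length(rna) + 1L]] <- nuc(c(60, 60, 0), c(1, 0, 0), c(0, 1, 0),
                                 999L)
  atoms <- rbind(prot, do.call(rbind, rna))
  rownames(atoms) <- NULL
  new("StructureModel", atoms = atoms, modelId = 1L)
}

#' Build a conformational ensemble with planted rigid/flexible regions
#'
#' Gaussian per-coordinate jitter around an ideal-helix base conformation:
#' residues inside `floppyIntervals` get `sigmaFloppy`, everything else
#' `sigmaRigid`, so the backbone RMSF of a floppy residue approaches
#' `sigmaFloppy * sqrt(3)` for large ensembles.
#'
#' @param nModels number of models.
#' @param nResidues protein length.
#' @param floppyIntervals 2-column matrix (or list of `c(start, end)`) of
#'   closed residue intervals made flexible.
#' @param sigmaRigid,sigmaFloppy per-coordinate jitter (Angstrom).
#' @param seed RNG seed.
#' @return a [StructureEnsemble-class].
#' @export
makeEnsemble <- function(nModels = 50, nResidues = 60,
                         floppyIntervals = NULL, sigmaRigid = 0.3,
                         sigmaFloppy = 2.5, seed = 1) {
  base <- helixBackbone(nResidues)
  sigma <- rep(sigmaRigid, nResidues)
  if (!is.null(floppyIntervals)) {
    if (is.list(floppyIntervals))
      floppyIntervals <- do.call(rbind, floppyIntervals)
    for (k in seq_len(nrow(floppyIntervals))) {
      sigma[floppyIntervals[k, 1]:floppyIntervals[k, 2]] <- sigmaFloppy
    }
  }
  atomSigma <- sigma[base$resno]
  nAtom <- nrow(base)
  models <- withSeed(seed, lapply(seq_len(nModels), function(m) {
    a <- base
    a$x <- a$x + stats::rnorm(nAtom, 0, atomSigma)
    a$y <- a$y + stats::rnorm(nAtom, 0, atomSigma)
    a$z <- a$z + stats::rnorm(nAtom, 0, atomSigma)
    new("StructureModel", atoms = a, modelId = as.integer(m))
  }))
  new("StructureEnsemble", models = models)
}

# median-matching helpers for the feature generator
rlnormMedian <- function(n, median, sdlog) {
  stats::rlnorm(n, meanlog = log(max(median, 1e-6)), sdlog = sdlog)
}

rbetaMedian <- function(n, median, shape1 = 2) {
  # Kerman approximation: median(Beta(a, b)) ~ (a - 1/3) / (a + b - 2/3)
  shape2 <- (shape1 - 1 / 3) / median - shape1 + 2 / 3
  stats::rbeta(n, shape1, max(shape2, 0.1))
}

#' Generate a labelled mutation feature table
#'
#' Samples disease-class and neutral-class mutations whose per-feature
#' distributions reproduce the published class medians by default:
#' ddG (kcal/mol, log-normal) 1.55 vs 0.106, site rSASA (beta) 0.13 vs
#' 0.42, normalised conservation (normal) -0.665 vs 0.0995.  Wild-type and
#' mutant residues are sampled (disease mutations enriched for Arg/Leu/Gly
#' wild types and for substitutions to Pro) and the table-driven features
#' (delta-charge, delta-helix, BLOSUM62, delta-disorder, volume and
#' hydrophobicity changes) are then computed from the property tables, so
#' the generated table is internally consistent.  Interface features (BSA,
#' rBSA, HB_Num) are sampled with the disease class more interfacial.
#'
#' @param nPositive,nNegative class sizes (51 and 30 by default).
#' @param ddgMedian,rsasaMedian,conservationMedian length-2 vectors
#'   `c(disease, neutral)` of class medians.
#' @param proFraction length-2 vector of the fraction of substitutions
#'   into proline per class.
#' @param ddgSdlog log-scale spread of the disease ddG distribution;
#'   the neutral class uses a normal spread `ddgNeutralSd` around its
#'   median.
#' @param ddgNeutralSd see above.
#' @param proteinLength positions are sampled in `1..proteinLength`.
#' @param diseaseWtBias enrich the disease class for Arg/Leu/Gly/Ala wild
#'   types (set FALSE for a fully exchangeable null table).
#' @param seed RNG seed; the generator is a pure function of its arguments.
#' @return data.frame: position, wt, mut, the 8 core features of
#'   [featureRegistry()] plus rsasa/conservation/d_volume_pct/
#'   d_hydrophobicity_pct, and `label` (`"dba"`/`"neutral"`).
#' @export
makeFeatureTable <- function(nPositive = 51, nNegative = 30,
                             ddgMedian = c(1.55, 0.106),
                             rsasaMedian = c(0.13, 0.42),
                             conservationMedian = c(-0.665, 0.0995),
                             proFraction = c(0.294, 0.05),
                             ddgSdlog = 1.0, ddgNeutralSd = 0.6,
                             proteinLength = 145, diseaseWtBias = TRUE,
                             seed = 1) {
  tables <- propertyTables()
  aas <- BLOSUM62_AA
  wtWeightsPos <- stats::setNames(rep(1, 20), aas)
  if (diseaseWtBias)
    wtWeightsPos[c("R", "L", "G", "A")] <- c(5, 4.5, 2.5, 2)
  wtWeightsNeg <- stats::setNames(rep(1, 20), aas)

  sampleClass <- function(n, cls) {
    i <- if (cls == "dba") 1 else 2
    w <- if (cls == "dba") wtWeightsPos else wtWeightsNeg
    wt <- sample(aas, n, replace = TRUE, prob = w)
    mut <- character(n)
    toPro <- stats::runif(n) < proFraction[i]
    for (k in seq_len(n)) {
      choices <- setdiff(aas, wt[k])
      mut[k] <- if (toPro[k] && wt[k] != "P") "P"
        else sample(setdiff(choices, "P"), 1)
    }
    # median-matched sampling: draw from the class distribution, then
    # remove the residual sampling error of the sample median so the
    # class medians are reproduced at any n (multiplicative for the
    # log-normal, additive for the normal, bounded for the beta)
    ddg <- if (cls == "dba") {
      d <- rlnormMedian(n, ddgMedian[1], ddgSdlog)
      d * ddgMedian[1] / stats::median(d)
    } else {
      d <- stats::rnorm(n, ddgMedian[2], ddgNeutralSd)
      d + ddgMedian[2] - stats::median(d)
    }
    rsasa <- rbetaMedian(n, rsasaMedian[i])
    rsasa <- pmin(0.999, pmax(1e-4,
                              rsasa * rsasaMedian[i] /
                                stats::median(rsasa)))
    cons <- stats::rnorm(n, conservationMedian[i], 0.5)
    cons <- cons + conservationMedian[i] - stats::median(cons)
    iface <- stats::runif(n) < (if (cls == "dba") 0.5 else 0.3)
    bsa <- ifelse(iface, rlnormMedian(n, if (cls == "dba") 25 else 10, 0.6),
                  0)
    rbsa <- pmin(1, bsa / (bsa + 40))
    hb <- ifelse(iface,
                 stats::rpois(n, if (cls == "dba") 1.0 else 0.4), 0)
    data.frame(position = sample(seq_len(proteinLength), n, replace = TRUE),
               wt = wt, mut = mut,
               bsa = bsa, rbsa = rbsa, hb_num = hb,
               d_charge = chargeChange(wt, mut, tables),
               ddg = ddg,
               d_helix = helixPropensityChange(wt, mut, tables),
               blosum62 = blosumScore(wt, mut, tables),
               d_disorder = disorderPropensityChange(wt, mut, tables),
               rsasa = rsasa,
               conservation = cons,
               d_volume_pct = volumeChangePct(wt, mut, tables),
               d_hydrophobicity_pct = hydrophobicityChangePct(wt, mut,
                                                              tables),
               label = cls, stringsAsFactors = FALSE)
  }
  withSeed(seed, {
    out <- rbind(sampleClass(nPositive, "dba"),
                 sampleClass(nNegative, "neutral"))
    rownames(out) <- NULL
    out
  })
}
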