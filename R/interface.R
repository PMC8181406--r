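#' Interface residues by buried surface area
#'
#' For each residue of the subject chain, the buried surface area on
#' complex formation is `BSA = SASA(subject alone) - SASA(subject in the
#' subject+partners complex)`, and the relative form is
#' `rBSA = BSA / SASA(subject alone)`.  A residue is an interface residue
#' when its BSA exceeds `bsaThreshold`.
#'
#' @param complex a [StructureModel-class] holding all chains.
#' @param subjectChain chain identifier of the analysed protein.
#' @param partnerChains chain identifiers of the binding partners.
#' @param bsaThreshold Angstrom^2; interface call threshold (0.1).
#' @param contactDistance Angstrom; a partner chain is listed for a residue
#'   when any partner atom lies within this distance of the residue.
#' @param ... passed to [shrakeRupley()].
#' @return data.frame, one row per subject residue: chain, resno, insert,
#'   resid, sasa_alone, sasa_complex, bsa, rbsa, is_interface,
#'   partner_chains (comma-separated).
#' @export
interfaceResidues <- function(complex, subjectChain, partnerChains,
                              bsaThreshold = 0.1, contactDistance = 5, ...) {
  stopifnot(is(complex, "StructureModel"))
  if (subjectChain %in% partnerChains)
    stop("subject chain must not be among the partner chains")
  chains <- unique(complex@atoms$chain)
  missing <- setdiff(c(subjectChain, partnerChains), chains)
  if (length(missing))
    stop("chain(s) not in model: ", paste(missing, collapse = ", "))

  subject <- extractChain(complex, subjectChain)
  sel <- complex@atoms$chain %in% c(subjectChain, partnerChains)
  pair <- new("StructureModel",
              atoms = {
                df <- complex@atoms[sel, , drop = FALSE]
                rownames(df) <- NULL
                df
              },
              modelId = complex@modelId)

  sAlone <- shrakeRupley(subject, ...)@perResidue
  sCplx <- shrakeRupley(pair, ...)@perResidue
  sCplx <- sCplx[sCplx$chain == subjectChain, , drop = FALSE]

  key <- function(d) paste(d$chain, d$resno, d$insert, sep = "\r")
  stopifnot(identical(key(sAlone), key(sCplx)))

  bsa <- pmax(0, sAlone$sasa - sCplx$sasa)
  rbsa <- ifelse(sAlone$sasa > 0, bsa / sAlone$sasa, 0)
  out <- data.frame(chain = sAlone$chain, resno = sAlone$resno,
                    insert = sAlone$insert, resid = sAlone$resid,
                    sasa_alone = sAlone$sasa, sasa_complex = sCplx$sasa,
                    bsa = bsa, rbsa = rbsa,
                    is_interface = bsa > bsaThreshold,
                    partner_chains = "", stringsAsFactors = FALSE)

  pAtoms <- complex@atoms[complex@atoms$chain %in% partnerChains, ,
                          drop = FALSE]
  if (nrow(pAtoms)) {
    sxyz <- coords(subject)
    skey <- key(subject@atoms)
    for (i in which(out$is_interface)) {
      rows <- skey == paste(out$chain[i], out$resno[i], out$insert[i],
                            sep = "\r")
      rx <- sxyz[rows, , drop = FALSE]
      near <- character(0)
      for (pc in unique(pAtoms$chain)) {
        px <- as.matrix(pAtoms[pAtoms$chain == pc, c("x", "y", "z")])
        d2min <- min(vapply(seq_len(nrow(rx)), function(k) {
          min((px[, 1] - rx[k, 1])^2 + (px[, 2] - rx[k, 2])^2 +
              (px[, 3] - rx[k, 3])^2)
        }, numeric(1)))
        if (d2min <= contactDistance^2) near <- c(near, pc)
      }
      out$partner_chains[i] <- paste(near, collapse = ",")
    }
  }
  out
}

#' Interface fraction of a chain
#'
#' @param records output of [interfaceResidues()].
#' @param chainLength number of residues in the full-length chain.
#' @return percent of the chain at the interface.
#' @export
interfaceFraction <- function(records, chainLength) {
  stopifnot(chainLength > 0)
  100 * sum(records$is_interface) / chainLength
}

# atom-level donor/acceptor annotation for one model
hbondAtomRoles <- function(model) {
  a <- model@atoms
  role <- rep(NA_character_, nrow(a))
  for (r in unique(a$resid)) {
    roles <- hbondRoles(r)
    if (is.null(roles)) {
      warning("unknown residue name for H-bond typing, skipped: ", r)
      next
    }
    sel <- a$resid == r
    m <- roles[a$elety[sel]]
    role[sel] <- unname(m)
  }
  role
}

#' Inter-molecular hydrogen bonds between two chain groups
#'
#' Geometric criterion over heavy atoms: every donor-acceptor pair across
#' the two groups with donor-acceptor distance `<= dMax` is reported.  When
#' explicit hydrogens are present on a donor, the D-H...A angle of the best
#' hydrogen must additionally be `>= angleMin`; heavy-atom-only models (the
#' cryo-EM case) are handled without the angle test.
#'
#' @param complex a [StructureModel-class].
#' @param groupA,groupB character vectors of chain identifiers.
#' @param dMax donor-acceptor heavy-atom distance cutoff (Angstrom).
#' @param angleMin minimum D-H...A angle in degrees (used only with
#'   explicit hydrogens).
#' @return data.frame sorted by donor residue: donor/acceptor chain, resno,
#'   resid, atom, plus `distance` (Angstrom) and `angle` (degrees or NA).
#' @export
hydrogenBonds <- function(complex, groupA, groupB, dMax = 3.5,
                          angleMin = 120) {
  stopifnot(is(complex, "StructureModel"))
  if (length(intersect(groupA, groupB)))
    stop("chain groups overlap")
  a <- complex@atoms
  role <- hbondAtomRoles(complex)
  xyz <- coords(complex)
  inA <- a$chain %in% groupA
  inB <- a$chain %in% groupB

  donors <- which(!is.na(role) & role %in% c("donor", "both"))
  acceptors <- which(!is.na(role) & role %in% c("acceptor", "both"))
  hIdx <- which(toupper(a$elesy) == "H")

  bonds <- list()
  addPairs <- function(dIdx, aIdx) {
    for (d in dIdx) {
      if (!length(aIdx)) next
      d2 <- (xyz[aIdx, 1] - xyz[d, 1])^2 + (xyz[aIdx, 2] - xyz[d, 2])^2 +
            (xyz[aIdx, 3] - xyz[d, 3])^2
      hits <- aIdx[d2 <= dMax^2]
      for (acc in hits) {
        ang <- NA_real_
        if (length(hIdx)) {
          # hydrogens covalently attached to the donor (within 1.3 A)
          hd2 <- (xyz[hIdx, 1] - xyz[d, 1])^2 +
                 (xyz[hIdx, 2] - xyz[d, 2])^2 +
                 (xyz[hIdx, 3] - xyz[d, 3])^2
          hs <- hIdx[hd2 <= 1.3^2]
          if (length(hs)) {
            angs <- vapply(hs, function(h) {
              v1 <- xyz[d, ] - xyz[h, ]
              v2 <- xyz[acc, ] - xyz[h, ]
              cosang <- sum(v1 * v2) /
                sqrt(sum(v1^2) * sum(v2^2))
              acos(pmin(1, pmax(-1, cosang))) * 180 / pi
            }, numeric(1))
            ang <- max(angs)
            if (ang < angleMin) next
          }
        }
        bonds[[length(bonds) + 1L]] <<- data.frame(
          donor_chain = a$chain[d], donor_resno = a$resno[d],
          donor_resid = a$resid[d], donor_atom = a$elety[d],
          acceptor_chain = a$chain[acc], acceptor_resno = a$resno[acc],
          acceptor_resid = a$resid[acc], acceptor_atom = a$elety[acc],
          distance = sqrt(sum((xyz[d, ] - xyz[acc, ])^2)),
          angle = ang, stringsAsFactors = FALSE)
      }
    }
  }
  addPairs(donors[inA[donors]], acceptors[inB[acceptors]])
  addPairs(donors[inB[donors]], acceptors[inA[acceptors]])

  if (!length(bonds)) {
    return(data.frame(donor_chain = character(0), donor_resno = integer(0),
                      donor_resid = character(0), donor_atom = character(0),
                      acceptor_chain = character(0),
                      acceptor_resno = integer(0),
                      acceptor_resid = character(0),
                      acceptor_atom = character(0),
                      distance = numeric(0), angle = numeric(0),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, bonds)
  # one bond per unordered atom pair (both/both pairs otherwise counted twice)
  pkey <- apply(cbind(
    paste(out$donor_chain, out$donor_resno, out$donor_atom),
    paste(out$acceptor_chain, out$acceptor_resno, out$acceptor_atom)), 1,
    function(z) paste(sort(z), collapse = "|"))
  out <- out[!duplicated(pkey), , drop = FALSE]
  out <- out[order(out$donor_chain, out$donor_resno, out$acceptor_chain,
                   out$acceptor_resno), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Inter-molecular hydrogen bonds per residue of one chain
#'
#' @param bonds output of [hydrogenBonds()].
#' @param subjectChain chain identifier.
#' @return named integer vector, residue number -> bond count (residues
#'   with no bonds are absent).
#' @export
hbondsPerResidue <- function(bonds, subjectChain) {
  res <- c(bonds$donor_resno[bonds$donor_chain == subjectChain],
           bonds$acceptor_resno[bonds$acceptor_chain == subjectChain])
  if (!length(res)) return(integer(0))
  tab <- table(res)
  structure(as.integer(tab), names = names(tab))
}

#' Assign a residue to a conserved interface patch
#'
#' Exact lookup against the shipped patch definitions (see
#' [patchDefinitions()]).
#'
#' @param resno author residue number (vectorised).
#' @param patches patch definition list.
#' @return character vector of patch identifiers (`"I"`..`"V"`) or NA.
#' @export
assignPatch <- function(resno, patches = patchDefinitions()) {
  out <- rep(NA_character_, length(resno))
  for (id in names(patches)) {
    out[resno %in% patches[[id]]$protein_residues] <- id
  }
  out
}
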