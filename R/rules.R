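# side-chain heavy-atom counts (reach proxy) and donor/acceptor capability
SC_HEAVY_ATOMS <- c(A = 1, R = 7, N = 4, D = 4, C = 2, Q = 5, E = 5, G = 0,
                    H = 6, I = 4, L = 4, K = 5, M = 4, F = 7, P = 3, S = 2,
                    T = 3, W = 10, Y = 8, V = 3)

sidechainHbClasses <- function(aa) {
  roles <- HB_PROTEIN_SIDECHAIN[[PROTEIN_1TO3[aa]]]
  c(donor = any(roles %in% c("donor", "both")),
    acceptor = any(roles %in% c("acceptor", "both")))
}

#' Default thresholds of the structural-basis rule engine
#'
#' @param ddg_cutoff destabilisation cutoff, kcal/mol (1.0 is the standard
#'   cutoff for destabilising mutations).
#' @param buried_rsasa residues with relative SASA below this are treated
#'   as buried (hydrophobic-core context).
#' @param steric_volume_pct minimum percent volume increase treated as a
#'   steric clash.
#' @param reach_change minimum side-chain heavy-atom count difference
#'   treated as a bonding-distance (reach) change.
#' @return named list of thresholds.
#' @export
basisThresholds <- function(ddg_cutoff = 1.0, buried_rsasa = 0.2,
                            steric_volume_pct = 30, reach_change = 2) {
  list(ddg_cutoff = ddg_cutoff, buried_rsasa = buried_rsasa,
       steric_volume_pct = steric_volume_pct, reach_change = reach_change)
}

#' Classify the structural basis of one mutation
#'
#' Multi-label rule engine mirroring the two destabilisation approaches and
#' three interaction-disruption avenues:
#' * `destabilizing`: ddG above `ddg_cutoff` (NA when no ddG is supplied).
#' * `hydrophobic_core_loss`: buried site whose hydrophobicity decreases,
#'   from a typical hydrophobic wild type (Leu/Trp/Val/Phe) or introducing
#'   a charged side chain into the core.
#' * `steric_core_clash`: buried small wild type (Gly/Ala) replaced by a
#'   residue at least `steric_volume_pct` percent larger.
#' * `helix_break_proline`: substitution to Pro inside a helix; flagged
#'   even when the supplied ddG is below the cutoff, since force-field ddG
#'   values for proline substitutions are unreliable.
#' * `hbond_loss`: the wild-type residue makes at least one inter-molecular
#'   hydrogen bond and the mutant loses the wild type's side-chain
#'   donor/acceptor class or changes side-chain reach by at least
#'   `reach_change` heavy atoms.
#' * `electrostatic_alteration`: patch residue whose formal charge drops by
#'   at least 1.
#' * `steric_interface_clash`: interface residue replaced by a residue at
#'   least `steric_volume_pct` percent larger.
#'
#' @param mutation list with `position`, `wt`, `mut`.
#' @param features named feature vector from [extractFeatures()].
#' @param context list with `rsasa` (packed-context relative SASA of the
#'   site; falls back to `features["rsasa"]`) and `in_helix` (logical).
#' @param thresholds from [basisThresholds()].
#' @param patches patch definitions.
#' @return one-row data.frame: position, wt, mut, destabilizing,
#'   hydrophobic_core_loss, steric_core_clash, helix_break_proline,
#'   interaction_disrupting, hbond_loss, electrostatic_alteration,
#'   steric_interface_clash, patch, notes.
#' @export
classifyMutation <- function(mutation, features, context = list(),
                             thresholds = basisThresholds(),
                             patches = patchDefinitions()) {
  wt <- aa1(mutation$wt)
  mut <- aa1(mutation$mut)
  pos <- mutation$position
  th <- thresholds

  rsasa <- context$rsasa
  if (is.null(rsasa) || is.na(rsasa)) rsasa <- unname(features["rsasa"])
  inHelix <- isTRUE(context$in_helix)
  notes <- character(0)

  ddg <- unname(features["ddg"])
  destab <- if (is.na(ddg)) NA else ddg > th$ddg_cutoff
  if (is.na(ddg)) notes <- c(notes, "ddG unavailable")

  buried <- !is.na(rsasa) && rsasa < th$buried_rsasa
  dvol <- unname(features["d_volume_pct"])
  dhyd <- unname(features["d_hydrophobicity_pct"])
  # a charged side chain entering the core counts as hydrophobic-core damage
  chargedIn <- abs(chargeChange("G", mut)) > abs(chargeChange("G", wt))

  hydrophobicCoreLoss <- buried &&
    unname(features["mut_hydrophobicity"]) <
      unname(features["wt_hydrophobicity"]) &&
    (wt %in% c("L", "W", "V", "F") || chargedIn)
  stericCoreClash <- buried && wt %in% c("G", "A") &&
    !is.na(dvol) && dvol >= th$steric_volume_pct
  helixBreakPro <- mut == "P" && inHelix
  if (helixBreakPro && !is.na(destab) && !destab)
    notes <- c(notes, "proline in helix flagged despite ddG <= cutoff")

  interfacial <- unname(features["bsa"]) > 0
  inPatch <- !is.na(assignPatch(pos, patches))

  wtClasses <- sidechainHbClasses(wt)
  mutClasses <- sidechainHbClasses(mut)
  losesClass <- (wtClasses["donor"] && !mutClasses["donor"]) ||
    (wtClasses["acceptor"] && !mutClasses["acceptor"])
  reachChange <- abs(SC_HEAVY_ATOMS[wt] - SC_HEAVY_ATOMS[mut]) >=
    th$reach_change
  hbondLoss <- unname(features["hb_num"]) >= 1 &&
    (losesClass || reachChange)

  electrostatic <- inPatch && unname(features["d_charge"]) <= -1
  stericInterface <- interfacial && !is.na(dvol) &&
    dvol >= th$steric_volume_pct

  data.frame(position = pos, wt = wt, mut = mut,
             destabilizing = destab,
             hydrophobic_core_loss = hydrophobicCoreLoss,
             steric_core_clash = stericCoreClash,
             helix_break_proline = helixBreakPro,
             interaction_disrupting = hbondLoss || electrostatic ||
               stericInterface,
             hbond_loss = hbondLoss,
             electrostatic_alteration = electrostatic,
             steric_interface_clash = stericInterface,
             patch = ifelse(inPatch, assignPatch(pos, patches),
                            NA_character_),
             notes = paste(notes, collapse = "; "),
             stringsAsFactors = FALSE)
}

#' Summarise a set of structural-basis classifications
#'
#' @param basis data.frame of rows from [classifyMutation()].
#' @return list with total and per-flag counts, the count and fraction of
#'   destabilising mutations acting through more than one approach, the
#'   same for interaction-disrupting mutations, and the count carrying both
#'   a stability and an interaction basis.
#' @export
summarizeBasis <- function(basis) {
  n <- nrow(basis)
  if (n == 0L) {
    return(list(n = 0L, destabilizing = 0L, approaches = c(
      hydrophobic_core_loss = 0L, steric_core_clash = 0L,
      helix_break_proline = 0L), interaction_disrupting = 0L,
      avenues = c(hbond_loss = 0L, electrostatic_alteration = 0L,
                  steric_interface_clash = 0L),
      multi_approach = 0L, multi_approach_fraction = NA_real_,
      multi_avenue = 0L, multi_avenue_fraction = NA_real_, both = 0L))
  }
  destab <- basis$destabilizing %in% TRUE
  appr <- as.matrix(basis[, c("hydrophobic_core_loss", "steric_core_clash",
                              "helix_break_proline")])
  aven <- as.matrix(basis[, c("hbond_loss", "electrostatic_alteration",
                              "steric_interface_clash")])
  inter <- basis$interaction_disrupting %in% TRUE
  multiAppr <- destab & rowSums(appr) > 1
  multiAven <- inter & rowSums(aven) > 1
  list(n = n,
       destabilizing = sum(destab),
       approaches = colSums(appr),
       interaction_disrupting = sum(inter),
       avenues = colSums(aven),
       multi_approach = sum(multiAppr),
       multi_approach_fraction =
         if (sum(destab)) 100 * sum(multiAppr) / sum(destab) else NA_real_,
       multi_avenue = sum(multiAven),
       multi_avenue_fraction =
         if (sum(inter)) 100 * sum(multiAven) / sum(inter) else NA_real_,
       both = sum(destab & inter))
}
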