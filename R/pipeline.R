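#' Default pipeline thresholds
#'
#' @return named list: `d_max` and `angle_min` (hydrogen bonds),
#'   `bsa_threshold` (interface call), `buried_rsasa`,
#'   `steric_volume_pct`, `reach_change` (rule engine), `rmsf_threshold`
#'   (IDR call), `ddg_cutoff` (destabilisation).
#' @export
pipelineThresholds <- function() {
  list(d_max = 3.5, angle_min = 120, bsa_threshold = 0.1,
       buried_rsasa = 0.2, steric_volume_pct = 30, reach_change = 2,
       rmsf_threshold = 2.0, ddg_cutoff = 1.0)
}

readConservation <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("position", "score") %in% names(d)))
    stop("conservation TSV must have columns position, score")
  stats::setNames(as.numeric(d$score), as.character(d$position))
}

inIntervals <- function(pos, intervals) {
  if (is.null(intervals) || !length(intervals)) return(FALSE)
  if (is.list(intervals)) intervals <- do.call(rbind, intervals)
  any(pos >= intervals[, 1] & pos <= intervals[, 2])
}

writeTsv <- function(d, path) {
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Run the full analysis pipeline from a configuration
#'
#' Wires every stage: structure reading, interface and hydrogen-bond
#' analysis, packed-context rSASA, optional ensemble flexibility, feature
#' extraction, structural-basis classification, group statistics, and
#' (optionally) predictor training with a saturation scan.  Per-stage TSV
#' files and a combined JSON report (with every threshold echoed for
#' provenance) are written under `out_dir`.
#'
#' @param config list or YAML file path.  Fields: `complex` (structure
#'   path), `subject_chain`, `partner_chains`, `mutations` (TSV path),
#'   optional `ddg` (ddG table path), `conservation` (TSV path),
#'   `ensemble` (multi-model PDB path), `helix_intervals` (list of
#'   `c(start, end)`), `thresholds` (overrides of
#'   [pipelineThresholds()]), `train` (logical), `training`
#'   (candidate_features/min_features/...); `seed`; `out_dir`.
#' @param outDir overrides `config$out_dir`.
#' @return invisibly, the report list.
#' @export
runPipeline <- function(config, outDir = NULL) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  known <- c("complex", "subject_chain", "partner_chains", "mutations",
             "ddg", "conservation", "ensemble", "helix_intervals",
             "thresholds", "train", "training", "seed", "out_dir")
  unknown <- setdiff(names(config), known)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  th <- utils::modifyList(pipelineThresholds(),
                          as.list(config$thresholds))
  if (any(unlist(th[c("d_max", "bsa_threshold", "buried_rsasa",
                      "steric_volume_pct", "rmsf_threshold",
                      "ddg_cutoff")]) <= 0))
    stop("thresholds must be positive")
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  outDir <- if (!is.null(outDir)) outDir else config$out_dir
  if (is.null(outDir)) stop("no output directory configured")
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  report <- list(thresholds = th, seed = seed)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  model <- stage("structure", readStructure(config$complex))
  if (is(model, "StructureEnsemble")) model <- model@models[[1]]
  subject <- config$subject_chain
  partners <- config$partner_chains

  iface <- stage("interface",
    interfaceResidues(model, subject, partners,
                      bsaThreshold = th$bsa_threshold))
  writeTsv(iface, file.path(outDir, "interface.tsv"))
  bonds <- stage("hbonds",
    hydrogenBonds(model, subject, partners, dMax = th$d_max,
                  angleMin = th$angle_min))
  writeTsv(bonds, file.path(outDir, "hbonds.tsv"))
  hbCounts <- hbondsPerResidue(bonds, subject)
  rsasaTab <- stage("rsasa", rsasaProfile(model, subject))
  writeTsv(rsasaTab, file.path(outDir, "rsasa.tsv"))
  rsasaVec <- stats::setNames(rsasaTab$rsasa, as.character(rsasaTab$resno))
  report$interface <- list(
    n_interface = sum(iface$is_interface),
    interface_fraction = interfaceFraction(iface, nrow(iface)),
    n_hbonds = nrow(bonds))

  if (!is.null(config$ensemble)) {
    ens <- stage("flexibility", readStructure(config$ensemble))
    prof <- backboneRmsf(ens)
    idr <- callIdrs(prof, th$rmsf_threshold)
    writeTsv(data.frame(resno = prof@resno, rmsf = prof@rmsf),
             file.path(outDir, "rmsf.tsv"))
    writeTsv(idr, file.path(outDir, "idrs.tsv"))
    report$flexibility <- list(n_idrs = nrow(idr))
  }

  muts <- stage("mutations", readMutationTable(config$mutations))
  ddg <- if (!is.null(config$ddg)) stage("ddg", loadDdgTable(config$ddg))
    else NULL
  cons <- if (!is.null(config$conservation))
    stage("conservation", readConservation(config$conservation)) else NULL

  featTab <- stage("features",
    extractFeatureTable(muts, interface = iface, hbondCounts = hbCounts,
                        rsasa = rsasaVec, ddg = ddg,
                        conservation = cons))
  writeTsv(featTab, file.path(outDir, "features.tsv"))

  basisTh <- basisThresholds(ddg_cutoff = th$ddg_cutoff,
                             buried_rsasa = th$buried_rsasa,
                             steric_volume_pct = th$steric_volume_pct,
                             reach_change = th$reach_change)
  basis <- stage("classify", do.call(rbind, lapply(
    seq_len(nrow(featTab)), function(i) {
      pos <- featTab$position[i]
      classifyMutation(
        list(position = pos, wt = featTab$wt[i], mut = featTab$mut[i]),
        unlist(featTab[i, setdiff(names(featTab),
                                  c("position", "wt", "mut", "label"))]),
        context = list(rsasa = featTab$rsasa[i],
                       in_helix = inIntervals(pos,
                                              config$helix_intervals)),
        thresholds = basisTh)
    })))
  basis$destabilizing[is.na(featTab$ddg)] <- NA
  writeTsv(basis, file.path(outDir, "basis.tsv"))
  report$basis <- summarizeBasis(basis)

  lab <- tolower(ifelse(is.na(featTab$label), "", featTab$label))
  if (all(c("dba", "neutral") %in% lab)) {
    cmp <- function(col, alt) {
      x <- featTab[[col]][lab == "dba"]
      y <- featTab[[col]][lab == "neutral"]
      x <- x[!is.na(x)]
      y <- y[!is.na(y)]
      if (!length(x) || !length(y)) return(NULL)
      mannWhitneyOneTailed(x, y, alt)
    }
    report$stats <- list(
      ddg = cmp("ddg", "greater"),       # disease destabilises more
      rsasa = cmp("rsasa", "less"),      # disease sites more buried
      conservation = cmp("conservation", "less"))  # more conserved
  }

  if (isTRUE(config$train)) {
    tcArgs <- as.list(config$training)
    if (is.null(tcArgs$candidate_features))
      tcArgs$candidate_features <- featureRegistry()[1:8]
    tcArgs$seed <- seed
    tc <- do.call(trainingConfig, tcArgs)
    sel <- stage("train", selectFeaturesAndHyperparams(featTab, tc))
    fit <- trainFinal(featTab, sel$features, sel$C, sel$gamma,
                      cvMcc = sel$cv_mcc)
    report$model <- list(features = sel$features, C = sel$C,
                         gamma = sel$gamma, cv_mcc = sel$cv_mcc)
    saveRDS(fit, file.path(outDir, "model.rds"))
  }

  jsonlite::write_json(report, file.path(outDir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(report)
}
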