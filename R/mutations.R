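#' Parse protein missense-mutation notation
#'
#' Accepts three-letter (`Gly127Arg`, optionally `p.Gly127Arg`) and
#' one-letter (`G127R`) notation and normalises to one-letter codes.
#'
#' @param text a single mutation string.
#' @return list with `position` (integer), `wt`, `mut` (one-letter codes).
#' @examples
#' parseProteinMutation("Gly127Arg")
#' parseProteinMutation("K38N")
#' @export
parseProteinMutation <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  s <- sub("^p\\.", "", trimws(text))
  m3 <- regmatches(s, regexec("^([A-Za-z]{3})([0-9]+)([A-Za-z]{3})$", s))[[1]]
  m1 <- regmatches(s, regexec("^([A-Za-z])([0-9]+)([A-Za-z])$", s))[[1]]
  if (length(m3) == 4L) {
    wt <- PROTEIN_3TO1[toupper(m3[2])]
    mut <- PROTEIN_3TO1[toupper(m3[4])]
    pos <- as.integer(m3[3])
  } else if (length(m1) == 4L) {
    wt <- toupper(m1[2])
    mut <- toupper(m1[4])
    pos <- as.integer(m1[3])
    if (!all(c(wt, mut) %in% BLOSUM62_AA)) wt <- NA_character_
  } else {
    stop("cannot parse mutation notation: '", text, "'")
  }
  if (is.na(wt) || is.na(mut))
    stop("unknown residue code in mutation: '", text, "'")
  if (wt == mut)
    stop("synonymous substitution (wild-type equals mutant): '", text, "'")
  list(position = pos, wt = unname(wt), mut = unname(mut))
}

#' Estimate the pathogenic minor-allele-frequency bound
#'
#' For an autosomal-dominant disease with prevalence `p` and a fraction
#' `f` of cases attributable to the gene, heterozygous carriers are
#' affected, so the pathogenic allele frequency is `p * f / 2`.  With a
#' prevalence range the estimate is a range.
#'
#' @param prevalence_low,prevalence_high disease prevalence per individual.
#' @param gene_fraction fraction of cases caused by the gene.
#' @param inheritance only `"dominant"` is supported.
#' @return named numeric `c(maf_low, maf_high)`.
#' @examples
#' estimatePathogenicMaf(5e-6, 7e-6, 0.25)  # 6.25e-07 8.75e-07
#' @export
estimatePathogenicMaf <- function(prevalence_low, prevalence_high,
                                  gene_fraction,
                                  inheritance = c("dominant")) {
  inheritance <- match.arg(inheritance)
  stopifnot(prevalence_low >= 0, prevalence_high >= prevalence_low,
            gene_fraction >= 0, gene_fraction <= 1)
  c(maf_low = prevalence_low * gene_fraction / 2,
    maf_high = prevalence_high * gene_fraction / 2)
}

#' Read a mutation table (TSV)
#'
#' Columns: `position`, `wt`, `mut` (one-letter), optional `label`
#' (`dba`/`neutral`/`unlabeled`), `patient_count`, `clinvar`, `functional`
#' (logical), `af` (allele frequency).
#'
#' @param path TSV file path.
#' @return data.frame with normalised columns.
#' @export
readMutationTable <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("position", "wt", "mut")
  if (!all(need %in% names(d)))
    stop("mutation table must have columns: ", paste(need, collapse = ", "))
  d$position <- as.integer(d$position)
  d$wt <- toupper(d$wt)
  d$mut <- toupper(d$mut)
  if (any(d$wt == d$mut))
    stop("synonymous rows (wt == mut) in mutation table")
  for (col in c("label", "clinvar")) if (is.null(d[[col]]))
    d[[col]] <- NA_character_
  if (is.null(d$patient_count)) d$patient_count <- NA_integer_
  if (is.null(d$functional)) d$functional <- NA
  if (is.null(d$af)) d$af <- NA_real_
  d
}

#' Select positive (disease) mutations by the curation criteria
#'
#' A record is kept when it meets at least one of: (1) identified in more
#' than one patient; (2) annotated "Pathogenic" or "Likely pathogenic";
#' (3) experimentally confirmed to affect physiological function.
#'
#' @param records mutation data.frame (see [readMutationTable()]).
#' @return the qualifying subset, with `label` set to `"dba"`.
#' @export
selectPositives <- function(records) {
  pc <- records$patient_count
  cv <- tolower(ifelse(is.na(records$clinvar), "", records$clinvar))
  fn <- records$functional
  keep <- (!is.na(pc) & pc > 1) |
    cv %in% c("pathogenic", "likely pathogenic") |
    (!is.na(fn) & fn)
  out <- records[keep, , drop = FALSE]
  out$label <- "dba"
  rownames(out) <- NULL
  out
}

#' Select negative (presumed-neutral) population variants
#'
#' Keeps variants whose allele frequency is at least `10^ordersOfMagnitude`
#' times the upper pathogenic-MAF bound and which are not on the explicit
#' disease-mutation exclusion list.
#'
#' @param variants mutation data.frame with an `af` column.
#' @param mafUpper upper bound of the pathogenic MAF estimate.
#' @param exclusion character vector of excluded mutations in any notation
#'   accepted by [parseProteinMutation()].
#' @param ordersOfMagnitude required margin above `mafUpper` (default 1).
#' @return the qualifying subset, with `label` set to `"neutral"`.
#' @export
selectNegatives <- function(variants, mafUpper, exclusion = character(0),
                            ordersOfMagnitude = 1) {
  stopifnot(mafUpper >= 0)
  thr <- mafUpper * 10^ordersOfMagnitude
  exKey <- vapply(exclusion, function(e) {
    p <- parseProteinMutation(e)
    paste0(p$wt, p$position, p$mut)
  }, character(1))
  key <- paste0(variants$wt, variants$position, variants$mut)
  keep <- !is.na(variants$af) & variants$af >= thr & !(key %in% exKey)
  out <- variants[keep, , drop = FALSE]
  out$label <- "neutral"
  rownames(out) <- NULL
  out
}
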