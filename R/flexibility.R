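# Kabsch least-squares superposition: returns `moving` aligned onto `fixed`
kabschAlign <- function(moving, fixed) {
  cm <- colMeans(moving)
  cf <- colMeans(fixed)
  P <- sweep(moving, 2, cm)
  Q <- sweep(fixed, 2, cf)
  s <- svd(crossprod(P, Q))
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  sweep(P %*% t(R), 2, cf, "+")
}

# backbone (N, CA, C, O) atom row indices of a protein model
backboneIdx <- function(model) {
  a <- model@atoms
  which(a$kind == "protein" & a$elety %in% c("N", "CA", "C", "O"))
}

#' Per-residue backbone RMSF of a conformational ensemble
#'
#' Each model's backbone (N, CA, C, O) is least-squares superposed onto the
#' average conformation (computed self-consistently: superpose, re-average,
#' repeat); the RMSF of residue i is the root mean square deviation of its
#' backbone atoms from the reference over all models.
#'
#' @param ensemble a [StructureEnsemble-class] with at least 2 models.
#' @param maxIter iterations of the superpose/re-average loop.
#' @return a [FlexibilityProfile-class].
#' @export
backboneRmsf <- function(ensemble, maxIter = 5) {
  stopifnot(is(ensemble, "StructureEnsemble"))
  if (length(ensemble@models) < 2L) stop("need at least 2 models")
  idx <- backboneIdx(ensemble@models[[1]])
  if (!length(idx)) stop("no protein backbone atoms present")
  X <- lapply(ensemble@models, function(m) coords(m)[idx, , drop = FALSE])
  ref <- X[[1]]
  for (iter in seq_len(maxIter)) {
    X <- lapply(X, kabschAlign, fixed = ref)
    newRef <- Reduce(`+`, X) / length(X)
    if (max(abs(newRef - ref)) < 1e-6 && iter > 1) { ref <- newRef; break }
    ref <- newRef
  }
  # squared deviation from reference, averaged over models
  dev2 <- Reduce(`+`, lapply(X, function(x) rowSums((x - ref)^2))) /
    length(X)
  a <- ensemble@models[[1]]@atoms[idx, , drop = FALSE]
  key <- paste(a$chain, a$resno, a$insert, sep = "\r")
  perRes <- rowsum(dev2, key, reorder = FALSE)
  cnt <- rowsum(rep(1, length(dev2)), key, reorder = FALSE)
  first <- !duplicated(key)
  new("FlexibilityProfile",
      rmsf = sqrt(perRes[, 1] / cnt[, 1]),
      resno = as.integer(a$resno[first]),
      reference = ref)
}

#' Call intrinsically disordered regions from an RMSF profile
#'
#' Maximal runs of residues with RMSF above the threshold, restricted to
#' the middle of the chain (the first and last residues are never part of
#' an IDR call, so terminal fraying is not reported as disorder).
#'
#' @param profile a [FlexibilityProfile-class].
#' @param threshold RMSF threshold in Angstrom (2.0).
#' @return data.frame of closed residue-number intervals (`start`, `end`);
#'   zero rows when nothing exceeds the threshold.
#' @export
callIdrs <- function(profile, threshold = 2.0) {
  stopifnot(is(profile, "FlexibilityProfile"))
  resno <- profile@resno
  hot <- profile@rmsf > threshold
  hot[resno == min(resno)] <- FALSE
  hot[resno == max(resno)] <- FALSE
  if (!any(hot))
    return(data.frame(start = integer(0), end = integer(0)))
  r <- rle(hot)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(start = resno[starts[keep]], end = resno[ends[keep]])
}

# classic DBSCAN on a precomputed distance matrix; labels 0 = noise
dbscanDist <- function(D, eps, minPts) {
  n <- nrow(D)
  labels <- rep(NA_integer_, n)
  cl <- 0L
  nb <- lapply(seq_len(n), function(i) which(D[i, ] <= eps))
  core <- vapply(nb, length, integer(1)) >= minPts
  for (i in seq_len(n)) {
    if (!is.na(labels[i]) || !core[i]) next
    cl <- cl + 1L
    labels[i] <- cl
    queue <- setdiff(nb[[i]], i)
    while (length(queue)) {
      j <- queue[1]
      queue <- queue[-1]
      if (is.na(labels[j]) || labels[j] == 0L) {
        expand <- is.na(labels[j]) && core[j]
        labels[j] <- cl
        if (expand) queue <- union(queue, setdiff(nb[[j]], i))
      }
    }
  }
  labels[is.na(labels)] <- 0L
  labels
}

#' Density-based clustering of ensemble conformations
#'
#' DBSCAN on the pairwise backbone-RMSD matrix (each pair superposed by
#' Kabsch least squares before the RMSD is taken).  The representative of a
#' cluster is its medoid (minimum summed RMSD to the other members) and the
#' occupancy is the member count over the total model count, so occupancies
#' sum to at most 1 (noise models carry label 0).
#'
#' @param ensemble a [StructureEnsemble-class].
#' @param rmsdCutoff DBSCAN neighbourhood radius in Angstrom (2.0).
#' @param minPoints DBSCAN core-point threshold, counting the point itself.
#' @return list with `labels` (integer per model, 0 = noise),
#'   `representatives` (named integer, model index per cluster),
#'   `occupancy` (named numeric), and `rmsd` (the model x model matrix).
#' @export
clusterConformations <- function(ensemble, rmsdCutoff = 2.0, minPoints = 4) {
  stopifnot(is(ensemble, "StructureEnsemble"))
  n <- length(ensemble@models)
  if (n < 2L) stop("need at least 2 models to cluster")
  idx <- backboneIdx(ensemble@models[[1]])
  X <- lapply(ensemble@models, function(m) coords(m)[idx, , drop = FALSE])
  D <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      al <- kabschAlign(X[[i]], X[[j]])
      D[i, j] <- D[j, i] <- sqrt(mean(rowSums((al - X[[j]])^2)))
    }
  }
  labels <- dbscanDist(D, rmsdCutoff, minPoints)
  ids <- sort(unique(labels[labels > 0]))
  reps <- vapply(ids, function(cl) {
    members <- which(labels == cl)
    members[which.min(rowSums(D[members, members, drop = FALSE]))]
  }, integer(1))
  occ <- vapply(ids, function(cl) sum(labels == cl) / n, numeric(1))
  names(reps) <- names(occ) <- as.character(ids)
  list(labels = labels, representatives = reps, occupancy = occ, rmsd = D)
}

#' Simplify an 8-state secondary-structure string to 3 states
#'
#' Positionwise mapping: G/H/I to H (helix), B/E to E (sheet), T/S/C and
#' blank (or `-`) to C (coil).
#'
#' @param ss8 character string over the 8-state DSSP alphabet.
#' @return string over `{H, E, C}` of the same length.
#' @export
simplifySs <- function(ss8) {
  if (!nzchar(ss8)) return("")
  ch <- strsplit(ss8, "")[[1]]
  bad <- setdiff(unique(ch), c("G", "H", "I", "B", "E", "T", "S", "C",
                               " ", "-"))
  if (length(bad))
    stop("unknown secondary-structure code(s): ",
         paste(bad, collapse = ", "))
  out <- rep("C", length(ch))
  out[ch %in% c("G", "H", "I")] <- "H"
  out[ch %in% c("B", "E")] <- "E"
  paste(out, collapse = "")
}
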