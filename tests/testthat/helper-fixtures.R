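# build a StructureModel from bare atom specs
atomModel <- function(x, y, z, elesy = "C", elety = NULL, chain = "A",
                      resno = NULL, resid = "UNL", kind = "other") {
  n <- length(x)
  if (is.null(elety)) elety <- paste0(elesy, seq_len(n))
  if (is.null(resno)) resno <- rep(1L, n)
  new("StructureModel",
      atoms = data.frame(chain = rep_len(chain, n),
                         resno = as.integer(rep_len(resno, n)),
                         insert = "", resid = rep_len(resid, n),
                         elety = elety, elesy = rep_len(elesy, n),
                         x = x, y = y, z = z,
                         kind = rep_len(kind, n),
                         stringsAsFactors = FALSE))
}

# Monte-Carlo SASA oracle: uniform random points on each expanded sphere,
# rejection against all other expanded spheres; independent of the
# golden-spiral implementation path
mcSasaOracle <- function(model, probe = 1.4, nMc = 1e5, seed = 42,
                         radii = vdwRadii()) {
  xyz <- coords(model)
  r <- unname(radii[toupper(model@atoms$elesy)]) + probe
  n <- nrow(xyz)
  set.seed(seed)
  out <- numeric(n)
  for (i in seq_len(n)) {
    # uniform directions via normalised Gaussians
    g <- matrix(stats::rnorm(3 * nMc), ncol = 3)
    g <- g / sqrt(rowSums(g^2))
    p <- sweep(g * r[i], 2, xyz[i, ], "+")
    free <- rep(TRUE, nMc)
    for (j in seq_len(n)[-i]) {
      d2 <- (p[, 1] - xyz[j, 1])^2 + (p[, 2] - xyz[j, 2])^2 +
            (p[, 3] - xyz[j, 3])^2
      free <- free & d2 > r[j]^2
    }
    out[i] <- mean(free) * 4 * pi * r[i]^2
  }
  out
}

# exhaustive-pair hydrogen-bond oracle: plain double loop over every atom
# pair across the two chain groups using the published role tables
bruteHbondOracle <- function(model, groupA, groupB, dMax = 3.5) {
  a <- model@atoms
  xyz <- coords(model)
  pairs <- character(0)
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(nrow(a))) {
      inAB <- (a$chain[i] %in% groupA && a$chain[j] %in% groupB) ||
              (a$chain[i] %in% groupB && a$chain[j] %in% groupA)
      if (!inAB) next
      ri <- hbondRoles(a$resid[i])[a$elety[i]]
      rj <- hbondRoles(a$resid[j])[a$elety[j]]
      if (is.null(ri) || is.na(ri) || is.null(rj) || is.na(rj)) next
      if (!(ri %in% c("donor", "both") && rj %in% c("acceptor", "both")))
        next
      if (sqrt(sum((xyz[i, ] - xyz[j, ])^2)) > dMax) next
      key <- paste(sort(c(paste(a$chain[i], a$resno[i], a$elety[i]),
                          paste(a$chain[j], a$resno[j], a$elety[j]))),
                   collapse = "|")
      pairs <- c(pairs, key)
    }
  }
  sort(unique(pairs))
}

# canonical atom-pair keys of a hydrogenBonds() result, for oracle equality
hbondPairKeys <- function(bonds) {
  if (!nrow(bonds)) return(character(0))
  sort(apply(cbind(
    paste(bonds$donor_chain, bonds$donor_resno, bonds$donor_atom),
    paste(bonds$acceptor_chain, bonds$acceptor_resno,
          bonds$acceptor_atom)), 1,
    function(z) paste(sort(z), collapse = "|")))
}

# exact one-tailed Mann-Whitney p by enumerating all label arrangements
exactMannWhitneyOracle <- function(x, y) {
  pooled <- c(x, y)
  nx <- length(x)
  u <- function(xs, ys) sum(outer(xs, ys, "<")) + 0.5 * sum(outer(xs, ys, "=="))
  uObs <- u(x, y)
  combos <- utils::combn(length(pooled), nx)
  us <- apply(combos, 2, function(idx) u(pooled[idx], pooled[-idx]))
  # alternative "less": small U (few x > y ... here u counts x<y pairs)
  mean(us >= uObs)
}

# apply a rigid-body rotation + translation to every model of an ensemble
rigidTransformEnsemble <- function(ens, angle = 0.7, shift = c(5, -3, 2)) {
  R <- rbind(c(cos(angle), -sin(angle), 0),
             c(sin(angle), cos(angle), 0),
             c(0, 0, 1))
  models <- lapply(ens@models, function(m) {
    xyz <- coords(m) %*% t(R)
    m@atoms$x <- xyz[, 1] + shift[1]
    m@atoms$y <- xyz[, 2] + shift[2]
    m@atoms$z <- xyz[, 3] + shift[3]
    m
  })
  new("StructureEnsemble", models = models)
}
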