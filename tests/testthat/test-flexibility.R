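test_that("identical models give zero RMSF everywhere", {
  ens <- makeEnsemble(nModels = 5, nResidues = 10, sigmaRigid = 0,
                      sigmaFloppy = 0, seed = 1)
  prof <- backboneRmsf(ens)
  expect_true(all(prof@rmsf < 1e-9))
})

test_that("planted jitter reproduces the sigma*sqrt(3) expectation", {
  sigma <- 0.5
  ens <- makeEnsemble(nModels = 500, nResidues = 20,
                      floppyIntervals = list(c(10, 10)),
                      sigmaRigid = 0.05, sigmaFloppy = sigma, seed = 8)
  prof <- backboneRmsf(ens)
  target <- sigma * sqrt(3)
  expect_lt(abs(prof@rmsf[10] - target) / target, 0.1)
  expect_gt(prof@rmsf[10], max(prof@rmsf[-(9:11)]))
})

test_that("RMSF is invariant under a global rigid-body transform", {
  ens <- makeEnsemble(nModels = 30, nResidues = 15,
                      floppyIntervals = list(c(6, 9)), seed = 3)
  prof <- backboneRmsf(ens)
  prof2 <- backboneRmsf(rigidTransformEnsemble(ens))
  expect_equal(prof2@rmsf, prof@rmsf, tolerance = 1e-6)
})

test_that("IDR calling returns maximal runs excluding chain termini", {
  mk <- function(rmsf) new("FlexibilityProfile", rmsf = rmsf,
                           resno = seq_along(rmsf),
                           reference = matrix(0, 1, 3))
  expect_equal(nrow(callIdrs(mk(rep(1, 60)))), 0)
  r <- rep(0.5, 60)
  r[30:55] <- 3
  expect_equal(callIdrs(mk(r)), data.frame(start = 30, end = 55))
  # three planted regions
  r3 <- rep(0.5, 80)
  r3[c(10:20, 35:50, 62:66)] <- 2.5
  expect_equal(callIdrs(mk(r3)),
               data.frame(start = c(10, 35, 62), end = c(20, 50, 66)))
  # a hot terminus is not disorder
  rTerm <- rep(3, 10)
  expect_equal(callIdrs(mk(rTerm)), data.frame(start = 2, end = 9))
})

test_that("IDR recovery from a generated ensemble is exact", {
  ens <- makeEnsemble(nModels = 200, nResidues = 60,
                      floppyIntervals = list(c(30, 55)), seed = 5)
  idr <- callIdrs(backboneRmsf(ens))
  expect_equal(idr, data.frame(start = 30, end = 55))
  # equal sigmas plant nothing
  flat <- makeEnsemble(nModels = 100, nResidues = 30,
                       floppyIntervals = list(c(10, 20)),
                       sigmaFloppy = 0.3, seed = 5)
  expect_equal(nrow(callIdrs(backboneRmsf(flat))), 0)
})

test_that("two well-separated conformers cluster 50/50 with medoids", {
  a <- makeEnsemble(nModels = 20, nResidues = 12, sigmaRigid = 0.05,
                    seed = 1)
  bBase <- makeEnsemble(nModels = 20, nResidues = 12, sigmaRigid = 0.05,
                        seed = 2)
  # second conformer: axially stretched helix, far beyond the 2 A cutoff
  b <- new("StructureEnsemble", models = lapply(bBase@models, function(m) {
    m@atoms$z <- m@atoms$z * 2.5
    m
  }))
  ens <- new("StructureEnsemble", models = c(a@models, b@models))
  cl <- clusterConformations(ens, rmsdCutoff = 2, minPoints = 4)
  expect_length(cl$occupancy, 2)
  expect_equal(sort(unname(cl$occupancy)), c(0.5, 0.5))
  expect_true(all(cl$representatives %in% seq_along(ens@models)))
  # representative is a member of its own cluster
  for (id in names(cl$representatives)) {
    expect_equal(cl$labels[cl$representatives[[id]]], as.integer(id))
  }
})

test_that("an all-identical ensemble is one cluster of occupancy 1", {
  ens <- makeEnsemble(nModels = 8, nResidues = 10, sigmaRigid = 0,
                      sigmaFloppy = 0, seed = 1)
  cl <- clusterConformations(ens)
  expect_equal(unname(cl$occupancy), 1.0)
})

test_that("clustering is invariant to model order and matches an RMSD oracle", {
  ens <- makeEnsemble(nModels = 12, nResidues = 10, sigmaRigid = 0.2,
                      seed = 7)
  cl <- clusterConformations(ens)
  perm <- c(7, 1, 12, 3, 9, 5, 11, 2, 8, 4, 10, 6)
  clP <- clusterConformations(new("StructureEnsemble",
                                  models = ens@models[perm]))
  expect_equal(clP$labels, cl$labels[perm])
  # pairwise backbone RMSD equals bio3d's superposition-based rmsd
  i <- 3; j <- 9
  bb <- function(m) {
    idx <- which(m@atoms$elety %in% c("N", "CA", "C", "O"))
    as.numeric(t(coords(m)[idx, ]))
  }
  oracle <- bio3d::rmsd(bb(ens@models[[i]]), bb(ens@models[[j]]),
                        fit = TRUE)
  expect_equal(cl$rmsd[i, j], oracle, tolerance = 1e-3)
})

test_that("8-state secondary structure simplifies positionwise", {
  expect_equal(simplifySs("HHHGGG"), "HHHHHH")
  expect_equal(simplifySs("BETS"), "EECC")
  expect_equal(simplifySs(""), "")
  expect_equal(simplifySs("GHIBETSC -"), "HHHEECCCCC")
  expect_error(simplifySs("HQX"), "unknown")
})
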