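test_that("planted contact residues are exactly the interface calls", {
  m <- makeToyComplex(nResidues = 12, contactPositions = c(5, 9),
                      hbondPositions = 5)
  rec <- interfaceResidues(m, "A", "B")
  expect_equal(nrow(rec), 12)
  expect_setequal(rec$resno[rec$is_interface], c(5, 9))
  expect_true(all(rec$bsa >= 0))
  expect_true(all(rec$rbsa <= 1 + 1e-9))
  expect_true(all(grepl("B", rec$partner_chains[rec$is_interface])))
})

test_that("chains far apart yield an empty interface", {
  m <- makeToyComplex(nResidues = 8)   # only the remote nucleotide
  rec <- interfaceResidues(m, "A", "B")
  expect_false(any(rec$is_interface))
  expect_equal(interfaceFraction(rec, 8), 0)
})

test_that("interface fraction is a plain percentage of chain length", {
  m <- makeToyComplex(nResidues = 12, contactPositions = c(5, 9),
                      hbondPositions = 5)
  rec <- interfaceResidues(m, "A", "B")
  expect_equal(interfaceFraction(rec, 12), 100 * 2 / 12)
  rec$is_interface <- TRUE
  expect_equal(interfaceFraction(rec, 12), 100)
  # the published ratio: 75 of 145 residues
  expect_equal(round(100 * 75 / 145, 1), 51.7)
})

test_that("subject chain may not be its own partner", {
  m <- makeToyComplex(nResidues = 6)
  expect_error(interfaceResidues(m, "A", c("A", "B")), "must not")
  expect_error(interfaceResidues(m, "A", "Q"), "not in model")
})

test_that("hydrogen-bond detection matches the exhaustive-pair oracle", {
  for (spec in list(list(n = 12, contacts = c(5, 9), hb = c(5, 9)),
                    list(n = 15, contacts = c(4, 8, 12), hb = 8),
                    list(n = 10, contacts = integer(0),
                         hb = integer(0)))) {
    m <- makeToyComplex(nResidues = spec$n,
                        contactPositions = spec$contacts,
                        hbondPositions = spec$hb, seed = spec$n)
    bonds <- hydrogenBonds(m, "A", "B")
    expect_identical(hbondPairKeys(bonds), bruteHbondOracle(m, "A", "B"))
    expect_setequal(bonds$donor_resno, spec$hb)
  }
})

test_that("bond distance cutoff is respected", {
  # Ser OG donor against a lone phosphate oxygen at 2.9 vs 4.2 A
  near <- atomModel(c(0, 2.9), c(0, 0), c(0, 0), elesy = "O",
                    elety = c("OG", "OP1"), chain = c("A", "B"),
                    resno = c(1, 2), resid = c("SER", "U"),
                    kind = c("protein", "rna"))
  far <- near
  far@atoms$x[2] <- 4.2
  expect_equal(nrow(hydrogenBonds(near, "A", "B")), 1)
  expect_equal(nrow(hydrogenBonds(far, "A", "B")), 0)
})

test_that("explicit hydrogens enforce the D-H...A angle criterion", {
  # donor N with H pointing toward (good) or away from (bad) the acceptor
  good <- atomModel(c(0, 1.0, 2.9), c(0, 0, 0), c(0, 0, 0),
                    elesy = c("N", "H", "O"), elety = c("N", "H", "OP1"),
                    chain = c("A", "A", "B"), resno = c(1, 1, 2),
                    resid = c("GLY", "GLY", "U"),
                    kind = c("protein", "protein", "rna"))
  bad <- good
  bad@atoms$x[2] <- -1.0
  expect_equal(nrow(hydrogenBonds(good, "A", "B")), 1)
  expect_equal(nrow(hydrogenBonds(bad, "A", "B")), 0)
})

test_that("per-residue bond counts conserve the total bond count", {
  m <- makeToyComplex(nResidues = 15, contactPositions = c(4, 8, 12),
                      hbondPositions = c(4, 8, 12))
  bonds <- hydrogenBonds(m, "A", "B")
  byRes <- hbondsPerResidue(bonds, "A")
  expect_equal(sum(byRes), nrow(bonds))
  expect_equal(unname(byRes[c("4", "8", "12")]), c(1L, 1L, 1L))
  expect_equal(sum(hbondsPerResidue(bonds, "B")), nrow(bonds))
})

test_that("patch assignment transcribes the published residue sets", {
  expect_equal(assignPatch(38), "I")
  expect_equal(assignPatch(59), "II")
  expect_equal(assignPatch(91), "III")
  expect_equal(assignPatch(120), "IV")
  expect_equal(assignPatch(c(2, 5, 9, 65, 135)), rep("V", 5))
  expect_true(is.na(assignPatch(200)))
  pd <- patchDefinitions()
  expect_named(pd, c("I", "II", "III", "IV", "V"))
  # 46 residues listed across the five patches, none duplicated
  all <- unlist(lapply(pd, `[[`, "protein_residues"))
  expect_equal(anyDuplicated(all), 0L)
})
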