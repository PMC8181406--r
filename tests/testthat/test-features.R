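test_that("ddG tables load from both dialects with duplicate handling", {
  tsv <- withr::local_tempfile(fileext = ".tsv", lines = c(
    "position\tmut\tddg", "127\tR\t18.72", "127\tE\t17.12", "55\tM\t1.9"))
  d <- loadDdgTable(tsv)
  expect_equal(nrow(d), 3)
  expect_equal(ddgOf(d, 127, "R"), 18.72)
  ps <- withr::local_tempfile(lines = c("GLYA127R\t18.72",
                                        "G127E 17.12", "SA59F\t3.4"))
  d2 <- loadDdgTable(ps)
  expect_equal(ddgOf(d2, 127, "E"), 17.12)
  expect_equal(ddgOf(d2, 59, "F"), 3.4)
  expect_true(is.na(ddgOf(d2, 1, "A")))
  dup <- withr::local_tempfile(lines = c("G127R 1.0", "G127R 2.0"))
  expect_warning(d3 <- loadDdgTable(dup), "duplicate")
  expect_equal(ddgOf(d3, 127, "R"), 2.0)
  bad <- withr::local_tempfile(lines = c("G127R 1.0", "oops"))
  expect_error(loadDdgTable(bad), "line 2")
})

test_that("feature extraction reads interface context and tables correctly", {
  m <- makeToyComplex(nResidues = 12, contactPositions = c(5, 9),
                      hbondPositions = c(5, 9))
  iface <- interfaceResidues(m, "A", "B")
  hb <- hbondsPerResidue(hydrogenBonds(m, "A", "B"), "A")
  rsasa <- setNames(rsasaProfile(m, "A")$rsasa, 1:12)
  ddg <- data.frame(position = 5, mut = "F", ddg = 2.2)
  class(ddg) <- c("ddg_table", "data.frame")
  cons <- setNames(rep(-0.5, 12), 1:12)

  fv <- extractFeatures(list(position = 5, wt = "S", mut = "F"),
                        interface = iface, hbondCounts = hb,
                        rsasa = rsasa, ddg = ddg, conservation = cons)
  expect_named(fv, featureRegistry(), ignore.order = FALSE)
  expect_gt(fv[["bsa"]], 0)
  expect_equal(fv[["hb_num"]], 1)
  expect_equal(fv[["ddg"]], 2.2)
  expect_equal(fv[["d_charge"]], 0)
  expect_equal(fv[["conservation"]], -0.5)
  expect_equal(fv[["in_patch"]], 1)   # residue 5 sits in patch V
  expect_equal(fv[["is_proline_sub"]], 0)

  # non-interface residue: bsa = rbsa = hb_num = 0, missing ddG stays NA
  fv2 <- extractFeatures(list(position = 3, wt = "A", mut = "P"),
                         interface = iface, hbondCounts = hb,
                         rsasa = rsasa, ddg = ddg)
  expect_equal(unname(fv2[c("bsa", "rbsa", "hb_num")]), c(0, 0, 0))
  expect_true(is.na(fv2[["ddg"]]))
  expect_equal(fv2[["is_proline_sub"]], 1)

  # purity: identical inputs give the identical vector
  expect_identical(fv, extractFeatures(list(position = 5, wt = "S",
                                            mut = "F"),
                                       interface = iface, hbondCounts = hb,
                                       rsasa = rsasa, ddg = ddg,
                                       conservation = cons))
})

test_that("positions absent from the structure are reported as errors", {
  m <- makeToyComplex(nResidues = 6)
  iface <- interfaceResidues(m, "A", "B")
  expect_error(extractFeatures(list(position = 99, wt = "A", mut = "V"),
                               interface = iface),
               "not resolvable")
  expect_error(extractFeatures(list(position = 2, wt = "W", mut = "R"),
                               interface = iface),
               "wild-type mismatch")
})

test_that("planted hydrogen-bond counts flow into hb_num", {
  m <- makeToyComplex(nResidues = 12, contactPositions = c(5, 9),
                      hbondPositions = c(5, 9))
  iface <- interfaceResidues(m, "A", "B")
  counts <- c("5" = 2L)   # residue 5 planted with two bonds
  fv <- extractFeatures(list(position = 5, wt = "S", mut = "A"),
                        interface = iface, hbondCounts = counts)
  expect_equal(fv[["hb_num"]], 2)
})

test_that("the surrogate ddG estimator is monotone in burial and clash", {
  expect_gt(surrogateDdg("G", "R", rsasa = 0),
            surrogateDdg("G", "R", rsasa = 0.8))
  expect_gt(surrogateDdg("L", "D", 0.1), 0)
  # more hydrophobic and no larger: no penalty from either term
  expect_equal(surrogateDdg("L", "I", 0.1), 0)
})
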