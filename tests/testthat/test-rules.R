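mkFeatures <- function(pos, wt, mut, bsa = 0, hb = 0, ddg = NA,
                       rsasa = 0.5) {
  fv <- extractFeatures(list(position = pos, wt = wt, mut = mut))
  fv["bsa"] <- bsa
  fv["rbsa"] <- if (bsa > 0) 0.3 else 0
  fv["hb_num"] <- hb
  fv["ddg"] <- ddg
  fv["rsasa"] <- rsasa
  fv
}

test_that("a buried Gly-to-Arg core mutation carries both stability approaches", {
  fv <- mkFeatures(127, "G", "R", ddg = 18.72, rsasa = 0)
  b <- classifyMutation(list(position = 127, wt = "G", mut = "R"), fv,
                        context = list(rsasa = 0, in_helix = TRUE))
  expect_true(b$destabilizing)
  expect_true(b$steric_core_clash)
  expect_true(b$hydrophobic_core_loss)  # charged side chain enters the core
  expect_false(b$interaction_disrupting)
})

test_that("an interface Ser-to-Phe mutation clashes and loses its bond", {
  fv <- mkFeatures(59, "S", "F", bsa = 25, hb = 1, ddg = 0.4,
                   rsasa = 0.45)
  b <- classifyMutation(list(position = 59, wt = "S", mut = "F"), fv,
                        context = list(in_helix = TRUE))
  expect_true(b$steric_interface_clash)   # +113% volume at the interface
  expect_true(b$hbond_loss)               # OG donor/acceptor lost
  expect_false(b$electrostatic_alteration)
  expect_equal(b$patch, "II")
  expect_true(b$interaction_disrupting)
  expect_false(b$destabilizing)
})

test_that("patch arginine losses flag the electrostatic avenue", {
  fv <- mkFeatures(62, "R", "W", bsa = 15, hb = 0, ddg = 0.2,
                   rsasa = 0.5)
  b <- classifyMutation(list(position = 62, wt = "R", mut = "W"), fv,
                        context = list(in_helix = FALSE))
  expect_true(b$electrostatic_alteration)
  expect_equal(fv[["d_charge"]], -1)
})

test_that("a bland surface mutation gets an empty basis", {
  fv <- mkFeatures(30, "T", "S", ddg = 0.1, rsasa = 0.8)
  b <- classifyMutation(list(position = 30, wt = "T", mut = "S"), fv,
                        context = list(in_helix = FALSE))
  expect_false(b$destabilizing)
  expect_false(any(unlist(b[c("hydrophobic_core_loss", "steric_core_clash",
                              "helix_break_proline", "hbond_loss",
                              "electrostatic_alteration",
                              "steric_interface_clash")])))
})

test_that("proline in a helix is flagged even below the ddG cutoff", {
  fv <- mkFeatures(64, "L", "P", ddg = 0.5, rsasa = 0.3)
  b <- classifyMutation(list(position = 64, wt = "L", mut = "P"), fv,
                        context = list(in_helix = TRUE))
  expect_true(b$helix_break_proline)
  expect_false(b$destabilizing)
  expect_match(b$notes, "despite")
  # outside a helix the flag stays off
  b2 <- classifyMutation(list(position = 64, wt = "L", mut = "P"), fv,
                         context = list(in_helix = FALSE))
  expect_false(b2$helix_break_proline)
})

test_that("classification is threshold-monotone in ddG", {
  for (ddg in c(0.5, 1.01, 5, 20)) {
    fv <- mkFeatures(40, "L", "R", ddg = ddg, rsasa = 0.1)
    b <- classifyMutation(list(position = 40, wt = "L", mut = "R"), fv,
                          context = list(in_helix = FALSE))
    expect_equal(b$destabilizing, ddg > 1.0)
  }
})

test_that("missing ddG leaves the stability call open, not FALSE", {
  fv <- mkFeatures(40, "L", "R", ddg = NA, rsasa = 0.1)
  b <- classifyMutation(list(position = 40, wt = "L", mut = "R"), fv,
                        context = list(in_helix = FALSE))
  expect_true(is.na(b$destabilizing))
  expect_match(b$notes, "unavailable")
})

test_that("planted flags aggregate exactly in the summary", {
  set.seed(31)
  n <- 51
  plant <- data.frame(
    position = sample(145, n, replace = TRUE), wt = "L", mut = "R",
    destabilizing = sample(c(TRUE, FALSE), n, TRUE),
    hydrophobic_core_loss = sample(c(TRUE, FALSE), n, TRUE),
    steric_core_clash = sample(c(TRUE, FALSE), n, TRUE),
    helix_break_proline = sample(c(TRUE, FALSE), n, TRUE),
    hbond_loss = sample(c(TRUE, FALSE), n, TRUE),
    electrostatic_alteration = sample(c(TRUE, FALSE), n, TRUE),
    steric_interface_clash = sample(c(TRUE, FALSE), n, TRUE))
  plant$interaction_disrupting <- plant$hbond_loss |
    plant$electrostatic_alteration | plant$steric_interface_clash
  s <- summarizeBasis(plant)
  expect_equal(s$n, n)
  expect_equal(s$destabilizing, sum(plant$destabilizing))
  expect_equal(unname(s$approaches["steric_core_clash"]),
               sum(plant$steric_core_clash))
  expect_equal(s$both, sum(plant$destabilizing &
                           plant$interaction_disrupting))
  # two destabilising mutations, one multi-approach: 50% overlap
  two <- plant[0, ]
  two[1, ] <- list(1, "L", "R", TRUE, TRUE, TRUE, FALSE, FALSE, FALSE,
                   FALSE, FALSE)
  two[2, ] <- list(2, "L", "R", TRUE, TRUE, FALSE, FALSE, FALSE, FALSE,
                   FALSE, FALSE)
  expect_equal(summarizeBasis(two)$multi_approach_fraction, 50)
  expect_equal(summarizeBasis(plant[0, ])$n, 0)
})
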