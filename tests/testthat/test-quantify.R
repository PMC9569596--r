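test_that("internal-standard quantification follows the ratio formula", {
  expect_equal(quantify_species(100, 100, 5), 5)
  expect_equal(quantify_species(200, 100, 5), 10)
  expect_equal(quantify_species(0, 100, 5), 0)
  expect_equal(quantify_species(c(50, 150), 100, 2), c(1, 3))
  expect_error(quantify_species(10, 0, 5), "positive")
  expect_error(quantify_species(10, -1, 5), "positive")
  expect_error(quantify_species(-1, 100, 5), "nonnegative")
})

test_that("class concentrations are member-species sums", {
  m <- matrix(c(1, 2, 4), nrow = 3,
              dimnames = list(c("TG(50:1) FA 16:0", "TG(52:2) FA 18:1",
                                "CE(18:1)"), "s1"))
  cc <- class_concentrations(m)
  expect_equal(cc$concentration[cc$lipid_class == "TG"], 3)
  expect_equal(cc$concentration[cc$lipid_class == "CE"], 4)
  # conservation: class sums equal the species total per sample, exactly
  expect_identical(sum(cc$concentration), sum(m))
  # categories sum their member classes
  cat <- category_concentrations(m)
  expect_equal(cat$concentration[cat$category == "glycerolipid"], 3)
  expect_equal(cat$concentration[cat$category == "sterol"], 4)
})

test_that("class and fatty-acid aggregation match brute-force enumeration", {
  m <- tiny_panel_matrix()
  cc <- class_concentrations(m)
  oracle <- oracle_class_sums(m)
  for (s in colnames(m)) {
    for (cls in names(oracle[[s]])) {
      expect_identical(cc$concentration[cc$lipid_class == cls & cc$sample == s],
                       unname(oracle[[s]][cls]))
    }
  }
  prof <- fatty_acid_composition(m, scope = "total")
  oprof <- oracle_fa_profile(m, "total")
  for (s in colnames(m)) {
    for (lab in names(oprof[[s]])) {
      expect_identical(prof$mol_pct[prof$fa == lab & prof$sample == s],
                       unname(oprof[[s]][lab]))
    }
    expect_setequal(prof$fa[prof$sample == s], names(oprof[[s]]))
  }
  # per-class scope against the oracle as well
  prof_c <- fatty_acid_composition(m, scope = "class")
  for (cls in c("TG", "PC")) {
    ocls <- oracle_fa_profile(m, cls)
    sub <- prof_c[prof_c$scope == cls, ]
    for (s in colnames(m)) {
      for (lab in names(ocls[[s]])) {
        expect_identical(sub$mol_pct[sub$fa == lab & sub$sample == s],
                         unname(ocls[[s]][lab]))
      }
    }
  }
})

test_that("compositions normalise to 100 mol% per sample", {
  m <- tiny_panel_matrix()
  comp <- class_composition(m)
  sums <- tapply(comp$mol_pct, comp$sample, sum)
  expect_true(all(abs(sums - 100) < 1e-9))
  # one-class data -> 100%
  m1 <- m[1:2, , drop = FALSE]
  comp1 <- class_composition(m1)
  expect_true(all(abs(comp1$mol_pct - 100) < 1e-12))
  # two equal classes -> 50/50
  m2 <- matrix(c(3, 3), nrow = 2,
               dimnames = list(c("CE(18:1)", "SM(16:0)"), "s1"))
  expect_equal(sort(class_composition(m2)$mol_pct), c(50, 50))
  # an all-zero sample is an error naming the sample
  m3 <- m; m3[, "s2"] <- 0
  expect_error(class_composition(m3), "s2")
})

test_that("chain attribution follows the per-chain convention", {
  # a two-chain species splits its concentration equally across chains
  m <- matrix(1, 1, 1, dimnames = list("PC(16:0/20:4)", "s1"))
  prof <- fatty_acid_composition(m)
  expect_equal(sort(prof$mol_pct), c(50, 50))
  expect_setequal(prof$fa, c("C16:0", "C20:4"))
  # a one-species class is 100% of its own scope
  m2 <- matrix(c(2, 5), 2, 1,
               dimnames = list(c("PC(16:0/16:0)", "CE(18:1)"), "s1"))
  p2 <- fatty_acid_composition(m2, scope = "class")
  expect_equal(p2$mol_pct[p2$scope == "PC"], 100)
  # TG contributes its full concentration to its single specified FA
  m3 <- matrix(c(3, 1), 2, 1,
               dimnames = list(c("TG(52:3) FA 18:2", "TG(50:1) FA 16:0"), "s1"))
  p3 <- fatty_acid_composition(m3)
  expect_equal(p3$mol_pct[p3$fa == "C18:2"], 75)
  expect_equal(p3$mol_pct[p3$fa == "C16:0"], 25)
})

test_that("mol% outputs are invariant to rescaling a sample", {
  m <- tiny_panel_matrix()
  m_scaled <- m
  m_scaled[, "s1"] <- m_scaled[, "s1"] * 7.3
  expect_equal(class_composition(m_scaled)$mol_pct,
               class_composition(m)$mol_pct, tolerance = 1e-12)
  expect_equal(fatty_acid_composition(m_scaled)$mol_pct,
               fatty_acid_composition(m)$mol_pct, tolerance = 1e-12)
})

test_that("saturation rollups partition the profile", {
  m <- tiny_panel_matrix()
  prof <- fatty_acid_composition(m)
  roll <- fa_rollups(prof)
  sat <- roll[roll$rollup == "saturation", ]
  sums <- tapply(sat$mol_pct, sat$sample, sum)
  expect_true(all(abs(sums - 100) < 1e-9))
  # SC + LC = total PUFA mol%
  chl <- roll[roll$rollup == "chain_length", ]
  pufa <- sat$mol_pct[sat$group == "PUFA"]
  expect_equal(as.numeric(tapply(chl$mol_pct, chl$sample, sum)),
               as.numeric(pufa), tolerance = 1e-12)
})
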