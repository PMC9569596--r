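# fixture: a hand-built total-lipid profile with known mol% per fatty acid
profile_fixture <- function(values, sample = "s1") {
  # values: named mol% vector, names like "18:2"
  toks <- strsplit(names(values), ":", fixed = TRUE)
  carbons <- as.integer(sapply(toks, `[`, 1))
  dbs <- as.integer(sapply(toks, `[`, 2))
  tibble::tibble(
    scope = "total",
    fa = fa_label(carbons, dbs),
    carbons = carbons, double_bonds = dbs,
    series = assign_series(carbons, dbs),
    sample = sample,
    mol_pct = unname(values)
  )
}

test_that("product-to-precursor ratios follow the definition and flag zeros", {
  prof <- profile_fixture(c("16:0" = 20, "16:1" = 10, "18:0" = 40, "18:1" = 30))
  r <- product_precursor_ratio(prof, "16:0", "16:1")
  expect_equal(r$value, 0.5)
  expect_true(r$defined)
  # zero precursor -> undefined, flagged, not dropped
  r0 <- product_precursor_ratio(prof, "20:1", "22:1")
  expect_false(r0$defined)
  expect_true(is.na(r0$value))
  expect_equal(nrow(r0), 1L)
  # monotonicity: raising only the product raises the ratio
  prof2 <- profile_fixture(c("16:0" = 20, "16:1" = 15, "18:0" = 40, "18:1" = 25))
  expect_gt(product_precursor_ratio(prof2, "16:0", "16:1")$value, r$value)
})

test_that("Valenzuela indices implement (EPA+DHA)/ALA and AA/LA", {
  prof <- profile_fixture(c("20:5" = 1, "22:6" = 2, "18:3" = 1,
                            "20:4" = 4, "18:2" = 8, "16:0" = 84))
  v <- valenzuela_indices(prof)
  expect_equal(v$value[v$index == "VALENZUELA_N3"], 3.0)
  expect_equal(v$value[v$index == "VALENZUELA_N6"], 0.5)
  # missing ALA -> n-3 index undefined
  v2 <- valenzuela_indices(profile_fixture(c("20:5" = 1, "22:6" = 2,
                                             "18:2" = 8, "20:4" = 4,
                                             "16:0" = 85)))
  expect_false(v2$defined[v2$index == "VALENZUELA_N3"])
})

test_that("n-6/n-3 ratio and n-3 index are series sums with the right algebra", {
  prof <- profile_fixture(c("18:2" = 10, "20:4" = 5, "18:3" = 9, "22:6" = 6,
                            "16:0" = 70))
  r <- n6_n3_ratio(prof)
  expect_equal(r$value, 15 / 15)
  idx <- n3_index(prof)
  expect_equal(idx$value, 15)
  # halving n-3 doubles the ratio (homogeneity)
  prof_half <- profile_fixture(c("18:2" = 10, "20:4" = 5, "18:3" = 4.5,
                                 "22:6" = 3, "16:0" = 77.5))
  expect_equal(n6_n3_ratio(prof_half)$value, 2)
  # ratio x n-3 sum = n-6 sum, exactly, where defined
  expect_equal(r$value * idx$value, 15)
  # no n-3 at all: index 0, ratio undefined
  prof0 <- profile_fixture(c("18:2" = 50, "16:0" = 50))
  expect_equal(n3_index(prof0)$value, 0)
  expect_false(n6_n3_ratio(prof0)$defined)
})

test_that("class ratios work per sample and from printed group means", {
  m <- matrix(c(6, 2, 3, 3), nrow = 2,
              dimnames = list(c("TG(52:3) FA 18:2", "DG(16:0/18:1)"),
                              c("s1", "s2")))
  cr <- class_ratio(m, "TG", "DG")
  expect_equal(cr$value, c(3, 1))
  # identical classes give ratio 1 exactly
  m2 <- matrix(c(4, 4), nrow = 2,
               dimnames = list(c("PC(16:0/18:1)", "PE(16:0/18:1)"), "s1"))
  expect_identical(class_ratio(m2, "PC", "PE")$value, 1)
  # ratio-of-printed-means mode reproduces the published PC/PE values
  pcpe <- reference_class_ratio("PC", "PE")
  expect_equal(round(pcpe$value[pcpe$group == "control"], 2), 1.17)
  expect_equal(round(pcpe$value[pcpe$group == "case"], 2), 1.15)
  # zero denominator flagged
  m3 <- matrix(c(1, 0), nrow = 2,
               dimnames = list(c("TG(52:3) FA 18:2", "DG(16:0/18:1)"), "s1"))
  expect_false(class_ratio(m3, "TG", "DG")$defined)
})

test_that("the default edge set has the expected connectivity", {
  edges <- default_pathway_edges()
  expect_setequal(unique(edges$enzyme),
                  c("SCD1", "ELOVL3", "ELOVL5", "ELOVL6", "FADS1", "FADS2"))
  scd1 <- edges[edges$enzyme == "SCD1", ]
  expect_equal(nrow(scd1), 2L)
  expect_setequal(paste(scd1$precursor, scd1$product),
                  c("16:0 16:1", "18:0 18:1"))
  expect_true(all(table(edges$enzyme) >= 1))
})

test_that("the full index table is computed and scale-invariant", {
  panel <- generate_panel(panel_spec(
    c(TG = 15, DG = 8, PC = 10, PE = 10, CE = 5), undetected_extra = 0),
    seed = 8)
  sim <- simulate_concentrations(panel, seed = 9)
  idx <- compute_indices(sim$concentrations)
  expect_setequal(unique(idx$index),
                  c("SCD1_16", "SCD1_18", "ELOVL3", "ELOVL5", "ELOVL6",
                    "FADS1", "FADS2", "VALENZUELA_N3", "VALENZUELA_N6",
                    "N6_N3_RATIO", "N3_INDEX", "TG_DG_RATIO", "PC_PE_RATIO"))
  expect_true(all(idx$value[idx$defined] >= 0))
  scaled <- sim$concentrations
  scaled[, 1] <- scaled[, 1] * 11
  idx2 <- compute_indices(scaled)
  expect_equal(idx2$value, idx$value, tolerance = 1e-12)
})
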