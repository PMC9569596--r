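test_that("the default panel has the study's size and class structure", {
  panel <- generate_panel(panel_spec(), seed = 1)
  expect_equal(nrow(panel), 941L)
  expect_equal(sum(panel$detected), 877L)
  expect_false(anyDuplicated(panel$species) > 0)
  counts <- table(panel$lipid_class[panel$detected])
  expect_equal(unname(counts[["TG"]]), 518L)
  expect_equal(unname(counts[["CE"]]), 26L)
  expect_setequal(names(counts), lipid_classes())
})

test_that("panel generation is deterministic and honours its spec", {
  expect_identical(generate_panel(panel_spec(), seed = 9)$species,
                   generate_panel(panel_spec(), seed = 9)$species)
  empty <- generate_panel(panel_spec(stats::setNames(rep(0L, 14), lipid_classes()),
                                     undetected_extra = 0L), seed = 1)
  expect_equal(nrow(empty), 0L)
  expect_error(generate_panel(panel_spec(c(CE = 1000L), undetected_extra = 0L)),
               "name pool")
})

test_that("species-level means conserve the configured class totals exactly", {
  panel <- generate_panel(panel_spec(), seed = 5)
  eff <- effect_config()
  sim <- simulate_concentrations(panel, effects = eff, seed = 6)
  tr <- sim$truth[sim$truth$detected, ]
  for (cls in unique(tr$lipid_class)) {
    sums <- tr[tr$lipid_class == cls, ]
    expect_equal(sum(sums$mu_control), unname(eff$class_mean[[cls]]),
                 tolerance = 1e-12)
    expect_equal(sum(sums$mu_case),
                 unname(eff$class_mean[[cls]] * eff$class_multiplier[[cls]]),
                 tolerance = 1e-12)
  }
  # undetected species stay zero everywhere
  expect_true(all(sim$concentrations[!sim$truth$detected, ] == 0))
  # a species is detected iff nonzero in at least one sample
  expect_identical(rowSums(sim$concentrations != 0) > 0,
                   stats::setNames(sim$truth$detected, sim$truth$species))
})

test_that("simulated control-group class means match the calibration target", {
  # mean of the TG class sum over replicate simulations approaches the
  # configured class mean (known Monte-Carlo standard error)
  panel <- generate_panel(panel_spec(), seed = 11)
  reps <- 50
  tg <- numeric(reps)
  for (r in seq_len(reps)) {
    sim <- simulate_concentrations(panel, seed = 100 + r)
    cc <- class_concentrations(sim)
    ctrl <- sim$design$sample[sim$design$group == "IRG"]
    tg[r] <- mean(cc$concentration[cc$lipid_class == "TG" & cc$sample %in% ctrl])
  }
  target <- class_reference()$conc_mean_control[
    class_reference()$lipid_class == "TG"]
  se <- stats::sd(tg) / sqrt(reps)
  expect_lt(abs(mean(tg) - target), 3 * se)
})

test_that("the noise-free limit recovers the configured multiplier", {
  panel <- generate_panel(panel_spec(c(TG = 10L, DG = 5L), undetected_extra = 0L),
                          seed = 2)
  eff <- effect_config(
    class_multiplier = c(TG = 2),
    class_cv = stats::setNames(rep(1e-6, 14), lipid_classes()),
    fa_tilt = NULL
  )
  sim <- simulate_concentrations(panel, effects = eff, seed = 3)
  cc <- class_concentrations(sim)
  case <- sim$design$sample[sim$design$group == "dIRG"]
  ratio <- mean(cc$concentration[cc$lipid_class == "TG" & cc$sample %in% case]) /
    mean(cc$concentration[cc$lipid_class == "TG" & !cc$sample %in% case])
  expect_equal(ratio, 2, tolerance = 1e-4)
})

test_that("fatty-acid tilts reweight within the class but preserve its total", {
  panel <- generate_panel(panel_spec(c(PC = 20L), undetected_extra = 0L), seed = 4)
  eff <- effect_config(class_multiplier = c(PC = 1))
  sim <- simulate_concentrations(panel, effects = eff, seed = 5)
  tr <- sim$truth
  expect_equal(sum(tr$mu_case), sum(tr$mu_control), tolerance = 1e-12)
  ch <- chain_table(parse_panel(panel$species))
  has_n3 <- panel$species %in% ch$species[ch$series == "n-3"]
  if (any(has_n3) && any(!has_n3)) {
    expect_lt(max(tr$multiplier[has_n3]), min(tr$multiplier[!has_n3]))
  }
})

test_that("invalid configurations are rejected", {
  expect_error(effect_config(class_multiplier = c(TG = -1)), "positive")
  expect_error(effect_config(class_cv = c(TG = 0)), "positive")
  expect_error(simulate_concentrations(character(0)), "empty")
  expect_error(
    simulate_concentrations(generate_panel(panel_spec(c(PC = 2L),
                                                      undetected_extra = 0L)),
                            design = tibble::tibble(
                              sample = c("a", "b", "c"),
                              group = factor(c("g1", "g1", "g2")))),
    ">= 2 samples"
  )
})

test_that("class logFC estimates recover the configured effects", {
  # short parameter-recovery check at the study's n = 7 vs 7
  panel <- generate_panel(panel_spec(), seed = 21)
  eff <- effect_config()
  ok <- 0L
  reps <- 10
  for (r in seq_len(reps)) {
    sim <- simulate_concentrations(panel, effects = eff, seed = 300 + r)
    cc <- class_concentrations(sim)
    case <- sim$design$sample[sim$design$group == "dIRG"]
    est <- sapply(c("TG", "CE"), function(cls) {
      log2(mean(cc$concentration[cc$lipid_class == cls & cc$sample %in% case]) /
           mean(cc$concentration[cc$lipid_class == cls & !cc$sample %in% case]))
    })
    truth <- log2(eff$class_multiplier[c("TG", "CE")])
    if (all(abs(est - truth) / abs(truth) < 0.25)) ok <- ok + 1L
  }
  expect_gte(ok, 9L)
})
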