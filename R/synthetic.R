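# Synthetic complex-lipid panels with the statistical structure of the
# calibrating study: 941 species in 14 classes (877 detected), two groups of
# 7 livers, class-level lognormal concentration noise, and configurable
# case-group class multipliers and fatty-acid composition tilts.

# Fatty-acid pool the generator draws chains from; spans the chains reported
# in the calibrating panel (14:0 ... 22:6) plus flanking chain lengths so
# every class has enough unique names.
.fa_pool <- tibble::tibble(
  carbons      = c(12L, 14L, 15L, 16L, 17L, 18L, 19L, 20L, 22L, 24L, 26L,
                   14L, 16L, 17L, 18L, 20L, 22L, 24L,
                   18L, 18L, 18L, 20L, 20L, 20L, 20L, 22L, 22L, 22L),
  double_bonds = c(0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L,
                   1L, 1L, 1L, 1L, 1L, 1L, 1L,
                   2L, 3L, 4L, 2L, 3L, 4L, 5L, 4L, 5L, 6L)
)

.default_counts <- c(
  TG = 518L, DG = 58L, MG = 22L, PC = 72L, PE = 93L, PI = 7L, LPC = 16L,
  LPE = 11L, Cer = 12L, HexCer = 10L, LacCer = 10L, dhCer = 10L, SM = 12L,
  CE = 26L
)

#' Specification of a synthetic lipid panel
#'
#' Defaults reproduce the calibrating study's panel: 877 detected species
#' distributed over the 14 classes as in the published class table, padded by
#' 64 never-detected species to the 941 measured species.
#'
#' @param counts Named integer vector of detected species per class. Partial
#'   vectors override the matching defaults.
#' @param undetected_extra Number of additional species that are generated
#'   but zero in every sample.
#' @return A list of class `"panel_spec"`.
#' @export
#' @examples
#' panel_spec()                      # the study panel: 877 + 64 = 941
#' panel_spec(c(TG = 5, PC = 3), undetected_extra = 0)
panel_spec <- function(counts = NULL, undetected_extra = 64L) {
  full <- .default_counts
  if (!is.null(counts)) {
    if (is.null(names(counts)) || !all(names(counts) %in% names(full))) {
      stop_lp("counts must be named by lipid class (%s)",
              paste(lipid_classes(), collapse = ", "))
    }
    # a partial vector overrides only the named classes unless it names all
    if (length(counts) < length(full)) {
      full[setdiff(names(full), names(counts))] <- 0L
    }
    full[names(counts)] <- as.integer(counts)
  }
  if (any(full < 0L) || !is_count(undetected_extra)) {
    stop_lp("species counts and undetected_extra must be nonnegative integers")
  }
  structure(list(counts = full, undetected_extra = as.integer(undetected_extra)),
            class = "panel_spec")
}

# all candidate names for one class, in deterministic order
class_name_pool <- function(cls) {
  fa <- .fa_pool
  tok <- sprintf("%d:%d", fa$carbons, fa$double_bonds)
  if (cls == "TG") {
    grid <- expand.grid(total_c = seq(40L, 60L, by = 2L), total_db = 0L:12L,
                        i = seq_len(nrow(fa)))
    keep <- fa$carbons[grid$i] + 4L <= grid$total_c &
      fa$double_bonds[grid$i] <= grid$total_db
    grid <- grid[keep, , drop = FALSE]
    sprintf("TG(%d:%d) FA %s", grid$total_c, grid$total_db, tok[grid$i])
  } else if (cls %in% c("DG", "PC", "PE", "PI")) {
    idx <- which(upper.tri(diag(nrow(fa)), diag = TRUE), arr.ind = TRUE)
    sprintf("%s(%s/%s)", cls, tok[idx[, "row"]], tok[idx[, "col"]])
  } else {
    sprintf("%s(%s)", cls, tok)
  }
}

#' Generate the species names of a synthetic panel
#'
#' Species names are drawn without replacement from per-class pools built
#' over the generator's fatty-acid pool; TG names use the sum-composition
#' plus single-fatty-acid dialect. The `undetected_extra` species are drawn
#' from the name pool left over after the detected draw and are flagged
#' `detected = FALSE`.
#'
#' @param spec A [panel_spec()].
#' @param seed Integer seed; the same seed reproduces the same panel.
#' @return Tibble with columns `species`, `lipid_class`, `detected`.
#' @export
#' @examples
#' panel <- generate_panel(panel_spec(), seed = 1)
#' nrow(panel); sum(panel$detected)
generate_panel <- function(spec = panel_spec(), seed = 1L) {
  stopifnot(inherits(spec, "panel_spec"))
  local_seed(seed, {
    detected <- list()
    leftover <- list()
    for (cls in names(spec$counts)) {
      k <- spec$counts[[cls]]
      pool <- class_name_pool(cls)
      if (k > length(pool)) {
        stop_lp("class %s: requested %d species but the name pool has only %d",
                cls, k, length(pool))
      }
      pick <- if (k > 0L) sample(pool, k) else character(0)
      detected[[cls]] <- pick
      leftover[[cls]] <- setdiff(pool, pick)
    }
    extra <- character(0)
    if (spec$undetected_extra > 0L) {
      rest <- unlist(leftover, use.names = FALSE)
      if (spec$undetected_extra > length(rest)) {
        stop_lp("undetected_extra exceeds the remaining name pool")
      }
      extra <- sample(rest, spec$undetected_extra)
    }
    species <- c(unlist(detected, use.names = FALSE), extra)
    cls_of <- sub("\\(.*$", "", species)
    tibble::tibble(
      species = species,
      lipid_class = cls_of,
      detected = rep(c(TRUE, FALSE),
                     c(length(species) - length(extra), length(extra)))
    )
  })
}

#' Two-group study design
#'
#' @param n_control,n_case Samples per group (>= 2 each).
#' @param group_labels Length-2 character vector, control first.
#' @return Tibble with columns `sample`, `group` (factor, control level
#'   first).
#' @export
study_design <- function(n_control = 7L, n_case = 7L,
                         group_labels = c("IRG", "dIRG")) {
  if (!is_count(n_control, 2L) || !is_count(n_case, 2L)) {
    stop_lp("each group needs at least 2 samples")
  }
  stopifnot(length(group_labels) == 2L, !anyDuplicated(group_labels))
  tibble::tibble(
    sample = c(sprintf("%s_%d", group_labels[1], seq_len(n_control)),
               sprintf("%s_%d", group_labels[2], seq_len(n_case))),
    group = factor(rep(group_labels, c(n_control, n_case)),
                   levels = group_labels)
  )
}

merge_named <- function(default, override, what) {
  if (is.null(override)) return(default)
  if (is.null(names(override)) || !all(names(override) %in% names(default))) {
    stop_lp("%s overrides must be named by lipid class", what)
  }
  default[names(override)] <- override
  default
}

#' Effect configuration for the concentration simulator
#'
#' Defaults are calibrated from the published class-level statistics
#' ([class_reference()]): control class means, class coefficients of
#' variation (SD/mean of the control group, floored at `cv_floor` because one
#' printed SD rounds to 0.000), and case/control class multipliers (ratio of
#' the printed group means, e.g. about 2.14 for TG and 1.88 for CE). The
#' default fatty-acid tilts depress every species carrying an n-3 chain
#' (factor 0.65) and favour species carrying an 18:1 chain (factor 1.25) in
#' the case group, reproducing the reported n-3 depletion and oleic-acid
#' accumulation directions.
#'
#' @param class_mean,class_cv,class_multiplier Named numeric vectors by
#'   class; partial vectors override the matching defaults.
#' @param fa_tilt Tibble with columns `carbons`, `double_bonds`, `series`
#'   (NA = wildcard) and `factor`; a species matching a row (any chain
#'   satisfies all non-NA fields) has its case-group mean multiplied by
#'   `factor` before renormalisation to the class total. `NULL` disables
#'   tilts.
#' @param dirichlet_alpha Concentration parameter of the Dirichlet species
#'   shares within a class.
#' @param cv_floor Lower bound applied to the calibrated CVs.
#' @param reference Reference table used for calibration.
#' @return A list of class `"effect_config"`.
#' @export
#' @examples
#' effect_config()                      # study-calibrated defaults
#' null_effect_config()                 # no group difference
effect_config <- function(class_mean = NULL, class_cv = NULL,
                          class_multiplier = NULL, fa_tilt = default_fa_tilt(),
                          dirichlet_alpha = 1, cv_floor = 0.05,
                          reference = class_reference()) {
  mean0 <- stats::setNames(reference$conc_mean_control, reference$lipid_class)
  cv0 <- stats::setNames(
    pmax(reference$conc_sd_control / reference$conc_mean_control, cv_floor),
    reference$lipid_class
  )
  mult0 <- stats::setNames(
    reference$conc_mean_case / reference$conc_mean_control,
    reference$lipid_class
  )
  cfg <- list(
    class_mean = merge_named(mean0, class_mean, "class_mean"),
    class_cv = merge_named(cv0, class_cv, "class_cv"),
    class_multiplier = merge_named(mult0, class_multiplier, "class_multiplier"),
    fa_tilt = fa_tilt,
    dirichlet_alpha = dirichlet_alpha
  )
  if (any(cfg$class_mean <= 0) || any(cfg$class_cv <= 0) ||
      any(cfg$class_multiplier <= 0)) {
    stop_lp("class means, CVs and multipliers must all be positive")
  }
  if (!is.null(fa_tilt)) {
    stopifnot(all(c("factor") %in% names(fa_tilt)))
    if (any(fa_tilt$factor <= 0)) stop_lp("fa_tilt factors must be positive")
  }
  if (dirichlet_alpha <= 0) stop_lp("dirichlet_alpha must be positive")
  structure(cfg, class = "effect_config")
}

#' @rdname effect_config
#' @export
default_fa_tilt <- function() {
  tibble::tibble(
    carbons = c(NA_integer_, 18L),
    double_bonds = c(NA_integer_, 1L),
    series = c("n-3", NA_character_),
    factor = c(0.65, 1.25)
  )
}

#' @rdname effect_config
#' @export
null_effect_config <- function(...) {
  ref <- class_reference()
  effect_config(
    class_multiplier = stats::setNames(rep(1, nrow(ref)), ref$lipid_class),
    fa_tilt = NULL, ...
  )
}

# per-species multiplicative tilt factor; a species matches a tilt row when
# any of its chains satisfies all non-NA fields of the row
tilt_factors <- function(chains_by_species, fa_tilt) {
  if (is.null(fa_tilt) || nrow(fa_tilt) == 0L) {
    return(rep(1, length(chains_by_species)))
  }
  vapply(chains_by_species, function(ch) {
    f <- 1
    for (i in seq_len(nrow(fa_tilt))) {
      hit <- rep(TRUE, nrow(ch))
      if (!is.na(fa_tilt$carbons[i])) hit <- hit & ch$carbons == fa_tilt$carbons[i]
      if (!is.na(fa_tilt$double_bonds[i])) {
        hit <- hit & ch$double_bonds == fa_tilt$double_bonds[i]
      }
      if (!is.na(fa_tilt$series[i])) hit <- hit & ch$series == fa_tilt$series[i]
      if (any(hit)) f <- f * fa_tilt$factor[i]
    }
    f
  }, numeric(1))
}

#' Simulate a species-by-sample concentration matrix
#'
#' Within each class, detected species receive Dirichlet-distributed shares
#' of the configured class mean; case-group means are the control means times
#' the class multiplier, tilted per fatty acid and renormalised so the class
#' total is preserved (class- and fatty-acid-level effects are independently
#' controllable). Observed values are independent lognormal draws around the
#' species means with the class coefficient of variation. Undetected species
#' are zero in every sample.
#'
#' @param panel A panel tibble from [generate_panel()], or a character vector
#'   of species names (then all species count as detectable).
#' @param design A [study_design()].
#' @param effects An [effect_config()].
#' @param seed Integer seed.
#' @return A list of class `"lipid_sim"` with elements `concentrations`
#'   (numeric matrix, species x samples, nmol/mg), `design`, and `truth`
#'   (tibble of the per-species means and realised case/control multipliers).
#' @export
#' @examples
#' sim <- simulate_concentrations(generate_panel(panel_spec(c(TG = 4, PC = 3),
#'                                                          undetected_extra = 0),
#'                                seed = 1), seed = 2)
#' dim(sim$concentrations)
simulate_concentrations <- function(panel, design = study_design(),
                                    effects = effect_config(), seed = 1L) {
  if (is.character(panel)) {
    panel <- tibble::tibble(species = panel,
                            lipid_class = sub("\\(.*$", "", panel),
                            detected = TRUE)
  }
  if (nrow(panel) == 0L) stop_lp("panel is empty")
  stopifnot(inherits(effects, "effect_config"))
  if (nlevels(design$group) != 2L || any(table(design$group) < 2L)) {
    stop_lp("design needs exactly two groups with >= 2 samples each")
  }
  parsed <- parse_panel(panel$species)
  tilt <- tilt_factors(parsed$chains, effects$fa_tilt)

  n_sp <- nrow(panel)
  samples <- design$sample
  is_case <- design$group == levels(design$group)[2]
  mu_control <- numeric(n_sp)
  mu_case <- numeric(n_sp)

  local_seed(seed, {
    for (cls in unique(panel$lipid_class)) {
      rows <- which(panel$lipid_class == cls & panel$detected)
      if (!length(rows)) next
      m <- effects$class_mean[[cls]]
      mult <- effects$class_multiplier[[cls]]
      g <- stats::rgamma(length(rows), shape = effects$dirichlet_alpha)
      share <- g / sum(g)
      mu1 <- m * share
      raw2 <- mu1 * tilt[rows]
      mu2 <- raw2 / sum(raw2) * m * mult
      mu_control[rows] <- mu1
      mu_case[rows] <- mu2
    }
    mat <- matrix(0, nrow = n_sp, ncol = length(samples),
                  dimnames = list(panel$species, samples))
    cv <- effects$class_cv[panel$lipid_class]
    sdlog <- sqrt(log1p(cv^2))
    for (j in seq_along(samples)) {
      mu <- if (is_case[j]) mu_case else mu_control
      pos <- mu > 0
      mat[pos, j] <- stats::rlnorm(sum(pos),
                                   meanlog = log(mu[pos]) - sdlog[pos]^2 / 2,
                                   sdlog = sdlog[pos])
    }
    truth <- tibble::tibble(
      species = panel$species,
      lipid_class = panel$lipid_class,
      detected = panel$detected,
      mu_control = mu_control,
      mu_case = mu_case,
      multiplier = ifelse(mu_control > 0, mu_case / mu_control, NA_real_),
      class_multiplier = unname(effects$class_multiplier[panel$lipid_class])
    )
    structure(list(concentrations = mat, design = design, truth = truth),
              class = "lipid_sim")
  })
}
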