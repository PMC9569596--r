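# From MRM signals to concentrations, and from concentrations to the
# aggregate tables: class/category concentrations, mol% compositions, and
# fatty-acid profiles.

#' Internal-standard quantification of one species
#'
#' Concentration = (signal / internal-standard signal) x internal-standard
#' concentration, the standard single-point quantification of targeted
#' panels.
#'
#' @param signal Analyte signal intensity (>= 0).
#' @param is_signal Internal-standard signal intensity (> 0).
#' @param is_conc Internal-standard concentration (> 0), in the output unit.
#' @return Concentration in the unit of `is_conc`.
#' @export
#' @examples
#' quantify_species(200, 100, 5)  # 10
quantify_species <- function(signal, is_signal, is_conc) {
  if (any(is_signal <= 0)) stop_lp("internal-standard signal must be positive")
  if (any(is_conc <= 0)) stop_lp("internal-standard concentration must be positive")
  if (any(signal < 0)) stop_lp("signal must be nonnegative")
  signal / is_signal * is_conc
}

as_conc_matrix <- function(x) {
  if (inherits(x, "lipid_sim")) x <- x$concentrations
  if (!is.matrix(x) || is.null(rownames(x)) || is.null(colnames(x))) {
    stop_lp("expected a species x sample matrix with dimnames")
  }
  if (any(x < 0)) stop_lp("concentrations must be nonnegative")
  x
}

#' Per-sample lipid class (and category) concentrations
#'
#' A class concentration is the sum of all member-species concentrations;
#' category concentrations sum the member classes.
#'
#' @param x Species x sample concentration matrix (rownames are shorthand
#'   species names) or a `"lipid_sim"`.
#' @param panel Optional pre-parsed [parse_panel()] result for the rownames.
#' @return Tidy tibble: `lipid_class`, `category`, `sample`, `concentration`.
#' @export
class_concentrations <- function(x, panel = NULL) {
  mat <- as_conc_matrix(x)
  if (is.null(panel)) panel <- parse_panel(rownames(mat))
  stopifnot(identical(panel$species, rownames(mat)))
  by_class <- rowsum(mat, group = panel$lipid_class)
  tibble::tibble(
    lipid_class = rep(rownames(by_class), ncol(by_class)),
    category = class_to_category(rep(rownames(by_class), ncol(by_class))),
    sample = rep(colnames(by_class), each = nrow(by_class)),
    concentration = as.vector(by_class)
  )
}

#' @rdname class_concentrations
#' @export
category_concentrations <- function(x, panel = NULL) {
  class_concentrations(x, panel) |>
    dplyr::group_by(.data$category, .data$sample) |>
    dplyr::summarise(concentration = sum(.data$concentration), .groups = "drop")
}

#' Per-sample class composition (mol%)
#'
#' Class mol% = 100 x class concentration / total lipid concentration of the
#' sample. Group-level compositions reported elsewhere in the package are
#' means of these per-sample values (mean of ratios), matching how panel
#' summary tables present "mean +/- SD" compositions; see
#' [class_ratio()] for the ratio-of-group-means alternative.
#'
#' @inheritParams class_concentrations
#' @return Tidy tibble: `lipid_class`, `category`, `sample`, `mol_pct`; per
#'   sample the `mol_pct` values sum to 100.
#' @export
class_composition <- function(x, panel = NULL) {
  cc <- class_concentrations(x, panel)
  totals <- tapply(cc$concentration, cc$sample, sum)
  if (any(totals <= 0)) {
    stop_lp("sample(s) with zero total concentration: %s",
            paste(names(totals)[totals <= 0], collapse = ", "))
  }
  cc$mol_pct <- 100 * cc$concentration / as.vector(totals[cc$sample])
  cc$concentration <- NULL
  cc
}

#' Fatty-acid composition profiles (mol%)
#'
#' Attributes each species' concentration once per specified acyl chain to
#' that chain's fatty-acid bucket, then normalises buckets to 100 mol% per
#' sample within each scope. With `scope = "class"` one profile per lipid
#' class is returned; with `scope = "total"` a single profile over all
#' lipids. TG species contribute their full concentration to their single
#' specified fatty acid (the panel reports only one esterified fatty acid per
#' TG); multi-chain species contribute equally per specified chain, with no
#' extra molar-multiplicity weighting.
#'
#' @inheritParams class_concentrations
#' @param scope `"total"` or `"class"`.
#' @return Tidy tibble: `scope` (`"total"` or the class), `fa`, `carbons`,
#'   `double_bonds`, `series`, `sample`, `mol_pct`. Per sample and scope the
#'   `mol_pct` sum to 100 (samples with no signal in a scope are dropped).
#' @export
#' @examples
#' m <- matrix(c(1, 1), nrow = 1, dimnames = list("PC(16:0/20:4)", c("a", "b")))
#' fatty_acid_composition(m)  # C16:0 and C20:4 at 50 mol% each
fatty_acid_composition <- function(x, scope = c("total", "class"),
                                   panel = NULL) {
  scope <- match.arg(scope)
  mat <- as_conc_matrix(x)
  if (is.null(panel)) panel <- parse_panel(rownames(mat))
  ct <- chain_table(panel)

  long <- tibble::tibble(
    species = rep(rownames(mat), ncol(mat)),
    sample = rep(colnames(mat), each = nrow(mat)),
    concentration = as.vector(mat)
  )
  contrib <- dplyr::inner_join(ct, long, by = "species",
                               relationship = "many-to-many")
  contrib$scope <- if (scope == "total") "total" else contrib$lipid_class

  prof <- contrib |>
    dplyr::group_by(.data$scope, .data$fa, .data$carbons, .data$double_bonds,
                    .data$series, .data$sample) |>
    dplyr::summarise(amount = sum(.data$concentration), .groups = "drop") |>
    dplyr::group_by(.data$scope, .data$sample) |>
    dplyr::mutate(total = sum(.data$amount)) |>
    dplyr::ungroup() |>
    dplyr::filter(.data$total > 0) |>
    dplyr::mutate(mol_pct = 100 * .data$amount / .data$total) |>
    dplyr::select(!dplyr::all_of(c("amount", "total")))
  prof
}

#' Saturation, series and chain-length rollups of a fatty-acid profile
#'
#' Sums member fatty-acid mol% into SFA/MUFA/PUFA, n-3/n-6, and
#' SC-PUFA/LC-PUFA groups per sample and scope.
#'
#' @param profile Result of [fatty_acid_composition()].
#' @param lc_cutoff Carbons cutoff for LC-PUFA, see [classify_chain_length()].
#' @return Tidy tibble: `scope`, `rollup` (`saturation`, `series`,
#'   `chain_length`), `group`, `sample`, `mol_pct`.
#' @export
fa_rollups <- function(profile, lc_cutoff = 20L) {
  base <- profile |>
    dplyr::mutate(
      saturation = saturation_class(.data$double_bonds),
      chain_length = classify_chain_length(.data$carbons, .data$double_bonds,
                                           lc_cutoff)
    )
  sat <- base |>
    dplyr::group_by(.data$scope, .data$sample, group = .data$saturation) |>
    dplyr::summarise(mol_pct = sum(.data$mol_pct), .groups = "drop") |>
    dplyr::mutate(rollup = "saturation")
  ser <- base |>
    dplyr::filter(.data$series %in% c("n-3", "n-6")) |>
    dplyr::group_by(.data$scope, .data$sample, group = .data$series) |>
    dplyr::summarise(mol_pct = sum(.data$mol_pct), .groups = "drop") |>
    dplyr::mutate(rollup = "series")
  chl <- base |>
    dplyr::filter(.data$chain_length != "not-PUFA") |>
    dplyr::group_by(.data$scope, .data$sample, group = .data$chain_length) |>
    dplyr::summarise(mol_pct = sum(.data$mol_pct), .groups = "drop") |>
    dplyr::mutate(rollup = "chain_length")
  dplyr::bind_rows(sat, ser, chl) |>
    dplyr::select(dplyr::all_of(c("scope", "rollup", "group", "sample",
                                  "mol_pct")))
}
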