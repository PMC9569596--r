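# Surrogate enzyme-activity indices and ratio biomarkers derived from
# fatty-acid profiles and class concentrations.

# samples x fatty-acid mol% matrix for one scope of a tidy profile
profile_wide <- function(profile, scope = "total") {
  p <- profile[profile$scope == scope, , drop = FALSE]
  if (nrow(p) == 0L) stop_lp("profile has no rows for scope '%s'", scope)
  samples <- unique(p$sample)
  fas <- unique(p$fa)
  m <- matrix(0, length(samples), length(fas), dimnames = list(samples, fas))
  m[cbind(match(p$sample, samples), match(p$fa, fas))] <- p$mol_pct
  m
}

fa_col <- function(wide, token) {
  tok <- parse_edge_fa(token)
  lab <- fa_label(tok$carbons, tok$double_bonds)
  if (lab %in% colnames(wide)) wide[, lab] else rep(0, nrow(wide))
}

#' Product-to-precursor ratio of two fatty acids
#'
#' The mol% of the product chain divided by the mol% of the precursor chain,
#' per sample — the surrogate measure of the desaturase or elongase
#' connecting them. The panel resolves chains only to carbons:double_bonds,
#' so series-suffixed tokens are matched by their carbon/double-bond bucket.
#'
#' @param profile A [fatty_acid_composition()] result.
#' @param precursor,product Chain tokens like `"16:0"`, `"18:3n-6"`.
#' @param scope Profile scope to evaluate in (default `"total"`).
#' @return Tibble: `sample`, `value`, `defined` (FALSE where the precursor
#'   mol% is zero; `value` is then NA, never silently dropped).
#' @export
product_precursor_ratio <- function(profile, precursor, product,
                                    scope = "total") {
  wide <- profile_wide(profile, scope)
  pre <- fa_col(wide, precursor)
  pro <- fa_col(wide, product)
  defined <- unname(pre > 0)
  tibble::tibble(
    sample = rownames(wide),
    value = unname(ifelse(defined, pro / pre, NA_real_)),
    defined = defined
  )
}

#' Series-specific desaturation-capacity (Valenzuela) indices
#'
#' n-3: (EPA + DHA) / ALA, i.e. (C20:5 + C22:6) / C18:3; n-6: AA / LA, i.e.
#' C20:4 / C18:2 — both on total-lipid mol%.
#'
#' @inheritParams product_precursor_ratio
#' @return Tibble: `index` (`VALENZUELA_N3`, `VALENZUELA_N6`), `sample`,
#'   `value`, `defined`.
#' @export
valenzuela_indices <- function(profile, scope = "total") {
  wide <- profile_wide(profile, scope)
  ala <- fa_col(wide, "18:3")
  la <- fa_col(wide, "18:2")
  n3 <- (fa_col(wide, "20:5") + fa_col(wide, "22:6")) / ifelse(ala > 0, ala, NA)
  n6 <- fa_col(wide, "20:4") / ifelse(la > 0, la, NA)
  tibble::tibble(
    index = rep(c("VALENZUELA_N3", "VALENZUELA_N6"), each = nrow(wide)),
    sample = rep(rownames(wide), 2L),
    value = unname(c(n3, n6)),
    defined = unname(c(ala > 0, la > 0))
  )
}

series_sums <- function(profile, scope = "total") {
  p <- profile[profile$scope == scope, , drop = FALSE]
  samples <- unique(p$sample)
  sum_for <- function(s) {
    vapply(samples, function(smp) {
      sum(p$mol_pct[p$sample == smp & p$series == s])
    }, numeric(1), USE.NAMES = FALSE)
  }
  list(samples = samples, n3 = sum_for("n-3"), n6 = sum_for("n-6"))
}

#' n-6/n-3 ratio over total lipids
#'
#' Ratio of the summed mol% of all n-6 chains to the summed mol% of all n-3
#' chains, per sample.
#'
#' @inheritParams product_precursor_ratio
#' @return Tibble: `sample`, `value`, `defined` (FALSE when the n-3 sum is 0).
#' @export
n6_n3_ratio <- function(profile, scope = "total") {
  s <- series_sums(profile, scope)
  defined <- s$n3 > 0
  tibble::tibble(sample = s$samples,
                 value = ifelse(defined, s$n6 / s$n3, NA_real_),
                 defined = defined)
}

#' n-3 index over total lipids
#'
#' The summed mol% of all n-3 fatty acids per sample.
#'
#' @inheritParams product_precursor_ratio
#' @return Tibble: `sample`, `value`.
#' @export
n3_index <- function(profile, scope = "total") {
  s <- series_sums(profile, scope)
  tibble::tibble(sample = s$samples, value = s$n3)
}

#' Per-sample ratio of two lipid class concentrations
#'
#' TG/DG (lipid-storage flux) and PC/PE (membrane integrity) are the
#' canonical uses. With a `design`, group summaries (mean +/- SD of the
#' per-sample ratios) are attached as an attribute.
#'
#' @param x Concentration matrix or `"lipid_sim"`, or a tidy
#'   [class_concentrations()] table.
#' @param numerator,denominator Class abbreviations.
#' @param design Optional [study_design()]; adds a `"group_summary"`
#'   attribute (tibble `group`, `mean`, `sd`, `n`).
#' @return Tibble: `sample`, `value`, `defined`.
#' @seealso [reference_class_ratio()] for the ratio-of-group-means mode on
#'   printed summary tables.
#' @export
class_ratio <- function(x, numerator, denominator, design = NULL) {
  cc <- if (is.data.frame(x)) x else class_concentrations(x)
  pick <- function(cls) {
    sub <- cc[cc$lipid_class == cls, , drop = FALSE]
    stats::setNames(sub$concentration, sub$sample)
  }
  num <- pick(numerator)
  den <- pick(denominator)
  samples <- unique(cc$sample)
  num <- as.numeric(ifelse(is.na(num[samples]), 0, num[samples]))
  den <- as.numeric(ifelse(is.na(den[samples]), 0, den[samples]))
  defined <- den > 0
  out <- tibble::tibble(sample = samples,
                        value = ifelse(defined, num / den, NA_real_),
                        defined = defined)
  if (!is.null(design)) {
    joined <- dplyr::inner_join(out, design, by = "sample")
    summ <- joined |>
      dplyr::group_by(.data$group) |>
      dplyr::summarise(mean = mean(.data$value, na.rm = TRUE),
                       sd = stats::sd(.data$value, na.rm = TRUE),
                       n = sum(!is.na(.data$value)), .groups = "drop")
    attr(out, "group_summary") <- summ
  }
  out
}

#' Class ratio from a printed summary table (ratio of group means)
#'
#' Computes numerator-mean / denominator-mean per group directly from a
#' class-level reference table — the only mode computable from printed group
#' means, provided for checks against published summary values.
#'
#' @param numerator,denominator Class abbreviations.
#' @param reference A [class_reference()]-layout tibble.
#' @return Tibble: `group` (`control`, `case`), `value`.
#' @export
#' @examples
#' reference_class_ratio("PC", "PE")  # about 1.17 (control) and 1.15 (case)
reference_class_ratio <- function(numerator, denominator,
                                  reference = class_reference()) {
  row_of <- function(cls) {
    i <- match(cls, reference$lipid_class)
    if (is.na(i)) stop_lp("class %s not in reference table", cls)
    i
  }
  i <- row_of(numerator); j <- row_of(denominator)
  tibble::tibble(
    group = c("control", "case"),
    value = c(reference$conc_mean_control[i] / reference$conc_mean_control[j],
              reference$conc_mean_case[i] / reference$conc_mean_case[j])
  )
}

#' Compute the full index table
#'
#' Per-sample values of the surrogate enzyme activities (SCD1 split into its
#' 16- and 18-carbon edges; ELOVL3/5/6, FADS1/2 averaged over their edges),
#' the Valenzuela indices, the n-6/n-3 ratio, the n-3 index, and the TG/DG
#' and PC/PE concentration ratios. All indices are computed on total-lipid
#' mol% (enzyme/series indices) or class concentrations (class ratios) and
#' are invariant to rescaling a sample's concentrations.
#'
#' @param x Concentration matrix or `"lipid_sim"`.
#' @param edges Pathway edge table, see [default_pathway_edges()].
#' @param panel Optional pre-parsed panel.
#' @return Tidy tibble: `index`, `sample`, `value`, `defined`.
#' @export
compute_indices <- function(x, edges = default_pathway_edges(), panel = NULL) {
  mat <- as_conc_matrix(x)
  if (is.null(panel)) panel <- parse_panel(rownames(mat))
  profile <- fatty_acid_composition(mat, scope = "total", panel = panel)
  cc <- class_concentrations(mat, panel = panel)

  parts <- list()
  for (enz in unique(edges$enzyme)) {
    e <- edges[edges$enzyme == enz, , drop = FALSE]
    per_edge <- lapply(seq_len(nrow(e)), function(i) {
      product_precursor_ratio(profile, e$precursor[i], e$product[i])
    })
    if (enz == "SCD1") {
      for (i in seq_len(nrow(e))) {
        pre <- parse_edge_fa(e$precursor[i])
        nm <- sprintf("SCD1_%d", pre$carbons)
        parts[[nm]] <- dplyr::mutate(per_edge[[i]], index = nm)
      }
    } else {
      vals <- sapply(per_edge, `[[`, "value")
      defs <- sapply(per_edge, `[[`, "defined")
      if (is.null(dim(vals))) { vals <- rbind(vals); defs <- rbind(defs) }
      parts[[enz]] <- tibble::tibble(
        index = enz,
        sample = per_edge[[1]]$sample,
        value = rowMeans(vals),
        defined = apply(defs, 1, all)
      )
    }
  }
  val <- valenzuela_indices(profile)
  n63 <- dplyr::mutate(n6_n3_ratio(profile), index = "N6_N3_RATIO")
  n3i <- dplyr::mutate(n3_index(profile), index = "N3_INDEX", defined = TRUE)
  tgdg <- dplyr::mutate(class_ratio(cc, "TG", "DG"), index = "TG_DG_RATIO")
  pcpe <- dplyr::mutate(class_ratio(cc, "PC", "PE"), index = "PC_PE_RATIO")

  dplyr::bind_rows(dplyr::bind_rows(parts), val, n63, n3i, tgdg, pcpe) |>
    dplyr::select(dplyr::all_of(c("index", "sample", "value", "defined")))
}
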