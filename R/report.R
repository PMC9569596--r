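# Pipeline orchestration and study-style report tables.

#' Per-class group statistics (study-table layout)
#'
#' For every lipid class: number of detected member species, group mean and
#' SD of the class concentration and of the class mol% composition (mean of
#' per-sample ratios), Welch p-values on both scales, and the counts of
#' member species significantly down-/up-regulated (case vs control) on each
#' scale.
#'
#' @param x Concentration matrix or `"lipid_sim"`.
#' @param design A [study_design()].
#' @param alpha Significance level (inclusive).
#' @param panel Optional pre-parsed panel.
#' @return Tibble with one row per class present in the data; `*_control` /
#'   `*_case` columns follow the design's group order. Group labels are kept
#'   in the `"groups"` attribute.
#' @export
class_group_stats <- function(x, design, alpha = 0.05, panel = NULL) {
  mat <- as_conc_matrix(x)
  if (inherits(x, "lipid_sim") && missing(design)) design <- x$design
  mat <- mat[, design$sample, drop = FALSE]
  if (is.null(panel)) panel <- parse_panel(rownames(mat))
  detected <- rowSums(mat != 0) > 0

  # class-level matrices on both scales
  by_class <- rowsum(mat, group = panel$lipid_class)
  totals <- colSums(mat)
  if (any(totals <= 0)) {
    stop_lp("sample(s) with zero total concentration: %s",
            paste(colnames(mat)[totals <= 0], collapse = ", "))
  }
  comp_class <- sweep(by_class, 2, totals, "/") * 100

  dt_conc <- differential_table(by_class, design, alpha, level = "class")
  dt_comp <- differential_table(comp_class, design, alpha, level = "class")

  # species-level significance counts per class, both scales
  sp_mat <- mat[detected, , drop = FALSE]
  sp_cls <- panel$lipid_class[detected]
  sp_conc <- differential_table(sp_mat, design, alpha, level = "species")
  sp_comp <- differential_table(sweep(sp_mat, 2, totals, "/") * 100,
                                design, alpha, level = "species")
  labels <- levels(design$group)
  count_updown <- function(dt) {
    diff <- dt[[paste0("mean_", labels[2])]] - dt[[paste0("mean_", labels[1])]]
    data.frame(
      down = as.integer(rowsum(as.integer(dt$significant & diff < 0), sp_cls)),
      up = as.integer(rowsum(as.integer(dt$significant & diff > 0), sp_cls)),
      row.names = sort(unique(sp_cls))
    )
  }
  ud_conc <- count_updown(sp_conc)
  ud_comp <- count_updown(sp_comp)

  cls <- rownames(by_class)
  pick <- function(dt, col) dt[[col]][match(cls, dt$feature)]
  n_species <- as.integer(rowsum(as.integer(detected), panel$lipid_class))
  out <- tibble::tibble(
    lipid_class = cls,
    category = class_to_category(cls),
    n_species = n_species,
    conc_mean_control = pick(dt_conc, paste0("mean_", labels[1])),
    conc_sd_control = pick(dt_conc, paste0("sd_", labels[1])),
    conc_mean_case = pick(dt_conc, paste0("mean_", labels[2])),
    conc_sd_case = pick(dt_conc, paste0("sd_", labels[2])),
    conc_p = pick(dt_conc, "p"),
    conc_species_down = ud_conc[cls, "down"],
    conc_species_up = ud_conc[cls, "up"],
    comp_mean_control = pick(dt_comp, paste0("mean_", labels[1])),
    comp_sd_control = pick(dt_comp, paste0("sd_", labels[1])),
    comp_mean_case = pick(dt_comp, paste0("mean_", labels[2])),
    comp_sd_case = pick(dt_comp, paste0("sd_", labels[2])),
    comp_p = pick(dt_comp, "p"),
    comp_species_down = ud_comp[cls, "down"],
    comp_species_up = ud_comp[cls, "up"]
  )
  # present classes in the conventional category order
  out <- out[order(match(out$lipid_class, lipid_classes())), ]
  attr(out, "groups") <- labels
  attr(out, "alpha") <- alpha
  out
}

#' Render class statistics as a formatted summary table
#'
#' Concentration and composition cells as `"mean +/- SD"` at 3 decimals,
#' with significant cells (Welch p <= alpha) marked by a trailing `*`;
#' column layout mirrors the published class table.
#'
#' @param class_stats Result of [class_group_stats()] (or a
#'   [class_reference()]-layout table, in which case no significance marks
#'   are available).
#' @param alpha Significance level for the marks.
#' @param digits Decimals for means and SDs.
#' @return A tibble of formatted strings.
#' @export
render_table1 <- function(class_stats, alpha = 0.05, digits = 3) {
  cell <- function(m, s, sig = FALSE) {
    out <- sprintf(paste0("%.", digits, "f ± %.", digits, "f"), m, s)
    out[is.na(m)] <- "0.000 ± 0.000"
    paste0(out, ifelse(sig, " *", ""))
  }
  has_p <- all(c("conc_p", "comp_p") %in% names(class_stats))
  conc_sig <- if (has_p) !is.na(class_stats$conc_p) & class_stats$conc_p <= alpha
              else rep(FALSE, nrow(class_stats))
  comp_sig <- if (has_p) !is.na(class_stats$comp_p) & class_stats$comp_p <= alpha
              else rep(FALSE, nrow(class_stats))
  tibble::tibble(
    lipid_class = class_stats$lipid_class,
    category = class_stats$category,
    n_species = class_stats$n_species,
    conc_control = cell(class_stats$conc_mean_control,
                        class_stats$conc_sd_control),
    conc_case = cell(class_stats$conc_mean_case, class_stats$conc_sd_case,
                     conc_sig),
    conc_down = class_stats$conc_species_down,
    conc_up = class_stats$conc_species_up,
    comp_control = cell(class_stats$comp_mean_control,
                        class_stats$comp_sd_control),
    comp_case = cell(class_stats$comp_mean_case, class_stats$comp_sd_case,
                     comp_sig),
    comp_down = class_stats$comp_species_down,
    comp_up = class_stats$comp_species_up
  )
}

#' Pipeline run configuration
#'
#' @param matrix_path,metadata_path Input TSVs ([read_concentration_matrix()]
#'   layout); `NULL` to simulate instead.
#' @param group_col Group column in the metadata file.
#' @param alpha Significance level.
#' @param sc_lc_cutoff LC-PUFA carbons cutoff.
#' @param seed Seed for the simulation branch.
#' @param out_dir Output directory (created if missing).
#' @return A list of class `"run_config"`.
#' @export
run_config <- function(matrix_path = NULL, metadata_path = NULL,
                       group_col = "group", alpha = 0.05,
                       sc_lc_cutoff = 20L, seed = 1L, out_dir = "lipidpanel_out") {
  if (!(alpha > 0 && alpha < 1)) stop_lp("alpha must be in (0, 1)")
  structure(list(matrix_path = matrix_path, metadata_path = metadata_path,
                 group_col = group_col, alpha = alpha,
                 sc_lc_cutoff = as.integer(sc_lc_cutoff),
                 seed = as.integer(seed), out_dir = out_dir),
            class = "run_config")
}

# fatty-acid-by-class logFC/significance export (the numeric heat map)
fa_class_heatmap <- function(mat, design, alpha, panel) {
  prof_cls <- fatty_acid_composition(mat, scope = "class", panel = panel)
  prof_tot <- fatty_acid_composition(mat, scope = "total", panel = panel)
  prof <- dplyr::bind_rows(prof_tot, prof_cls)
  out <- list()
  for (sc in unique(prof$scope)) {
    wide <- t(profile_wide(prof, sc))   # fa x sample
    wide <- wide[, design$sample, drop = FALSE]
    dt <- differential_table(wide, design, alpha, level = "fa")
    labels <- attr(dt, "groups")
    out[[sc]] <- tibble::tibble(scope = sc, fa = dt$feature,
                                logFC = dt$logFC, p = dt$p,
                                significant = dt$significant)
  }
  dplyr::bind_rows(out)
}

#' Run the full lipid-panel pipeline
#'
#' Either reads a concentration matrix and metadata from `config` paths or
#' simulates the default calibrated panel, then computes and writes to
#' `config$out_dir`:
#' * `class_stats.tsv` / `table1.tsv` — per-class group statistics, raw and
#'   formatted (class, species count, concentration and mol% mean +/- SD per
#'   group, per-class up/down species counts);
#' * `fa_profile_total.tsv`, `fa_profile_class.tsv` — fatty-acid profiles;
#' * `fa_heatmap.tsv` — fatty-acid-by-scope logFC with significance flags;
#' * `indices.tsv`, `indices_diff.tsv` — per-sample index values and their
#'   group comparison;
#' * `species_differential.tsv`, `summary.tsv` — per-species Welch results
#'   and the significant/up/down fractions;
#' * for simulated runs also `concentrations.tsv`, `metadata.tsv`,
#'   `ground_truth.tsv`.
#'
#' Every tunable setting in effect is logged to stderr.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with all computed tables (`class_stats`,
#'   `table1`, `fa_profile_total`, `fa_profile_class`, `fa_heatmap`,
#'   `indices`, `indices_diff`, `species_differential`, `summary`, `design`).
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  emit <- function(...) message("[lipidpanel] ", sprintf(...))
  emit("alpha = %g (inclusive, raw p); logFC base = 2; LC-PUFA cutoff = %d carbons",
       config$alpha, config$sc_lc_cutoff)

  if (is.null(config$matrix_path)) {
    emit("no input matrix: simulating the default calibrated panel (seed %d)",
         config$seed)
    panel <- generate_panel(panel_spec(), seed = config$seed)
    sim <- simulate_concentrations(panel, seed = config$seed + 1L)
    mat <- sim$concentrations
    design <- sim$design
    write_concentration_matrix(mat, file.path(config$out_dir, "concentrations.tsv"))
    write_design(design, file.path(config$out_dir, "metadata.tsv"))
    readr::write_tsv(sim$truth, file.path(config$out_dir, "ground_truth.tsv"))
  } else {
    if (!file.exists(config$matrix_path) || file.size(config$matrix_path) == 0) {
      stop_lp("input matrix file missing or empty: %s", config$matrix_path)
    }
    mat <- read_concentration_matrix(config$matrix_path)
    design <- read_design(config$metadata_path, config$group_col)
  }
  missing <- setdiff(design$sample, colnames(mat))
  if (length(missing)) {
    stop_lp("sample(s) in metadata but not in matrix: %s",
            paste(missing, collapse = ", "))
  }
  panel_tab <- parse_panel(rownames(mat))
  emit("%d species (%d detected), %d classes, groups %s",
       nrow(mat), sum(rowSums(mat[, design$sample]) > 0),
       length(unique(panel_tab$lipid_class)),
       paste(sprintf("%s (n=%d)", levels(design$group), table(design$group)),
             collapse = " vs "))

  stats <- class_group_stats(mat, design, config$alpha, panel = panel_tab)
  table1 <- render_table1(stats, config$alpha)
  prof_tot <- fatty_acid_composition(mat, "total", panel = panel_tab)
  prof_cls <- fatty_acid_composition(mat, "class", panel = panel_tab)
  heat <- fa_class_heatmap(mat, design, config$alpha, panel_tab)
  idx <- compute_indices(mat, panel = panel_tab)
  idx_wide <- t(profile_like_matrix(idx))
  idx_diff <- differential_table(idx_wide[, design$sample, drop = FALSE],
                                 design, config$alpha, level = "index")
  detected <- rowSums(mat[, design$sample, drop = FALSE] != 0) > 0
  sp_diff <- differential_table(mat[detected, design$sample, drop = FALSE],
                                design, config$alpha, level = "species")
  summ <- differential_summary(mat, design, config$alpha)

  res <- list(class_stats = stats, table1 = table1,
              fa_profile_total = prof_tot, fa_profile_class = prof_cls,
              fa_heatmap = heat, indices = idx, indices_diff = idx_diff,
              species_differential = sp_diff, summary = summ, design = design)
  files <- c(class_stats = "class_stats.tsv", table1 = "table1.tsv",
             fa_profile_total = "fa_profile_total.tsv",
             fa_profile_class = "fa_profile_class.tsv",
             fa_heatmap = "fa_heatmap.tsv", indices = "indices.tsv",
             indices_diff = "indices_diff.tsv",
             species_differential = "species_differential.tsv",
             summary = "summary.tsv")
  for (nm in names(files)) {
    readr::write_tsv(res[[nm]], file.path(config$out_dir, files[[nm]]))
  }
  emit("%.1f%% of detected species significant (%.1f%% up, %.1f%% down)",
       summ$pct_significant, summ$pct_up, summ$pct_down)
  invisible(res)
}

# index table -> samples x index matrix
profile_like_matrix <- function(idx) {
  samples <- unique(idx$sample)
  indices <- unique(idx$index)
  m <- matrix(NA_real_, length(samples), length(indices),
              dimnames = list(samples, indices))
  m[cbind(match(idx$sample, samples), match(idx$index, indices))] <- idx$value
  m
}
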