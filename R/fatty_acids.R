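# Fatty-acid identities: carbons, double bonds, series, and the derived
# saturation and chain-length classes used for profile rollups.

.series_levels <- c("n-3", "n-6", "n-7", "n-9", "saturated", "unassigned")

# Canonical physiological isomers: MRM panels report only carbons:double_bonds,
# so each combination is mapped to the isomer that dominates in mammalian
# tissue (e.g. 18:2 -> linoleic acid, n-6; 22:6 -> DHA, n-3). Combinations not
# listed here stay "unassigned" and are excluded from series rollups.
.default_series <- tibble::tribble(
  ~carbons, ~double_bonds, ~series,
  16L, 1L, "n-7",
  17L, 1L, "n-7",
  18L, 1L, "n-9",
  20L, 1L, "n-9",
  22L, 1L, "n-9",
  24L, 1L, "n-9",
  26L, 1L, "n-9",
  18L, 2L, "n-6",
  18L, 3L, "n-3",
  18L, 4L, "n-3",
  20L, 2L, "n-6",
  20L, 3L, "n-6",
  20L, 4L, "n-6",
  20L, 5L, "n-3",
  22L, 2L, "n-6",
  22L, 4L, "n-6",
  22L, 5L, "n-3",
  22L, 6L, "n-3"
)

#' Default series lookup table
#'
#' Maps `(carbons, double_bonds)` to the canonical physiological isomer's
#' series (n-3, n-6, n-7 or n-9). Direct-infusion MRM lipidomics cannot
#' resolve double-bond positional isomers, so the assignment is by convention:
#' each combination is mapped to the isomer overwhelmingly most abundant in
#' mammalian tissue (18:2 is treated as linoleic acid, 18:3 as alpha-linolenic
#' acid, 20:4 as arachidonic acid, and so on). Combinations absent from the
#' table with at least one double bond are `"unassigned"`; saturated chains
#' never consult the table.
#'
#' A copy ships as plain text in
#' `system.file("extdata", "fa_series.tsv", package = "lipidpanel")`; edit a
#' copy and load it with [read_series_table()] to override the defaults.
#'
#' @return A tibble with columns `carbons`, `double_bonds`, `series`.
#' @export
#' @examples
#' default_series_table()
default_series_table <- function() .default_series

#' Read a fatty-acid series lookup table from a TSV file
#'
#' The file must be tab-delimited with a header row and columns `carbons`,
#' `double_bonds`, `series` (values among n-3, n-6, n-7, n-9).
#'
#' @param path Path to the table.
#' @return A tibble usable wherever `series_table` is accepted.
#' @export
read_series_table <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE)
  need <- c("carbons", "double_bonds", "series")
  if (!all(need %in% names(tab))) {
    stop_lp("series table must have columns: %s", paste(need, collapse = ", "))
  }
  bad <- setdiff(unique(tab$series), c("n-3", "n-6", "n-7", "n-9"))
  if (length(bad)) stop_lp("unknown series label(s): %s", paste(bad, collapse = ", "))
  tibble::tibble(
    carbons = as.integer(tab$carbons),
    double_bonds = as.integer(tab$double_bonds),
    series = as.character(tab$series)
  )
}

#' Construct fatty-acid records
#'
#' Vectorised constructor; validates chain chemistry (carbons >= 2, double
#' bonds between 0 and carbons/2) and fills the `series` slot via
#' [assign_series()] unless given explicitly.
#'
#' @param carbons Integer vector of chain carbons.
#' @param double_bonds Integer vector of C=C double bonds.
#' @param series Optional explicit series labels (recycled); `NA` entries are
#'   filled from the lookup table.
#' @param series_table Lookup table, see [default_series_table()].
#' @return A tibble with columns `carbons`, `double_bonds`, `series`.
#' @export
#' @examples
#' fatty_acid(22, 6)   # DHA -> n-3
#' fatty_acid(20, 4)   # arachidonic acid -> n-6
fatty_acid <- function(carbons, double_bonds, series = NULL,
                       series_table = default_series_table()) {
  carbons <- as.integer(carbons)
  double_bonds <- as.integer(double_bonds)
  n <- max(length(carbons), length(double_bonds))
  carbons <- rep_len(carbons, n)
  double_bonds <- rep_len(double_bonds, n)
  if (anyNA(carbons) || any(carbons < 2L)) {
    stop_lp("fatty-acid carbons must be integers >= 2")
  }
  if (anyNA(double_bonds) || any(double_bonds < 0L) ||
      any(double_bonds > carbons %/% 2L)) {
    stop_lp("double bonds must lie in [0, carbons/2]")
  }
  auto <- assign_series(carbons, double_bonds, series_table)
  if (is.null(series)) {
    series <- auto
  } else {
    series <- rep_len(as.character(series), n)
    series[is.na(series)] <- auto[is.na(series)]
    series[!series %in% .series_levels] <- "unassigned"
    # a chain with no double bond is saturated no matter what the caller says
    series[double_bonds == 0L] <- "saturated"
  }
  tibble::tibble(carbons = carbons, double_bonds = double_bonds, series = series)
}

#' Assign the fatty-acid series from the canonical-isomer lookup
#'
#' Total and idempotent: saturated chains map to `"saturated"`, unsaturated
#' chains found in the lookup table map to their canonical series, and
#' everything else maps to `"unassigned"`.
#'
#' @inheritParams fatty_acid
#' @return Character vector of series labels.
#' @export
assign_series <- function(carbons, double_bonds,
                          series_table = default_series_table()) {
  carbons <- as.integer(carbons)
  double_bonds <- as.integer(double_bonds)
  key <- paste(carbons, double_bonds)
  idx <- match(key, paste(series_table$carbons, series_table$double_bonds))
  out <- series_table$series[idx]
  out[is.na(out)] <- "unassigned"
  out[double_bonds == 0L] <- "saturated"
  out
}

#' Saturation class of a chain
#'
#' @param double_bonds Integer vector.
#' @return `"SFA"` (0 double bonds), `"MUFA"` (1) or `"PUFA"` (>= 2).
#' @export
saturation_class <- function(double_bonds) {
  double_bonds <- as.integer(double_bonds)
  ifelse(double_bonds == 0L, "SFA", ifelse(double_bonds == 1L, "MUFA", "PUFA"))
}

#' Chain-length class of a PUFA
#'
#' Long-chain PUFAs are, by the standard lipid-biochemistry convention,
#' polyunsaturated chains with at least `lc_cutoff` (default 20) carbons —
#' AA (20:4), EPA (20:5) and DHA (22:6) are the archetypes. Chains with fewer
#' carbons and >= 2 double bonds are short-chain PUFAs; everything else is
#' `"not-PUFA"`.
#'
#' @inheritParams fatty_acid
#' @param lc_cutoff Minimum carbons for a long-chain PUFA.
#' @return Character vector among `"SC-PUFA"`, `"LC-PUFA"`, `"not-PUFA"`.
#' @export
#' @examples
#' classify_chain_length(c(20, 18, 18), c(5, 2, 1))
classify_chain_length <- function(carbons, double_bonds, lc_cutoff = 20L) {
  carbons <- as.integer(carbons)
  double_bonds <- as.integer(double_bonds)
  ifelse(double_bonds < 2L, "not-PUFA",
         ifelse(carbons >= lc_cutoff, "LC-PUFA", "SC-PUFA"))
}

#' Fatty-acid display label
#'
#' @inheritParams fatty_acid
#' @return Labels like `"C18:2"`.
#' @export
fa_label <- function(carbons, double_bonds) {
  sprintf("C%d:%d", as.integer(carbons), as.integer(double_bonds))
}
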