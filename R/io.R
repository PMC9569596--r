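# Tab-delimited I/O: species x sample matrices, sample metadata, and tidy
# result tables. All files are UTF-8, tab-delimited, '.' decimal separator,
# header row mandatory; numeric output is written at full precision.

#' Read a species-by-sample concentration matrix from TSV
#'
#' First column: shorthand species names; remaining columns: samples.
#'
#' @param path Path to the TSV file.
#' @return Numeric matrix with species rownames and sample colnames.
#' @export
read_concentration_matrix <- function(path) {
  # base read.delim: strtod parsing is correctly rounded, so matrices written
  # at 17 significant digits round-trip bit-identically
  tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 2L) stop_lp("matrix file needs a species column plus >= 1 sample")
  species <- as.character(tab[[1]])
  if (anyDuplicated(species)) stop_lp("duplicated species names in %s", path)
  m <- as.matrix(tab[, -1, drop = FALSE])
  if (!is.numeric(m)) stop_lp("non-numeric sample columns in %s", path)
  rownames(m) <- species
  m
}

#' Write a species-by-sample matrix to TSV
#'
#' @param mat Matrix with dimnames.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_concentration_matrix <- function(mat, path) {
  tab <- tibble::as_tibble(mat, rownames = "species")
  # 17 significant digits guarantee bit-exact double round-trips
  num <- vapply(tab, is.numeric, logical(1))
  tab[num] <- lapply(tab[num], function(v) sprintf("%.17g", v))
  readr::write_tsv(tab, path)
  invisible(path)
}

#' Read a sample metadata table from TSV
#'
#' Needs columns `sample` and the group column (default `group`); the first
#' group label encountered becomes the control (reference) level.
#'
#' @param path Path to the TSV file.
#' @param group_col Name of the group column.
#' @return Design tibble (`sample`, `group` factor).
#' @export
read_design <- function(path, group_col = "group") {
  tab <- readr::read_tsv(path, show_col_types = FALSE)
  if (!all(c("sample", group_col) %in% names(tab))) {
    stop_lp("metadata needs columns 'sample' and '%s'", group_col)
  }
  g <- as.character(tab[[group_col]])
  lev <- unique(g)
  if (length(lev) != 2L) stop_lp("expected exactly two groups, found %d", length(lev))
  tibble::tibble(sample = as.character(tab$sample),
                 group = factor(g, levels = lev))
}

#' Write a design tibble to TSV
#' @param design Design tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_design <- function(design, path) {
  readr::write_tsv(design, path)
  invisible(path)
}
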