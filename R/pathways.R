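# Desaturase/elongase pathway edges for surrogate enzyme-activity indices.

# Figure-derived defaults: SCD1's two edges are stated explicitly in the
# source pathway scheme; the ELOVL/FADS edges follow the standard n-3/n-6/
# MUFA biosynthesis route and are configurable via read_pathway_edges().
.default_edges <- tibble::tribble(
  ~enzyme, ~step, ~precursor, ~product,
  "SCD1",   "desaturase", "16:0",    "16:1",
  "SCD1",   "desaturase", "18:0",    "18:1",
  "ELOVL6", "elongase",   "16:0",    "18:0",
  "ELOVL3", "elongase",   "20:1",    "22:1",
  "ELOVL3", "elongase",   "22:1",    "24:1",
  "ELOVL5", "elongase",   "18:3n-6", "20:3n-6",
  "ELOVL5", "elongase",   "20:5n-3", "22:5n-3",
  "FADS2",  "desaturase", "18:2n-6", "18:3n-6",
  "FADS2",  "desaturase", "18:3n-3", "18:4n-3",
  "FADS1",  "desaturase", "20:3n-6", "20:4n-6",
  "FADS1",  "desaturase", "20:4n-3", "20:5n-3"
)

parse_edge_fa <- function(token) {
  m <- regmatches(token, regexec(.chain_token_rx, token))[[1]]
  if (length(m) == 0L) stop_lp("malformed fatty-acid token '%s' in pathway edge", token)
  list(carbons = as.integer(m[2]), double_bonds = as.integer(m[3]))
}

validate_edges <- function(edges) {
  need <- c("enzyme", "step", "precursor", "product")
  if (!all(need %in% names(edges))) {
    stop_lp("pathway edge table needs columns: %s", paste(need, collapse = ", "))
  }
  if (any(!nzchar(edges$enzyme))) stop_lp("pathway edges need a nonempty enzyme label")
  for (i in seq_len(nrow(edges))) {
    pre <- parse_edge_fa(edges$precursor[i])
    pro <- parse_edge_fa(edges$product[i])
    elong <- pro$carbons == pre$carbons + 2L && pro$double_bonds == pre$double_bonds
    desat <- pro$carbons == pre$carbons && pro$double_bonds == pre$double_bonds + 1L
    if (!(elong || desat)) {
      stop_lp("edge %s -> %s (%s) is neither a +2-carbon elongation nor a +1-double-bond desaturation",
              edges$precursor[i], edges$product[i], edges$enzyme[i])
    }
  }
  edges
}

#' Default desaturase/elongase pathway edges
#'
#' Product-to-precursor edges for SCD1 (16:0 -> 16:1, 18:0 -> 18:1), ELOVL6,
#' ELOVL3, ELOVL5, FADS1 and FADS2. The two SCD1 edges are canonical; the
#' remaining edges follow the standard MUFA and n-3/n-6 PUFA biosynthesis
#' schemes and can be overridden from a plain-text table with
#' [read_pathway_edges()]. Note that the panel resolves chains only to
#' `carbons:double_bonds`, so series-annotated edge endpoints (e.g. `20:4n-3`)
#' are matched to the corresponding `C20:4` profile bucket.
#'
#' @return Tibble with columns `enzyme`, `step`, `precursor`, `product`.
#' @export
default_pathway_edges <- function() validate_edges(.default_edges)

#' Read a pathway edge table from a TSV file
#'
#' Tab-delimited with header `enzyme`, `step`, `precursor`, `product`; chain
#' tokens use the `c:d` shorthand with optional `n-k` suffix. Each edge must
#' be a +2-carbon elongation or a +1-double-bond desaturation.
#'
#' @param path Path to the table.
#' @return Validated edge tibble.
#' @export
read_pathway_edges <- function(path) {
  validate_edges(readr::read_tsv(path, show_col_types = FALSE,
                                 col_types = readr::cols(.default = "c")))
}
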