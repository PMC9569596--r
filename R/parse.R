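# Shorthand lipid nomenclature: CLASS(c:d), CLASS(c1:d1/c2:d2), and the
# sum-composition dialect CLASS(total_c:total_db) FA c:d used for TG, where
# only one esterified fatty acid is reported per species.

.lipid_classes <- c("TG", "DG", "MG", "PC", "PE", "PI", "LPC", "LPE",
                    "Cer", "HexCer", "LacCer", "dhCer", "SM", "CE")

.category_map <- c(
  TG = "glycerolipid", DG = "glycerolipid", MG = "glycerolipid",
  PC = "phospholipid", PE = "phospholipid", PI = "phospholipid",
  LPC = "phospholipid", LPE = "phospholipid",
  Cer = "sphingolipid", HexCer = "sphingolipid", LacCer = "sphingolipid",
  dhCer = "sphingolipid", SM = "sphingolipid",
  CE = "sterol"
)

# classes whose shorthand carries exactly one acyl chain; for sphingolipids
# that chain is the N-acyl chain (the sphingoid backbone is not modelled)
.single_chain_classes <- c("CE", "MG", "LPC", "LPE",
                           "Cer", "HexCer", "LacCer", "dhCer", "SM")

#' Supported lipid classes
#'
#' The 14 class abbreviations of the complex-lipid panel: triacylglycerols
#' (TG), diacylglycerols (DG), monoacylglycerols (MG), phosphatidylcholines
#' (PC), phosphatidylethanolamines (PE), phosphatidylinositols (PI),
#' lysophosphatidylcholines (LPC), lysophosphatidylethanolamines (LPE),
#' ceramides (Cer), hexosylceramides (HexCer), lactosylceramides (LacCer),
#' dihydroceramides (dhCer), sphingomyelins (SM), cholesteryl esters (CE).
#'
#' @return Character vector of the 14 abbreviations.
#' @export
lipid_classes <- function() .lipid_classes

#' Map a lipid class to its category
#'
#' The 14 classes partition into four categories: glycerolipids (TG, DG, MG),
#' phospholipids (PC, PE, PI, LPC, LPE), sphingolipids (Cer, HexCer, LacCer,
#' dhCer, SM) and sterols (CE).
#'
#' @param lipid_class Character vector of class abbreviations.
#' @return Character vector of categories.
#' @export
#' @examples
#' class_to_category(c("CE", "SM", "TG"))
class_to_category <- function(lipid_class) {
  out <- unname(.category_map[as.character(lipid_class)])
  if (anyNA(out)) {
    bad <- unique(lipid_class[is.na(out)])
    stop_lp("unknown lipid class: %s", paste(bad, collapse = ", "))
  }
  out
}

.chain_token_rx <- "^([0-9]+):([0-9]+)(?:n-([0-9]+))?$"

parse_chain_token <- function(token, name, position, series_table) {
  m <- regmatches(token, regexec(.chain_token_rx, token))[[1]]
  if (length(m) == 0L) {
    stop_lp("malformed chain token '%s' at position %d in '%s'",
            token, position, name)
  }
  carbons <- as.integer(m[2])
  db <- as.integer(m[3])
  series <- NA_character_
  if (nzchar(m[4])) {
    explicit <- paste0("n-", m[4])
    series <- if (explicit %in% c("n-3", "n-6", "n-7", "n-9")) explicit else "unassigned"
  }
  list(carbons = carbons, double_bonds = db, series = series,
       explicit = nzchar(m[4]))
}

#' Parse a shorthand lipid species name
#'
#' Supported dialects:
#' * `CLASS(c:d)` — one specified chain (single-chain classes, or a
#'   one-chain-specified DG/PC/PE/PI);
#' * `CLASS(c1:d1/c2:d2)` — two specified chains (DG, PC, PE, PI);
#' * `CLASS(total_c:total_db) FA c:d` — sum composition plus one specified
#'   esterified fatty acid. TG species must use this dialect: the panel
#'   reports only one esterified fatty acid per triacylglycerol.
#'
#' Any chain token may carry an explicit series suffix (`18:3n-6`); the suffix
#' overrides the canonical-isomer lookup. Sphingolipid tokens describe the
#' N-acyl chain only.
#'
#' @param name Species name string.
#' @param series_table Series lookup, see [default_series_table()].
#' @return An object of class `"lipid_species"`: a list with `name`,
#'   `lipid_class`, `chains` (tibble of carbons/double_bonds/series),
#'   `total_carbons`, `total_double_bonds` (NA unless the sum dialect was
#'   used) and `dialect`.
#' @export
#' @examples
#' parse_species_name("TG(52:3) FA 18:2")
#' parse_species_name("PC(16:0/20:4)")
parse_species_name <- function(name, series_table = default_series_table()) {
  stopifnot(is.character(name), length(name) == 1L)
  rx <- "^\\s*([A-Za-z]+)\\(([^()]+)\\)(?:\\s+FA\\s+(\\S+))?\\s*$"
  m <- regmatches(name, regexec(rx, name))[[1]]
  if (length(m) == 0L) stop_lp("cannot parse species name '%s'", name)
  cls <- m[2]
  if (!cls %in% .lipid_classes) {
    stop_lp("unknown class '%s' in species name '%s'", cls, name)
  }
  tokens <- trimws(strsplit(m[3], "/", fixed = TRUE)[[1]])
  fa_token <- m[4]
  has_fa <- nzchar(fa_token)

  total_c <- NA_integer_
  total_db <- NA_integer_
  if (has_fa) {
    if (length(tokens) != 1L) {
      stop_lp("'%s': the FA dialect requires a single sum-composition token", name)
    }
    sum_tok <- parse_chain_token(tokens[1], name, 1L, series_table)
    total_c <- sum_tok$carbons
    total_db <- sum_tok$double_bonds
    chain_toks <- list(parse_chain_token(fa_token, name, 2L, series_table))
    if (chain_toks[[1]]$carbons > total_c ||
        chain_toks[[1]]$double_bonds > total_db) {
      stop_lp("'%s': specified fatty acid exceeds the sum composition", name)
    }
  } else {
    if (cls == "TG") {
      stop_lp("'%s': TG species must use the sum-composition dialect 'TG(c:d) FA c:d'",
              name)
    }
    chain_toks <- lapply(seq_along(tokens), function(i) {
      parse_chain_token(tokens[i], name, i, series_table)
    })
  }

  n_chains <- length(chain_toks)
  if (cls %in% .single_chain_classes && n_chains != 1L) {
    stop_lp("'%s': class %s carries exactly one acyl chain", name, cls)
  }
  if (cls %in% c("DG", "PC", "PE", "PI") && !n_chains %in% c(1L, 2L)) {
    stop_lp("'%s': class %s carries one or two chains", name, cls)
  }

  carbons <- vapply(chain_toks, `[[`, integer(1), "carbons")
  dbs <- vapply(chain_toks, `[[`, integer(1), "double_bonds")
  series <- vapply(chain_toks, `[[`, character(1), "series")
  chains <- fatty_acid(carbons, dbs, series = series, series_table = series_table)

  structure(
    list(name = name, lipid_class = cls, chains = chains,
         total_carbons = total_c, total_double_bonds = total_db,
         dialect = if (has_fa) "sum_fa" else "chains"),
    class = "lipid_species"
  )
}

#' Format a parsed species back to its canonical shorthand name
#'
#' Emits an explicit `n-k` suffix only where the chain's series differs from
#' the canonical-isomer lookup, so `format(parse(x))` re-parses to an
#' identical structure.
#'
#' @param x A `"lipid_species"` object.
#' @param series_table Series lookup used to decide when a suffix is needed.
#' @return Canonical name string.
#' @export
format_species_name <- function(x, series_table = default_series_table()) {
  stopifnot(inherits(x, "lipid_species"))
  tok <- function(c, d, s) {
    base <- sprintf("%d:%d", c, d)
    default <- assign_series(c, d, series_table)
    if (d > 0L && s %in% c("n-3", "n-6", "n-7", "n-9") && s != default) {
      paste0(base, s)
    } else base
  }
  ch <- x$chains
  toks <- mapply(tok, ch$carbons, ch$double_bonds, ch$series)
  if (x$dialect == "sum_fa") {
    sprintf("%s(%d:%d) FA %s", x$lipid_class, x$total_carbons,
            x$total_double_bonds, toks[1])
  } else {
    sprintf("%s(%s)", x$lipid_class, paste(toks, collapse = "/"))
  }
}

#' @export
print.lipid_species <- function(x, ...) {
  cat(sprintf("<lipid_species> %s [%s, %d chain(s)]\n",
              x$name, x$lipid_class, nrow(x$chains)))
  invisible(x)
}

#' Parse a vector of species names into a panel table
#'
#' @param names Character vector of shorthand species names.
#' @param series_table Series lookup.
#' @return A tibble with one row per species: `species`, `lipid_class`,
#'   `category`, and a `chains` list-column of per-chain tibbles.
#' @export
parse_panel <- function(names, series_table = default_series_table()) {
  parsed <- lapply(names, parse_species_name, series_table = series_table)
  tibble::tibble(
    species = names,
    lipid_class = vapply(parsed, `[[`, character(1), "lipid_class"),
    category = class_to_category(vapply(parsed, `[[`, character(1), "lipid_class")),
    chains = lapply(parsed, `[[`, "chains")
  )
}

#' Long table of specified acyl chains per species
#'
#' Expands a parsed panel into one row per (species, chain); the unit in
#' which species concentrations are attributed to fatty-acid buckets.
#'
#' @param panel Result of [parse_panel()].
#' @return Tibble: `species`, `lipid_class`, `fa`, `carbons`, `double_bonds`,
#'   `series`, `n_chains` (chains of the parent species).
#' @export
chain_table <- function(panel) {
  n_per <- vapply(panel$chains, nrow, integer(1))
  chains <- dplyr::bind_rows(panel$chains)
  tibble::tibble(
    species = rep(panel$species, n_per),
    lipid_class = rep(panel$lipid_class, n_per),
    fa = fa_label(chains$carbons, chains$double_bonds),
    carbons = chains$carbons,
    double_bonds = chains$double_bonds,
    series = chains$series,
    n_chains = rep(n_per, n_per)
  )
}
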