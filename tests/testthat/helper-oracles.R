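# Independent brute-force oracles used to cross-check the package's
# aggregation and statistics. These deliberately avoid the package's parsing
# and aggregation code paths: plain loops and a minimal regex chain reader.

# class abbreviation straight off the name prefix
oracle_class_of <- function(name) sub("\\(.*$", "", name)

# specified chains as a list of c(carbons, double_bonds); minimal independent
# reader of the shorthand grammar
oracle_chains_of <- function(name) {
  if (grepl(" FA ", name, fixed = TRUE)) {
    toks <- sub("^.* FA ", "", name)
  } else {
    inner <- sub("^[A-Za-z]+\\(", "", sub("\\)$", "", name))
    toks <- strsplit(inner, "/", fixed = TRUE)[[1]]
  }
  lapply(toks, function(t) {
    t <- sub("n-[0-9]+$", "", t)
    as.integer(strsplit(t, ":", fixed = TRUE)[[1]])
  })
}

# per-sample class sums by explicit accumulation
oracle_class_sums <- function(mat) {
  out <- list()
  for (s in colnames(mat)) {
    acc <- numeric(0)
    for (sp in rownames(mat)) {
      cls <- oracle_class_of(sp)
      if (is.na(acc[cls])) acc[cls] <- 0
      acc[cls] <- acc[cls] + mat[sp, s]
    }
    out[[s]] <- acc
  }
  out
}

# per-sample fatty-acid mol% by explicit accumulation; scope "total" or a
# class abbreviation
oracle_fa_profile <- function(mat, scope = "total") {
  out <- list()
  for (s in colnames(mat)) {
    acc <- numeric(0)
    for (sp in rownames(mat)) {
      if (scope != "total" && oracle_class_of(sp) != scope) next
      for (ch in oracle_chains_of(sp)) {
        lab <- sprintf("C%d:%d", ch[1], ch[2])
        if (is.na(acc[lab])) acc[lab] <- 0
        acc[lab] <- acc[lab] + mat[sp, s]
      }
    }
    total <- sum(acc)
    out[[s]] <- if (total > 0) 100 * acc / total else acc
  }
  out
}

# small fixture: a mixed-class panel with integer concentrations
tiny_panel_matrix <- function() {
  species <- c("TG(52:3) FA 18:2", "TG(50:1) FA 16:0", "PC(16:0/20:4)",
               "PC(18:0/18:1)", "PE(16:0/22:6)", "CE(18:1)", "SM(16:0)",
               "DG(16:0/18:1)", "LPC(18:2)", "Cer(24:1)")
  m <- matrix(c(4, 2, 3, 1, 2, 5, 1, 2, 1, 1,
                1, 3, 2, 2, 4, 1, 2, 1, 3, 2),
              nrow = length(species),
              dimnames = list(species, c("s1", "s2")))
  m
}
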