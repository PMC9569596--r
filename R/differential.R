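# Two-group statistics: Welch's t-test per feature, one-sample t, logFC,
# significance summaries, and the delta-Ct qPCR expression utility.

#' Welch's two-sample t-test
#'
#' Unpaired t-test without the equal-variance assumption:
#' t = (mean(x) - mean(y)) / sqrt(s2x/nx + s2y/ny), with degrees of freedom
#' by the Welch–Satterthwaite approximation and a two-sided p-value.
#'
#' @param x,y Numeric vectors, each with >= 2 finite values.
#' @return List with `t`, `df`, `p`.
#' @export
#' @examples
#' welch_t_test(c(1, 2, 3), c(2, 4, 6))
welch_t_test <- function(x, y) {
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  nx <- length(x); ny <- length(y)
  if (nx < 2L || ny < 2L) stop_lp("each group needs >= 2 finite values")
  vx <- stats::var(x); vy <- stats::var(y)
  se2 <- vx / nx + vy / ny
  if (se2 == 0) {
    # both groups constant: no evidence of a difference unless means differ
    t <- if (mean(x) == mean(y)) 0 else Inf * sign(mean(x) - mean(y))
    return(list(t = t, df = nx + ny - 2, p = if (is.finite(t)) 1 else 0))
  }
  t <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

# row-wise Welch test for a feature x sample matrix; returns a data frame
welch_rows <- function(mat, is_case) {
  X <- mat[, !is_case, drop = FALSE]
  Y <- mat[, is_case, drop = FALSE]
  nx <- ncol(X); ny <- ncol(Y)
  mx <- rowMeans(X); my <- rowMeans(Y)
  vx <- rowSums((X - mx)^2) / (nx - 1)
  vy <- rowSums((Y - my)^2) / (ny - 1)
  se2 <- vx / nx + vy / ny
  t <- ifelse(se2 > 0, (my - mx) / sqrt(se2),
              ifelse(my == mx, 0, Inf * sign(my - mx)))
  df <- ifelse(se2 > 0,
               se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1)),
               nx + ny - 2)
  p <- ifelse(is.finite(t), 2 * stats::pt(-abs(t), df), 0)
  p[se2 == 0 & my == mx] <- 1
  data.frame(mean_control = mx, sd_control = sqrt(vx),
             mean_case = my, sd_case = sqrt(vy),
             t = t, df = df, p = p)
}

#' One-sample t-test against a reference value
#'
#' Zero-variance inputs are handled by explicit convention rather than
#' returning NaN: all values equal to `mu0` gives t = 0, p = 1; all values
#' equal but different from `mu0` gives t = +/-Inf, p = 0, with
#' `zero_variance = TRUE` either way.
#'
#' @param values Numeric vector with >= 2 finite values.
#' @param mu0 Null value (default 0).
#' @return List with `t`, `df`, `p`, `zero_variance`.
#' @export
one_sample_t <- function(values, mu0 = 0) {
  values <- values[is.finite(values)]
  n <- length(values)
  if (n < 2L) stop_lp("need >= 2 finite values")
  m <- mean(values); s <- stats::sd(values)
  if (s == 0) {
    t <- if (m == mu0) 0 else Inf * sign(m - mu0)
    return(list(t = t, df = n - 1, p = if (m == mu0) 1 else 0,
                zero_variance = TRUE))
  }
  t <- (m - mu0) / (s / sqrt(n))
  list(t = t, df = n - 1, p = 2 * stats::pt(-abs(t), n - 1),
       zero_variance = FALSE)
}

#' Log fold change between two positive group means
#'
#' Base-2 by default (the community convention for lipidomics fold changes).
#'
#' @param mean_case,mean_control Positive group means.
#' @param base Logarithm base.
#' @return `log(mean_case / mean_control, base)`; NA if either mean is not
#'   positive.
#' @export
#' @examples
#' log_fold_change(63.494, 29.687)  # about 1.097
log_fold_change <- function(mean_case, mean_control, base = 2) {
  ifelse(mean_case > 0 & mean_control > 0,
         log(mean_case / mean_control, base), NA_real_)
}

#' Per-feature differential table
#'
#' Welch's t-test per detected feature (row), with group means/SDs, base-2
#' logFC and an inclusive significance flag at `alpha` (p <= alpha). Raw
#' p-values by default — matching the calibrating study's analysis; set
#' `adjust = "BH"` for Benjamini–Hochberg-adjusted significance calls (not
#' the source study's behaviour).
#'
#' @param mat Feature x sample numeric matrix (species concentrations, class
#'   concentrations, mol% values, or index values).
#' @param design A [study_design()] covering the matrix columns.
#' @param alpha Significance level (inclusive).
#' @param level Label stored in the `level` column (e.g. `"species"`,
#'   `"class"`, `"fa"`, `"index"`).
#' @param adjust `"none"` (default) or `"BH"`.
#' @return Tibble: `feature`, `level`, `mean_<control>`, `sd_<control>`,
#'   `mean_<case>`, `sd_<case>`, `logFC`, `t`, `df`, `p`, `significant`.
#'   Column names carry the design's group labels.
#' @export
differential_table <- function(mat, design, alpha = 0.05, level = "species",
                               adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  stopifnot(is.matrix(mat), !is.null(rownames(mat)))
  if (!all(design$sample %in% colnames(mat))) {
    stop_lp("design samples missing from the matrix columns")
  }
  mat <- mat[, design$sample, drop = FALSE]
  is_case <- design$group == levels(design$group)[2]
  if (sum(is_case) < 2L || sum(!is_case) < 2L) {
    stop_lp("each group needs >= 2 samples")
  }
  w <- welch_rows(mat, is_case)
  # features with missing values (e.g. undefined index entries) get NA
  # statistics and are never called significant
  bad <- rowSums(!is.finite(mat)) > 0
  w$t[bad] <- NA_real_; w$df[bad] <- NA_real_; w$p[bad] <- NA_real_
  p_eff <- if (adjust == "BH") stats::p.adjust(w$p, method = "BH") else w$p
  out <- tibble::tibble(
    feature = rownames(mat),
    level = level,
    mean_control = w$mean_control, sd_control = w$sd_control,
    mean_case = w$mean_case, sd_case = w$sd_case,
    logFC = log_fold_change(w$mean_case, w$mean_control),
    t = w$t, df = w$df, p = w$p,
    significant = !is.na(p_eff) & p_eff <= alpha
  )
  labels <- levels(design$group)
  names(out)[names(out) == "mean_control"] <- paste0("mean_", labels[1])
  names(out)[names(out) == "sd_control"] <- paste0("sd_", labels[1])
  names(out)[names(out) == "mean_case"] <- paste0("mean_", labels[2])
  names(out)[names(out) == "sd_case"] <- paste0("sd_", labels[2])
  attr(out, "groups") <- labels
  attr(out, "alpha") <- alpha
  attr(out, "logFC_base") <- 2
  out
}

#' Fractions of significantly regulated features
#'
#' Welch's test per detected feature at `alpha`; "up" and "down" are the
#' significant features with positive / negative logFC (case over control).
#' Percentages are over all detected (non-all-zero) features, so
#' `pct_up + pct_down = pct_significant` exactly.
#'
#' @inheritParams differential_table
#' @return One-row tibble: `n_features`, `n_significant`, `n_up`, `n_down`,
#'   `pct_significant`, `pct_up`, `pct_down`.
#' @export
differential_summary <- function(mat, design, alpha = 0.05) {
  detected <- rowSums(mat[, design$sample, drop = FALSE] != 0) > 0
  dt <- differential_table(mat[detected, , drop = FALSE], design, alpha)
  labels <- attr(dt, "groups")
  diff <- dt[[paste0("mean_", labels[2])]] - dt[[paste0("mean_", labels[1])]]
  sig <- dt$significant
  # direction by the sign of the mean difference (= sign of logFC where the
  # latter is defined); a significant feature always has a nonzero difference,
  # so pct_up + pct_down = pct_significant exactly
  up <- sig & diff > 0
  down <- sig & diff < 0
  n <- nrow(dt)
  pct_up <- 100 * sum(up) / n
  pct_down <- 100 * sum(down) / n
  tibble::tibble(
    n_features = n, n_significant = sum(sig), n_up = sum(up),
    n_down = sum(down),
    # a significant feature always has a nonzero mean difference, so the
    # up/down split partitions the significant set and the sum is exact
    pct_significant = pct_up + pct_down,
    pct_up = pct_up, pct_down = pct_down
  )
}

#' Relative gene expression by the delta-Ct method
#'
#' delta-Ct = Ct(target) - mean(Ct of the reference genes); relative
#' expression = 2^(-delta-Ct). The arithmetic mean of the reference Ct values
#' corresponds to the geometric mean of the reference expression levels.
#'
#' @param ct Sample x gene numeric matrix or data frame of Ct values
#'   (rownames are samples).
#' @param target Target gene name.
#' @param reference Character vector of reference gene names (default the
#'   Eef2/Ppia/Hprt trio used for mouse liver).
#' @return Tibble: `sample`, `delta_ct`, `rel_expression`.
#' @export
#' @examples
#' ct <- matrix(c(25, 20, 20, 20), nrow = 1,
#'              dimnames = list("s1", c("Scd1", "Eef2", "Ppia", "Hprt")))
#' delta_ct_expression(ct, "Scd1")  # 2^-5
delta_ct_expression <- function(ct, target,
                                reference = c("Eef2", "Ppia", "Hprt")) {
  ct <- as.matrix(ct)
  missing <- setdiff(c(target, reference), colnames(ct))
  if (length(missing)) {
    stop_lp("gene(s) not in Ct table: %s", paste(missing, collapse = ", "))
  }
  if (length(reference) < 1L) stop_lp("need >= 1 reference gene")
  if (!all(is.finite(ct[, c(target, reference)]))) {
    stop_lp("Ct values must be finite")
  }
  dct <- ct[, target] - rowMeans(ct[, reference, drop = FALSE])
  tibble::tibble(
    sample = rownames(ct),
    delta_ct = unname(dct),
    rel_expression = 2^(-unname(dct))
  )
}
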