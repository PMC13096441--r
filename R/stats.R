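# Group-level inference and robust outlier handling.

#' Scaled-MAD outlier mask
#'
#' Flags values more than `factor` scaled median absolute deviations from
#' the median, where the scaled MAD is `1.4826 * median(|x - median(x)|)`
#' (the robust standard-deviation analogue). An all-equal vector has no
#' outliers. This rule is used to trim distribution summaries (violin-style
#' descriptives); hypothesis tests run on the full data.
#'
#' @param values Numeric vector (at least one value).
#' @param factor MAD multiplier (default 3).
#' @return Logical mask, `TRUE` for outliers.
#' @examples
#' mad_outlier_mask(c(1, 2, 3, 100))   # only 100 flagged
#' @export
mad_outlier_mask <- function(values, factor = 3) {
  if (!length(values)) stop_invalid("mad_outlier_mask needs at least one value")
  med <- median(values)
  smad <- 1.4826 * median(abs(values - med))
  abs(values - med) > factor * smad
}

#' Omnibus test with Bonferroni-corrected post hocs
#'
#' Runs the study-standard designs on a per-neuron metric table: one-way
#' ANOVA across groups with pairwise t post hocs, a two-sample or paired
#' t test for two-group contrasts, or a chi-squared test (no continuity
#' correction) on a categorical contingency table. Post-hoc p values are
#' Bonferroni-adjusted (multiplied by the number of comparisons, capped
#' at 1).
#'
#' @param table Data frame with columns `value` and `group` (designs other
#'   than `"chisq"`); rows with missing values are dropped before testing.
#' @param design `"oneway"`, `"ttest"`, `"paired"`, or `"chisq"`.
#' @param contingency Integer matrix for `design = "chisq"`.
#' @param alpha Significance level recorded in the report (default 0.05).
#' @return Data frame of results: `contrast`, `statistic` (F, t or X^2),
#'   `df`, `df2`, `p_raw`, `p_adj`, `n`.
#' @export
omnibus_and_posthoc <- function(table = NULL,
                                design = c("oneway", "ttest", "paired", "chisq"),
                                contingency = NULL, alpha = 0.05) {
  design <- match.arg(design)
  if (design == "chisq") {
    if (is.null(contingency)) stop_invalid("chisq design needs a contingency table")
    ct <- chisq.test(contingency, correct = FALSE)
    return(data.frame(contrast = "contingency", statistic = unname(ct$statistic),
                      df = unname(ct$parameter), df2 = NA_real_,
                      p_raw = ct$p.value, p_adj = ct$p.value,
                      n = sum(contingency), stringsAsFactors = FALSE))
  }
  stopifnot(is.data.frame(table), all(c("value", "group") %in% names(table)))
  table <- table[is.finite(table$value) & !is.na(table$group), , drop = FALSE]
  table$group <- factor(table$group)
  sizes <- table(table$group)
  if (any(sizes == 0) || nlevels(table$group) < 2)
    stop_invalid("every group must be non-empty and >= 2 groups are required")
  if (design %in% c("ttest", "paired")) {
    if (nlevels(table$group) != 2)
      stop_invalid("t-test designs need exactly 2 groups")
    g <- levels(table$group)
    x <- table$value[table$group == g[1]]
    y <- table$value[table$group == g[2]]
    tt <- t.test(x, y, paired = design == "paired", var.equal = TRUE)
    return(data.frame(contrast = paste(g, collapse = " vs "),
                      statistic = unname(tt$statistic),
                      df = unname(tt$parameter), df2 = NA_real_,
                      p_raw = tt$p.value, p_adj = tt$p.value,
                      n = length(x) + length(y), stringsAsFactors = FALSE))
  }
  fit <- aov(value ~ group, data = table)
  an <- summary(fit)[[1]]
  omni <- data.frame(contrast = "omnibus", statistic = an["group", "F value"],
                     df = an["group", "Df"], df2 = an["Residuals", "Df"],
                     p_raw = an["group", "Pr(>F)"],
                     p_adj = an["group", "Pr(>F)"],
                     n = nrow(table), stringsAsFactors = FALSE)
  ph <- pairwise.t.test(table$value, table$group, p.adjust.method = "none",
                        pool.sd = TRUE)
  pm <- ph$p.value
  rows <- list(omni)
  raw <- c()
  labs <- c()
  for (i in seq_len(nrow(pm))) for (j in seq_len(ncol(pm))) {
    if (!is.na(pm[i, j])) {
      raw <- c(raw, pm[i, j])
      labs <- c(labs, paste(colnames(pm)[j], "vs", rownames(pm)[i]))
    }
  }
  if (length(raw)) {
    adj <- p.adjust(raw, method = "bonferroni")
    rows[[2]] <- data.frame(contrast = labs, statistic = NA_real_,
                            df = an["Residuals", "Df"], df2 = NA_real_,
                            p_raw = raw, p_adj = adj, n = nrow(table),
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  attr(out, "alpha") <- alpha
  rownames(out) <- NULL
  out
}
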