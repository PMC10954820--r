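#' Demographic comparison table
#'
#' Summarises the cohort per group and compares the groups pairwise:
#' Kruskal-Wallis (two-group rank comparison) for continuous variables,
#' Fisher's exact test for categorical ones.
#'
#' @param cohort cohort tibble.
#' @param continuous,categorical variable names; defaults cover the
#'   cohort generator's columns that are present.
#' @return Tibble: `variable`, one summary column per group
#'   (`mean +/- sd` or `yes/no` counts), one p-value column per group
#'   pair.
#' @export
demographic_table <- function(cohort,
                              continuous = c("age", "education", "icv",
                                             "fazekas", "homa_ir", "fpg",
                                             "ogtt_2h", "hba1c", "alps"),
                              categorical = c("sex", "hypertension",
                                              "hyperlipidemia")) {
  grp <- droplevels(factor(cohort$group, levels = alps_group_levels))
  lv <- levels(grp)
  if (length(lv) < 2) abort("demographic table needs >= 2 groups.")
  continuous <- intersect(continuous, names(cohort))
  categorical <- intersect(categorical, names(cohort))
  pairs <- utils::combn(lv, 2, simplify = FALSE)
  pair_names <- vapply(pairs, function(p) paste0("p ", p[1], " vs. ", p[2]),
                       character(1))

  row_cont <- function(v) {
    x <- as.numeric(cohort[[v]])
    summ <- vapply(lv, function(g)
      sprintf("%.2f +/- %.2f", mean(x[grp == g]), sd(x[grp == g])),
      character(1))
    ps <- vapply(pairs, function(p) {
      sel <- grp %in% p
      kruskal_wallis(data.frame(x = x[sel], g = droplevels(grp[sel])),
                     "x", "g")$p.value
    }, numeric(1))
    tibble(variable = v, !!!setNames(as.list(summ), lv),
           !!!setNames(as.list(ps), pair_names))
  }
  row_cat <- function(v) {
    x <- cohort[[v]]
    xb <- if (is.factor(x)) x == levels(factor(x))[2] else as.numeric(x) > 0
    summ <- vapply(lv, function(g)
      sprintf("%d/%d", sum(xb[grp == g]), sum(!xb[grp == g])),
      character(1))
    ps <- vapply(pairs, function(p) {
      tab <- rbind(c(sum(xb[grp == p[1]]), sum(!xb[grp == p[1]])),
                   c(sum(xb[grp == p[2]]), sum(!xb[grp == p[2]])))
      fisher_exact(tab)$p.value
    }, numeric(1))
    tibble(variable = v, !!!setNames(as.list(summ), lv),
           !!!setNames(as.list(ps), pair_names))
  }
  dplyr::bind_rows(
    purrr::map_dfr(categorical, row_cat),
    purrr::map_dfr(continuous, row_cont)
  )
}

#' Plain-markdown analysis report
#'
#' Formats an `alps_results` object (see [analyze_cohort()]) as a
#' markdown document with the demographic table, the adjusted group
#' comparison and the ALPS/HOMA-IR partial correlation.
#'
#' @param results an `alps_results`.
#' @param alpha significance level quoted in the text.
#' @return Character vector of markdown lines.
#' @export
format_report <- function(results, alpha = 0.05) {
  md_table <- function(df) {
    df <- as.data.frame(df)
    num <- vapply(df, is.numeric, logical(1))
    df[num] <- lapply(df[num], function(x) signif(x, 4))
    hdr <- paste0("| ", paste(names(df), collapse = " | "), " |")
    sep <- paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|")
    rows <- apply(df, 1, function(r) paste0("| ", paste(r, collapse = " | "), " |"))
    c(hdr, sep, rows)
  }
  out <- c("# ALPS index analysis report", "")
  if (!is.null(results$demographics)) {
    out <- c(out, "## Cohort profile", "", md_table(results$demographics), "")
  }
  if (!is.null(results$group_comparison)) {
    out <- c(out, "## Covariate-adjusted group comparison", "",
             sprintf("GLM of the bilateral ALPS index on group and %d covariates; Bonferroni family-wise correction; alpha = %g.",
                     length(results$group_comparison$covariates), alpha),
             "", md_table(tidy(results$group_comparison)), "")
  }
  if (!is.null(results$partial_correlation)) {
    pc <- results$partial_correlation
    out <- c(out, "## ALPS index and insulin resistance", "",
             sprintf("Partial correlation (merged Pre-DM + T2DM, %d covariates removed): r = %.3f, df = %d, p = %.4g.",
                     pc$n - pc$df - 2, pc$r, pc$df, pc$p.value), "")
  }
  if (!is.null(results$vif)) {
    out <- c(out, "## Multicollinearity screen", "", md_table(results$vif), "")
  }
  if (length(results$skipped) > 0) {
    out <- c(out, "## Skipped analyses", "",
             paste0("- ", names(results$skipped), ": ",
                    unlist(results$skipped)))
  }
  out
}
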