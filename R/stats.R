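#' Proliferation rate of a condition
#'
#' The rate is defined on counts: for a non-control condition it is the
#' ratio of transfected proliferating cells to all transfected cells; for
#' the control-transfected condition it is the ratio of all proliferating
#' cells to all cells (transfection is not informative there, so the whole
#' population is used).
#'
#' @param n_total total cells in the field.
#' @param n_transfected transfected cells.
#' @param n_proliferating EdU-positive cells.
#' @param n_transfected_proliferating double-positive cells.
#' @param is_control logical; use the control definition?
#' @param condition condition name, used in error messages.
#' @return the rate, a fraction in \[0, 1\].
#' @export
#' @examples
#' proliferation_rate(100, 20, 30, 8)                    # 8/20 = 0.4
#' proliferation_rate(100, 0, 50, 0, is_control = TRUE)  # 50/100 = 0.5
proliferation_rate <- function(n_total, n_transfected, n_proliferating,
                               n_transfected_proliferating,
                               is_control = FALSE,
                               condition = "condition") {
  stopifnot(n_transfected_proliferating <= n_transfected ||
              is_control,
            n_proliferating <= n_total)
  if (is_control) {
    if (n_total <= 0)
      stop("zero total cells in control condition '", condition, "'")
    n_proliferating / n_total
  } else {
    if (n_transfected <= 0)
      stop("zero transfected cells in condition '", condition,
           "': proliferation rate undefined")
    n_transfected_proliferating / n_transfected
  }
}

#' Summarize classified cells per condition and replicate
#'
#' Aggregates a classified cell table into one row per
#' condition/replicate: total, transfected, proliferating and
#' double-positive counts plus the proliferation rate under the
#' control/non-control definition.
#'
#' @param cells classified cell table (needs `transfected`,
#'   `proliferating`, `condition` and optionally `replicate` columns).
#' @param control_condition name of the control condition (its rate uses
#'   all cells); `NA` for none.
#' @return data frame of class `condition_summary`.
#' @export
summarize_conditions <- function(cells, control_condition = NA_character_) {
  stopifnot(is.data.frame(cells),
            all(c("transfected", "proliferating", "condition") %in% names(cells)))
  if (!"replicate" %in% names(cells)) cells$replicate <- 1L
  key <- interaction(cells$condition, cells$replicate, drop = TRUE)
  rows <- lapply(levels(key), function(k) {
    sub <- cells[key == k, ]
    cond <- sub$condition[1]; rep_id <- sub$replicate[1]
    is_ctrl <- !is.na(control_condition) && cond == control_condition
    n_tot <- nrow(sub)
    n_tr <- sum(sub$transfected)
    n_pr <- sum(sub$proliferating)
    n_tp <- sum(sub$transfected & sub$proliferating)
    data.frame(condition = cond, replicate = rep_id, n_total = n_tot,
               n_transfected = n_tr, n_proliferating = n_pr,
               n_transfected_proliferating = n_tp,
               proliferation_rate = proliferation_rate(
                 n_tot, n_tr, n_pr, n_tp, is_control = is_ctrl,
                 condition = as.character(cond)))
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$condition, out$replicate), ]
  rownames(out) <- NULL
  class(out) <- c("condition_summary", "data.frame")
  out
}

significance_stars <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "ns")))
}

#' Compare proliferation rates across conditions
#'
#' The assay's group-comparison chain: Levene's test for homogeneity of
#' variances (mean-centred, as in SPSS) is run first; if its P > 0.05, a
#' one-way ANOVA is fitted and Tukey's honestly-significant-difference
#' post hoc comparisons (studentized-range distribution) are reported with
#' the conventional star levels (*P < 0.05, **P < 0.01, ***P < 0.001).
#' If the Levene precheck fails, the violation is recorded and only
#' descriptive statistics are returned, rather than silently switching
#' tests.
#'
#' @param rates data frame with columns `condition` and
#'   `proliferation_rate` (one row per replicate), e.g. from
#'   [summarize_conditions()]; or a named list of numeric vectors.
#' @param alpha significance level for the Levene precheck; default 0.05.
#' @return object of class `group_comparison`: a list with
#'   `descriptives`, `levene_p`, `levene_ok`, `anova_p`, `anova_F`,
#'   `tukey` (pairwise table with `p_adj` and `stars`).
#' @export
compare_groups <- function(rates, alpha = 0.05) {
  if (is.list(rates) && !is.data.frame(rates)) {
    rates <- data.frame(
      condition = rep(names(rates), lengths(rates)),
      proliferation_rate = unlist(rates, use.names = FALSE))
  }
  stopifnot(all(c("condition", "proliferation_rate") %in% names(rates)))
  rates$condition <- factor(rates$condition)
  tab <- table(rates$condition)
  if (length(tab) < 2L) stop("need at least 2 conditions to compare")
  if (any(tab < 2L))
    stop("need at least 2 replicates per condition; short: ",
         paste(names(tab)[tab < 2L], collapse = ", "))
  desc <- do.call(rbind, lapply(split(rates$proliferation_rate,
                                      rates$condition), function(v)
    data.frame(n = length(v), mean = mean(v), sd = stats::sd(v))))
  desc <- cbind(condition = rownames(desc), desc)
  rownames(desc) <- NULL

  lev <- withCallingHandlers(
    car::leveneTest(proliferation_rate ~ condition, data = rates,
                    center = mean),
    warning = function(w) {
      # tiny balanced designs trigger a spurious perfect-fit note
      if (grepl("essentially perfect fit", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  levene_p <- lev[["Pr(>F)"]][1]
  levene_ok <- is.na(levene_p) || levene_p > alpha
  out <- list(descriptives = desc, levene_p = levene_p,
              levene_ok = levene_ok, alpha = alpha,
              anova_p = NA_real_, anova_F = NA_real_, tukey = NULL)
  if (levene_ok) {
    fit <- stats::aov(proliferation_rate ~ condition, data = rates)
    s <- summary(fit)[[1]]
    out$anova_F <- s[["F value"]][1]
    out$anova_p <- s[["Pr(>F)"]][1]
    tk <- stats::TukeyHSD(fit)$condition
    out$tukey <- data.frame(pair = rownames(tk),
                            diff = tk[, "diff"], lwr = tk[, "lwr"],
                            upr = tk[, "upr"], p_adj = tk[, "p adj"],
                            stars = significance_stars(tk[, "p adj"]))
    rownames(out$tukey) <- NULL
  }
  class(out) <- "group_comparison"
  out
}

#' @export
print.group_comparison <- function(x, ...) {
  cat("Group comparison of proliferation rates\n")
  print(x$descriptives, row.names = FALSE)
  cat(sprintf("Levene's test (center = mean): P = %.4g -> %s\n", x$levene_p,
              if (x$levene_ok) "variances homogeneous, ANOVA valid"
              else "variance homogeneity violated; descriptives only"))
  if (x$levene_ok) {
    cat(sprintf("One-way ANOVA: F = %.4g, P = %.4g\n", x$anova_F, x$anova_p))
    cat("Tukey HSD pairwise comparisons:\n")
    print(x$tukey, row.names = FALSE)
    cat("Stars: *P < 0.05, **P < 0.01, ***P < 0.001\n")
  }
  invisible(x)
}

#' Unpaired two-tailed t test between two groups
#'
#' Pooled-variance (equal-variance) by default, matching the use of a
#' Levene precheck in the workflow; set `var_equal = FALSE` for the Welch
#' variant. If both groups are constant with equal means the comparison
#' carries no evidence of a difference and p = 1 is returned by
#' convention.
#'
#' @param a,b numeric vectors (each >= 2 values).
#' @param var_equal pooled (default TRUE) or Welch.
#' @return the two-tailed p-value.
#' @export
two_group_test <- function(a, b, var_equal = TRUE) {
  if (length(a) < 2L || length(b) < 2L)
    stop("each group needs at least 2 values")
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    if (mean(a) == mean(b)) return(1)
    stop("both groups are constant with different means; t statistic undefined")
  }
  stats::t.test(a, b, var.equal = var_equal)$p.value
}
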