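#' Remove extreme outliers by the 3 x IQR rule
#'
#' Single-pass removal of values lying strictly below Q1 - 3 IQR or strictly
#' above Q3 + 3 IQR, with quartiles by linear interpolation (type 7). When
#' the IQR degenerates to 0 on non-constant data, nothing is removed and a
#' warning is issued.
#'
#' @param values numeric vector of at least 4 observations.
#' @return A list: `values` (kept), `removed` (indices into the input).
#' @export
#' @examples
#' remove_extreme_outliers(c(1, 2, 3, 4, 100))
remove_extreme_outliers <- function(values) {
  if (length(values) < 4L) stop("need at least 4 observations")
  if (anyNA(values)) stop("missing values not allowed")
  q <- stats::quantile(values, c(0.25, 0.75), type = 7, names = FALSE)
  iqr <- q[2] - q[1]
  if (iqr == 0) {
    if (any(values != values[1]))
      warning("degenerate IQR = 0 with non-constant data; nothing removed")
    return(list(values = values, removed = integer(0)))
  }
  removed <- which(values < q[1] - 3 * iqr | values > q[2] + 3 * iqr)
  list(values = if (length(removed)) values[-removed] else values,
       removed = removed)
}

effect_stats <- function(F, df1, df2, ss_effect = NA_real_,
                         ss_error = NA_real_) {
  structure(list(F = F, df1 = df1, df2 = df2,
                 p = stats::pf(F, df1, df2, lower.tail = FALSE),
                 eta_sq_partial = partial_eta_squared(F, df1, df2),
                 cohens_d = if (df1 == 1) cohens_d_from_f(F, df2) else NA_real_,
                 ss_effect = ss_effect, ss_error = ss_error),
            class = "effect_stats")
}

#' @export
print.effect_stats <- function(x, ...) {
  cat(sprintf("F(%g, %g) = %.3f, p = %.4g, eta2p = %.3f%s\n",
              x$df1, x$df2, x$F, x$p, x$eta_sq_partial,
              if (!is.na(x$cohens_d)) sprintf(", d = %.2f", x$cohens_d) else ""))
  invisible(x)
}

#' Mixed-design 2 x 2 ANOVA (group between, time within)
#'
#' Classical split-plot sums-of-squares ANOVA for a pre/post design with a
#' between-subject group factor, fitted with `stats::aov` using an
#' `Error(subject)` stratum: the group effect is tested against the
#' between-subject residual, time and group x time against the
#' within-subject residual. Effect sizes (partial eta squared; Cohen's d
#' from F for 1-df effects) are attached to each effect.
#'
#' @param table data frame with columns `subject`, `group` (2 levels),
#'   `time` (2 levels) and `score`; every subject must have both time
#'   points.
#' @return A list of class `mixed_anova` with `effect_stats` entries
#'   `group`, `time`, `interaction`, plus per-group sample sizes.
#' @export
mixed_anova_2x2 <- function(table) {
  need <- c("subject", "group", "time", "score")
  if (!all(need %in% names(table)))
    stop("table must have columns ", paste(need, collapse = ", "))
  tab <- data.frame(subject = factor(table$subject),
                    group = factor(table$group),
                    time = factor(table$time),
                    score = as.numeric(table$score))
  if (nlevels(tab$group) != 2L || nlevels(tab$time) != 2L)
    stop("'group' and 'time' must each have exactly 2 levels")
  counts <- table(tab$subject, tab$time)
  bad <- rownames(counts)[rowSums(counts == 1L) != 2L]
  if (length(bad))
    stop("subjects without both time points: ", paste(bad, collapse = ", "))
  per_group <- table(tab$group[!duplicated(tab$subject)])
  if (any(per_group < 2L)) stop("need at least 2 subjects per group")
  fit <- stats::aov(score ~ group * time + Error(subject), data = tab)
  sm <- summary(fit)
  between <- as.data.frame(sm[["Error: subject"]][[1L]])
  within <- as.data.frame(sm[["Error: Within"]][[1L]])
  rn <- function(df) trimws(rownames(df))
  pick <- function(df, term) df[rn(df) == term, , drop = FALSE]
  sstol <- 1e-12 * (sum(tab$score^2) + 1)
  mk <- function(df, term) {
    eff <- pick(df, term)
    res <- pick(df, "Residuals")
    F <- eff$`F value`
    ## degenerate tables (effect and residual SS both ~0) have no effect
    if (!is.finite(F) || (eff$`Sum Sq` < sstol && res$`Sum Sq` < sstol))
      F <- 0
    effect_stats(F = F, df1 = eff$Df, df2 = res$Df,
                 ss_effect = eff$`Sum Sq`, ss_error = res$`Sum Sq`)
  }
  structure(list(group = mk(between, "group"),
                 time = mk(within, "time"),
                 interaction = mk(within, "group:time"),
                 n = as.list(per_group)),
            class = "mixed_anova")
}

#' @export
print.mixed_anova <- function(x, ...) {
  for (e in c("group", "time", "interaction")) {
    cat(format(e, width = 12)); print(x[[e]])
  }
  invisible(x)
}

#' Partial eta squared from an F statistic
#'
#' eta2p = F df1 / (F df1 + df2), equal to SS_effect / (SS_effect +
#' SS_error).
#'
#' @param F F statistic (>= 0).
#' @param df1,df2 numerator and denominator degrees of freedom (> 0).
#' @return Partial eta squared in \[0, 1\].
#' @export
#' @examples
#' partial_eta_squared(24.579, 1, 23)
partial_eta_squared <- function(F, df1, df2) {
  if (F < 0 || df1 <= 0 || df2 <= 0) stop("invalid inputs")
  F * df1 / (F * df1 + df2)
}

#' Cohen's d from a 1-df F statistic
#'
#' d = 2 sqrt(F / df_error), the standardized mean difference implied by a
#' two-group 1-df contrast.
#'
#' @param F F statistic (>= 0).
#' @param df_error error degrees of freedom (> 0).
#' @return Cohen's d.
#' @export
#' @examples
#' cohens_d_from_f(24.579, 23)
cohens_d_from_f <- function(F, df_error) {
  if (F < 0 || df_error <= 0) stop("invalid inputs")
  2 * sqrt(F / df_error)
}

#' Pooled two-sample t-test from summary statistics
#'
#' Independent-samples t with pooled variance and df = n_a + n_b - 2,
#' computed directly from group means, SDs and sizes so that printed summary
#' tables can be tested without raw data. Two-sided p.
#'
#' @param mean_a,sd_a,n_a first group summary.
#' @param mean_b,sd_b,n_b second group summary.
#' @return A list: `t`, `df`, `p`.
#' @export
#' @examples
#' two_sample_t_pooled(42.64, 6.79, 14, 50.69, 10.74, 13)
two_sample_t_pooled <- function(mean_a, sd_a, n_a, mean_b, sd_b, n_b) {
  if (n_a < 2L || n_b < 2L) stop("need n >= 2 in each group")
  if (sd_a < 0 || sd_b < 0) stop("SDs must be >= 0")
  df <- n_a + n_b - 2
  if (sd_a == 0 && sd_b == 0) {
    if (mean_a == mean_b) return(list(t = 0, df = df, p = 1))
    stop("zero variance in both groups with unequal means")
  }
  sp2 <- ((n_a - 1) * sd_a^2 + (n_b - 1) * sd_b^2) / df
  t <- (mean_a - mean_b) / sqrt(sp2 * (1 / n_a + 1 / n_b))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}
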