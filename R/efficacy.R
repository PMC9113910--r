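#' VAS weighted value
#'
#' Fractional pain reduction from baseline:
#' `(before - after) / before`, with VAS scored 0-10 points. Scale
#' invariant; undefined (error) at a zero baseline.
#'
#' @param before,after VAS scores in \[0, 10\]; `before` must be > 0.
#'   Vectorized.
#' @return weighted value(s) as fractions (0.75 = 75%).
#' @export
vas_weighted_value <- function(before, after) {
  if (any(before < 0 | before > 10 | after < 0 | after > 10))
    stop("VAS scores must lie in [0, 10]")
  if (any(before == 0))
    stop("weighted value undefined at zero baseline VAS")
  (before - after) / before
}

.outcome_levels <- c("cured", "markedly_effective", "effective",
                     "ineffective")

#' Classify a treatment outcome from the VAS weighted value
#'
#' Thresholds (closed at the lower bound, open above):
#' cured >= 0.75; markedly effective in \[0.50, 0.75); effective in
#' \[0.25, 0.50); ineffective < 0.25.
#'
#' @param wv weighted value(s), fraction scale.
#' @return factor with levels cured, markedly_effective, effective,
#'   ineffective.
#' @export
classify_outcome <- function(wv) {
  out <- ifelse(wv >= 0.75, "cured",
         ifelse(wv >= 0.50, "markedly_effective",
         ifelse(wv >= 0.25, "effective", "ineffective")))
  factor(out, levels = .outcome_levels)
}

#' Total effective rate
#'
#' Cure rate + marked-effective rate + effective rate: the fraction of
#' subjects in any category other than ineffective.
#'
#' @param categories factor/character vector of outcome categories.
#' @export
total_effective_rate <- function(categories) {
  categories <- factor(categories, levels = .outcome_levels)
  if (anyNA(categories)) stop("unknown outcome category")
  mean(categories != "ineffective")
}

#' Two-sample pooled t test from printed summary statistics
#'
#' Reconstructs the classical pooled-variance Student t test from group
#' means, standard deviations and sizes as printed in study tables
#' (mean ± SD, n): t = (m1 - m2) / (sp sqrt(1/n1 + 1/n2)) with
#' sp^2 = ((n1-1) s1^2 + (n2-1) s2^2) / (n1 + n2 - 2), df = n1 + n2 - 2,
#' two-sided p.
#'
#' @param m1,s1,n1 group 1 mean, SD, size.
#' @param m2,s2,n2 group 2 mean, SD, size.
#' @return list: `t`, `df`, `p`.
#' @export
two_sample_t_from_summary <- function(m1, s1, n1, m2, s2, n2) {
  if (n1 < 2 || n2 < 2) stop("need n >= 2 per group")
  if (s1 <= 0 || s2 <= 0) stop("need positive SDs")
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / df
  tval <- (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  list(t = tval, df = df, p = 2 * stats::pt(-abs(tval), df))
}

#' Clinical efficacy report
#'
#' The full clinical analysis for a follow-up table: per-week mean ± SD by
#' group for VAS and sleep hours; within-group paired t tests of each week
#' against baseline (VAS); between-group pooled two-sample t tests per
#' week (VAS and sleep); per-subject VAS weighted values at week 4,
#' outcome category counts, and the total effective rate per group.
#'
#' @param table clinical data.frame (see [validate_clinical_table()]);
#'   needs at least 2 subjects per group.
#' @return list: `summary` (per group/endpoint/week mean, sd, n),
#'   `within_group` (paired t vs baseline, VAS), `between_group`
#'   (two-sample t per week), `outcomes` (per-subject weighted value and
#'   category), `category_counts`, `total_effective_rate` (per group).
#' @export
efficacy_report <- function(table) {
  table <- validate_clinical_table(table)
  ng <- table(table$group)
  if (any(ng < 2)) stop("need at least 2 subjects per group")
  weeks <- 1:4
  endpoints <- list(vas = c("vas_baseline", paste0("vas_week", weeks)),
                    sleep = paste0("sleep_week", weeks))

  summ <- do.call(rbind, lapply(names(endpoints), function(ep) {
    cols <- endpoints[[ep]]
    do.call(rbind, lapply(levels(table$group), function(g) {
      sub <- table[table$group == g, cols, drop = FALSE]
      data.frame(group = g, endpoint = ep,
                 week = if (ep == "vas") c(0, weeks) else weeks,
                 mean = apply(sub, 2, mean), sd = apply(sub, 2, stats::sd),
                 n = nrow(sub), row.names = NULL)
    }))
  }))

  within <- do.call(rbind, lapply(levels(table$group), function(g) {
    sub <- table[table$group == g, , drop = FALSE]
    do.call(rbind, lapply(weeks, function(w) {
      tt <- stats::t.test(sub[[paste0("vas_week", w)]], sub$vas_baseline,
                          paired = TRUE)
      data.frame(group = g, endpoint = "vas", week = w,
                 t = unname(tt$statistic), df = unname(tt$parameter),
                 p = tt$p.value)
    }))
  }))

  between <- do.call(rbind, lapply(names(endpoints), function(ep) {
    do.call(rbind, lapply(weeks, function(w) {
      col <- paste0(ep, "_week", w)
      a <- table[[col]][table$group == "treatment"]
      b <- table[[col]][table$group == "control"]
      tt <- stats::t.test(a, b, var.equal = TRUE)
      data.frame(endpoint = ep, week = w, t = unname(tt$statistic),
                 df = unname(tt$parameter), p = tt$p.value)
    }))
  }))

  wv <- vas_weighted_value(table$vas_baseline, table$vas_week4)
  outcomes <- data.frame(subject_id = table$subject_id,
                         group = table$group,
                         weighted_value = wv,
                         weighted_value_pct = round(100 * wv, 2),
                         category = classify_outcome(wv))
  counts <- table(outcomes$group, outcomes$category)
  ter <- tapply(outcomes$category, outcomes$group, total_effective_rate)

  list(summary = summ, within_group = within, between_group = between,
       outcomes = outcomes, category_counts = counts,
       total_effective_rate = ter)
}
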