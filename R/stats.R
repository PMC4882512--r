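#' Percentiles of a speed population
#'
#' Quantiles of pooled per-track mean speeds under the package-wide
#' check-loss midpoint convention ([check_quantile()]).
#'
#' @param speeds Per-track mean speeds (um/s), non-empty.
#' @param taus Quantile levels in (0, 1); default the 10th, 25th, 50th,
#'   75th and 90th percentiles.
#' @return Named numeric vector of percentile values (non-decreasing in
#'   tau).
#' @export
speed_percentiles <- function(speeds,
                              taus = c(0.1, 0.25, 0.5, 0.75, 0.9)) {
  out <- check_quantile(speeds, taus)
  names(out) <- paste0("p", taus * 100)
  out
}

#' Quantile contrast between two speed populations
#'
#' For each quantile level tau, the group effect is the difference of the
#' two groups' tau-quantiles, `q_tau(patient) - q_tau(control)` -- the
#' check-loss-minimising coefficient of a binary group covariate in a
#' quantile regression. Standard errors come from a seeded case-resampling
#' bootstrap (resampling within each group); the two-sided p-value uses
#' the normal approximation of the bootstrap distribution and the 95% CI
#' is `estimate +/- 1.96 SE`.
#'
#' @param control,patient Numeric vectors of per-track mean speeds.
#' @param taus Quantile levels.
#' @param n_boot Bootstrap resamples (at least 200).
#' @param seed Integer seed for the bootstrap.
#' @return Data frame with one row per tau: `tau`, `estimate`, `se`,
#'   `p`, `ci_lo`, `ci_hi`, `degenerate` (flag: a group was all ties).
#' @export
quantile_group_contrast <- function(control, patient,
                                    taus = c(0.1, 0.25, 0.5, 0.75, 0.9),
                                    n_boot = 1000, seed = 1) {
  if (!length(control) || !length(patient))
    stop("both populations must be non-empty", call. = FALSE)
  if (n_boot < 200) stop("n_boot must be at least 200", call. = FALSE)
  degen <- length(unique(control)) == 1 || length(unique(patient)) == 1
  if (degen)
    warning("degenerate population (all ties); bootstrap still returned",
            call. = FALSE)
  est <- check_quantile(patient, taus) - check_quantile(control, taus)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old))
    assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed %% 2147483647)
  boot <- matrix(NA_real_, n_boot, length(taus))
  for (b in seq_len(n_boot)) {
    cb <- control[sample.int(length(control), replace = TRUE)]
    pb <- patient[sample.int(length(patient), replace = TRUE)]
    boot[b, ] <- check_quantile(pb, taus) - check_quantile(cb, taus)
  }
  se <- apply(boot, 2, stats::sd)
  z <- ifelse(se > 0, est / se, ifelse(est == 0, 0, Inf))
  data.frame(tau = taus, estimate = est, se = se,
             p = 2 * stats::pnorm(-abs(z)),
             ci_lo = est - stats::qnorm(0.975) * se,
             ci_hi = est + stats::qnorm(0.975) * se,
             degenerate = degen)
}

group_test_result <- function(statistic, df, p, estimate, se, ci95) {
  structure(list(statistic = statistic, df = df, p = p,
                 estimate = estimate, se = se, ci95 = ci95),
            class = "group_test")
}

#' @export
print.group_test <- function(x, ...) {
  cat(sprintf("t/statistic = %.4g, df = %s, p = %.4g\n", x$statistic,
              paste(signif(x$df, 4), collapse = ", "), x$p))
  cat(sprintf("estimate = %.4g +/- %.4g (95%% CI %.4g to %.4g)\n",
              x$estimate, x$se, x$ci95[1], x$ci95[2]))
  invisible(x)
}

#' Unpaired t-test from printed summary statistics
#'
#' Reconstructs the two-sample Student t-test from group means, SEMs and
#' sizes as printed in figure legends: `t = (m1 - m2) / sqrt(sem1^2 +
#' sem2^2)` with `df = n1 + n2 - 2` (pooled convention, matching printed
#' df = 8 for 5 + 5 cell lines).
#'
#' @param mean1,sem1,n1 First group: mean, SEM, size.
#' @param mean2,sem2,n2 Second group.
#' @return A `group_test` with the difference in means as estimate.
#' @export
t_from_summary <- function(mean1, sem1, n1, mean2, sem2, n2) {
  if (sem1 <= 0 || sem2 <= 0)
    stop("SEMs must be positive", call. = FALSE)
  if (n1 < 2 || n2 < 2) stop("group sizes must be at least 2", call. = FALSE)
  se <- sqrt(sem1^2 + sem2^2)
  tt <- (mean1 - mean2) / se
  df <- n1 + n2 - 2
  p <- 2 * stats::pt(-abs(tt), df)
  ci <- (mean1 - mean2) + c(-1, 1) * stats::qt(0.975, df) * se
  group_test_result(tt, df, p, mean1 - mean2, se, ci)
}

#' Two-sample pooled-variance t-test from raw values
#'
#' Classical Student t-test with pooled variance; consistent with
#' [t_from_summary()] when the summaries are computed from the same values
#' and group sizes are equal.
#'
#' @param g1,g2 Numeric vectors (each at least 2 values).
#' @return A `group_test`; degenerate zero-variance input yields an
#'   infinite statistic with a warning (or NaN if the means also tie).
#' @export
t_from_values <- function(g1, g2) {
  n1 <- length(g1); n2 <- length(g2)
  if (n1 < 2 || n2 < 2) stop("each group needs at least 2 values",
                             call. = FALSE)
  sp2 <- ((n1 - 1) * stats::var(g1) + (n2 - 1) * stats::var(g2)) /
    (n1 + n2 - 2)
  if (sp2 == 0)
    warning("zero variance in both groups; t is degenerate", call. = FALSE)
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  d <- mean(g1) - mean(g2)
  tt <- d / se
  df <- n1 + n2 - 2
  p <- if (is.nan(tt)) NaN else 2 * stats::pt(-abs(tt), df)
  ci <- d + c(-1, 1) * stats::qt(0.975, df) * se
  group_test_result(tt, df, p, d, se, ci)
}

#' Pearson chi-square test of independence for a contingency table
#'
#' `X^2 = sum (O - E)^2 / E` against the independence expectation, with
#' `df = (r - 1)(c - 1)`; no continuity correction.
#'
#' @param counts Numeric matrix of non-negative counts, at least 2 x 2.
#' @return A `group_test`; the `estimate` slot holds the expected-count
#'   matrix.
#' @export
chi_square_table <- function(counts) {
  counts <- as.matrix(counts)
  if (nrow(counts) < 2 || ncol(counts) < 2)
    stop("table must be at least 2 x 2", call. = FALSE)
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  rs <- rowSums(counts); cs <- colSums(counts)
  if (any(rs == 0) || any(cs == 0))
    stop("a row or column sums to zero", call. = FALSE)
  E <- outer(rs, cs) / sum(counts)
  stat <- sum((counts - E)^2 / E)
  df <- (nrow(counts) - 1) * (ncol(counts) - 1)
  p <- stats::pchisq(stat, df, lower.tail = FALSE)
  group_test_result(stat, df, p, E, NA_real_, c(NA_real_, NA_real_))
}

#' Mixed repeated-measures ANOVA (one between, one within factor)
#'
#' Univariate mixed-model ANOVA computed from sums of squares, with
#' subjects (cell lines) nested in the between-subjects group: the group
#' effect is tested against subjects-within-group, and the condition and
#' group x condition effects against the subject x condition residual.
#' The design must be balanced (every line measured in every condition).
#'
#' @param values Numeric matrix: rows = subjects (cell lines), columns =
#'   within-subject conditions.
#' @param groups Between-subjects group label per row.
#' @return A list with components `group`, `condition`, `interaction`
#'   (each `list(F, df, p)`, df as effect/error pair) and the full `ss`
#'   table. All-zero error strata give F = 0 with a warning.
#' @export
mixed_rm_anova <- function(values, groups) {
  values <- as.matrix(values)
  groups <- as.factor(groups)
  if (length(groups) != nrow(values))
    stop("one group label per row required", call. = FALSE)
  if (any(is.na(values)))
    stop("unbalanced design: every line must be measured in every condition",
         call. = FALSE)
  if (any(table(groups) < 2))
    stop("need at least 2 lines per group", call. = FALSE)
  N <- nrow(values); C <- ncol(values); G <- nlevels(groups)
  gm <- mean(values)
  m_subj <- rowMeans(values)
  m_cond <- colMeans(values)
  m_grp <- tapply(m_subj, groups, mean)
  m_gc <- apply(values, 2, function(col) tapply(col, groups, mean))
  if (G == 1) m_gc <- matrix(m_gc, nrow = 1)
  n_g <- as.vector(table(groups))

  ss_group <- C * sum(n_g * (m_grp - gm)^2)
  ss_subj <- C * sum((m_subj - m_grp[groups])^2)
  ss_cond <- N * sum((m_cond - gm)^2)
  ss_int <- sum(n_g * (m_gc - outer(m_grp, rep(1, C)) -
                         outer(rep(1, G), m_cond) + gm)^2)
  resid <- values - m_subj -
    m_gc[cbind(as.integer(groups), rep(seq_len(C), each = N))] +
    rep(m_grp[groups], C)
  ss_err <- sum(resid^2)

  df_group <- G - 1; df_subj <- N - G
  df_cond <- C - 1; df_int <- (G - 1) * (C - 1)
  df_err <- (N - G) * (C - 1)
  degenerate <- FALSE
  safe_f <- function(ss_e, df_e, ss_r, df_r) {
    msr <- ss_r / df_r
    if (msr == 0) {
      if (ss_e / df_e == 0) {
        degenerate <<- TRUE
        return(list(F = 0, df = c(df_e, df_r), p = 1))
      }
      return(list(F = Inf, df = c(df_e, df_r), p = 0))
    }
    f <- (ss_e / df_e) / msr
    list(F = f, df = c(df_e, df_r),
         p = stats::pf(f, df_e, df_r, lower.tail = FALSE))
  }
  on.exit(if (degenerate)
    warning("zero variance in an error stratum: F reported as 0",
            call. = FALSE))
  list(group = safe_f(ss_group, df_group, ss_subj, df_subj),
       condition = safe_f(ss_cond, df_cond, ss_err, df_err),
       interaction = safe_f(ss_int, df_int, ss_err, df_err),
       ss = data.frame(
         term = c("group", "subjects_within_group", "condition",
                  "group_x_condition", "residual"),
         ss = c(ss_group, ss_subj, ss_cond, ss_int, ss_err),
         df = c(df_group, df_subj, df_cond, df_int, df_err)))
}

#' Percentage of fast-moving organelles, per cell line and overall
#'
#' The unit of analysis for the group comparison is the cell line: the
#' per-line percentages of tracks with mean speed strictly above the fast
#' threshold are averaged and their SEM across lines reported, alongside
#' the pooled overall percentage.
#'
#' @param speeds Per-track mean speeds (um/s).
#' @param line_ids Parallel vector of cell-line labels.
#' @param thresholds A [motion_thresholds()] object.
#' @return List with `overall_pct`, `per_line` (data frame `line`,
#'   `pct`, `n_tracks`), `mean_pct` and `sem_pct` across lines.
#' @export
percent_fast <- function(speeds, line_ids,
                         thresholds = motion_thresholds()) {
  if (length(speeds) != length(line_ids))
    stop("speeds and line_ids must be parallel", call. = FALSE)
  fast <- classify_fast(speeds, thresholds)
  n_line <- table(line_ids)
  if (any(n_line == 0)) stop("a line has zero tracks", call. = FALSE)
  pct <- tapply(fast, line_ids, mean) * 100
  per_line <- data.frame(line = names(pct), pct = as.numeric(pct),
                         n_tracks = as.integer(n_line[names(pct)]))
  list(overall_pct = mean(fast) * 100,
       per_line = per_line,
       mean_pct = mean(per_line$pct),
       sem_pct = stats::sd(per_line$pct) / sqrt(nrow(per_line)))
}
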