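#' Group summaries as mean +/- SEM
#'
#' @param values Numeric endpoint values.
#' @param group Grouping factor/vector, same length.
#' @return Data.frame with columns `group`, `n`, `mean`, `sem`
#'   (`sd/sqrt(n)`).
#' @export
group_summary <- function(values, group) {
  stopifnot(length(values) == length(group))
  out <- do.call(rbind, lapply(split(as.numeric(values), group), function(v) {
    v <- v[is.finite(v)]
    n <- length(v)
    data.frame(n = n, mean = mean(v),
               sem = if (n > 1) stats::sd(v) / sqrt(n) else NA_real_)
  }))
  data.frame(group = rownames(out), out, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Significance stars
#'
#' `*` for p <= 0.05, `**` for p <= 0.01, `***` for p <= 0.001,
#' `****` for p <= 0.0001, `ns` above 0.05; the most extreme applicable
#' label is returned.
#'
#' @param p P-value(s) in `[0, 1]`. Vectorized.
#' @return Character vector of star labels.
#' @export
significance_stars <- function(p) {
  if (any(!is.finite(p) | p < 0 | p > 1))
    stop("`p` must lie in [0, 1]")
  ifelse(p <= 1e-4, "****",
  ifelse(p <= 1e-3, "***",
  ifelse(p <= 1e-2, "**",
  ifelse(p <= 0.05, "*", "ns"))))
}

new_comparison <- function(groups, method, statistic, df, p_value,
                           posthoc = NULL) {
  structure(
    list(groups = groups, method = method, statistic = statistic, df = df,
         p_value = p_value, stars = significance_stars(p_value),
         posthoc = posthoc),
    class = "comparison_result"
  )
}

#' Unpaired two-group Student's t-test
#'
#' Pooled-variance (classic Student, not Welch) two-sided t-test, the
#' convention for the pairwise endpoint contrasts in this design.
#'
#' @param a,b Numeric vectors, each with n >= 2.
#' @param labels Length-2 group labels for reporting.
#' @return A `comparison_result`: list with `statistic` (t), `df`,
#'   `p_value`, `stars`, `groups`, `method`.
#' @export
two_group_test <- function(a, b, labels = c("a", "b")) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 2 || length(b) < 2)
    stop("each group needs at least 2 observations")
  df <- length(a) + length(b) - 2
  sp2 <- ((length(a) - 1) * stats::var(a) +
            (length(b) - 1) * stats::var(b)) / df
  if (sp2 <= .Machine$double.eps * max(abs(c(a, b, 1)))^2) {
    # degenerate: both groups constant (e.g. saturated ordinal scores)
    delta <- mean(a) - mean(b)
    tstat <- if (delta == 0) 0 else sign(delta) * Inf
    p <- if (delta == 0) 1 else 0
    return(new_comparison(labels,
                          "Student t (pooled variance, two-sided)",
                          tstat, df, p))
  }
  ht <- stats::t.test(a, b, var.equal = TRUE)
  new_comparison(labels, "Student t (pooled variance, two-sided)",
                 unname(ht$statistic), unname(ht$parameter),
                 unname(ht$p.value))
}

#' One-way ANOVA with Tukey HSD post-hoc
#'
#' @param groups Named list of numeric vectors (>= 2 groups, each
#'   n >= 2), or a single data.frame with columns `value` and `group`.
#' @param posthoc `"tukey"` (default; pairwise table attached when the
#'   omnibus F is significant at 0.05), `"pairwise_t"` (unadjusted
#'   pairwise Student t-tests), or `"none"`.
#' @return A `comparison_result` with `statistic` (F), `df`
#'   (c(between, within)), `p_value`, `stars`, and `posthoc` (pairwise
#'   data.frame or `NULL`).
#' @export
oneway_anova <- function(groups, posthoc = c("tukey", "pairwise_t", "none")) {
  posthoc <- match.arg(posthoc)
  if (is.data.frame(groups)) {
    stopifnot(all(c("value", "group") %in% names(groups)))
    groups <- split(as.numeric(groups$value), groups$group)
  }
  if (length(groups) < 2) stop("ANOVA needs at least 2 groups")
  if (any(vapply(groups, length, 1L) < 2))
    stop("every group needs at least 2 observations")
  if (is.null(names(groups)) || any(!nzchar(names(groups))))
    names(groups) <- paste0("g", seq_along(groups))
  df <- data.frame(
    value = unlist(groups, use.names = FALSE),
    group = factor(rep(names(groups), vapply(groups, length, 1L)),
                   levels = names(groups))
  )
  fit <- stats::aov(value ~ group, data = df)
  tab <- summary(fit)[[1]]
  fstat <- tab[["F value"]][1]
  p <- tab[["Pr(>F)"]][1]
  dfs <- tab[["Df"]]
  ph <- NULL
  if (posthoc == "tukey" && is.finite(p) && p <= 0.05) {
    tk <- stats::TukeyHSD(fit)$group
    ph <- data.frame(contrast = rownames(tk), diff = tk[, "diff"],
                     lwr = tk[, "lwr"], upr = tk[, "upr"],
                     p_adj = tk[, "p adj"],
                     stars = significance_stars(tk[, "p adj"]),
                     row.names = NULL, stringsAsFactors = FALSE)
  } else if (posthoc == "pairwise_t") {
    prs <- utils::combn(names(groups), 2, simplify = FALSE)
    ph <- do.call(rbind, lapply(prs, function(pr) {
      r <- two_group_test(groups[[pr[1]]], groups[[pr[2]]], pr)
      data.frame(contrast = paste(pr[2], pr[1], sep = "-"),
                 diff = mean(groups[[pr[2]]]) - mean(groups[[pr[1]]]),
                 lwr = NA_real_, upr = NA_real_, p_adj = r$p_value,
                 stars = r$stars, stringsAsFactors = FALSE)
    }))
  }
  new_comparison(names(groups), "one-way ANOVA", fstat, dfs, p, ph)
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("<comparison_result> %s: %s\n", x$method,
              paste(x$groups, collapse = " vs ")))
  stat_name <- if (grepl("ANOVA", x$method)) "F" else "t"
  cat(sprintf("  %s = %.4g (df %s), p = %.4g  %s\n", stat_name,
              x$statistic, paste(round(x$df, 2), collapse = ", "),
              x$p_value, x$stars))
  if (!is.null(x$posthoc)) {
    cat("  post-hoc:\n")
    print(x$posthoc, row.names = FALSE)
  }
  invisible(x)
}

#' Fold change of a treated mean over a control mean
#'
#' @param treated_mean,control_mean Group means in the same units;
#'   `control_mean` must be > 0.
#' @return `treated_mean / control_mean`.
#' @export
fold_change <- function(treated_mean, control_mean) {
  if (!is.finite(control_mean) || control_mean <= 0)
    stop("`control_mean` must be > 0")
  treated_mean / control_mean
}

#' Tidy endpoint comparisons across a cohort table
#'
#' Mirrors the figure-panel structure of a sex-stratified design: for
#' each endpoint and each sex, groups defined by `group_col` are
#' compared with a Student t-test (2 groups) or one-way ANOVA + Tukey
#' (> 2 groups).
#'
#' @param data Data.frame with one row per animal.
#' @param endpoints Character vector of endpoint column names.
#' @param group_col Column defining the compared groups (default
#'   `"disease"`).
#' @param by Optional stratification column (default `"sex"` when
#'   present).
#' @param posthoc Passed to [oneway_anova()].
#' @return Tidy data.frame: `endpoint`, `stratum`, `comparison`,
#'   `method`, `n`, `statistic`, `p_value`, `stars`, `fold_change`
#'   (last group mean over first group mean, `NA` when undefined).
#' @export
compare_endpoints <- function(data, endpoints, group_col = "disease",
                              by = if ("sex" %in% names(data)) "sex" else NULL,
                              posthoc = "tukey") {
  stopifnot(group_col %in% names(data))
  missing_cols <- setdiff(endpoints, names(data))
  if (length(missing_cols))
    stop(sprintf("endpoint column(s) absent: %s",
                 paste(missing_cols, collapse = ", ")))
  strata <- if (is.null(by)) list(all = data) else split(data, data[[by]])
  rows <- list()
  for (sname in names(strata)) {
    d <- strata[[sname]]
    glev <- unique(as.character(d[[group_col]]))
    if (length(glev) < 2) next
    for (ep in endpoints) {
      vals <- split(as.numeric(d[[ep]]), as.character(d[[group_col]]))
      vals <- vals[glev]
      if (any(vapply(vals, function(v) sum(is.finite(v)), 1L) < 2)) next
      if (length(glev) == 2) {
        cmp <- two_group_test(vals[[1]], vals[[2]], glev)
      } else {
        cmp <- oneway_anova(vals, posthoc = posthoc)
      }
      fc <- tryCatch(
        fold_change(mean(vals[[length(vals)]]), mean(vals[[1]])),
        error = function(e) NA_real_)
      rows[[length(rows) + 1]] <- data.frame(
        endpoint = ep, stratum = sname,
        comparison = paste(glev, collapse = " vs "),
        method = cmp$method,
        n = paste(vapply(vals, length, 1L), collapse = "/"),
        statistic = cmp$statistic, p_value = cmp$p_value,
        stars = cmp$stars, fold_change = fc,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(endpoint = character(0), stratum = character(0),
                      comparison = character(0), method = character(0),
                      n = character(0), statistic = numeric(0),
                      p_value = numeric(0), stars = character(0),
                      fold_change = numeric(0), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
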