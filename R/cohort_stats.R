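# Cohort-level statistics: group summaries, ANOVA with Tukey post hoc,
# the BT~CCT ordinary least-squares regression, and the BT/CCT ratio
# independence analysis via a general linear model.

# Recompute the ratio columns from their parts; ratios are never stored stale.
add_ratios <- function(df) {
  df$ratio_bt_cct <- df$bt_um / df$cct_um
  df$ratio_bt_et <- df$bt_um / df$et_um
  df
}

#' Per-group summary of corneal variables
#'
#' Mean, SD, min and max of each variable per group, including the BT/ET and
#' BT/CCT ratios recomputed from their components.
#'
#' @param df Data frame with columns `group`, `bt_um`, `et_um`, `cct_um`, and
#'   any of the `variables`.
#' @param variables Variables to summarize.
#' @return Long data frame: group, variable, n, mean, sd, min, max.
#' @export
group_summary <- function(df, variables = c("age_y", "bt_um", "et_um", "cct_um",
                                            "kmax_d", "ratio_bt_et",
                                            "ratio_bt_cct")) {
  df <- add_ratios(df)
  variables <- intersect(variables, names(df))
  groups <- unique(df$group)
  out <- do.call(rbind, lapply(groups, function(g) {
    sub <- df[df$group == g, , drop = FALSE]
    if (nrow(sub) < 2) stop("group ", g, " has fewer than 2 subjects")
    do.call(rbind, lapply(variables, function(v) {
      x <- sub[[v]]
      data.frame(group = g, variable = v, n = sum(is.finite(x)),
                 mean = mean(x, na.rm = TRUE), sd = stats::sd(x, na.rm = TRUE),
                 min = min(x, na.rm = TRUE), max = max(x, na.rm = TRUE),
                 stringsAsFactors = FALSE)
    }))
  }))
  rownames(out) <- NULL
  out
}

#' Compare a variable across groups: one-way ANOVA with Tukey HSD
#'
#' @param df Data frame with `group` and the variable.
#' @param variable Column name to compare.
#' @return List: `anova_f`, `anova_p`, `tukey` (data frame of pairwise
#'   contrasts with differences and adjusted p-values), `degenerate` (TRUE
#'   when every group has zero variance, in which case the p-values are NA).
#' @export
compare_groups <- function(df, variable) {
  stopifnot(variable %in% names(df))
  df <- df[is.finite(df[[variable]]), , drop = FALSE]
  df$group <- factor(df$group)
  if (nlevels(df$group) < 2) stop("need at least 2 groups")
  counts <- table(df$group)
  if (any(counts < 2)) stop("every group needs at least 2 subjects")
  wvar <- tapply(df[[variable]], df$group, stats::var)
  if (all(wvar == 0)) {
    return(list(anova_f = NA_real_, anova_p = NA_real_, tukey = NULL,
                degenerate = TRUE))
  }
  fit <- stats::aov(stats::reformulate("group", variable), data = df)
  s <- summary(fit)[[1]]
  tk <- stats::TukeyHSD(fit)$group
  list(anova_f = s$`F value`[1], anova_p = s$`Pr(>F)`[1],
       tukey = data.frame(contrast = rownames(tk), diff = tk[, "diff"],
                          p_adj = tk[, "p adj"], row.names = NULL,
                          stringsAsFactors = FALSE),
       degenerate = FALSE)
}

#' Ordinary least-squares regression of BT on CCT
#'
#' Fits `bt_um ~ cct_um`, optionally with additional covariates (age, sex,
#' diagnosis, Kmax, ET), and returns the CCT slope, intercept, R^2 and the
#' p-value of the CCT coefficient.
#'
#' @param df Data frame with `bt_um`, `cct_um` and any covariates used.
#' @param covariates Optional character vector of extra covariate columns.
#' @return List: `slope`, `intercept`, `r_squared`, `p_value`, `n`,
#'   `singular` (TRUE when CCT is constant; estimates are then NA), `fit`.
#' @export
fit_bt_cct <- function(df, covariates = NULL) {
  df <- df[is.finite(df$bt_um) & is.finite(df$cct_um), , drop = FALSE]
  if (nrow(df) < 3) stop("need at least 3 subjects")
  if (stats::sd(df$cct_um) == 0)
    return(list(slope = NA_real_, intercept = NA_real_, r_squared = NA_real_,
                p_value = NA_real_, n = nrow(df), singular = TRUE, fit = NULL))
  fml <- stats::reformulate(c("cct_um", covariates), "bt_um")
  fit <- stats::lm(fml, data = df)
  s <- summary(fit)
  list(slope = unname(stats::coef(fit)["cct_um"]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = s$r.squared,
       p_value = s$coefficients["cct_um", "Pr(>|t|)"],
       n = nrow(df), singular = FALSE, fit = fit)
}

#' BT/CCT ratio independence analysis
#'
#' Computes the per-group mean and SD of the BT/CCT ratio and fits a general
#' linear model of the ratio on diagnosis, age, sex, Kmax and epithelial
#' thickness (all as fixed effects), reporting a marginal F-test p-value per
#' factor. Records with non-positive CCT are rejected. Factor p-values can
#' optionally be Holm-adjusted as a family.
#'
#' @param df Data frame with `group`, `age_y`, `sex`, `kmax_d`, `et_um`,
#'   `bt_um`, `cct_um`.
#' @param adjust `"none"` (default) or `"holm"` for the factor family.
#' @return List: `group_ratio` (per-group n/mean/sd), `factor_p` (raw
#'   marginal p-values), `factor_p_adj`, `n_rejected` (non-positive CCT),
#'   `dropped_terms` (covariates without variation), `fit`.
#' @export
ratio_analysis <- function(df, adjust = c("none", "holm")) {
  adjust <- match.arg(adjust)
  bad <- !is.finite(df$cct_um) | df$cct_um <= 0 | !is.finite(df$bt_um)
  df <- df[!bad, , drop = FALSE]
  if (!nrow(df)) stop("no records with computable ratios")
  df <- add_ratios(df)
  df$group <- factor(df$group)
  df$sex <- factor(df$sex)

  gr <- do.call(rbind, lapply(levels(df$group), function(g) {
    x <- df$ratio_bt_cct[df$group == g]
    data.frame(group = g, n = length(x), mean = mean(x), sd = stats::sd(x),
               stringsAsFactors = FALSE)
  }))

  terms_all <- c(diagnosis = "group", age = "age_y", sex = "sex",
                 kmax = "kmax_d", et = "et_um")
  varies <- vapply(terms_all, function(v) {
    x <- df[[v]]
    if (is.factor(x)) nlevels(droplevels(x)) > 1 else stats::sd(x) > 0
  }, logical(1))
  terms <- terms_all[varies]
  if (!length(terms)) stop("no covariate varies; nothing to test")
  if (stats::var(df$ratio_bt_cct) < 1e-18) {
    # a constant ratio depends on nothing: marginal tests are vacuous
    fit <- NULL
    p <- stats::setNames(rep(1, length(terms)), names(terms))
  } else {
    fit <- stats::lm(stats::reformulate(terms, "ratio_bt_cct"), data = df)
    dr <- stats::drop1(fit, test = "F")
    p <- stats::setNames(dr[["Pr(>F)"]][match(terms, rownames(dr))], names(terms))
  }
  list(group_ratio = gr,
       factor_p = p,
       factor_p_adj = if (adjust == "holm") stats::p.adjust(p, "holm") else p,
       n_rejected = sum(bad),
       dropped_terms = names(terms_all)[!varies],
       fit = fit)
}
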