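#' Significance stars
#'
#' Maps p-values to the star bands used throughout the package's reports:
#' `*` p < 0.05, `**` p < 0.005, `***` p < 0.001, `****` p < 0.0001.
#'
#' @param p Numeric vector of p-values.
#' @return Character vector of star strings (empty for p >= 0.05).
#' @export
significance_stars <- function(p) {
  vapply(p, function(x) {
    if (is.na(x)) NA_character_
    else if (x < 0.0001) "****"
    else if (x < 0.001) "***"
    else if (x < 0.005) "**"
    else if (x < 0.05) "*"
    else ""
  }, character(1))
}

.shapiro_normal <- function(x, alpha) {
  if (length(unique(x)) == 1) return(FALSE) # constant: not testable, treat as non-normal
  stats::shapiro.test(x)$p.value >= alpha
}

#' Choose the comparison test for a set of groups
#'
#' Implements the decision tree used for group comparisons of fold
#' changes: (1) assess normality per group (Shapiro-Wilk at
#' `alpha_normal`); (2) if every group looks normal, assess equality of
#' SDs (median-centred Levene test at `alpha_var`) and pick the plain or
#' Welch unpaired t-test (two groups), or ordinary one-way ANOVA versus
#' Brown-Forsythe/Welch ANOVA, both followed by Dunnett's comparison
#' against the control (more groups); (3) if any group looks non-normal,
#' fall back to rank tests — exact Wilcoxon for two groups,
#' Kruskal-Wallis with Dunn's post-hoc for more.
#'
#' @param groups Named list of numeric vectors (>= 3 values each, needed
#'   for the normality assessment).
#' @param alpha_normal,alpha_var Significance levels for the normality and
#'   equal-variance screens.
#' @return A list of class `test_spec`: `test` (one of `"t"`,
#'   `"welch_t"`, `"wilcoxon"`, `"anova_dunnett"`,
#'   `"welch_anova_dunnett"`, `"kruskal_dunn"`), `n_groups`, `normal`
#'   (named logical), `equal_variance`, `shapiro_p`, `levene_p`.
#' @export
select_test <- function(groups, alpha_normal = 0.05, alpha_var = 0.05) {
  stopifnot(is.list(groups), length(groups) >= 2)
  if (is.null(names(groups)) || any(names(groups) == "")) {
    names(groups) <- paste0("group", seq_along(groups))
  }
  sizes <- lengths(groups)
  if (any(sizes < 3)) {
    abort(sprintf("insufficient replicates for normality assessment (group size(s) %s < 3)",
                  paste(sizes[sizes < 3], collapse = ", ")),
          class = "seapscreen_decision_error")
  }
  shapiro_p <- vapply(groups, function(x) {
    if (length(unique(x)) == 1) NA_real_ else stats::shapiro.test(x)$p.value
  }, numeric(1))
  normal <- vapply(groups, .shapiro_normal, logical(1), alpha = alpha_normal)
  k <- length(groups)

  levene_p <- NA_real_
  if (all(normal)) {
    df <- data.frame(value = unlist(groups),
                     group = factor(rep(names(groups), sizes)))
    levene_p <- car::leveneTest(value ~ group, data = df,
                                center = stats::median)[1, "Pr(>F)"]
    equal_var <- levene_p >= alpha_var
    test <- if (k == 2) {
      if (equal_var) "t" else "welch_t"
    } else {
      if (equal_var) "anova_dunnett" else "welch_anova_dunnett"
    }
  } else {
    equal_var <- NA
    test <- if (k == 2) "wilcoxon" else "kruskal_dunn"
  }
  structure(list(test = test, n_groups = k, normal = normal,
                 equal_variance = equal_var, shapiro_p = shapiro_p,
                 levene_p = levene_p),
            class = "test_spec")
}

#' @export
print.test_spec <- function(x, ...) {
  cat(sprintf("<test_spec> %s (%d groups; normal: %s; equal SDs: %s)\n",
              x$test, x$n_groups,
              paste(ifelse(x$normal, "yes", "no"), collapse = "/"),
              ifelse(is.na(x$equal_variance), "-",
                     ifelse(x$equal_variance, "yes", "no"))))
  invisible(x)
}

#' Dunn's post-hoc test after Kruskal-Wallis
#'
#' Pairwise z-tests on mean ranks over the pooled sample, with the
#' standard tie correction, as the post-hoc companion of the
#' Kruskal-Wallis test. P-values are adjusted within the reported family
#' (Holm by default). If `control` is given, only comparisons against the
#' control group form the family.
#'
#' @param groups Named list of numeric vectors.
#' @param control Optional name of the control group.
#' @param p_adjust Adjustment method passed to [stats::p.adjust()].
#' @return Tibble with columns `comparison`, `z`, `p_unadjusted`, `p`.
#' @export
dunn_test <- function(groups, control = NULL, p_adjust = "holm") {
  stopifnot(is.list(groups), length(groups) >= 2, !is.null(names(groups)))
  x <- unlist(groups)
  g <- rep(names(groups), lengths(groups))
  N <- length(x)
  r <- rank(x)
  rbar <- tapply(r, g, mean)
  n <- tapply(r, g, length)
  ties <- table(x)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  v0 <- N * (N + 1) / 12 - tie_term

  pairs <- if (is.null(control)) {
    utils::combn(names(groups), 2, simplify = FALSE)
  } else {
    stopifnot(control %in% names(groups))
    lapply(setdiff(names(groups), control), function(g2) c(control, g2))
  }
  res <- purrr::map_dfr(pairs, function(p2) {
    i <- p2[1]; j <- p2[2]
    z <- (rbar[[i]] - rbar[[j]]) / sqrt(v0 * (1 / n[[i]] + 1 / n[[j]]))
    tibble::tibble(comparison = paste(i, "vs", j), z = z,
                   p_unadjusted = 2 * stats::pnorm(-abs(z)))
  })
  res$p <- stats::p.adjust(res$p_unadjusted, method = p_adjust)
  res
}

## Dunnett comparisons against the control level; `robust` switches to a
## heteroscedasticity-consistent covariance for the unequal-SD branch.
.dunnett <- function(df, control, robust = FALSE) {
  df$group <- stats::relevel(factor(df$group), ref = control)
  fit <- stats::aov(value ~ group, data = df)
  gl <- if (robust) {
    multcomp::glht(fit, linfct = multcomp::mcp(group = "Dunnett"),
                   vcov = sandwich::vcovHC(fit, type = "HC3"))
  } else {
    multcomp::glht(fit, linfct = multcomp::mcp(group = "Dunnett"))
  }
  s <- summary(gl)
  tibble::tibble(
    comparison = paste(control, "vs",
                       sub(" - .*$", "", names(s$test$coefficients))),
    p = as.numeric(s$test$pvalues))
}

#' Run the selected group comparison
#'
#' Executes the test chosen by [select_test()] (or a caller-supplied
#' specification) and reports per-comparison p-values with significance
#' stars. Multi-group tests compare every treated group against the
#' `control` group, with the correction the spec demands (Dunnett for the
#' ANOVA branches, Dunn with Holm adjustment for the rank branch). If all
#' values in all groups are identical the comparison is degenerate and
#' p = 1 is reported with a warning.
#'
#' @inheritParams select_test
#' @param spec A `test_spec` from [select_test()]; computed from the data
#'   when `NULL`.
#' @param control Name of the control group (default: the first group).
#' @return Tibble with columns `comparison`, `test`, `p`, `stars`; the
#'   omnibus p-value (ANOVA F, Welch ANOVA, or Kruskal-Wallis) is in
#'   attribute `omnibus_p` where one exists.
#' @export
run_comparison <- function(groups, spec = NULL, control = NULL) {
  if (is.null(names(groups)) || any(names(groups) == "")) {
    names(groups) <- paste0("group", seq_along(groups))
  }
  if (is.null(control)) control <- names(groups)[1]
  stopifnot(control %in% names(groups))

  if (length(unique(unlist(groups))) == 1) {
    warn("degenerate comparison: all values identical; reporting p = 1")
    out <- tibble::tibble(
      comparison = paste(control, "vs", setdiff(names(groups), control)),
      test = "degenerate", p = 1, stars = "")
    return(out)
  }
  if (is.null(spec)) spec <- select_test(groups)
  stopifnot(inherits(spec, "test_spec"))

  treated <- setdiff(names(groups), control)
  df <- data.frame(value = unlist(groups),
                   group = rep(names(groups), lengths(groups)))
  omnibus <- NA_real_

  res <- switch(
    spec$test,
    t = tibble::tibble(
      comparison = paste(control, "vs", treated[1]),
      p = stats::t.test(groups[[control]], groups[[treated[1]]],
                        var.equal = TRUE)$p.value),
    welch_t = tibble::tibble(
      comparison = paste(control, "vs", treated[1]),
      p = stats::t.test(groups[[control]], groups[[treated[1]]])$p.value),
    wilcoxon = tibble::tibble(
      comparison = paste(control, "vs", treated[1]),
      p = suppressWarnings(
        stats::wilcox.test(groups[[control]], groups[[treated[1]]],
                           exact = TRUE)$p.value)),
    anova_dunnett = {
      omnibus <- summary(stats::aov(value ~ factor(group),
                                    data = df))[[1]][1, "Pr(>F)"]
      .dunnett(df, control, robust = FALSE)
    },
    welch_anova_dunnett = {
      omnibus <- stats::oneway.test(value ~ factor(group), data = df,
                                    var.equal = FALSE)$p.value
      .dunnett(df, control, robust = TRUE)
    },
    kruskal_dunn = {
      omnibus <- stats::kruskal.test(df$value, factor(df$group))$p.value
      d <- dunn_test(groups, control = control, p_adjust = "holm")
      dplyr::select(d, "comparison", "p")
    },
    abort(sprintf("unknown test '%s'", spec$test))
  )
  res$test <- spec$test
  res$stars <- significance_stars(res$p)
  res <- dplyr::select(res, "comparison", "test", "p", "stars")
  attr(res, "omnibus_p") <- omnibus
  attr(res, "spec") <- spec
  res
}
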