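#' Compare per-limb GSM between edema groups
#'
#' Implements the variance-homogeneity-gated testing plan used for
#' group-level GSM comparisons: Levene's test (mean-centered, the classic
#' form) decides the branch at `alpha`; with homogeneous variances the
#' omnibus test is one-way ANOVA with Tukey-HSD pairwise comparisons,
#' otherwise Kruskal-Wallis with Dunn's rank-based post hoc
#' (Bonferroni-adjusted by default).
#'
#' Fully degenerate input (every value identical) leaves both Levene's and
#' the omnibus statistic undefined (0/0); such data carry no evidence
#' against either null, so the report fixes all p-values at 1 on the ANOVA
#' branch.
#'
#' @param values Named list, one numeric vector of per-limb GSM values per
#'   group (at least 2 groups, each with at least 2 finite values). Limbs
#'   are treated as exchangeable rows; when several limbs come from one
#'   participant this overstates the effective sample size.
#' @param region Optional region code carried into the report.
#' @param alpha Significance level for the branch decision and flags,
#'   default 0.05.
#' @param dunn_adjust Multiplicity adjustment for Dunn's test, passed to
#'   [stats::p.adjust()]; default `"bonferroni"`.
#' @return A `comparison_report`: list with `region`, `groups` (per-group n,
#'   mean, sd), `levene_p`, `omnibus` (`"ANOVA"` or `"Kruskal-Wallis"`),
#'   `omnibus_p`, `posthoc` (`"Tukey-HSD"` or `"Dunn"`), `pairwise_p`
#'   (named vector, `"A-B"`), `alpha`.
#' @examples
#' set.seed(1)
#' compare_groups(list(VEG = rnorm(10, 80, 5), NEG = rnorm(10, 110, 5)))
#' @export
compare_groups <- function(values, region = NA_character_, alpha = 0.05,
                           dunn_adjust = "bonferroni") {
  stopifnot(is.list(values), length(values) >= 2L)
  if (is.null(names(values)) || any(!nzchar(names(values)))) {
    stop("'values' must be a named list of groups")
  }
  sizes <- vapply(values, length, integer(1))
  if (any(sizes < 2L)) stop("every group needs at least 2 values")
  if (any(!vapply(values, function(v) all(is.finite(v)), logical(1)))) {
    stop("non-finite GSM values")
  }
  g <- factor(rep(names(values), sizes), levels = names(values))
  y <- unlist(values, use.names = FALSE)
  summary_df <- data.frame(
    group = names(values), n_limbs = sizes,
    mean_gsm = vapply(values, mean, numeric(1)),
    sd_gsm = vapply(values, stats::sd, numeric(1)),
    row.names = NULL
  )
  pair_names <- utils::combn(names(values), 2L,
                             FUN = function(p) paste(p, collapse = "-"))

  if (all(y == y[1L])) {
    pairwise <- stats::setNames(rep(1, length(pair_names)), pair_names)
    return(new_comparison_report(region, summary_df, levene_p = 1,
                                 omnibus = "ANOVA", omnibus_p = 1,
                                 posthoc = "Tukey-HSD", pairwise_p = pairwise,
                                 alpha = alpha))
  }

  lev <- car::leveneTest(y ~ g, center = "mean")
  levene_p <- lev[["Pr(>F)"]][1L]
  if (!is.finite(levene_p)) levene_p <- 1  # all groups internally constant

  if (levene_p > alpha) {
    fit <- stats::aov(y ~ g)
    omnibus_p <- summary(fit)[[1L]][["Pr(>F)"]][1L]
    tk <- stats::TukeyHSD(fit)$g
    # TukeyHSD labels pairs "B-A" by factor order; normalize to "A-B"
    pairwise <- stats::setNames(tk[, "p adj"], flip_pair(rownames(tk)))
    pairwise <- pairwise[pair_names]
    report <- new_comparison_report(region, summary_df, levene_p,
                                    "ANOVA", omnibus_p, "Tukey-HSD",
                                    pairwise, alpha)
  } else {
    kw <- stats::kruskal.test(y, g)
    pairwise <- dunn_test(y, g, adjust = dunn_adjust)
    pairwise <- pairwise[pair_names]
    report <- new_comparison_report(region, summary_df, levene_p,
                                    "Kruskal-Wallis", kw$p.value, "Dunn",
                                    pairwise, alpha)
  }
  report
}

flip_pair <- function(x) {
  parts <- strsplit(x, "-", fixed = TRUE)
  vapply(parts, function(p) paste(rev(p), collapse = "-"), character(1))
}

new_comparison_report <- function(region, groups, levene_p, omnibus,
                                  omnibus_p, posthoc, pairwise_p, alpha) {
  structure(list(region = region, groups = groups, levene_p = levene_p,
                 omnibus = omnibus, omnibus_p = omnibus_p, posthoc = posthoc,
                 pairwise_p = pairwise_p, alpha = alpha),
            class = "comparison_report")
}

#' Dunn's rank-based multiple comparison test
#'
#' Post hoc companion to Kruskal-Wallis: pairwise z statistics on mean
#' ranks with the usual tie correction,
#' `z = (Rbar_i - Rbar_j) / sqrt((N(N+1)/12 - T) (1/n_i + 1/n_j))` with
#' `T = sum(t^3 - t) / (12 (N - 1))` over tied groups, two-sided normal
#' p-values, multiplicity-adjusted.
#'
#' @param y Numeric response vector.
#' @param g Grouping factor of the same length.
#' @param adjust Method for [stats::p.adjust()], default `"bonferroni"`.
#' @return Named vector of adjusted p-values, names `"A-B"` in the order of
#'   `utils::combn` over the factor levels.
#' @export
dunn_test <- function(y, g, adjust = "bonferroni") {
  g <- droplevels(as.factor(g))
  stopifnot(length(y) == length(g), nlevels(g) >= 2L)
  N <- length(y)
  r <- rank(y)
  rbar <- tapply(r, g, mean)
  n <- tapply(r, g, length)
  t_sizes <- table(y)
  tie_term <- sum(t_sizes^3 - t_sizes) / (12 * (N - 1))
  sigma2 <- N * (N + 1) / 12 - tie_term
  pairs <- utils::combn(levels(g), 2L)
  z <- apply(pairs, 2L, function(p) {
    (rbar[p[1L]] - rbar[p[2L]]) /
      sqrt(sigma2 * (1 / n[p[1L]] + 1 / n[p[2L]]))
  })
  p_raw <- 2 * stats::pnorm(-abs(z))
  stats::setNames(stats::p.adjust(p_raw, method = adjust),
                  apply(pairs, 2L, paste, collapse = "-"))
}

#' @export
print.comparison_report <- function(x, ...) {
  cat(sprintf("<comparison_report>%s\n",
              if (is.na(x$region)) "" else paste0(" region ", x$region)))
  print(x$groups, row.names = FALSE)
  cat(sprintf("Levene p = %.4g -> %s (p = %.4g), post hoc %s\n",
              x$levene_p, x$omnibus, x$omnibus_p, x$posthoc))
  print(round(x$pairwise_p, 4))
  invisible(x)
}

#' Group comparison from a characterization report CSV
#'
#' Reads a report written by [write_report()], splits per-limb GSM by
#' `group_label` (optionally within one region), and runs [compare_groups()].
#'
#' @param path Report CSV path.
#' @param region Optional region code filter.
#' @inheritParams compare_groups
#' @return A `comparison_report`.
#' @export
compare_groups_from_report <- function(path, region = NULL, alpha = 0.05,
                                       dunn_adjust = "bonferroni") {
  df <- read_report(path)
  if (!is.null(region)) df <- df[df$region == region, , drop = FALSE]
  df <- df[nzchar(df$group_label), , drop = FALSE]
  if (nrow(df) == 0L) stop("no labeled rows to compare")
  values <- split(df$gsm, df$group_label)
  compare_groups(values, region = if (is.null(region)) NA_character_ else region,
                 alpha = alpha, dunn_adjust = dunn_adjust)
}
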