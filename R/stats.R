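#' Two-group comparison
#'
#' Compares a measurement between two groups with either the two-tailed
#' Student's t-test or the Mann-Whitney (Wilcoxon rank-sum) test. The rank
#' test uses the exact permutation distribution when the combined sample size
#' is at most 20 and there are no ties, and the normal approximation with tie
#' correction otherwise.
#'
#' @param data a data frame.
#' @param value name of the measurement column.
#' @param group name of the grouping column (exactly two levels).
#' @param method `"t_test"` or `"mann_whitney"`.
#' @return a `bq_test` object; use [generics::tidy()] for a one-row tibble.
#' @examples
#' df <- data.frame(v = c(1, 2, 3, 4, 5, 6), g = rep(c("a", "b"), each = 3))
#' tidy(compare_two_groups(df, v, g, method = "mann_whitney"))
#' @export
compare_two_groups <- function(data, value, group,
                               method = c("t_test", "mann_whitney")) {
  method <- match.arg(method)
  v <- rlang::eval_tidy(rlang::enquo(value), data)
  g <- rlang::eval_tidy(rlang::enquo(group), data)
  g <- as.factor(g)
  if (nlevels(droplevels(g)) != 2) {
    rlang::abort("`group` must have exactly two levels.")
  }
  g <- droplevels(g)
  a <- v[g == levels(g)[1]]
  b <- v[g == levels(g)[2]]
  if (length(a) == 0 || length(b) == 0) rlang::abort("Empty group.")
  ht <- if (method == "t_test") {
    if (length(a) < 2 || length(b) < 2) {
      rlang::abort("The t-test needs at least two observations per group.")
    }
    stats::t.test(a, b, var.equal = TRUE)
  } else {
    n <- length(a) + length(b)
    exact <- n <= 20 && !anyDuplicated(c(a, b))
    suppressWarnings(stats::wilcox.test(a, b, exact = exact, correct = !exact))
  }
  structure(list(htest = ht, method = method, levels = levels(g),
                 n = c(length(a), length(b)),
                 means = c(mean(a), mean(b))),
            class = "bq_test")
}

#' @export
print.bq_test <- function(x, ...) {
  print(x$htest)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.bq_test <- function(x, ...) {
  ht <- x$htest
  tibble::tibble(
    method = x$method,
    statistic = unname(ht$statistic),
    df = if (!is.null(ht$parameter)) unname(ht$parameter) else NA_real_,
    p.value = ht$p.value,
    estimate = x$means[1] - x$means[2],
    group1 = x$levels[1], group2 = x$levels[2],
    n1 = x$n[1], n2 = x$n[2]
  )
}

#' @export
glance.bq_test <- function(x, ...) tidy(x)[, c("method", "statistic", "p.value")]

#' Two-way analysis of variance with post-hoc comparisons
#'
#' Fits `value ~ f1 * f2` and reports Type II sums-of-squares F tests for
#' both main effects and the interaction (Type II behaves correctly for the
#' unbalanced per-slice designs typical of histological quantification).
#' Pairwise post-hoc comparisons of the factor-level means use either the
#' Bonferroni correction (default) or the Newman-Keuls step-down studentized
#' range procedure (provided for completeness; non-conservative). With
#' `f2 = NULL` a one-way ANOVA is fitted.
#'
#' @param data a data frame.
#' @param value measurement column.
#' @param f1,f2 factor columns; `f2` may be `NULL`.
#' @param posthoc `"bonferroni"`, `"newman_keuls"` or `"none"`; applied to
#'   the levels of `f1`.
#' @return a `bq_anova` object; `tidy()` gives the ANOVA table, `glance()`
#'   model-level summaries; `$posthoc` holds the pairwise table.
#' @examples
#' df <- expand.grid(sector = c("a", "b", "c"), layer = c("I-IV", "V"),
#'                   rep = 1:3)
#' df$density <- rnorm(nrow(df), 20)
#' fit <- two_way_anova(df, density, sector, layer)
#' tidy(fit)
#' @export
two_way_anova <- function(data, value, f1, f2 = NULL,
                          posthoc = c("bonferroni", "newman_keuls", "none")) {
  posthoc <- match.arg(posthoc)
  v <- rlang::eval_tidy(rlang::enquo(value), data)
  a <- as.factor(rlang::eval_tidy(rlang::enquo(f1), data))
  f2q <- rlang::enquo(f2)
  b <- if (rlang::quo_is_null(f2q)) NULL
       else as.factor(rlang::eval_tidy(f2q, data))
  if (nlevels(droplevels(a)) < 2) {
    rlang::abort("`f1` must have at least two levels.")
  }
  df <- data.frame(v = v, a = droplevels(a))
  if (!is.null(b)) {
    if (nlevels(droplevels(b)) < 2) {
      rlang::abort("`f2` must have at least two levels (or be NULL for one-way).")
    }
    df$b <- droplevels(b)
    if (all(table(df$a, df$b) == 0)) rlang::abort("All interaction cells are empty.")
    has_rep <- any(table(df$a, df$b) > 1)
    form <- if (has_rep) v ~ a * b else v ~ a + b
    fit <- stats::lm(form, data = df)
  } else {
    fit <- stats::lm(v ~ a, data = df)
  }
  tab <- car::Anova(fit, type = 2)
  ph <- if (posthoc == "none") NULL else {
    posthoc_pairwise(df$v, df$a, fit, method = posthoc)
  }
  structure(list(fit = fit, table = tab, posthoc = ph,
                 posthoc_method = posthoc,
                 factors = c("a", if (!is.null(b)) "b")),
            class = "bq_anova")
}

# Pairwise comparisons of the marginal means of `g`, using the model's
# residual mean square. Bonferroni multiplies the per-pair p by the number of
# pairs; Newman-Keuls uses the studentized range over the span of ordered
# means with step-down monotonicity.
posthoc_pairwise <- function(v, g, fit, method) {
  ms <- tapply(v, g, mean)
  ns <- tapply(v, g, length)
  ord <- order(ms)
  ms <- ms[ord]; ns <- ns[ord]
  k <- length(ms)
  if (k < 2) return(NULL)
  mse <- sum(stats::residuals(fit)^2) / stats::df.residual(fit)
  dfr <- stats::df.residual(fit)
  pairs <- utils::combn(k, 2)
  res <- purrr::map_dfr(seq_len(ncol(pairs)), function(j) {
    i1 <- pairs[1, j]; i2 <- pairs[2, j]
    se <- sqrt(mse / 2 * (1 / ns[i1] + 1 / ns[i2]))
    q <- abs(ms[i2] - ms[i1]) / se
    tibble::tibble(
      i1 = i1, i2 = i2,
      group1 = names(ms)[i1], group2 = names(ms)[i2],
      diff = unname(ms[i2] - ms[i1]), span = i2 - i1 + 1L, q = q
    )
  })
  if (method == "bonferroni") {
    tstat <- res$q / sqrt(2)
    res$p.adj <- pmin(1, 2 * stats::pt(abs(tstat), dfr, lower.tail = FALSE) *
                        nrow(res))
  } else {
    p_raw <- stats::ptukey(res$q, res$span, dfr, lower.tail = FALSE)
    # step-down rule: a pair is no more significant than any pair of ordered
    # means whose span contains it
    res$p.adj <- vapply(seq_len(nrow(res)), function(j) {
      contains <- res$i1 <= res$i1[j] & res$i2 >= res$i2[j]
      max(p_raw[contains])
    }, numeric(1))
  }
  res$i1 <- res$i2 <- NULL
  res
}

#' @export
tidy.bq_anova <- function(x, ...) {
  tab <- as.data.frame(x$table)
  terms <- rownames(tab)
  lbl <- c(a = "f1", b = "f2", `a:b` = "f1:f2", Residuals = "Residuals")
  tibble::tibble(
    term = ifelse(terms %in% names(lbl), lbl[terms], terms),
    sumsq = tab[["Sum Sq"]],
    df = tab[["Df"]],
    statistic = tab[["F value"]],
    p.value = tab[["Pr(>F)"]]
  )
}

#' @export
glance.bq_anova <- function(x, ...) {
  s <- summary(x$fit)
  tibble::tibble(r.squared = s$r.squared, df.residual = stats::df.residual(x$fit),
                 sigma = s$sigma, nobs = length(stats::residuals(x$fit)))
}

#' @export
print.bq_anova <- function(x, ...) {
  print(x$table)
  if (!is.null(x$posthoc)) {
    cat(sprintf("\nPost-hoc (%s):\n", x$posthoc_method))
    print(x$posthoc)
  }
  invisible(x)
}
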