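# Group-level PRS comparisons (t-test / one-way ANOVA) and the
# ancestry-risk regression with decile-bin summaries.

#' Compare polygenic-score distributions between population groups
#'
#' Two groups: two-sample t-test (pooled variance by default, Welch on
#' request). More than two: one-way ANOVA F-test. Undefined scores are
#' excluded with a reported count. Degenerate inputs (zero within-group
#' variance everywhere) are guarded: identical group means give statistic 0
#' with p = 1, different means give an infinite statistic with p = 0 and a
#' degeneracy flag.
#'
#' @param prs a `prs_result` tibble (or any tibble with `population` and
#'   `score` columns).
#' @param groups optional character vector selecting and ordering the
#'   population labels to compare; default all labels present. For the
#'   two-group t, the statistic is group1 minus group2.
#' @param welch if TRUE use Welch's unequal-variance t (two groups only).
#' @return a `group_test` object: test ("t" or "anova"), statistic,
#'   p_value, df, a per-group summary tibble, n_excluded, degenerate.
#' @export
group_prs_test <- function(prs, groups = NULL, welch = FALSE) {
  tbl <- as_tibble(prs)
  if (!all(c("population", "score") %in% names(tbl))) {
    abort("prs needs columns population and score")
  }
  groups <- groups %||% unique(tbl$population)
  tbl <- dplyr::filter(tbl, .data$population %in% groups)
  n_excluded <- sum(is.na(tbl$score))
  tbl <- dplyr::filter(tbl, !is.na(.data$score))
  sizes <- table(factor(tbl$population, levels = groups))
  if (length(groups) < 2) abort("need at least 2 groups")
  if (any(sizes < 2)) {
    abort(paste("each group needs at least 2 usable scores; short:",
                paste(names(sizes)[sizes < 2], collapse = ", ")))
  }
  summary_tbl <- tbl |>
    dplyr::group_by(.data$population) |>
    dplyr::summarise(n = dplyr::n(), mean = mean(.data$score),
                     sd = sd(.data$score), .groups = "drop") |>
    dplyr::arrange(match(.data$population, groups))
  degenerate <- all(summary_tbl$sd == 0)
  if (length(groups) == 2) {
    x <- tbl$score[tbl$population == groups[1]]
    y <- tbl$score[tbl$population == groups[2]]
    if (degenerate) {
      same <- mean(x) == mean(y)
      res <- list(test = "t",
                  statistic = if (same) 0 else sign(mean(x) - mean(y)) * Inf,
                  p_value = if (same) 1 else 0, df = NA_real_)
    } else {
      tt <- t.test(x, y, var.equal = !welch)
      res <- list(test = "t", statistic = unname(tt$statistic),
                  p_value = tt$p.value, df = unname(tt$parameter))
    }
  } else {
    if (degenerate) {
      same <- length(unique(summary_tbl$mean)) == 1
      res <- list(test = "anova", statistic = if (same) 0 else Inf,
                  p_value = if (same) 1 else 0, df = NA_real_)
    } else {
      fit <- aov(score ~ population, data = tbl)
      a <- anova(fit)
      res <- list(test = "anova", statistic = a$`F value`[1],
                  p_value = a$`Pr(>F)`[1], df = a$Df[1])
    }
  }
  structure(
    c(res, list(groups = summary_tbl, n_excluded = n_excluded,
                degenerate = degenerate)),
    class = "group_test"
  )
}

#' @export
print.group_test <- function(x, ...) {
  cat(sprintf("<group_test> %s: statistic = %.3f, p = %.3g%s\n",
              x$test, x$statistic, x$p_value,
              if (x$degenerate) " [degenerate variance]" else ""))
  print(x$groups)
  invisible(x)
}

#' Regression of polygenic scores on an ancestry fraction
#'
#' Pearson correlation between one ancestry fraction and the polygenic risk
#' score across individuals matched by sample ID, with its exact-t p-value
#' (t = r sqrt((n-2)/(1-r^2))), the least-squares line, and a decile-bin
#' summary: samples are cut into 10 equal-count bins of the ancestry
#' fraction and per-bin PRS quartiles are reported.
#'
#' @param fractions ancestry-fraction tibble (sample + one column per
#'   ancestry label), e.g. from [estimate_ancestry_supervised()].
#' @param ancestry name of the ancestry column to regress on.
#' @param prs a `prs_result` tibble.
#' @return an `ancestry_regression` object: pearson_r, p_value, n, slope,
#'   intercept, deciles tibble (bin, n, fraction_min, fraction_max, and PRS
#'   quartiles q25/median/q75), and the matched per-sample data.
#' @export
ancestry_prs_regression <- function(fractions, ancestry, prs) {
  fr <- as_tibble(fractions)
  if (!ancestry %in% names(fr)) {
    abort(paste("no ancestry column named", ancestry))
  }
  dat <- dplyr::inner_join(
    dplyr::select(fr, "sample", fraction = dplyr::all_of(ancestry)),
    dplyr::select(as_tibble(prs), "sample", "score"),
    by = "sample"
  )
  dat <- dat[complete.cases(dat), , drop = FALSE]
  n <- nrow(dat)
  if (n < 10) abort("need at least 10 matched samples")
  if (var(dat$fraction) == 0 || var(dat$score) == 0) {
    abort("zero variance in ancestry fraction or PRS")
  }
  ct <- cor.test(dat$fraction, dat$score, method = "pearson")
  fit <- lm(score ~ fraction, data = dat)
  deciles <- dat |>
    dplyr::mutate(bin = dplyr::ntile(.data$fraction, 10)) |>
    dplyr::group_by(.data$bin) |>
    dplyr::summarise(
      n = dplyr::n(),
      fraction_min = min(.data$fraction),
      fraction_max = max(.data$fraction),
      prs_q25 = quantile(.data$score, 0.25),
      prs_median = quantile(.data$score, 0.5),
      prs_q75 = quantile(.data$score, 0.75),
      .groups = "drop"
    )
  structure(
    list(
      pearson_r = unname(ct$estimate), p_value = ct$p.value, n = n,
      slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
      ancestry = ancestry, deciles = deciles, data = dat
    ),
    class = "ancestry_regression"
  )
}

#' @export
print.ancestry_regression <- function(x, ...) {
  cat(sprintf(
    "<ancestry_regression> r = %.3f (p = %.3g, n = %d); PRS = %.4f + %.4f x %s\n",
    x$pearson_r, x$p_value, x$n, x$intercept, x$slope, x$ancestry
  ))
  invisible(x)
}
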