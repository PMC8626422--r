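# Welch (unequal-variance) two-sample statistics. The screen, the iCLIP
# window comparison and the RNA-type summary all report this same test, so it
# lives here once.

#' Welch two-sample t test with degenerate-variance conventions
#'
#' Computes the difference of group means, the Welch t statistic,
#' Welch–Satterthwaite degrees of freedom and the two-sided p-value for two
#' groups of (at least two) finite values. Non-finite values are dropped
#' before testing. The regular case delegates to [stats::t.test()] with
#' `var.equal = FALSE`.
#'
#' When both groups have zero variance the t distribution is degenerate and
#' `t.test()` refuses; by package convention identical constant groups return
#' `p = 1` (no evidence of difference) and constant groups with unequal means
#' return `p = 0` with a degenerate-variance warning.
#'
#' @param a,b numeric vectors; at least two finite values each.
#' @return one-row tibble with columns `difference` (`mean(a) - mean(b)`),
#'   `t`, `df`, `p`, `n1`, `n2`.
#' @export
#' @examples
#' welch_test(c(10, 11, 12), c(1, 2, 3))
welch_test <- function(a, b) {
  a <- a[is.finite(a)]
  b <- b[is.finite(b)]
  n1 <- length(a)
  n2 <- length(b)
  if (n1 < 2L || n2 < 2L) {
    abort_param("insufficient replicates: Welch test needs >= 2 finite ",
                "values per group (got ", n1, " and ", n2, ")")
  }
  d <- mean(a) - mean(b)
  if (var(a) == 0 && var(b) == 0) {
    if (d == 0) {
      return(tibble::tibble(difference = 0, t = 0, df = n1 + n2 - 2,
                            p = 1, n1 = n1, n2 = n2))
    }
    warning("degenerate zero-variance groups with unequal means: p set to 0",
            call. = FALSE)
    return(tibble::tibble(difference = d, t = sign(d) * Inf,
                          df = n1 + n2 - 2, p = 0, n1 = n1, n2 = n2))
  }
  tt <- t.test(a, b, var.equal = FALSE)
  tibble::tibble(difference = d,
                 t = unname(tt$statistic),
                 df = unname(tt$parameter),
                 p = tt$p.value,
                 n1 = n1, n2 = n2)
}

#' Row-wise Welch tests for two value matrices
#'
#' Vectorized Welch–Satterthwaite test across the rows of two matrices that
#' share row identity (e.g. proteins), used by the screen where thousands of
#' per-protein tests are run. `NA` cells are treated as missing. Rows with
#' fewer than two observed values in either matrix get `NA` statistics.
#' Degenerate zero-variance rows follow the [welch_test()] conventions.
#'
#' @param A,B numeric matrices with equal row counts; columns are replicates.
#' @return tibble, one row per input row: `difference` (`rowMean(A) -
#'   rowMean(B)`), `t`, `df`, `p`, `n1`, `n2`.
#' @export
row_welch <- function(A, B) {
  stopifnot(is.matrix(A), is.matrix(B), nrow(A) == nrow(B))
  n1 <- rowSums(is.finite(A))
  n2 <- rowSums(is.finite(B))
  m1 <- rowMeans(A, na.rm = TRUE)
  m2 <- rowMeans(B, na.rm = TRUE)
  v1 <- (rowSums(A * A, na.rm = TRUE) - n1 * m1 * m1) / (n1 - 1)
  v2 <- (rowSums(B * B, na.rm = TRUE) - n2 * m2 * m2) / (n2 - 1)
  v1 <- pmax(v1, 0)  # guard tiny negative rounding
  v2 <- pmax(v2, 0)
  d <- m1 - m2
  s1 <- v1 / n1
  s2 <- v2 / n2
  se2 <- s1 + s2
  t_stat <- d / sqrt(se2)
  df <- se2^2 / (s1^2 / (n1 - 1) + s2^2 / (n2 - 1))
  p <- 2 * pt(-abs(t_stat), df)

  degenerate <- se2 == 0 & n1 >= 2 & n2 >= 2
  if (any(degenerate, na.rm = TRUE)) {
    idx <- which(degenerate)
    equal <- d[idx] == 0
    t_stat[idx] <- ifelse(equal, 0, sign(d[idx]) * Inf)
    df[idx] <- n1[idx] + n2[idx] - 2
    p[idx] <- ifelse(equal, 1, 0)
    if (any(!equal)) {
      warning("degenerate zero-variance rows with unequal means: p set to 0",
              call. = FALSE)
    }
  }
  untested <- n1 < 2 | n2 < 2
  d[untested] <- NA_real_
  t_stat[untested] <- NA_real_
  df[untested] <- NA_real_
  p[untested] <- NA_real_
  tibble::tibble(difference = unname(d), t = unname(t_stat),
                 df = unname(df), p = unname(p),
                 n1 = as.integer(unname(n1)), n2 = as.integer(unname(n2)))
}

#' Compare per-cell counts (or any per-unit measure) between conditions
#'
#' Two conditions are compared with an unpaired two-sided t test
#' (unequal-variance form); three or more with a one-way ANOVA followed by
#' Tukey HSD pairwise comparisons. Per-condition mean and SD and
#' significance tiers ([significance_tier()]) are reported.
#'
#' @param values numeric vector of per-unit measurements.
#' @param condition character/factor vector parallel to `values`.
#' @return list with `summary` (tibble: condition, n, mean, sd) and
#'   `comparisons` (tibble: comparison label, estimate = difference of means,
#'   p, tier; plus the ANOVA F and its p as attributes when >2 conditions).
#' @export
compare_groups <- function(values, condition) {
  stopifnot(length(values) == length(condition))
  condition <- as.character(condition)
  keep <- is.finite(values) & !is.na(condition)
  values <- values[keep]
  condition <- condition[keep]
  counts <- table(condition)
  if (length(counts) < 2L) {
    abort_param("need >= 2 conditions to compare")
  }
  small <- names(counts)[counts < 2]
  if (length(small) > 0) {
    abort_param("insufficient cells in condition: ",
                paste(small, collapse = ", "))
  }
  group_means <- vapply(names(counts),
                        function(g) mean(values[condition == g]), 0)
  group_sds <- vapply(names(counts),
                      function(g) sd(values[condition == g]), 0)
  summary_tbl <- tibble::tibble(condition = names(counts),
                                n = as.integer(counts),
                                mean = unname(group_means),
                                sd = unname(group_sds))
  if (length(counts) == 2L) {
    g <- names(counts)
    a <- values[condition == g[1]]
    b <- values[condition == g[2]]
    if (var(a) == 0 && var(b) == 0) {
      p <- if (mean(a) == mean(b)) 1 else 0
    } else {
      p <- t.test(a, b, var.equal = FALSE)$p.value
    }
    comparisons <- tibble::tibble(
      comparison = paste(g[1], "vs", g[2]),
      estimate = mean(a) - mean(b),
      p = p,
      tier = significance_tier(p)
    )
  } else {
    df <- data.frame(y = values, g = factor(condition))
    fit <- aov(y ~ g, data = df)
    tuk <- TukeyHSD(fit)$g
    comparisons <- tibble::tibble(
      comparison = gsub("-", " vs ", rownames(tuk), fixed = TRUE),
      estimate = tuk[, "diff"],
      p = tuk[, "p adj"],
      tier = significance_tier(tuk[, "p adj"])
    )
    anova_row <- summary(fit)[[1]]
    attr(comparisons, "anova_F") <- anova_row[["F value"]][1]
    attr(comparisons, "anova_p") <- anova_row[["Pr(>F)"]][1]
  }
  list(summary = summary_tbl, comparisons = comparisons)
}
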