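# Statistical comparisons and distribution summaries: two-tailed unpaired
# Welch's t-test, one-way ANOVA with Dunnett's multiple comparisons against
# a control (single pooled variance, multivariate-t critical values), and
# scatter-with-mean distribution summaries.

starLevels <- c(1e-4, 1e-3, 1e-2, 5e-2)

#' Significance stars
#'
#' `*` p<0.05, `**` p<0.01, `***` p<0.001, `****` p<0.0001, else `ns`.
#'
#' @param p p-value(s)
#' @return character vector of stars
#' @export
significanceStars <- function(p) {
  vapply(p, function(pp) {
    if (!is.finite(pp)) return(NA_character_)
    if (pp < 1e-4) "****" else if (pp < 1e-3) "***"
    else if (pp < 1e-2) "**" else if (pp < 5e-2) "*" else "ns"
  }, character(1))
}

testResult <- function(test, statistic, df, p, ns, comparison = NA_character_,
                       degenerate = FALSE) {
  structure(list(test = test, comparison = comparison,
                 statistic = statistic, df = df, p = p,
                 stars = significanceStars(p), groupNs = ns,
                 degenerate = degenerate),
            class = "TestResult")
}

#' @export
print.TestResult <- function(x, ...) {
  cat(sprintf("%s%s: statistic = %.4g, df = %.4g, p = %.3g %s%s\n",
              x$test,
              if (is.na(x$comparison)) "" else paste0(" [", x$comparison, "]"),
              x$statistic, x$df, x$p, x$stars,
              if (x$degenerate) " (degenerate)" else ""))
  invisible(x)
}

#' Welch's two-sample t-test
#'
#' Two-tailed, unpaired, unequal-variance t-test with Welch-Satterthwaite
#' degrees of freedom. Zero-variance groups are handled as a degenerate
#' limit (p = 1 for equal means, p = 0 otherwise) rather than an error.
#'
#' @param valuesA,valuesB numeric group samples (each n >= 2)
#' @return a `TestResult`
#' @export
welchTTest <- function(valuesA, valuesB) {
  if (length(valuesA) < 2L || length(valuesB) < 2L)
    stop("insufficient data: each group needs n >= 2")
  ns <- c(length(valuesA), length(valuesB))
  if (stats::var(valuesA) == 0 && stats::var(valuesB) == 0) {
    eq <- mean(valuesA) == mean(valuesB)
    return(testResult("Welch t-test", if (eq) 0 else Inf,
                      sum(ns) - 2, if (eq) 1 else 0, ns, degenerate = TRUE))
  }
  tt <- stats::t.test(valuesA, valuesB, var.equal = FALSE)
  testResult("Welch t-test", unname(tt$statistic), unname(tt$parameter),
             tt$p.value, ns)
}

# Dunnett two-sided p-value / adjusted p for one comparison statistic,
# via the multivariate-t distribution of the k comparison statistics under
# the null (common correlation structure from shared control).
dunnettPAdjust <- function(tObs, corr, df) {
  k <- nrow(corr)
  p <- mvtnorm::pmvt(lower = rep(-abs(tObs), k), upper = rep(abs(tObs), k),
                     df = df, corr = corr,
                     algorithm = mvtnorm::GenzBretz(abseps = 1e-8,
                                                    maxpts = 2e6))
  max(0, min(1, 1 - as.numeric(p)))
}

#' One-way ANOVA with Dunnett's multiple comparisons against a control
#'
#' Ordinary one-way ANOVA (via [stats::aov()]) followed by Dunnett's test:
#' each group is compared with the control using the single pooled variance
#' (the ANOVA mean-square error), and p-values are adjusted over the joint
#' multivariate-t distribution of the comparison statistics, evaluated
#' numerically.
#'
#' @param values numeric measurements
#' @param groups group labels (same length as `values`)
#' @param control the control group label
#' @return list with `anova` (a `TestResult`) and `comparisons` (a list of
#'   `TestResult`, one per non-control group)
#' @export
anovaDunnett <- function(values, groups, control) {
  groups <- as.character(groups)
  if (!control %in% groups)
    stop("parameter error: control label '", control, "' not among groups")
  gl <- unique(groups)
  if (length(gl) < 2L) stop("need at least 2 groups")
  ns <- table(groups)
  if (any(ns < 2L)) stop("insufficient data: each group needs n >= 2")
  fit <- stats::aov(values ~ factor(groups, levels = c(control,
                                                       setdiff(gl, control))))
  an <- stats::anova(fit)
  anovaRes <- testResult("one-way ANOVA", an$`F value`[1L],
                         an$Df[1L], an$`Pr(>F)`[1L], as.integer(ns))
  mse <- an$`Mean Sq`[2L]
  dfe <- an$Df[2L]
  others <- setdiff(gl, control)
  n0 <- ns[[control]]
  ni <- vapply(others, function(g) ns[[g]], numeric(1))
  lam <- sqrt(ni / (ni + n0))
  corr <- outer(lam, lam)
  diag(corr) <- 1
  m0 <- mean(values[groups == control])
  comparisons <- lapply(seq_along(others), function(i) {
    g <- others[i]
    t_i <- (mean(values[groups == g]) - m0) /
      sqrt(mse * (1 / ni[i] + 1 / n0))
    p <- if (mse == 0) {
      if (mean(values[groups == g]) == m0) 1 else 0
    } else dunnettPAdjust(t_i, corr, dfe)
    testResult("Dunnett", t_i, dfe, p, c(ni[i], n0),
               comparison = paste(g, "vs", control), degenerate = mse == 0)
  })
  list(anova = anovaRes, comparisons = comparisons)
}

#' Distribution summary with scatter-and-mean figure
#'
#' Mean, sd, median and n, plus a per-point scatter with the mean marked;
#' the log10 axis is a display option only and never transforms the stored
#' values.
#'
#' @param values finite numeric values
#' @param label condition label
#' @param log10Display display the value axis on a log10 scale (all values
#'   must be positive)
#' @return list with `summary` (a [conditionSummary()]) and `plot` (a
#'   ggplot object)
#' @export
distributionSummary <- function(values, label = "condition",
                                log10Display = FALSE) {
  if (any(!is.finite(values))) stop("values must be finite")
  if (log10Display && any(values <= 0))
    stop("display error: log10 display with non-positive value(s) at ",
         paste(which(values <= 0), collapse = ", "))
  s <- conditionSummary(values, label)
  df <- data.frame(condition = label, value = values)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = condition, y = value)) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.5, size = 0.8) +
    ggplot2::stat_summary(fun = mean, geom = "crossbar", width = 0.4,
                          color = "red", linewidth = 0.4) +
    ggplot2::labs(y = "value", x = NULL) +
    ggplot2::theme_classic()
  if (log10Display) p <- p + ggplot2::scale_y_log10()
  list(summary = s, plot = p)
}
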