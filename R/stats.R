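#' Kruskal-Wallis rank test across groups
#'
#' Tie-corrected Kruskal-Wallis H with the chi-square approximation on k-1
#' degrees of freedom (the omnibus test used for compartment comparisons).
#' All-identical data degenerate to H = 0, p = 1 rather than an error.
#'
#' @param groups list of >= 2 numeric vectors (each nonempty, total n >= 3).
#' @return list with `H`, `p`, `df`.
#' @examples
#' kruskal_wallis(list(c(1, 2), c(3, 4), c(5, 6)))$H  # 32/7
#' @export
kruskal_wallis <- function(groups) {
  if (!is.list(groups) || length(groups) < 2)
    stop("need at least two groups", call. = FALSE)
  ns <- lengths(groups)
  if (any(ns < 1) || sum(ns) < 3)
    stop("each group needs n >= 1 and total n >= 3", call. = FALSE)
  x <- unlist(groups)
  if (length(unique(x)) == 1L)
    return(list(H = 0, p = 1, df = length(groups) - 1L))
  kt <- stats::kruskal.test(x, factor(rep(seq_along(groups), ns)))
  list(H = unname(kt$statistic), p = kt$p.value, df = unname(kt$parameter))
}

#' Mann-Whitney (Wilcoxon rank-sum) test
#'
#' Two-sample rank test with the exact null distribution when the combined
#' sample is small (`n_a + n_b <= exact_max_n`, default 12, keeping the
#' enumeration under ~1,000 cases) and no ties are present; otherwise the
#' tie-corrected normal approximation with continuity correction. U counts
#' the pairs with `a > b`.
#'
#' @param a,b numeric samples (each nonempty).
#' @param alternative `"two.sided"` (default), `"less"` or `"greater"`.
#' @param exact_max_n combined-n cutoff for the exact path.
#' @return list with `U`, `p` and `method` (`"exact"` or `"normal_approx"`).
#' @examples
#' mann_whitney(c(1, 2), c(3, 4))$p  # exact: 2/6
#' @export
mann_whitney <- function(a, b, alternative = "two.sided", exact_max_n = 12) {
  if (length(a) < 1 || length(b) < 1) stop("both groups must be nonempty", call. = FALSE)
  ties <- anyDuplicated(c(a, b)) > 0
  exact <- (length(a) + length(b) <= exact_max_n) && !ties
  wt <- suppressWarnings(stats::wilcox.test(a, b, alternative = alternative,
                                            exact = exact, correct = TRUE))
  list(U = unname(wt$statistic), p = wt$p.value,
       method = if (exact) "exact" else "normal_approx")
}

# number of Benjamini-Hochberg step-up rejections at a given level
bh_n_reject <- function(p, level) {
  m <- length(p)
  s <- sort(p)
  k <- which(s <= level * seq_len(m) / m)
  if (length(k)) max(k) else 0L
}

bky_reject_at <- function(p, q) {
  m <- length(p)
  q1 <- q / (1 + q)
  r1 <- bh_n_reject(p, q1)
  if (r1 == 0L) return(rep(FALSE, m))
  if (r1 == m) return(rep(TRUE, m))
  q2 <- q1 * m / (m - r1)
  r2 <- bh_n_reject(p, q2)
  if (r2 == 0L) return(rep(FALSE, m))
  thr <- sort(p)[r2]
  p <= thr
}

#' Two-stage Benjamini-Krieger-Yekutieli FDR step-up
#'
#' The adaptive two-stage linear step-up procedure: stage 1 runs
#' Benjamini-Hochberg at level `q' = q / (1 + q)` to estimate the number of
#' true nulls `m - r1`; if anything but nothing-or-everything is rejected,
#' stage 2 re-runs the step-up at the inflated level `q' m / (m - r1)`. The
#' reject set is always a prefix of the p-sorted list. Adjusted q-values are
#' the smallest nominal q at which each hypothesis would be rejected,
#' obtained by bisection.
#'
#' @param pvalues numeric vector in `[0, 1]`.
#' @param q nominal FDR level (default 0.05).
#' @param compute_q also return adjusted q-values (bisection; switch off for
#'   bulk simulation).
#' @return list with `reject` (logical) and `qvalue` (or `NULL`).
#' @examples
#' bky_two_stage(c(0.01, 0.02, 0.5))$reject  # TRUE TRUE FALSE
#' @export
bky_two_stage <- function(pvalues, q = 0.05, compute_q = TRUE) {
  if (length(pvalues) < 1) stop("need at least one p-value", call. = FALSE)
  if (anyNA(pvalues) || any(pvalues < 0) || any(pvalues > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  if (!is.finite(q) || q <= 0 || q >= 1) stop("`q` must lie in (0, 1)", call. = FALSE)
  reject <- bky_reject_at(pvalues, q)
  qv <- NULL
  if (compute_q) {
    qv <- vapply(seq_along(pvalues), function(i) {
      if (bky_reject_at(pvalues, 1 - 1e-12)[i] == FALSE) return(1)
      lo <- 1e-12; hi <- 1
      for (it in 1:40) {
        mid <- (lo + hi) / 2
        if (bky_reject_at(pvalues, mid)[i]) hi <- mid else lo <- mid
      }
      hi
    }, numeric(1))
  }
  list(reject = reject, qvalue = qv)
}

#' Two-way ANOVA with Type II sums of squares
#'
#' Least-squares fit of the two-factor model with interaction
#' (`value ~ region * age`) and Type II F-tests against the residual mean
#' square, appropriate for the unbalanced cell counts that arise when cells
#' are reconstructed opportunistically. Empty design cells are rejected
#' with an error naming the cell.
#'
#' @param values numeric response.
#' @param factor_region,factor_age factors (>= 2 levels each).
#' @return data frame with one row per term (`region`, `age`,
#'   `region:age`): `F`, `p`, `df`.
#' @export
two_way_anova <- function(values, factor_region, factor_age) {
  fr <- factor(factor_region)
  fa <- factor(factor_age)
  if (nlevels(fr) < 2 || nlevels(fa) < 2)
    stop("both factors need at least two levels", call. = FALSE)
  tab <- table(fr, fa)
  if (any(tab == 0)) {
    empty <- which(tab == 0, arr.ind = TRUE)[1, ]
    stop(sprintf("empty design cell: region=%s, age=%s",
                 levels(fr)[empty[1]], levels(fa)[empty[2]]), call. = FALSE)
  }
  fit <- stats::lm(values ~ fr * fa)
  aa <- car::Anova(fit, type = 2)
  terms <- c("fr", "fa", "fr:fa")
  idx <- match(terms, rownames(aa))
  data.frame(term = c("region", "age", "region:age"),
             F = aa[idx, "F value"], p = aa[idx, "Pr(>F)"], df = aa[idx, "Df"],
             stringsAsFactors = FALSE)
}

#' Distribution-free confidence interval for the median
#'
#' Median with a binomial order-statistic confidence interval: the interval
#' `(x_(l), x_(n+1-l))` with `l` the largest rank keeping two-sided
#' coverage at least `level`. When n is too small for any such interval
#' (n < 6 at 95%), the full range `(min, max)` is returned with an
#' under-coverage warning.
#'
#' @param values numeric sample.
#' @param level nominal coverage (default 0.95).
#' @return list with `median`, `lo`, `hi`, `coverage` (achieved).
#' @export
median_ci <- function(values, level = 0.95) {
  n <- length(values)
  if (n < 1) stop("empty sample", call. = FALSE)
  x <- sort(values)
  med <- stats::median(x)
  alpha <- (1 - level) / 2
  l <- stats::qbinom(alpha, n, 0.5)            # largest l-1 with cdf <= alpha
  if (stats::pbinom(l - 1, n, 0.5) > alpha) l <- l - 1L
  l <- l  # ranks are 1-based: interval (x_(l+1- shift)) handled below
  if (l < 1) {
    warning(sprintf("n = %d cannot achieve %.0f%% coverage; returning the range",
                    n, 100 * level))
    return(list(median = med, lo = x[1], hi = x[n],
                coverage = 1 - 2 * stats::pbinom(0, n, 0.5)))
  }
  lo <- x[l]
  hi <- x[n + 1 - l]
  list(median = med, lo = lo, hi = hi,
       coverage = 1 - 2 * stats::pbinom(l - 1, n, 0.5))
}

#' Percent difference of a relative to b
#'
#' `100 (a - b) / b`, the convention behind statements like "dendritic
#' mitochondria were 42% larger than somatic".
#'
#' @param a,b numeric; `b != 0`.
#' @return percent difference (vectorized).
#' @examples
#' percent_difference(0.27, 0.19)  # ~42.1
#' @export
percent_difference <- function(a, b) {
  if (any(b == 0)) stop("reference value b must be nonzero", call. = FALSE)
  100 * (a - b) / b
}

#' Fraction of values beyond a threshold
#'
#' Percentage of values strictly beyond a threshold, e.g. the share of
#' exceptionally large organelles (> 1 um^3) or of highly complex ones
#' (MCI > 7).
#'
#' @param values numeric sample (nonempty).
#' @param threshold cutoff.
#' @param direction `"greater"` (default) or `"less"` (strict comparisons).
#' @return percentage in `[0, 100]`.
#' @export
threshold_fraction <- function(values, threshold, direction = c("greater", "less")) {
  direction <- match.arg(direction)
  if (length(values) == 0) stop("empty sample", call. = FALSE)
  hit <- if (direction == "greater") values > threshold else values < threshold
  100 * mean(hit)
}

#' Empirical cumulative distribution function
#'
#' Right-continuous ECDF on the sorted sample, evaluable at arbitrary
#' points (the "cumulative frequency distribution" presentation).
#'
#' @param values numeric sample.
#' @return a function (of class `ecdf`).
#' @export
ecdf_fn <- function(values) stats::ecdf(values)

#' Mitotype summary points
#'
#' A mitotype is a group-level point in (mean MCI, mean volume) space:
#' per-group mean and standard error of organelle volume and MCI, with n.
#' A single-organelle group has SEM 0.
#'
#' @param records data frame with columns `V_um3` and `MCI` (e.g. from
#'   [measure_stack()]).
#' @param group_key column name(s) to group by.
#' @return data frame with one row per group: `n`, `mean_V_um3`,
#'   `sem_V_um3`, `mean_MCI`, `sem_MCI`.
#' @export
mitotype_summary <- function(records, group_key) {
  stopifnot(all(c("V_um3", "MCI") %in% names(records)),
            all(group_key %in% names(records)))
  key <- interaction(records[group_key], drop = TRUE, sep = "|")
  sem <- function(x) if (length(x) < 2) 0 else stats::sd(x) / sqrt(length(x))
  out <- do.call(rbind, lapply(split(records, key), function(d) {
    cbind(d[1, group_key, drop = FALSE],
          data.frame(n = nrow(d),
                     mean_V_um3 = mean(d$V_um3), sem_V_um3 = sem(d$V_um3),
                     mean_MCI = mean(d$MCI), sem_MCI = sem(d$MCI)))
  }))
  rownames(out) <- NULL
  out
}
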