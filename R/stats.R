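# Population-level statistics over fiber ratio distributions.

#' Cliff's delta effect size
#'
#' `delta = (#\{x_i > y_j\} - #\{x_i < y_j\}) / (|x| |y|)`, computed via
#' midranks in O((m+n) log(m+n)); ties contribute zero.
#'
#' @param x,y non-empty numeric samples.
#' @return delta in `[-1, 1]`.
#' @export
cliffs_delta <- function(x, y) {
  m <- length(x); n <- length(y)
  if (m == 0 || n == 0) stop("samples must be non-empty")
  r <- rank(c(x, y))
  u <- sum(r[seq_len(m)]) - m * (m + 1) / 2  # #\{x>y\} + 0.5 #ties
  2 * u / (m * n) - 1
}

#' Bootstrap percentile confidence interval for Cliff's delta
#'
#' Resamples `x` and `y` independently with replacement `B` times and
#' returns the percentile interval of the resampled deltas. Seeded and
#' reproducible; the caller's RNG state is untouched.
#'
#' @param x,y numeric samples.
#' @param B number of bootstrap replicates (>= 100, default 1000).
#' @param level confidence level (default 0.95).
#' @param seed integer seed.
#' @return numeric `c(lo, hi)`.
#' @export
bootstrap_delta_ci <- function(x, y, B = 1000, level = 0.95, seed = 1) {
  if (B < 100) stop("B must be >= 100")
  m <- length(x); n <- length(y)
  with_seed(seed, {
    deltas <- vapply(seq_len(B), function(b) {
      cliffs_delta(x[sample.int(m, m, replace = TRUE)],
                   y[sample.int(n, n, replace = TRUE)])
    }, numeric(1))
    unname(quantile(deltas, probs = c((1 - level) / 2, (1 + level) / 2),
                    type = 7))
  })
}

#' Compare every condition to a reference
#'
#' For each condition: the median ratio, the median normalized by the
#' reference median, Cliff's delta against the reference with a bootstrap
#' confidence interval, and a significance flag (the interval excludes 0).
#' Without an explicit `reference`, the condition whose median sits at the
#' midpoint of all condition medians is selected.
#'
#' @param conditions named list of numeric vectors (one per condition).
#' @param reference reference condition name, or `NULL` for auto-selection.
#' @param B bootstrap replicates (default 1000).
#' @param level confidence level (default 0.95).
#' @param seed integer seed.
#' @return data.frame: `condition`, `n`, `median`, `normalized_median`,
#'   `delta`, `ci_lo`, `ci_hi`, `significant`, `reference`.
#' @export
compare_to_reference <- function(conditions, reference = NULL, B = 1000,
                                 level = 0.95, seed = 1) {
  if (length(conditions) == 0 || any(lengths(conditions) == 0))
    stop("every condition needs at least one value")
  meds <- vapply(conditions, median, numeric(1))
  if (is.null(reference)) {
    reference <- names(conditions)[which.min(abs(meds - median(meds)))]
  }
  if (!reference %in% names(conditions))
    stop("reference condition not found: ", reference)
  ref <- conditions[[reference]]
  rows <- lapply(seq_along(conditions), function(i) {
    nm <- names(conditions)[i]
    x <- conditions[[i]]
    if (nm == reference) {
      d <- 0; ci <- c(0, 0); sig <- FALSE
    } else {
      d <- cliffs_delta(x, ref)
      ci <- bootstrap_delta_ci(x, ref, B = B, level = level,
                               seed = seed + i)
      sig <- ci[1] > 0 || ci[2] < 0
    }
    data.frame(condition = nm, n = length(x), median = meds[i],
               normalized_median = meds[i] / meds[reference],
               delta = d, ci_lo = ci[1], ci_hi = ci[2], significant = sig,
               reference = reference, row.names = NULL)
  })
  do.call(rbind, rows)
}

#' Flag grader disagreements
#'
#' Two graders disagree on a condition when exactly one of them finds it
#' significantly different from the reference.
#'
#' @param report_a,report_b [compare_to_reference()] outputs on the same
#'   conditions.
#' @return data.frame `condition`, `significant_a`, `significant_b`,
#'   `disagreement`.
#' @export
grader_disagreement <- function(report_a, report_b) {
  m <- merge(report_a[, c("condition", "significant")],
             report_b[, c("condition", "significant")],
             by = "condition", suffixes = c("_a", "_b"))
  m$disagreement <- xor(m$significant_a, m$significant_b)
  m
}

#' Mann-Whitney U test (two-sided)
#'
#' Exact enumeration for small tie-free samples, otherwise the normal
#' approximation with tie correction and continuity correction.
#'
#' @param x,y non-empty numeric samples.
#' @param method `"auto"` (exact when both n <= 20 and there are no ties),
#'   `"exact"`, or `"normal"`.
#' @return list `U` (for x over y), `p`.
#' @export
mann_whitney <- function(x, y, method = c("auto", "exact", "normal")) {
  method <- match.arg(method)
  m <- length(x); n <- length(y)
  if (m == 0 || n == 0) stop("samples must be non-empty")
  r <- rank(c(x, y))
  U <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  ties <- any(duplicated(c(x, y)))
  if (method == "auto") method <- if (m <= 20 && n <= 20 && !ties)
    "exact" else "normal"
  if (method == "exact") {
    if (ties) warning("ties present; exact p-value is approximate")
    u <- round(U)
    p <- if (u > m * n / 2) {
      2 * (1 - pwilcox(u - 1, m, n))
    } else {
      2 * pwilcox(u, m, n)
    }
    p <- min(1, p)
  } else {
    N <- m + n
    tie_tab <- table(r)
    correction <- sum(tie_tab^3 - tie_tab) / (N * (N - 1))
    sigma2 <- m * n / 12 * (N + 1 - correction)
    z <- (U - m * n / 2)
    z <- (z - sign(z) * 0.5) / sqrt(sigma2)  # continuity correction
    p <- 2 * stats::pnorm(-abs(z))
  }
  list(U = U, p = p)
}

#' Chi-square test on structure-type counts
#'
#' Pearson chi-square on a 2 x k contingency table of replication-structure
#' counts (e.g. ongoing forks vs divergent origins per condition), with
#' k - 1 degrees of freedom.
#'
#' @param counts_a,counts_b equal-length non-negative count vectors.
#' @return list `statistic`, `df`, `p`.
#' @export
chi_square_types <- function(counts_a, counts_b) {
  if (length(counts_a) != length(counts_b))
    stop("count vectors must have equal length")
  tab <- rbind(counts_a, counts_b)
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expected == 0))
    stop("zero expected count; merge the affected structure categories")
  ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p = unname(ct$p.value))
}
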