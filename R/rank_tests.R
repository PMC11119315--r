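#' @include classify.R
NULL

rankTestResult <- function(statistic, p_value, method, tie_correction) {
  structure(list(statistic = unname(statistic),
                 p_value = min(max(p_value, 0), 1),
                 method = method,
                 tie_correction_applied = tie_correction),
            class = "RankTestResult")
}

#' @export
print.RankTestResult <- function(x, ...) {
  cat("RankTestResult: statistic = ", signif(x$statistic, 6),
      ", p = ", signif(x$p_value, 4), " (", x$method,
      if (x$tie_correction_applied) ", tie-corrected" else "", ")\n",
      sep = "")
  invisible(x)
}

#' Mann-Whitney U test (rank-sum test for two samples)
#'
#' Reports U1, the statistic of the first sample, computed from midranks.
#' The p-value comes from full enumeration of all rank assignments when
#' the pooled size is at most 12 and the data are untied, and otherwise
#' from the normal approximation with tie correction and continuity
#' correction. Two-sided by default (equality of distributions against
#' any shift).
#'
#' @param x,y numeric samples, both nonempty
#' @param alternative only \code{"two.sided"} is implemented
#' @return a \code{"RankTestResult"} with fields \code{statistic} (U1),
#'   \code{p_value}, \code{method} (\code{"exact-enumeration"} or
#'   \code{"normal-approx"}), \code{tie_correction_applied}
#' @examples
#' mannWhitneyU(c(1, 2), c(3, 4))  # U1 = 0, exact p = 1/3
#' @export
mannWhitneyU <- function(x, y, alternative = "two.sided") {
  if (!length(x) || !length(y)) stop("both samples must be nonempty")
  stopifnot(alternative == "two.sided")
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  pooled <- c(x, y)
  r <- rank(pooled)  # midranks
  U1 <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- any(duplicated(pooled))
  mu <- n1 * n2 / 2

  if (N <= 12 && !ties) {
    # enumerate every assignment of ranks to the first sample
    combs <- utils::combn(N, n1)
    Uall <- colSums(matrix(seq_len(N)[combs], nrow = n1)) -
      n1 * (n1 + 1) / 2
    p <- mean(abs(Uall - mu) >= abs(U1 - mu) - 1e-12)
    return(rankTestResult(U1, p, "exact-enumeration", FALSE))
  }

  tab <- table(pooled)
  tie_term <- sum(tab^3 - tab) / (N * (N - 1))
  sigma2 <- n1 * n2 / 12 * ((N + 1) - tie_term)
  if (sigma2 <= 0)
    return(rankTestResult(U1, 1, "normal-approx", ties))
  z <- (abs(U1 - mu) - 0.5) / sqrt(sigma2)  # continuity correction
  p <- 2 * stats::pnorm(z, lower.tail = FALSE)
  rankTestResult(U1, p, "normal-approx", ties)
}

#' Kruskal-Wallis H test across two or more groups
#'
#' \eqn{H = 12/(N(N+1)) \sum_j R_j^2/n_j - 3(N+1)} on midranks, divided by
#' the tie-correction factor \eqn{1 - \sum(t^3 - t)/(N^3 - N)}; the
#' p-value is chi-squared with (groups - 1) degrees of freedom. When all
#' pooled values are identical the degenerate result is H = 0, p = 1. H is
#' invariant under strictly monotone transformations of the pooled data.
#'
#' @param groups list of numeric samples (>= 2 groups, each nonempty,
#'   pooled size >= 3)
#' @return a \code{"RankTestResult"} with \code{method = "chi2-approx"}
#' @examples
#' kruskalH(list(c(1, 2, 3), c(4, 5, 6), c(7, 8, 9)))  # H = 7.2
#' @export
kruskalH <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L)
    stop("need at least 2 groups")
  if (any(lengths(groups) == 0L)) stop("every group must be nonempty")
  N <- sum(lengths(groups))
  if (N < 3L) stop("need a pooled size of at least 3")
  pooled <- unlist(groups, use.names = FALSE)
  r <- rank(pooled)
  idx <- rep(seq_along(groups), lengths(groups))
  Rj <- tapply(r, idx, sum)
  nj <- lengths(groups)
  H <- 12 / (N * (N + 1)) * sum(Rj^2 / nj) - 3 * (N + 1)
  tab <- table(pooled)
  C <- 1 - sum(tab^3 - tab) / (N^3 - N)
  ties <- any(tab > 1)
  if (C == 0)  # every pooled value identical
    return(rankTestResult(0, 1, "chi2-approx", ties))
  H <- H / C
  p <- stats::pchisq(H, df = length(groups) - 1, lower.tail = FALSE)
  rankTestResult(H, p, "chi2-approx", ties)
}

#' Rank-test separability report for feature columns
#'
#' For each requested feature: a Kruskal-Wallis H test across the three
#' activity classes (1 = no activity, 2 = mental drawing, 3 = spatial
#' navigation) and a Mann-Whitney U test of motor (labels 2 and 3 pooled)
#' versus no-motor (label 1), each with the alpha = 0.05 decision.
#'
#' @param features feature data.frame with a \code{label} column carrying
#'   all three codes
#' @param feature_names columns to test; default: all feature columns
#' @param alpha significance level for the reported decision
#' @return data.frame with columns \code{test}, \code{feature},
#'   \code{statistic}, \code{p_value}, \code{reject_at_alpha}
#' @export
featureSeparabilityReport <- function(features, feature_names = NULL,
                                      alpha = 0.05) {
  if (!all(c(1L, 2L, 3L) %in% features$label))
    stop("all three activity classes must be present")
  if (is.null(feature_names)) feature_names <- featureColumns(features)
  missing <- setdiff(feature_names, names(features))
  if (length(missing))
    stop("unknown feature(s): ", paste(missing, collapse = ", "))
  rows <- lapply(feature_names, function(fn) {
    v <- features[[fn]]
    kw <- kruskalH(split(v, features$label))
    mw <- mannWhitneyU(v[features$label %in% c(2L, 3L)],
                       v[features$label == 1L])
    data.frame(
      test = c("kruskal_wallis_H", "mann_whitney_U"),
      feature = fn,
      statistic = c(kw$statistic, mw$statistic),
      p_value = c(kw$p_value, mw$p_value),
      reject_at_alpha = c(kw$p_value < alpha, mw$p_value < alpha),
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
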