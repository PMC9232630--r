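new_dis_assoc <- function(statistic, df, p_value, method, table,
                          odds_ratio = NA_real_) {
  structure(
    list(statistic = statistic, df = df, p_value = p_value, method = method,
         table = table, odds_ratio = odds_ratio, n = sum(table)),
    class = "dis_assoc"
  )
}

as_count_table <- function(x, min_dim = 2L) {
  m <- as.matrix(x)
  storage.mode(m) <- "double"
  if (any(is.na(m)) || any(m < 0) || any(m != round(m))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  if (nrow(m) < min_dim || ncol(m) < min_dim) {
    stop("contingency table must be at least 2x2", call. = FALSE)
  }
  m
}

check_margins <- function(m) {
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    stop("zero marginal row/column: expected counts undefined", call. = FALSE)
  }
  m
}

table_odds_ratio <- function(m) {
  if (!all(dim(m) == c(2, 2))) return(NA_real_)
  if (any(m == 0)) m <- m + 0.5 # Haldane-Anscombe correction
  (m[1, 1] * m[2, 2]) / (m[1, 2] * m[2, 1])
}

#' Likelihood-ratio G-test of independence
#'
#' The likelihood-ratio chi-square for an r x c contingency table:
#' \eqn{G = 2 \sum O \ln(O/E)} over cells with observed count
#' \eqn{O > 0}, with expected counts \eqn{E} from the independence model
#' and \eqn{(r-1)(c-1)} degrees of freedom. This is the "Likelihood-ratio
#' Chi-square" used throughout the swarm-association analyses.
#'
#' @param x A matrix/table of counts (rows and columns at least 2), or a
#'   data frame of counts.
#' @return A `dis_assoc` object with `statistic`, `df`, `p_value`,
#'   `method`, `odds_ratio` (2x2 only; Haldane-corrected when a cell is
#'   zero) and `n`. Supports [generics::tidy()] and [generics::glance()].
#' @examples
#' g_test(matrix(c(67, 691, 1230, 33), 2)) # swarm type vs hybrid status
#' @export
g_test <- function(x) {
  m <- check_margins(as_count_table(x))
  n <- sum(m)
  e <- outer(rowSums(m), colSums(m)) / n
  pos <- m > 0
  stat <- 2 * sum(m[pos] * log(m[pos] / e[pos]))
  df <- (nrow(m) - 1) * (ncol(m) - 1)
  new_dis_assoc(stat, df, stats::pchisq(stat, df, lower.tail = FALSE),
                "LR_G", m, table_odds_ratio(m))
}

#' Pearson and N-1 chi-square tests for 2x2 tables
#'
#' `pearson_chi2()` is the ordinary (uncorrected) Pearson chi-square.
#' `n_minus_1_chi2()` rescales it by \eqn{(n-1)/n}, the small-sample
#' correction recommended for 2x2 tables with low expected counts.
#'
#' @inheritParams g_test
#' @return A `dis_assoc` object.
#' @examples
#' n_minus_1_chi2(matrix(c(1, 9, 9, 1), 2))
#' @export
n_minus_1_chi2 <- function(x) {
  m <- check_margins(as_count_table(x))
  if (!all(dim(m) == c(2, 2))) {
    stop("the N-1 chi-square is defined for 2x2 tables", call. = FALSE)
  }
  n <- sum(m)
  # only the statistic is used; chisq.test's small-expected-count warning
  # does not apply to the (n-1)-corrected test
  pearson <- unname(suppressWarnings(
    stats::chisq.test(m, correct = FALSE))$statistic)
  stat <- pearson * (n - 1) / n
  new_dis_assoc(stat, 1L, stats::pchisq(stat, 1L, lower.tail = FALSE),
                "N_MINUS_1", m, table_odds_ratio(m))
}

#' @rdname n_minus_1_chi2
#' @export
pearson_chi2 <- function(x) {
  m <- check_margins(as_count_table(x))
  stat <- unname(suppressWarnings(
    stats::chisq.test(m, correct = FALSE))$statistic)
  df <- (nrow(m) - 1) * (ncol(m) - 1)
  new_dis_assoc(stat, df, stats::pchisq(stat, df, lower.tail = FALSE),
                "PEARSON", m, table_odds_ratio(m))
}

#' Fisher-Irwin exact test for 2x2 tables
#'
#' Two-sided exact test conditioning on both margins: the p-value sums
#' the hypergeometric probabilities of all tables with the observed
#' margins whose probability does not exceed that of the observed table
#' (within a small relative tolerance, the usual convention for the
#' two-sided rule).
#'
#' @inheritParams g_test
#' @return A `dis_assoc` object with `df = NA` (exact test).
#' @examples
#' fisher_irwin(matrix(c(0, 10, 10, 0), 2))
#' @export
fisher_irwin <- function(x) {
  m <- as_count_table(x)
  if (!all(dim(m) == c(2, 2))) {
    stop("the Fisher-Irwin test is defined for 2x2 tables", call. = FALSE)
  }
  r1 <- sum(m[1, ]); c1 <- sum(m[, 1]); n <- sum(m)
  support <- max(0, r1 + c1 - n):min(r1, c1)
  probs <- stats::dhyper(support, c1, n - c1, r1)
  p_obs <- stats::dhyper(m[1, 1], c1, n - c1, r1)
  p <- min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
  new_dis_assoc(NA_real_, NA_integer_, p, "FISHER", m, table_odds_ratio(m))
}

#' Compare swarm-match odds between two islands
#'
#' Builds the 2x2 table (island x match/mismatch) from a match table and
#' tests whether the odds of matching the swarm of capture differ between
#' the two islands — the pairwise comparisons reported alongside the
#' per-chromosome logistic regression. The default likelihood-ratio test
#' can be swapped for the exact Fisher-Irwin or the N-1 chi-square, both
#' robust to the near-empty mismatch cells these comparisons produce.
#'
#' Per-island rows from the same individuals are treated as independent
#' observations, exactly as in the source analyses; with strong
#' within-individual correlation the nominal p-values are optimistic.
#'
#' @param match_table Output of [build_match_table()], typically
#'   pre-filtered to one species and sex.
#' @param island_a,island_b Islands to compare (`"X"`, `"2L"`, `"3L"`).
#' @param method `"lr"`, `"fisher"` or `"n1chi2"`.
#' @return A `dis_assoc` object; `odds_ratio` is the odds of matching in
#'   `island_a` relative to `island_b`.
#' @export
pairwise_match_comparison <- function(match_table, island_a, island_b,
                                      method = c("lr", "fisher", "n1chi2")) {
  method <- match.arg(method)
  sub <- dplyr::filter(match_table, .data$island %in% c(island_a, island_b))
  if (nrow(sub) == 0) stop("no rows for the requested islands", call. = FALSE)
  counts <- vapply(list(island_a, island_b), function(isl) {
    mi <- sub$matches_swarm[sub$island == isl]
    if (length(mi) == 0) stop("empty stratum for island ", isl, call. = FALSE)
    c(sum(mi), sum(!mi))
  }, numeric(2))
  m <- t(counts) # rows: islands; cols: match, mismatch
  dimnames(m) <- list(c(island_a, island_b), c("match", "mismatch"))
  res <- switch(method,
    lr = tryCatch(g_test(m), error = function(e) {
      # both islands matching perfectly: no evidence of a difference
      new_dis_assoc(0, 1L, 1, "LR_G", m, table_odds_ratio(m))
    }),
    fisher = fisher_irwin(m),
    n1chi2 = n_minus_1_chi2(m)
  )
  res
}

#' @export
print.dis_assoc <- function(x, ...) {
  label <- c(LR_G = "Likelihood-ratio G-test", PEARSON = "Pearson chi-square",
             N_MINUS_1 = "N-1 chi-square", FISHER = "Fisher-Irwin exact test")
  cat(label[[x$method]], "\n")
  if (!is.na(x$statistic)) {
    cat(sprintf("  chi2 = %.4g, df = %d, n = %d, p = %.4g\n",
                x$statistic, x$df, x$n, x$p_value))
  } else {
    cat(sprintf("  n = %d, p = %.4g (exact)\n", x$n, x$p_value))
  }
  if (!is.na(x$odds_ratio)) cat(sprintf("  odds ratio = %.4g\n", x$odds_ratio))
  invisible(x)
}

#' Tidy an association test result
#'
#' @param x A `dis_assoc` object.
#' @param ... Unused.
#' @return A one-row tibble with `statistic`, `df`, `p.value`, `method`,
#'   `odds.ratio`, `n`.
#' @method tidy dis_assoc
#' @export
tidy.dis_assoc <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, df = x$df, p.value = x$p_value,
                 method = x$method, odds.ratio = x$odds_ratio, n = x$n)
}

#' @rdname tidy.dis_assoc
#' @method glance dis_assoc
#' @export
glance.dis_assoc <- function(x, ...) tidy.dis_assoc(x)
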