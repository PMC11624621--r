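#' Rank candidate offspring by total expected realised load
#'
#' Lower total load means less inbreeding depression, so the most optimal
#' offspring is the minimum and the least optimal the maximum. Ties break
#' lexicographically by `cross_id`, making the ranking deterministic and
#' invariant to input order.
#'
#' @param totals Tibble with columns `cross_id` and `total` (e.g. from
#'   [cross_totals()]); at least one row.
#' @return Tibble `cross_id`, `total`, `rank` sorted ascending by load. The
#'   first row is the most optimal cross, the last the least optimal.
#' @export
rank_crosses <- function(totals) {
  stopifnot(all(c("cross_id", "total") %in% names(totals)))
  if (!nrow(totals)) stop("no crosses to rank")
  ord <- order(totals$total, totals$cross_id, method = "radix")
  out <- tibble::as_tibble(totals[ord, c("cross_id", "total")])
  out$rank <- seq_len(nrow(out))
  out
}

#' @rdname rank_crosses
#' @param ranking Output of `rank_crosses()`.
#' @export
most_optimal <- function(ranking) ranking$cross_id[1L]

#' @rdname rank_crosses
#' @export
least_optimal <- function(ranking) ranking$cross_id[nrow(ranking)]

#' Read survey responses from CSV
#'
#' Expects columns `respondent_id`, `most_optimal`, `least_optimal`.
#'
#' @param path CSV path.
#' @return Tibble of responses.
#' @export
read_responses <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("respondent_id", "most_optimal", "least_optimal")
  if (!all(need %in% names(tab))) {
    stop("response table needs columns: ", paste(need, collapse = ", "))
  }
  tibble::as_tibble(tab[need])
}

#' Score survey responses against the true ranking
#'
#' Tallies, for each presented offspring, how often it was chosen as most
#' and as least optimal, with percentages to one decimal place, and counts
#' the respondents who identified both extremes correctly. Responses naming
#' an offspring outside the presented set are rejected (not counted in `n`)
#' and reported.
#'
#' @param responses Tibble with `most_optimal` and `least_optimal` columns
#'   (labels of the presented offspring).
#' @param truth_most,truth_least Labels of the truly most and least optimal
#'   offspring; must differ.
#' @param options All presented offspring labels; defaults to the labels
#'   occurring in the truth and the responses.
#' @return A list of class `survey_summary`: `n`, `n_rejected`, `summary`
#'   (tibble: `option`, `n_most`, `pct_most`, `n_least`, `pct_least`),
#'   `n_most_correct`, `n_least_correct`, `n_both_correct`, `pct_both_correct`,
#'   and the truth labels.
#' @export
score_responses <- function(responses, truth_most, truth_least,
                            options = NULL) {
  stopifnot(all(c("most_optimal", "least_optimal") %in% names(responses)))
  if (identical(truth_most, truth_least)) {
    stop("truth must name distinct most- and least-optimal offspring")
  }
  if (is.null(options)) {
    options <- sort(unique(c(
      truth_most, truth_least,
      responses$most_optimal, responses$least_optimal
    )), method = "radix")
  }
  if (!all(c(truth_most, truth_least) %in% options)) {
    stop("truth labels must be among the presented options")
  }
  valid <- responses$most_optimal %in% options &
    responses$least_optimal %in% options
  n_rejected <- sum(!valid)
  responses <- responses[valid, ]
  n <- nrow(responses)
  pct <- function(x) if (n > 0L) round(100 * x / n, 1) else numeric(length(x))
  n_most <- vapply(options, function(o) sum(responses$most_optimal == o),
    integer(1), USE.NAMES = FALSE)
  n_least <- vapply(options, function(o) sum(responses$least_optimal == o),
    integer(1), USE.NAMES = FALSE)
  both <- responses$most_optimal == truth_most &
    responses$least_optimal == truth_least
  structure(
    list(
      n = n,
      n_rejected = n_rejected,
      summary = tibble::tibble(
        option = options,
        n_most = n_most, pct_most = pct(n_most),
        n_least = n_least, pct_least = pct(n_least)
      ),
      n_most_correct = sum(responses$most_optimal == truth_most),
      n_least_correct = sum(responses$least_optimal == truth_least),
      n_both_correct = sum(both),
      pct_both_correct = if (n > 0L) round(100 * sum(both) / n, 1) else NA_real_,
      truth_most = truth_most,
      truth_least = truth_least
    ),
    class = "survey_summary"
  )
}

#' @export
print.survey_summary <- function(x, ...) {
  cat("<survey_summary> n =", x$n)
  if (x$n_rejected) cat(" (", x$n_rejected, " rejected)", sep = "")
  cat("\n")
  print(x$summary)
  cat(
    "both extremes correct:", x$n_both_correct,
    if (!is.na(x$pct_both_correct)) paste0("(", x$pct_both_correct, "%)"),
    "\n"
  )
  invisible(x)
}

#' Exact upper-tail binomial probability
#'
#' `P(X >= x)` for `X ~ Binomial(n, pi0)`, the one-sided exact test of
#' whether `x` successes in `n` trials beat chance. Computed in log space via
#' the binomial CDF, so extreme tails (far below `1e-20`) do not underflow
#' to zero when `log = TRUE` is requested.
#'
#' With three candidate offspring, the chance of naming both the most and
#' the least optimal at random is `1/3 * 1/2 = 1/6` — the default null. For
#' `k` presented options the analogue is `1 / (k * (k - 1))`.
#'
#' @param x Number of successes, `0 <= x <= n`.
#' @param n Number of trials.
#' @param pi0 Null success probability in `(0, 1)`; default `1/6`.
#' @param log Return the natural log of the p-value.
#' @return The upper-tail probability (or its log).
#' @export
binomial_exact_upper <- function(x, n, pi0 = 1 / 6, log = FALSE) {
  if (length(x) != 1L || length(n) != 1L || is.na(x) || is.na(n) ||
    x < 0 || x > n || n < 1) {
    stop("need 0 <= x <= n with n >= 1")
  }
  if (length(pi0) != 1L || is.na(pi0) || pi0 <= 0 || pi0 >= 1) {
    stop("pi0 must lie strictly between 0 and 1")
  }
  # P(X >= x) = P(X > x - 1)
  stats::pbinom(x - 1, n, pi0, lower.tail = FALSE, log.p = log)
}

#' Null probability of guessing both extremes of k options
#'
#' @param k Number of presented offspring (>= 2).
#' @return `1 / (k * (k - 1))`.
#' @export
guess_both_prob <- function(k) {
  if (k < 2) stop("need at least two options")
  1 / (k * (k - 1))
}

#' Evaluate a survey against a ranking with the exact binomial test
#'
#' Scores the responses with [score_responses()] and tests whether the
#' count of respondents correct on both extremes beats the random-guessing
#' null with [binomial_exact_upper()].
#'
#' @inheritParams score_responses
#' @param pi0 Null probability; defaults to [guess_both_prob()] of the
#'   number of options.
#' @return The `survey_summary` with elements `pi0`, `p_value` and
#'   `log10_p_value` added.
#' @export
survey_test <- function(responses, truth_most, truth_least, options = NULL,
                        pi0 = NULL) {
  res <- score_responses(responses, truth_most, truth_least, options)
  if (is.null(pi0)) pi0 <- guess_both_prob(nrow(res$summary))
  res$pi0 <- pi0
  res$p_value <- binomial_exact_upper(res$n_both_correct, res$n, pi0)
  res$log10_p_value <-
    binomial_exact_upper(res$n_both_correct, res$n, pi0, log = TRUE) / log(10)
  res
}
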