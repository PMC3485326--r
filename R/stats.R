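# From counts to frequencies: binomial point estimates with score intervals,
# pure-sample error rates, and between-run comparison of error rates.

# Wilson score interval, vectorised.
.wilson <- function(x, n, level) {
  z <- qnorm(1 - (1 - level) / 2)
  p <- x / n
  denom <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  cbind(low = pmax(0, centre - half), high = pmin(1, centre + half))
}

# Clopper-Pearson (exact) interval via beta quantiles, vectorised.
.clopper_pearson <- function(x, n, level) {
  al <- 1 - level
  low <- ifelse(x == 0, 0, qbeta(al / 2, x, n - x + 1))
  high <- ifelse(x == n, 1, qbeta(1 - al / 2, x + 1, n - x))
  cbind(low = low, high = high)
}

#' Estimate an allele frequency from read counts
#'
#' Point estimate `n_allele / n_total` with a binomial confidence interval
#' (Wilson score by default; Clopper-Pearson as an option).  With
#' `n_total == 0` the estimate is absent and flagged.
#'
#' @param n_allele Reads assigned to the allele (vectorised).
#' @param n_total Total assigned reads (shared denominator).
#' @param ci_method `"wilson"` (default) or `"clopper-pearson"`.
#' @param level Confidence level (default 0.95).
#' @return Data frame with columns `n_allele`, `n_total`, `freq`, `ci_low`,
#'   `ci_high`, `estimable`.
#' @examples
#' estimate_frequency(1470, 147000)
#' @export
estimate_frequency <- function(n_allele, n_total,
                               ci_method = c("wilson", "clopper-pearson"),
                               level = 0.95) {
  ci_method <- match.arg(ci_method)
  stopifnot(level > 0, level < 1)
  k <- max(length(n_allele), length(n_total))
  n_allele <- rep_len(n_allele, k)
  n_total <- rep_len(n_total, k)
  if (any(n_allele < 0 | n_total < 0)) {
    stop("counts must be non-negative", call. = FALSE)
  }
  if (any(n_allele > n_total)) {
    stop("n_allele exceeds n_total", call. = FALSE)
  }
  est <- n_total > 0
  freq <- ifelse(est, n_allele / n_total, NA_real_)
  ci <- matrix(NA_real_, k, 2, dimnames = list(NULL, c("low", "high")))
  if (any(est)) {
    ci[est, ] <- switch(ci_method,
      "wilson" = .wilson(n_allele[est], n_total[est], level),
      "clopper-pearson" = .clopper_pearson(n_allele[est], n_total[est], level))
  }
  data.frame(n_allele = n_allele, n_total = n_total, freq = freq,
             ci_low = ci[, "low"], ci_high = ci[, "high"], estimable = est)
}

#' Frequency estimates for every (sample, locus, allele) of a count table
#'
#' The denominator per sample is the total of assigned reads at its locus,
#' so allele frequencies within a sample sum to 1 exactly.  If calibration
#' models are supplied, a `calibrated_freq` column is added per locus.
#'
#' @param x A `freq_counts` object (from [process_fastq()]) or a data frame
#'   with columns `sample_id`, `locus`, `allele`, `count`.
#' @param calibration Optional: a single `freq_calibration`, or a named list
#'   of them keyed by locus name (loci without a model pass through
#'   uncalibrated).
#' @param ci_method,level Passed to [estimate_frequency()].
#' @return Data frame with one row per (sample, locus, allele).
#' @export
estimate_frequencies <- function(x, calibration = NULL,
                                 ci_method = c("wilson", "clopper-pearson"),
                                 level = 0.95) {
  counts <- if (inherits(x, "freq_counts")) x$counts else x
  stopifnot(all(c("sample_id", "locus", "allele", "count") %in%
                  names(counts)))
  ci_method <- match.arg(ci_method)
  totals <- aggregate(count ~ sample_id, counts, sum)
  n_total <- totals$count[match(counts$sample_id, totals$sample_id)]
  est <- estimate_frequency(counts$count, n_total, ci_method, level)
  out <- cbind(counts[c("sample_id", "locus", "allele")], est)
  if (!is.null(calibration)) {
    if (inherits(calibration, "freq_calibration")) {
      models <- setNames(list(calibration),
                         if (is.null(calibration$locus)) unique(out$locus)[1]
                         else calibration$locus)
    } else {
      models <- calibration
    }
    out$calibrated_freq <- out$freq
    for (loc in intersect(names(models), out$locus)) {
      i <- out$locus == loc & !is.na(out$freq)
      out$calibrated_freq[i] <- as.numeric(
        apply_calibration(models[[loc]], out$freq[i]))
    }
  }
  rownames(out) <- NULL
  out
}

#' Pure-sample error rate
#'
#' For a control sample known to contain exactly one allele, the rate of
#' reads assigned to any *other* allele of its locus estimates the
#' sequencing/assignment error floor.  Only assigned reads enter the
#' denominator; discarded reads are excluded.
#'
#' @param counts A `freq_counts` or counts data frame (see
#'   [estimate_frequencies()]).
#' @param sample_id The pure sample.
#' @param true_allele The allele the sample actually contains.
#' @param run_id Optional run/date label carried into the result.
#' @return One-row data frame: `run_id`, `sample_id`, `locus`,
#'   `true_allele`, `discordant`, `total`, `rate`, `estimable`.
#' @examples
#' tab <- data.frame(sample_id = "P1", locus = "gshA",
#'                   allele = c("WT", "EVO"), count = c(9977, 23))
#' estimate_error_rate(tab, "P1", "WT")$rate # 0.0023
#' @export
estimate_error_rate <- function(counts, sample_id, true_allele,
                                run_id = NA_character_) {
  tab <- if (inherits(counts, "freq_counts")) counts$counts else counts
  rows <- tab[tab$sample_id == sample_id, , drop = FALSE]
  if (!nrow(rows)) stop("unknown sample: ", sample_id, call. = FALSE)
  if (!true_allele %in% rows$allele) {
    stop("sample ", sample_id, " has no allele ", true_allele, call. = FALSE)
  }
  total <- sum(rows$count)
  discordant <- sum(rows$count[rows$allele != true_allele])
  data.frame(run_id = run_id, sample_id = sample_id,
             locus = rows$locus[1], true_allele = true_allele,
             discordant = discordant, total = total,
             rate = if (total > 0) discordant / total else NA_real_,
             estimable = total > 0,
             stringsAsFactors = FALSE)
}

#' @rdname estimate_error_rate
#' @param rates Data frame of pooled [estimate_error_rate()] rows.
#' @return `summarize_error_rates`: list with the `median_rate` across
#'   estimable samples, `n_samples`, and the input `rates`.
#' @export
summarize_error_rates <- function(rates) {
  stopifnot(is.data.frame(rates), "rate" %in% names(rates))
  ok <- rates$estimable & !is.na(rates$rate)
  list(median_rate = if (any(ok)) median(rates$rate[ok]) else NA_real_,
       n_samples = sum(ok),
       rates = rates)
}

#' Compare error rates between sequencing runs
#'
#' Grouped-binomial logistic regression of the discordant proportion on run
#' identity, per locus: the run effect is judged by the deviance
#' (likelihood-ratio) test of `cbind(discordant, total - discordant) ~ run`
#' against the intercept-only model.  A run with zero (or saturated)
#' discordant counts would put the MLE on the boundary, so in that case a
#' Haldane-Anscombe continuity correction (+0.5 discordant, +1 total, every
#' run of that locus) is applied and flagged.
#'
#' @param runs Data frame with columns `run_id`, `discordant`, `total` and
#'   optionally `locus` (absent = single locus).
#' @return Object of class `freq_run_comparison`: data frame with one row
#'   per locus (`locus`, `deviance`, `df`, `p.value`, `corrected`).  No
#'   multiple-testing adjustment is applied across loci; p-values are
#'   per locus.
#' @export
compare_runs <- function(runs) {
  stopifnot(is.data.frame(runs),
            all(c("run_id", "discordant", "total") %in% names(runs)))
  if (is.null(runs$locus)) runs$locus <- "locus"
  if (any(runs$total <= 0)) stop("totals must be positive", call. = FALSE)
  if (any(runs$discordant < 0 | runs$discordant > runs$total)) {
    stop("discordant counts must lie in [0, total]", call. = FALSE)
  }
  res <- do.call(rbind, lapply(split(runs, runs$locus), function(g) {
    if (length(unique(g$run_id)) < 2L) {
      stop("need >= 2 runs per locus", call. = FALSE)
    }
    corrected <- any(g$discordant == 0 | g$discordant == g$total)
    d <- g$discordant
    n <- g$total
    if (corrected) {
      d <- d + 0.5
      n <- n + 1
    }
    quiet_glm <- function(...) {
      # the continuity correction makes counts non-integer on purpose
      withCallingHandlers(glm(...), warning = function(w) {
        if (grepl("non-integer", conditionMessage(w))) {
          invokeRestart("muffleWarning")
        }
      })
    }
    fit <- quiet_glm(cbind(d, n - d) ~ factor(g$run_id),
                     family = binomial())
    null <- quiet_glm(cbind(d, n - d) ~ 1, family = binomial())
    dev <- max(0, null$deviance - fit$deviance)
    df <- null$df.residual - fit$df.residual
    data.frame(locus = g$locus[1],
               deviance = dev,
               df = df,
               p.value = pchisq(dev, df, lower.tail = FALSE),
               corrected = corrected,
               stringsAsFactors = FALSE)
  }))
  rownames(res) <- NULL
  class(res) <- c("freq_run_comparison", "data.frame")
  res
}

#' @export
print.freq_run_comparison <- function(x, ...) {
  cat("Between-run comparison of error rates",
      "(logistic regression, deviance test; per-locus p-values,",
      "no multiplicity adjustment)\n")
  df <- as.data.frame(x)
  df$p.value <- format.pval(df$p.value, digits = 3)
  print(df, row.names = FALSE)
  if (any(x$corrected)) {
    cat("note: continuity correction (+0.5/+1) applied where a run had",
        "zero or saturated discordant counts\n")
  }
  invisible(x)
}

#' @importFrom stats binomial
NULL
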