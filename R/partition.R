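#' Fraction of the mother chain in the larger daughter
#'
#' Folds a division event onto `[0.5, 1]`: `x = max(a, b) / (a + b)`. The
#' mother chain (sum of both daughter measurements, length in nm or
#' magnetosome count) is 100 %; the folded fraction is symmetric in the two
#' daughters, so 0.5 is a perfect split and 1 means one daughter inherited
#' the whole chain.
#'
#' @param daughter_a,daughter_b nonnegative daughter-chain measurements
#'   (same unit). Vectorized.
#' @return Fractions in `[0.5, 1]`.
#' @export
#' @examples
#' fold_fraction(1400, 600) # 0.70
fold_fraction <- function(daughter_a, daughter_b) {
  if (any(daughter_a < 0) || any(daughter_b < 0))
    abort("daughter measurements must be nonnegative.")
  tot <- daughter_a + daughter_b
  if (any(tot == 0)) abort("daughter_a + daughter_b must be > 0 for every event.")
  pmax(daughter_a, daughter_b) / tot
}

#' Per-event folded fractions of a partition-event table
#'
#' @param events a data frame with columns `daughter_a` and `daughter_b`
#'   (and, typically, `event_id` and `measure_kind`), as produced by
#'   [gen_partition_events()] or [read_partition_events()].
#' @param exclude_whole_chain drop events where one daughter inherited the
#'   entire chain (`x = 1`), the sensitivity check for whole-chain
#'   inheritance.
#' @param equal_max,unequal_min bucket boundaries passed to
#'   [classify_partition()].
#' @return The input tibble with columns `fraction` and `bucket` appended.
#' @export
partition_fractions <- function(events, exclude_whole_chain = FALSE,
                                equal_max = 0.60, unequal_min = 0.70) {
  need <- c("daughter_a", "daughter_b")
  miss <- setdiff(need, names(events))
  if (length(miss) > 0)
    abort(paste0("events table lacks column(s): ", paste(miss, collapse = ", ")))
  out <- as_tibble(events)
  out$fraction <- fold_fraction(out$daughter_a, out$daughter_b)
  if (exclude_whole_chain) out <- dplyr::filter(out, .data$fraction < 1)
  out$bucket <- classify_partition(out$fraction, equal_max, unequal_min)
  out
}

#' Empirical cumulative distribution of folded fractions
#'
#' @param xs folded fractions.
#' @return A tibble of the right-continuous step function: sorted unique `x`
#'   and cumulative height `F` = (number of observations `<= x`) / n, so tied
#'   values stack.
#' @export
#' @examples
#' partition_ecdf(c(0.58, 0.72, 0.95))
partition_ecdf <- function(xs) {
  if (length(xs) < 1) abort("need at least one observation.")
  tab <- table(sort(xs))
  tibble(x = as.numeric(names(tab)),
         F = cumsum(as.numeric(tab)) / length(xs))
}

#' Fit the exponential-suppression partition model
#'
#' Least-squares fit of the cumulative model
#' `F(x) = 1 - exp(-(x - 0.5)/lambda)` to the empirical distribution of folded
#' fractions, using midpoint plotting heights `(i - 0.5)/n` at the sorted
#' observations to reduce small-n bias. `lambda` measures the accuracy with
#' which cleavage finds the chain centre, as a fraction of chain length;
#' the model median is `0.5 + lambda * ln 2` exactly. The closed-form
#' maximum-likelihood estimate `lambda_mle = mean(x) - 0.5` is reported
#' alongside as a cross-check.
#'
#' Goodness of fit is reported both as the Pearson correlation `fit_R`
#' between model and empirical heights and as `r_squared` of the residuals,
#' since published "R" values are ambiguous between the two.
#'
#' @param xs folded fractions in `[0.5, 1]`, n >= 5.
#' @return A `partition_fit` object: `lambda`, `lambda_se`, `lambda_mle`,
#'   `median`, `fit_R`, `r_squared`, `n`, `degenerate` flag and `fit_method`
#'   label. Has [tidy()], [glance()] and [autoplot()] methods.
#' @export
#' @examples
#' set.seed(1)
#' x <- 0.5 + stats::rexp(200, rate = 1 / 0.061)
#' fit <- fit_partition_cdf(x[x <= 1])
#' glance(fit)
fit_partition_cdf <- function(xs) {
  if (length(xs) < 5) abort("need at least 5 events to fit the partition model.")
  if (any(xs < 0.5 | xs > 1)) abort("all fractions must lie in [0.5, 1].")
  n <- length(xs)
  x <- sort(xs)
  h <- (seq_len(n) - 0.5) / n
  lambda_mle <- mean(x) - 0.5

  if (all(x == 0.5)) {
    fit <- list(lambda = 0, lambda_se = NA_real_, lambda_mle = 0,
                median = 0.5, fit_R = NA_real_, r_squared = NA_real_,
                n = n, degenerate = TRUE,
                fit_method = "degenerate (all fractions 0.5)")
    return(structure(fit, class = "partition_fit", x = x, h = h))
  }

  df <- tibble(x = x, h = h)
  mod <- minpack.lm::nlsLM(
    h ~ 1 - exp(-(x - 0.5) / lambda),
    data = df,
    start = list(lambda = max(lambda_mle, 1e-4)),
    lower = 1e-8, upper = 10,
    control = minpack.lm::nls.lm.control(maxiter = 200))
  lambda <- unname(coef(mod)[["lambda"]])
  pred <- 1 - exp(-(x - 0.5) / lambda)
  fit <- list(
    lambda = lambda,
    lambda_se = sqrt(diag(vcov(mod)))[["lambda"]],
    lambda_mle = lambda_mle,
    median = partition_median(lambda),
    fit_R = cor(pred, h),
    r_squared = 1 - sum((h - pred)^2) / sum((h - mean(h))^2),
    n = n,
    degenerate = FALSE,
    fit_method = "nonlinear least squares on ECDF midpoint heights")
  structure(fit, class = "partition_fit", x = x, h = h)
}

#' Median of the exponential-suppression partition model
#'
#' Solves `F(x) = 0.5` for `F(x) = 1 - exp(-(x - 0.5)/lambda)`:
#' the median is `0.5 + lambda * ln 2` exactly. Its distance from 0.5 is the
#' typical deviation from perfectly equal partitioning.
#'
#' @param lambda accuracy parameter, fraction of chain length, `>= 0`.
#' @return The model median, a fraction in `[0.5, 1)`. Vectorized.
#' @export
#' @examples
#' partition_median(0.061) # 0.542...
partition_median <- function(lambda) {
  if (any(lambda < 0)) abort("`lambda` must be >= 0.")
  0.5 + lambda * log(2)
}

#' Kolmogorov-Smirnov test against the random-splitting null
#'
#' One-sample KS test of folded fractions against Uniform(0.5, 1), the folded
#' distribution obtained by cleaving a chain at a uniformly random position
#' (a linear cumulative distribution). The p-value comes from
#' [stats::ks.test()]: exact (Marsaglia-Tsang-Wang) for n < 100 without ties,
#' asymptotic Kolmogorov otherwise.
#'
#' @param xs folded fractions in `[0.5, 1]`.
#' @return A list: `D` (sup-distance between the ECDF and the null CDF),
#'   `p_value`, `n`, `method`.
#' @export
#' @examples
#' ks_test_uniform(c(0.58, 0.72, 0.95))$D # 0.2333
ks_test_uniform <- function(xs) {
  if (length(xs) < 1) abort("need at least one observation.")
  if (any(xs < 0.5 | xs > 1)) abort("all fractions must lie in [0.5, 1].")
  kt <- suppressWarnings(stats::ks.test(xs, stats::punif, min = 0.5, max = 1))
  list(D = unname(kt$statistic), p_value = kt$p.value,
       n = length(xs), method = kt$method)
}

#' Classify a folded fraction into partitioning buckets
#'
#' `equal`: within 10 % fluctuation of a perfect split (`x <= equal_max`);
#' `unequal`: a 70/30 to 100/0 split (`x >= unequal_min`); `intermediate`
#' otherwise. Both boundaries are inclusive and configurable.
#'
#' @param x folded fractions in `[0.5, 1]`. Vectorized.
#' @param equal_max,unequal_min bucket boundaries.
#' @return A factor with levels `equal`, `intermediate`, `unequal`.
#' @export
classify_partition <- function(x, equal_max = 0.60, unequal_min = 0.70) {
  if (any(x < 0.5 | x > 1)) abort("all fractions must lie in [0.5, 1].")
  out <- ifelse(x <= equal_max, "equal",
                ifelse(x >= unequal_min, "unequal", "intermediate"))
  factor(out, levels = c("equal", "intermediate", "unequal"))
}

#' Score intracellular chain position
#'
#' Assigns a chain to the `Pole` (< 400 nm from the nearest cell pole or
#' constriction site), `Adjacent` (400-800 nm) or `Midcell` (> 800 nm) zone.
#' The anchor is the chain's outermost magnetosome closest to the nearest
#' pole/constriction, i.e. `near_nm`. An anchor in the Adjacent band is only
#' scored `Adjacent` if at least `min_fraction` (51 %) of the chain's length
#' lies within the 400-800 nm band; otherwise the chain is `Midcell`.
#'
#' @param near_nm,far_nm chain extent: distances (nm) of the chain's nearest
#'   and farthest points from the nearest pole/constriction; `near_nm <=
#'   far_nm`. Vectorized.
#' @param pole_zone,adjacent_zone zone boundaries, nm.
#' @param min_fraction minimal length fraction in the Adjacent band.
#' @return A factor with levels `Pole`, `Adjacent`, `Midcell`.
#' @export
#' @examples
#' classify_chain_position(500, 780)  # Adjacent (chain fully in band)
#' classify_chain_position(600, 1600) # Midcell  (only 20 % in band)
classify_chain_position <- function(near_nm, far_nm,
                                    pole_zone = 400, adjacent_zone = 800,
                                    min_fraction = 0.51) {
  if (any(is.na(near_nm)) || any(is.na(far_nm)))
    abort("landmark distances must not be missing.")
  if (any(near_nm > far_nm)) abort("`near_nm` must be <= `far_nm`.")
  if (any(near_nm < 0)) abort("landmark distances must be nonnegative.")
  len <- far_nm - near_nm
  in_band <- pmax(0, pmin(far_nm, adjacent_zone) - pmax(near_nm, pole_zone))
  frac <- ifelse(len > 0, in_band / len,
                 as.numeric(near_nm >= pole_zone & near_nm < adjacent_zone))
  out <- ifelse(near_nm < pole_zone, "Pole",
         ifelse(near_nm < adjacent_zone,
                ifelse(frac >= min_fraction, "Adjacent", "Midcell"),
                "Midcell"))
  factor(out, levels = c("Pole", "Adjacent", "Midcell"))
}

#' Full partitioning report for an event table
#'
#' Runs the whole partition-statistics stage: folded fractions, bucket
#' counts, exponential-suppression model fit and KS test against the
#' random-splitting null.
#'
#' @inheritParams partition_fractions
#' @return A list of class `partition_report`: `fractions` (per-event tibble),
#'   `fit` ([fit_partition_cdf()] result), `ks` ([ks_test_uniform()] result)
#'   and `bucket_counts`.
#' @seealso [write_report()]
#' @export
partition_report <- function(events, exclude_whole_chain = FALSE,
                             equal_max = 0.60, unequal_min = 0.70) {
  fr <- partition_fractions(events, exclude_whole_chain, equal_max, unequal_min)
  structure(list(
    fractions = fr,
    fit = fit_partition_cdf(fr$fraction),
    ks = ks_test_uniform(fr$fraction),
    bucket_counts = table(fr$bucket)
  ), class = "partition_report")
}

#' @export
print.partition_fit <- function(x, ...) {
  cat(sprintf(
    "<partition_fit> n = %d\n  lambda = %.4f (SE %.4f; MLE %.4f)\n  median = %.4f (%.1f%% deviation from equal split)\n  fit R = %.4f, R^2 = %.4f\n",
    x$n, x$lambda, x$lambda_se, x$lambda_mle, x$median,
    100 * (x$median - 0.5), x$fit_R, x$r_squared))
  invisible(x)
}

#' @export
print.partition_report <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  KS vs random splitting: D = %.4f, p = %.3g\n", x$ks$D, x$ks$p_value))
  cat("  buckets:", paste(names(x$bucket_counts), as.integer(x$bucket_counts),
                          sep = "=", collapse = ", "), "\n")
  invisible(x)
}
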