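#' Permutation test configuration
#'
#' @param n_permutations number of label permutations (default 1000, the
#'   standard choice for group-level covariance network comparisons; at
#'   least 100 for reportable p-values).
#' @param seed integer seed driving the permutation stream.
#' @param alpha significance level applied to adjusted p-values.
#' @param ci_level coverage of the percentile interval of the null
#'   difference distribution.
#' @return An object of class `permutation_config`.
#' @export
permutation_config <- function(n_permutations = 1000L, seed = 1L,
                               alpha = 0.05, ci_level = 0.95) {
  n_permutations <- as.integer(n_permutations)
  if (n_permutations < 100L)
    warning("fewer than 100 permutations; p-values will be coarse")
  if (ci_level <= 0 || ci_level >= 1) stop("ci_level must lie in (0, 1)")
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  structure(list(n_permutations = n_permutations, seed = as.integer(seed),
                 alpha = alpha, ci_level = ci_level),
            class = "permutation_config")
}

# Measures of one pseudo-group, fast path (no warnings, no objects).
group_measures_fast <- function(vols, age, sex, conv = 0L) {
  res <- residualize_matrix(vols, age, sex, warn = FALSE)
  w <- correlation_weights(res, warn = FALSE)
  measures_from_weights(w, conv)
}

#' Null distribution of between-group measure differences
#'
#' Pools the subjects of both (single-group) cohorts and, for each
#' permutation, randomly relabels them into pseudo-groups of the original
#' sizes, then reruns the full pipeline (residualize within pseudo-group,
#' build the covariance network, compute all measures) and records the
#' pseudo-difference (pseudo-b minus pseudo-a) for every measure.
#' Residualization is redone within each pseudo-group: the statistic is
#' recomputed under relabeling exactly as it was observed. Permutations
#' whose pseudo-groups violate the residualization preconditions (constant
#' age) are redrawn, up to `10 * n_permutations` attempts.
#'
#' @param cohort_a,cohort_b single-group [cohort()]s sharing a region set.
#' @param config a [permutation_config()].
#' @param convention weight-to-length mapping, see [net_distances()].
#' @return `n_permutations` x 7 matrix of null differences, with
#'   attributes `measures` and `redraws`.
#' @export
permutation_null <- function(cohort_a, cohort_b,
                             config = permutation_config(),
                             convention = "inverse") {
  stopifnot(inherits(cohort_a, "cohort"), inherits(cohort_b, "cohort"),
            inherits(config, "permutation_config"))
  if (!identical(cohort_a$region_set$regions, cohort_b$region_set$regions))
    stop("cohorts must share the same region set")
  conv <- conv_code(convention)
  na <- nrow(cohort_a$subjects)
  nb <- nrow(cohort_b$subjects)
  vols <- rbind(cohort_a$volumes, cohort_b$volumes)
  age <- c(cohort_a$subjects$age, cohort_b$subjects$age)
  sex <- c(cohort_a$subjects$sex, cohort_b$subjects$sex)
  n <- na + nb
  set.seed(config$seed)
  nperm <- config$n_permutations
  null <- matrix(NA_real_, nperm, length(.measure_names),
                 dimnames = list(NULL, .measure_names))
  redraws <- 0L
  max_attempts <- 10L * nperm
  attempts <- 0L
  p <- 1L
  while (p <= nperm) {
    attempts <- attempts + 1L
    if (attempts > max_attempts)
      stop("exceeded ", max_attempts,
           " permutation attempts without valid pseudo-groups")
    ia <- sample.int(n, na)
    in_a <- logical(n); in_a[ia] <- TRUE
    if (var(age[in_a]) == 0 || var(age[!in_a]) == 0) {
      redraws <- redraws + 1L
      next
    }
    ma <- group_measures_fast(vols[in_a, , drop = FALSE], age[in_a],
                              sex[in_a], conv)
    mb <- group_measures_fast(vols[!in_a, , drop = FALSE], age[!in_a],
                              sex[!in_a], conv)
    null[p, ] <- mb - ma
    p <- p + 1L
  }
  if (redraws > 0)
    message(redraws, " degenerate permutation(s) redrawn")
  attr(null, "measures") <- .measure_names
  attr(null, "redraws") <- redraws
  null
}

#' Two-sided permutation p-value
#'
#' Uses the add-one estimator `p = (#{|null| >= |observed|} + 1) / (n + 1)`,
#' which never returns exactly 0. Non-finite null values (e.g. undefined
#' assortativity in a degenerate permutation) are dropped from the count;
#' an undefined observed difference gives `NA`.
#'
#' @param observed_diff observed between-group difference.
#' @param null_diffs numeric vector of null differences.
#' @return A p-value in `(0, 1]`.
#' @export
permutation_pvalue <- function(observed_diff, null_diffs) {
  if (is.na(observed_diff)) return(NA_real_)
  null_diffs <- null_diffs[is.finite(null_diffs)]
  if (length(null_diffs) == 0L) stop("empty null distribution")
  (sum(abs(null_diffs) >= abs(observed_diff)) + 1) /
    (length(null_diffs) + 1)
}

#' Percentile interval of the null difference distribution
#'
#' Returns the central `ci_level` percentile interval of the permutation
#' null distribution of differences. Note this is an interval of the
#' *null* distribution (what difference magnitudes label shuffling alone
#' produces), not a bootstrap interval around the observed estimate — it
#' need not bracket the observed difference.
#'
#' @param null_diffs numeric vector of null differences (>= 40 values for
#'   a 95% interval).
#' @param ci_level coverage in (0, 1).
#' @return Named numeric `c(ci_lower, ci_upper)`.
#' @export
permutation_ci <- function(null_diffs, ci_level = 0.95) {
  if (ci_level <= 0 || ci_level >= 1) stop("ci_level must lie in (0, 1)")
  null_diffs <- null_diffs[is.finite(null_diffs)]
  need <- ceiling(2 / (1 - ci_level))
  if (length(null_diffs) < need)
    stop("need at least ", need, " finite null values for a ",
         ci_level * 100, "% interval")
  q <- quantile(null_diffs, c((1 - ci_level) / 2, 1 - (1 - ci_level) / 2),
                names = FALSE)
  c(ci_lower = q[1], ci_upper = q[2])
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Standard step-up adjustment: with `p_(1) <= ... <= p_(m)`,
#' `q_(i) = min_{j >= i} (m / j) p_(j)`, capped at 1, returned in input
#' order. `NA` entries pass through and do not count toward `m`.
#'
#' @param p_values numeric vector of raw p-values in `(0, 1]`.
#' @return Adjusted p-values, same length and order.
#' @examples
#' fdr_bh(c(0.051, 0.024, 0.004, 0.019, 0.043, 0.040))
#' @export
fdr_bh <- function(p_values) {
  p <- as.numeric(p_values)
  ok <- !is.na(p)
  if (any(p[ok] <= 0 | p[ok] > 1))
    stop("p-values must lie in (0, 1]")
  out <- rep(NA_real_, length(p))
  pp <- p[ok]
  m <- length(pp)
  if (m > 0) {
    o <- order(pp)
    q <- pp[o] * m / seq_len(m)
    q <- rev(cummin(rev(q)))
    q <- pmin(q, 1)
    adj <- numeric(m)
    adj[o] <- q
    out[ok] <- adj
  }
  out
}

#' Compare two groups' covariance networks
#'
#' The full group-inference procedure: observed measures from each
#' cohort's covariance network, observed differences (b minus a), a
#' permutation null distribution via [permutation_null()], two-sided
#' permutation p-values, percentile intervals of the null, and
#' Benjamini-Hochberg adjustment across the measure family of this one
#' network comparison.
#'
#' @inheritParams permutation_null
#' @param include_average_degree include average degree in the measure
#'   family (7 measures) or drop it (6 measures).
#' @param keep_null attach the null matrix as attribute `"null"`.
#' @return data.frame of class `network_comparison` with columns
#'   `measure`, `group_a`, `group_b`, `difference`, `ci_lower`,
#'   `ci_upper`, `p_value`, `adjusted_p_value`, `significant`.
#' @export
compare_groups <- function(cohort_a, cohort_b,
                           config = permutation_config(),
                           convention = "inverse",
                           include_average_degree = TRUE,
                           keep_null = FALSE) {
  conv <- conv_code(convention)
  ga <- cohort_groups(cohort_a)
  gb <- cohort_groups(cohort_b)
  if (length(ga) != 1L || length(gb) != 1L)
    stop("each cohort must contain exactly one group; use cohort_subset()")
  obs_a <- group_measures_fast(cohort_a$volumes, cohort_a$subjects$age,
                               cohort_a$subjects$sex, conv)
  obs_b <- group_measures_fast(cohort_b$volumes, cohort_b$subjects$age,
                               cohort_b$subjects$sex, conv)
  null <- permutation_null(cohort_a, cohort_b, config, convention)
  keep <- .measure_names
  if (!include_average_degree) keep <- setdiff(keep, "average_degree")
  diff <- (obs_b - obs_a)[keep]
  # Measures can be undefined for some permutations (assortativity on a
  # regular pseudo-network); if too few finite null values remain, the
  # p-value / CI are reported as NA instead of aborting the comparison.
  p_raw <- vapply(keep, function(m)
    tryCatch(permutation_pvalue(diff[[m]], null[, m]),
             error = function(e) NA_real_), numeric(1))
  ci <- t(vapply(keep, function(m)
    tryCatch(permutation_ci(null[, m], config$ci_level),
             error = function(e) c(ci_lower = NA_real_,
                                   ci_upper = NA_real_)),
    numeric(2)))
  p_adj <- fdr_bh(p_raw)
  out <- data.frame(measure = keep,
                    group_a = unname(obs_a[keep]),
                    group_b = unname(obs_b[keep]),
                    difference = unname(diff),
                    ci_lower = ci[, 1], ci_upper = ci[, 2],
                    p_value = unname(p_raw),
                    adjusted_p_value = p_adj,
                    significant = !is.na(p_adj) & p_adj < config$alpha,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "groups") <- c(a = ga, b = gb)
  attr(out, "config") <- config
  if (keep_null) attr(out, "null") <- null
  class(out) <- c("network_comparison", "data.frame")
  out
}

#' Write a comparison table as delimited text
#'
#' One file per (network, comparison), mirroring the usual published
#' layout: measure, per-group values, difference, CI bounds, raw and
#' adjusted p-values, significance flag.
#'
#' @param x a `network_comparison` data.frame.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_comparison <- function(x, path) {
  write.table(format_df_full(as.data.frame(x)), path, sep = "\t",
              row.names = FALSE, quote = FALSE)
  invisible(path)
}
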