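#' Correlation templates for synthetic cohorts
#'
#' Builds a symmetric, unit-diagonal, positive semi-definite correlation
#' matrix in one of three styles:
#'
#' * `"uniform"`: compound symmetry — every off-diagonal equals `strength`.
#' * `"modular"`: `n_blocks` contiguous blocks, as equal in size as
#'   possible; within-block correlation `strength`, between-block
#'   `strength / 4`. Constructed as a non-negative combination of the
#'   identity, the all-ones matrix and a block-diagonal of all-ones blocks,
#'   so it is PSD by construction.
#' * `"smallworld-like"`: ring lattice in which each region is correlated
#'   at `strength` with its `neighbors` nearest ring neighbors on each
#'   side, projected to the nearest PSD matrix (eigenvalues clipped at 0)
#'   and re-normalized to unit diagonal.
#'
#' @param n_regions number of regions (>= 3).
#' @param style `"uniform"`, `"modular"` or `"smallworld-like"`.
#' @param strength target correlation in `[0, 1)`.
#' @param seed unused for these deterministic styles; kept so that template
#'   construction has the same signature as the stochastic generator.
#' @param n_blocks number of blocks for `"modular"` (default 2).
#' @param neighbors ring radius for `"smallworld-like"` (default 2).
#' @return An `n_regions` x `n_regions` correlation matrix.
#' @examples
#' correlation_template(4, "uniform", 0.5)
#' @export
correlation_template <- function(n_regions,
                                 style = c("uniform", "modular",
                                           "smallworld-like"),
                                 strength = 0.5, seed = NULL,
                                 n_blocks = 2L, neighbors = 2L) {
  style <- match.arg(style)
  n <- as.integer(n_regions)
  if (n < 3L) stop("n_regions must be >= 3")
  if (!is.finite(strength) || strength < 0 || strength >= 1)
    stop("strength must lie in [0, 1)")
  s <- strength
  m <- switch(style,
    "uniform" = (1 - s) * diag(n) + s,
    "modular" = {
      sizes <- diff(floor(seq(0, n, length.out = n_blocks + 1)))
      member <- rep(seq_len(n_blocks), times = sizes)
      same <- outer(member, member, "==")
      (1 - s) * diag(n) + (s / 4) + (3 * s / 4) * same
    },
    "smallworld-like" = {
      ring <- pmin(abs(outer(seq_len(n), seq_len(n), "-")),
                   n - abs(outer(seq_len(n), seq_len(n), "-")))
      m0 <- ifelse(ring >= 1 & ring <= neighbors, s, 0)
      diag(m0) <- 1
      psd_project(m0)
    })
  m <- (m + t(m)) / 2
  diag(m) <- 1
  ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-10)
    stop("internal error: template is not positive semi-definite")
  dimnames(m) <- NULL
  m
}

# Nearest-PSD projection: clip eigenvalues at 0, then rescale to unit
# diagonal (a congruence transform, so PSD is preserved).
psd_project <- function(m) {
  e <- eigen((m + t(m)) / 2, symmetric = TRUE)
  m2 <- e$vectors %*% (pmax(e$values, 0) * t(e$vectors))
  d <- sqrt(diag(m2))
  if (any(d <= 0)) stop("PSD projection produced a zero-variance region")
  m2 <- m2 / outer(d, d)
  m2 <- (m2 + t(m2)) / 2
  diag(m2) <- 1
  m2
}

#' Specify a synthetic cohort
#'
#' The generative model matches the statistical structure the covariance
#' network method assumes: for subject `s` in group `g`,
#' \deqn{v_s = \mu + \beta_{age}(age_s - \bar a) + \beta_{sex} sex_s +
#'       \sigma \odot z_s, \quad z_s \sim N(0, R_g),}
#' with `R_g` the group's target correlation matrix. Ages are normal
#' (truncated to `[40, 95]` by resampling) and sex is Bernoulli. Default
#' demographics mirror a typical late-onset dementia cohort: age 69.9 +/-
#' 11.9 years, 47% male.
#'
#' @param group_sizes named integer vector, group label -> subject count.
#' @param regions a [region_set()], a character vector of labels, or an
#'   integer region count (labels `R1..Rn` are invented).
#' @param mean_volumes mean volume per region, mm^3 (recycled).
#' @param age_effect volume change per year of age, mm^3/year (recycled).
#' @param sex_effect male-minus-female volume offset, mm^3 (recycled).
#' @param target_correlation one correlation matrix used for every group,
#'   or a named list with one matrix per group.
#' @param noise_sd residual standard deviation per region, mm^3 (> 0,
#'   recycled).
#' @param age_mean,age_sd age distribution in years.
#' @param sex_balance proportion of males in `[0, 1]`.
#' @param seed integer seed; identical specs give identical cohorts.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(group_sizes, regions,
                           mean_volumes = 5000, age_effect = -15,
                           sex_effect = 300,
                           target_correlation = NULL,
                           noise_sd = 500,
                           age_mean = 69.9, age_sd = 11.9,
                           sex_balance = 0.47, seed = 1L) {
  if (is.null(names(group_sizes)) || any(names(group_sizes) == ""))
    stop("group_sizes must be a named vector (group label -> count)")
  if (any(group_sizes < 1)) stop("group sizes must be positive")
  if (inherits(regions, "region_set")) {
    rs <- regions
  } else if (is.character(regions)) {
    rs <- region_set(regions, name = "synthetic")
  } else {
    rs <- region_set(paste0("R", seq_len(as.integer(regions))),
                     name = "synthetic")
  }
  p <- length(rs)
  if (is.null(target_correlation)) target_correlation <- diag(p)
  if (is.matrix(target_correlation)) {
    target_correlation <- stats::setNames(
      rep(list(target_correlation), length(group_sizes)), names(group_sizes))
  }
  missing <- setdiff(names(group_sizes), names(target_correlation))
  if (length(missing) > 0)
    stop("no target_correlation entry for group(s): ",
         paste(missing, collapse = ", "))
  for (g in names(group_sizes)) {
    m <- target_correlation[[g]]
    if (!is.matrix(m) || nrow(m) != p || ncol(m) != p)
      stop("target_correlation for group '", g, "' must be ", p, " x ", p)
    if (max(abs(m - t(m))) > 1e-8 || max(abs(diag(m) - 1)) > 1e-8)
      stop("target_correlation for group '", g,
           "' must be symmetric with unit diagonal")
    ev <- eigen((m + t(m)) / 2, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-8)
      stop("target_correlation for group '", g,
           "' is not positive semi-definite")
  }
  rec <- function(x) {
    x <- rep_len(as.numeric(x), p)
    x
  }
  noise_sd <- rec(noise_sd)
  if (any(noise_sd <= 0)) stop("noise_sd must be strictly positive")
  if (sex_balance < 0 || sex_balance > 1)
    stop("sex_balance must lie in [0, 1]")
  structure(list(group_sizes = group_sizes, region_set = rs,
                 mean_volumes = rec(mean_volumes),
                 age_effect = rec(age_effect),
                 sex_effect = rec(sex_effect),
                 target_correlation = target_correlation,
                 noise_sd = noise_sd,
                 age_mean = age_mean, age_sd = age_sd,
                 sex_balance = sex_balance,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' @export
print.synthetic_spec <- function(x, ...) {
  cat("<synthetic_spec: ", length(x$region_set), " regions; groups ",
      paste(names(x$group_sizes), x$group_sizes, sep = "=", collapse = ", "),
      "; seed ", x$seed, ">\n", sep = "")
  invisible(x)
}

# Normal draws truncated to [lo, hi] by resampling.
truncated_normal <- function(n, mean, sd, lo = 40, hi = 95) {
  x <- rnorm(n, mean, sd)
  bad <- which(x < lo | x > hi)
  while (length(bad) > 0) {
    x[bad] <- rnorm(length(bad), mean, sd)
    bad <- bad[x[bad] < lo | x[bad] > hi]
  }
  x
}

# Factor A with A %*% t(A) = R, valid for any PSD R (eigen form, so
# rank-deficient targets are handled too).
correlation_factor <- function(r) {
  e <- eigen((r + t(r)) / 2, symmetric = TRUE)
  e$vectors %*% diag(sqrt(pmax(e$values, 0)), nrow(r))
}

#' Generate a synthetic cohort
#'
#' Draws a [cohort()] from a [synthetic_spec()]: covariates first (age
#' truncated-normal, sex Bernoulli), then correlated Gaussian region noise
#' with the group's target correlation, then the linear covariate effects.
#' Identical specs (including `seed`) produce identical cohorts.
#'
#' @param spec a [synthetic_spec()].
#' @return A [cohort()].
#' @examples
#' sp <- synthetic_spec(c(a = 10, b = 12), regions = 4, seed = 7)
#' generate_cohort(sp)
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  p <- length(spec$region_set)
  ids <- character(0); grp <- character(0)
  age <- numeric(0); sex <- integer(0)
  vols <- matrix(numeric(0), 0, p)
  for (g in names(spec$group_sizes)) {
    n <- spec$group_sizes[[g]]
    a <- truncated_normal(n, spec$age_mean, spec$age_sd)
    s <- rbinom(n, 1, spec$sex_balance)
    fac <- correlation_factor(spec$target_correlation[[g]])
    z <- matrix(rnorm(n * p), n, p) %*% t(fac)
    v <- matrix(spec$mean_volumes, n, p, byrow = TRUE) +
      outer(a - spec$age_mean, spec$age_effect) +
      outer(as.numeric(s), spec$sex_effect) +
      z * matrix(spec$noise_sd, n, p, byrow = TRUE)
    if (any(v <= 0)) {
      # volumes must stay physical; clip at a tiny positive floor
      v[v <= 0] <- 1e-6
      warning("group '", g, "': ", sum(v == 1e-6),
              " generated volume(s) clipped to a positive floor")
    }
    ids <- c(ids, sprintf("%s_%03d", g, seq_len(n)))
    grp <- c(grp, rep(g, n))
    age <- c(age, a); sex <- c(sex, s)
    vols <- rbind(vols, v)
  }
  cohort(ids, grp, age, sex, vols, spec$region_set)
}
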