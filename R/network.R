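#' Residualize regional volumes on age and sex
#'
#' Removes linear age and sex effects from each region's volumes by
#' ordinary least squares on the design `[1, age, sex]`, within a single
#' group. If sex is constant in the group it is dropped from the design
#' with a warning; constant age is an error (it would be collinear with
#' the intercept). The residuals are what the covariance network
#' correlates, so that edges reflect covariate-adjusted covariance only.
#'
#' @param x a [cohort()] containing a single group, or a multi-group
#'   cohort together with `group`.
#' @param group group label to restrict to (required if `x` has several).
#' @return An object of class `residual_matrix`: list with `values`
#'   (subjects x regions residuals), `region_set`, `group`, `n_subjects`.
#' @export
residualize <- function(x, group = NULL) {
  stopifnot(inherits(x, "cohort"))
  if (!is.null(group)) x <- cohort_subset(x, group = group)
  grps <- cohort_groups(x)
  if (length(grps) != 1L)
    stop("cohort contains several groups (",
         paste(grps, collapse = ", "), "); pass 'group' to pick one")
  n <- nrow(x$subjects)
  if (n < 4L)
    stop("residualization needs at least 4 subjects per group; group '",
         grps, "' has ", n)
  if (var(x$subjects$age) == 0)
    stop("age is constant in group '", grps,
         "'; it is collinear with the intercept")
  res <- residualize_matrix(x$volumes, x$subjects$age, x$subjects$sex,
                            region_labels = x$region_set$regions)
  structure(list(values = res, region_set = x$region_set,
                 group = grps, n_subjects = n),
            class = "residual_matrix")
}

# Core OLS residual computation shared by the public path and the
# permutation engine. QR-based, exact least squares.
residualize_matrix <- function(vols, age, sex, region_labels = NULL,
                               warn = TRUE) {
  if (var(sex) == 0) {
    if (warn)
      warning("sex is constant; dropping it from the residualization design")
    X <- cbind(1, age)
  } else {
    X <- cbind(1, age, sex)
  }
  if (nrow(vols) < ncol(X) + 1L)
    stop("need more subjects (", nrow(vols), ") than design columns (",
         ncol(X), ") plus one")
  res <- qr.resid(qr(X), vols)
  zero <- which(apply(vols, 2, var) == 0)
  if (length(zero) > 0) {
    res[, zero] <- 0
    if (warn)
      warning("zero-variance volume column(s): ",
              paste(if (is.null(region_labels)) zero
                    else region_labels[zero], collapse = ", "),
              "; residuals set to zero")
  }
  res
}

#' @export
print.residual_matrix <- function(x, ...) {
  cat("<residual_matrix: group '", x$group, "', ", x$n_subjects,
      " subjects x ", length(x$region_set), " regions>\n", sep = "")
  invisible(x)
}

#' Build a weighted covariance network from residual volumes
#'
#' Edge weights are Pearson correlations of residual volumes across
#' subjects, with negative coefficients set to zero and the diagonal set
#' to zero. The result is the group-level structural covariance network:
#' it exists per group, not per subject.
#'
#' @param residuals a `residual_matrix` from [residualize()].
#' @return An object of class `connectivity`: list with `weights`
#'   (regions x regions, symmetric, entries in `[0, 1]`, zero diagonal),
#'   `region_set`, `group`, `n_subjects`.
#' @export
build_network <- function(residuals) {
  stopifnot(inherits(residuals, "residual_matrix"))
  if (residuals$n_subjects < 4L)
    stop("need at least 4 subjects to correlate; got ",
         residuals$n_subjects)
  w <- correlation_weights(residuals$values,
                           region_labels = residuals$region_set$regions)
  structure(list(weights = w, region_set = residuals$region_set,
                 group = residuals$group,
                 n_subjects = residuals$n_subjects),
            class = "connectivity")
}

# Pearson correlations -> non-negative weights; zero-variance columns get
# all-zero rows/columns. Exact symmetry is enforced by mirroring the upper
# triangle.
correlation_weights <- function(res, region_labels = NULL, warn = TRUE) {
  sds <- apply(res, 2, sd)
  zero <- which(sds == 0)
  w <- suppressWarnings(cor(res))
  if (length(zero) > 0) {
    w[zero, ] <- 0
    w[, zero] <- 0
    if (warn)
      warning("zero-variance residual column(s) ",
              paste(if (is.null(region_labels)) zero
                    else region_labels[zero], collapse = ", "),
              ": their correlations are defined as 0")
  }
  w[is.na(w)] <- 0
  w[w < 0] <- 0
  w[lower.tri(w)] <- t(w)[lower.tri(w)]
  diag(w) <- 0
  if (!is.null(region_labels)) dimnames(w) <- list(region_labels,
                                                   region_labels)
  w
}

#' @export
print.connectivity <- function(x, ...) {
  nz <- sum(x$weights > 0) / 2
  cat("<connectivity: group '", x$group, "', ", length(x$region_set),
      " regions, ", nz, " positive edges, n = ", x$n_subjects, ">\n",
      sep = "")
  invisible(x)
}

#' Group-level covariance network in one step
#'
#' Convenience composition of [cohort_subset()], [residualize()] and
#' [build_network()].
#'
#' @param x a [cohort()].
#' @param group group label.
#' @param regions optional region subset defining the network's nodes.
#' @return A `connectivity` object.
#' @examples
#' sp <- synthetic_spec(c(a = 20, b = 20), regions = 5, seed = 1)
#' net <- group_network(generate_cohort(sp), "a")
#' net$weights[1:3, 1:3]
#' @export
group_network <- function(x, group, regions = NULL) {
  sub <- cohort_subset(x, group = group, regions = regions)
  build_network(residualize(sub))
}

#' Write / read a connectivity matrix as labeled square TSV
#'
#' The first row and first column carry region labels; values keep full
#' double precision.
#'
#' @param x a `connectivity` object (or bare weight matrix with dimnames).
#' @param path file path.
#' @return `write_network` returns `path` invisibly; `read_network`
#'   returns the labeled weight matrix.
#' @export
write_network <- function(x, path) {
  w <- as_weight_matrix(x)
  df <- data.frame(region = rownames(w), w, check.names = FALSE)
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_network
#' @export
read_network <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE)
  w <- as.matrix(df[, -1, drop = FALSE])
  rownames(w) <- df[[1]]
  as_weight_matrix(w)
}

#' Long-format edge list of a network
#'
#' @param x a `connectivity` object or weight matrix.
#' @param positive_only drop zero-weight pairs (default `TRUE`).
#' @return data.frame with columns `region_a`, `region_b`, `weight`, one
#'   row per unordered pair `a < b` (by region-set order).
#' @export
network_edge_list <- function(x, positive_only = TRUE) {
  w <- as_weight_matrix(x)
  labels <- rownames(w)
  if (is.null(labels)) labels <- paste0("R", seq_len(nrow(w)))
  idx <- which(upper.tri(w), arr.ind = TRUE)
  out <- data.frame(region_a = labels[idx[, 1]],
                    region_b = labels[idx[, 2]],
                    weight = w[idx], stringsAsFactors = FALSE)
  if (positive_only) out <- out[out$weight > 0, , drop = FALSE]
  rownames(out) <- NULL
  out
}
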