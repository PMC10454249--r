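# Weighted graph summary measures of a covariance network.
#
# All functions accept either a `connectivity` object or a bare symmetric
# non-negative weight matrix with zero diagonal. Shortest paths treat edge
# weights as conductances: the default length of an edge with weight w is
# 1/w, so strongly correlated region pairs are "close".

.conventions <- c("inverse" = 0L, "one-minus" = 1L, "neglog" = 2L)

as_weight_matrix <- function(x) {
  if (inherits(x, "connectivity")) return(x$weights)
  w <- as.matrix(x)
  if (nrow(w) != ncol(w)) stop("weight matrix must be square")
  if (!is.numeric(w) || any(!is.finite(w)))
    stop("weights must be finite numerics")
  if (any(w < 0)) stop("weights must be non-negative")
  if (max(abs(w - t(w))) > 1e-8) stop("weight matrix must be symmetric")
  w[lower.tri(w)] <- t(w)[lower.tri(w)]
  diag(w) <- 0
  w
}

conv_code <- function(convention) {
  convention <- match.arg(convention, names(.conventions))
  .conventions[[convention]]
}

#' Shortest-path distances of a weighted network
#'
#' Maps each positive weight `w` to an edge length (`1/w` by default) and
#' runs an exact all-pairs shortest-path search. Unreachable pairs get
#' `Inf`; the diagonal is 0.
#'
#' @param x a `connectivity` object or symmetric non-negative weight matrix.
#' @param convention weight-to-length mapping: `"inverse"` (`1/w`, the
#'   default and the convention tested throughout), `"one-minus"` (`1 - w`)
#'   or `"neglog"` (`-log w`).
#' @return Symmetric matrix of distances.
#' @examples
#' w <- matrix(0.5, 3, 3); diag(w) <- 0
#' net_distances(w)  # all off-diagonals 2
#' @export
net_distances <- function(x, convention = "inverse") {
  w <- as_weight_matrix(x)
  d <- cpp_distances(w, conv_code(convention))
  dimnames(d) <- dimnames(w)
  d
}

#' Global efficiency
#'
#' Mean inverse shortest-path distance over ordered node pairs, with
#' unreachable pairs contributing 0. An integration measure: 1 on the
#' complete unit-weight graph, 0 on the edgeless graph.
#'
#' @inheritParams net_distances
#' @return A scalar in `[0, Inf)` (in `[0, 1]` for weights in `[0, 1]`).
#' @export
global_efficiency <- function(x, convention = "inverse") {
  w <- as_weight_matrix(x)
  if (nrow(w) < 2L) stop("need at least 2 nodes")
  cpp_global_efficiency(w, conv_code(convention))
}

#' Local efficiency
#'
#' For each node with at least two neighbors (positive-weight edges), the
#' global efficiency of the subnetwork induced on its neighbors (original
#' weights kept, no renormalization); nodes with fewer than two neighbors
#' contribute 0. Returns the mean over all nodes. A segregation /
#' fault-tolerance measure.
#'
#' @inheritParams net_distances
#' @return A scalar (mean over nodes).
#' @export
local_efficiency <- function(x, convention = "inverse") {
  w <- as_weight_matrix(x)
  if (nrow(w) < 2L) stop("need at least 2 nodes")
  mean(cpp_local_efficiency(w, conv_code(convention)))
}

#' Mean weighted clustering coefficient (Onnela)
#'
#' Per-node clustering is the geometric-mean triangle intensity
#' \deqn{C_i = \frac{1}{k_i (k_i - 1)} \sum_{j,h}
#'   (\hat w_{ij} \hat w_{ih} \hat w_{jh})^{1/3}}
#' with weights normalized by the network maximum
#' (\eqn{\hat w = w / \max w}) and \eqn{k_i} the binary degree. Nodes with
#' degree < 2 contribute 0. Returns the mean over nodes; invariant under
#' uniform weight scaling.
#'
#' @inheritParams net_distances
#' @return A scalar in `[0, 1]`.
#' @export
mean_clustering <- function(x) {
  w <- as_weight_matrix(x)
  if (nrow(w) < 3L) stop("need at least 3 nodes")
  mx <- max(w)
  if (mx <= 0) {
    warning("all-zero weight matrix; mean clustering defined as 0")
    return(0)
  }
  wh <- (w / mx)^(1 / 3)
  tri <- diag(wh %*% wh %*% wh)  # ordered (j, h) triangle intensity sums
  k <- rowSums(w > 0)
  ci <- ifelse(k >= 2, tri / (k * (k - 1)), 0)
  mean(ci)
}

#' Characteristic path length
#'
#' Mean shortest-path distance over ordered pairs of distinct nodes,
#' excluding unreachable pairs (their count is attached as attribute
#' `excluded_pairs` and reported with a message when nonzero). If no pair
#' is reachable the result is `Inf`.
#'
#' @inheritParams net_distances
#' @return A scalar with attribute `excluded_pairs`.
#' @export
characteristic_path_length <- function(x, convention = "inverse") {
  w <- as_weight_matrix(x)
  if (nrow(w) < 2L) stop("need at least 2 nodes")
  d <- cpp_distances(w, conv_code(convention))
  off <- d[row(d) != col(d)]
  excluded <- sum(is.infinite(off))
  if (excluded == length(off)) {
    out <- Inf
  } else {
    if (excluded > 0)
      message(excluded, " unreachable ordered pair(s) excluded from the ",
              "characteristic path length")
    out <- mean(off[is.finite(off)])
  }
  attr(out, "excluded_pairs") <- excluded
  out
}

#' Node strength and degree
#'
#' Strength is the row sum of weights; degree counts strictly positive
#' entries per row.
#'
#' @inheritParams net_distances
#' @return List with per-node `strength` and `degree` and their averages
#'   `average_strength` and `average_degree`.
#' @export
strength_degree <- function(x) {
  w <- as_weight_matrix(x)
  s <- rowSums(w)
  k <- rowSums(w > 0)
  list(strength = s, degree = k,
       average_strength = mean(s), average_degree = mean(k))
}

#' Degree assortativity
#'
#' Pearson correlation of endpoint degrees over the directed edge list
#' (each positive-weight unordered edge contributes both orientations).
#' Degrees are binary counts; edge weights do not enter the endpoint
#' attribute. Returns `NA` when fewer than 2 positive edges exist or when
#' endpoint degrees have zero variance (e.g. regular graphs): undefined is
#' reported as missing, never as 0.
#'
#' @inheritParams net_distances
#' @param weighted if `TRUE`, use node strength instead of binary degree
#'   as the endpoint attribute (non-default variant).
#' @return A scalar in `[-1, 1]`, or `NA`.
#' @export
degree_assortativity <- function(x, weighted = FALSE) {
  w <- as_weight_matrix(x)
  idx <- which(w > 0 & upper.tri(w), arr.ind = TRUE)
  if (nrow(idx) < 2L) return(NA_real_)
  k <- if (weighted) rowSums(w) else rowSums(w > 0)
  a <- c(k[idx[, 1]], k[idx[, 2]])
  b <- c(k[idx[, 2]], k[idx[, 1]])
  if (sd(a) == 0 || sd(b) == 0) return(NA_real_)
  cor(a, b)
}

.measure_names <- c("global_efficiency", "local_efficiency",
                    "mean_clustering_coefficient",
                    "characteristic_path_length",
                    "average_strength", "average_degree",
                    "assortative_coefficient")

# Fast internal bundle used by the permutation engine: one distance pass
# shared between global efficiency and path length; no validation, no
# messages.
measures_from_weights <- function(w, conv = 0L) {
  n <- nrow(w)
  d <- cpp_distances(w, conv)
  off <- d[row(d) != col(d)]
  fin <- is.finite(off)
  ge <- sum(ifelse(fin, 1 / off, 0)) / (n * (n - 1))
  cpl <- if (any(fin)) mean(off[fin]) else Inf
  le <- mean(cpp_local_efficiency(w, conv))
  mx <- max(w)
  if (mx > 0) {
    wh <- (w / mx)^(1 / 3)
    tri <- diag(wh %*% wh %*% wh)
    k <- rowSums(w > 0)
    mc <- mean(ifelse(k >= 2, tri / (k * (k - 1)), 0))
  } else mc <- 0
  sd_ <- list(average_strength = mean(rowSums(w)),
              average_degree = mean(rowSums(w > 0)))
  assort <- degree_assortativity(w)
  out <- c(ge, le, mc, cpl, sd_$average_strength, sd_$average_degree,
           assort)
  names(out) <- .measure_names
  out
}

#' All network summary measures at once
#'
#' Computes the seven group-level summary statistics of one covariance
#' network: global efficiency, local efficiency, mean clustering
#' coefficient, characteristic path length, average strength, average
#' degree and the assortative coefficient (NA when undefined).
#'
#' @inheritParams net_distances
#' @return Named numeric vector of class `network_measures` with one entry
#'   per measure, plus attributes `network` and `group` when `x` is a
#'   `connectivity` object.
#' @examples
#' k4 <- matrix(1, 4, 4); diag(k4) <- 0
#' all_measures(k4)
#' @export
all_measures <- function(x, convention = "inverse") {
  w <- as_weight_matrix(x)
  if (nrow(w) < 3L) stop("need at least 3 nodes")
  out <- measures_from_weights(w, conv_code(convention))
  class(out) <- "network_measures"
  if (inherits(x, "connectivity")) {
    attr(out, "network") <- x$region_set$name
    attr(out, "group") <- x$group
  }
  out
}

#' @export
print.network_measures <- function(x, digits = 4, ...) {
  hdr <- "<network_measures"
  if (!is.null(attr(x, "network")))
    hdr <- paste0(hdr, ": ", attr(x, "network"), " / ", attr(x, "group"))
  cat(hdr, ">\n", sep = "")
  print(round(unclass(x)[.measure_names], digits))
  invisible(x)
}

#' Serialize network measures to a one-row delimited record
#'
#' @param x a `network_measures` vector (or list of them).
#' @param path file path.
#' @param network,group labels for the key columns (taken from attributes
#'   when present).
#' @return `path`, invisibly. Undefined values are rendered as `NA`.
#' @export
write_measures <- function(x, path, network = NULL, group = NULL) {
  rows <- if (inherits(x, "network_measures")) list(x) else x
  df <- do.call(rbind, lapply(rows, function(m) {
    data.frame(network = network %||% attr(m, "network") %||% "network",
               group = group %||% attr(m, "group") %||% "group",
               as.data.frame(as.list(unclass(m)[.measure_names])),
               stringsAsFactors = FALSE)
  }))
  write.table(format_df_full(df), path, sep = "\t", row.names = FALSE,
              quote = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Full-precision text rendering shared by the result writers, so reruns
# with the same seed are byte-identical.
format_df_full <- function(df) {
  df[] <- lapply(df, function(col) {
    if (is.double(col)) sprintf("%.15g", col) else col
  })
  df
}
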