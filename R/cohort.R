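#' Cohorts: per-subject regional volumes with covariates
#'
#' A cohort bundles the subject table (ID, group label, age in years, sex
#' coded 0 = female / 1 = male) with the subjects x regions matrix of
#' volumes in cubic millimetres. It is the sole empirical input of the
#' pipeline; typically it comes from a FreeSurfer volume export read with
#' [read_cohort()] or from the synthetic generator [generate_cohort()].
#'
#' @param subject_id character vector of unique subject identifiers.
#' @param group character vector of group labels, one per subject.
#' @param age numeric vector of ages in years (non-negative).
#' @param sex sex codes: 0/1 or "F"/"M" (normalized to 0 = female, 1 = male).
#' @param volumes numeric matrix, subjects x regions, strictly positive mm^3.
#' @param region_set a [region_set()] whose length matches `ncol(volumes)`.
#' @return An object of class `cohort` with elements `region_set`,
#'   `subjects` (data.frame) and `volumes` (matrix, regions as columns).
#' @seealso [read_cohort()], [write_cohort()], [cohort_subset()]
#' @export
cohort <- function(subject_id, group, age, sex, volumes, region_set) {
  stopifnot(inherits(region_set, "region_set"))
  volumes <- as.matrix(volumes)
  n <- length(subject_id)
  if (anyDuplicated(subject_id))
    stop("duplicated subject IDs: ",
         paste(unique(subject_id[duplicated(subject_id)]), collapse = ", "))
  if (length(group) != n || length(age) != n || length(sex) != n ||
      nrow(volumes) != n)
    stop("subject_id, group, age, sex and volumes must agree in length")
  if (ncol(volumes) != length(region_set))
    stop("volumes has ", ncol(volumes), " columns but the region set has ",
         length(region_set), " regions")
  sex <- normalize_sex(sex)
  age <- as.numeric(age)
  if (any(!is.finite(age)) || any(age < 0))
    stop("ages must be finite and non-negative")
  bad <- which(!is.finite(volumes) | volumes <= 0, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop("non-positive or non-finite volume for subject '",
         subject_id[bad[1, 1]], "', region '",
         region_set$regions[bad[1, 2]], "'")
  }
  colnames(volumes) <- region_set$regions
  rownames(volumes) <- NULL
  structure(list(
    region_set = region_set,
    subjects = data.frame(subject_id = as.character(subject_id),
                          group = as.character(group),
                          age = age, sex = sex,
                          stringsAsFactors = FALSE),
    volumes = volumes), class = "cohort")
}

# Accepts 0/1 (possibly as character) or F/M; anything else is an error,
# never a guess.
normalize_sex <- function(sex) {
  if (is.numeric(sex)) {
    if (!all(sex %in% c(0, 1))) stop("numeric sex codes must be 0 or 1")
    return(as.integer(sex))
  }
  s <- toupper(trimws(as.character(sex)))
  out <- ifelse(s %in% c("0", "F", "FEMALE"), 0L,
         ifelse(s %in% c("1", "M", "MALE"), 1L, NA_integer_))
  if (anyNA(out))
    stop("unrecognized sex codes: ",
         paste(unique(s[is.na(out)]), collapse = ", "),
         " (accepted: 0/1, F/M)")
  out
}

#' @export
print.cohort <- function(x, ...) {
  tab <- table(x$subjects$group)
  cat("<cohort: ", nrow(x$subjects), " subjects, ",
      length(x$region_set), " regions ('", x$region_set$name, "')>\n",
      sep = "")
  cat("  groups:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' List the group labels present in a cohort
#' @param x a [cohort()].
#' @return Character vector of group labels in order of first appearance.
#' @export
cohort_groups <- function(x) unique(x$subjects$group)

#' Restrict a cohort to one group or a subset of regions
#'
#' @param x a [cohort()].
#' @param group optional single group label to keep.
#' @param regions optional character vector of region labels to keep (their
#'   order becomes the order of the restricted region set).
#' @param name optional name for the restricted region set.
#' @return A [cohort()].
#' @export
cohort_subset <- function(x, group = NULL, regions = NULL, name = NULL) {
  stopifnot(inherits(x, "cohort"))
  keep <- rep(TRUE, nrow(x$subjects))
  if (!is.null(group)) {
    if (!group %in% x$subjects$group)
      stop("unknown group '", group, "'; available: ",
           paste(cohort_groups(x), collapse = ", "))
    keep <- x$subjects$group == group
  }
  rs <- x$region_set
  vols <- x$volumes[keep, , drop = FALSE]
  if (!is.null(regions)) {
    missing <- setdiff(regions, rs$regions)
    if (length(missing) > 0)
      stop("regions not in cohort: ", paste(missing, collapse = ", "))
    idx <- match(regions, rs$regions)
    rs <- region_set(regions,
                     name = if (is.null(name)) rs$name else name,
                     hemisphere = if (is.null(rs$hemisphere)) NULL
                                  else rs$hemisphere[idx])
    vols <- vols[, idx, drop = FALSE]
  } else if (!is.null(name)) {
    rs <- region_set(rs$regions, name = name, hemisphere = rs$hemisphere)
  }
  cohort(x$subjects$subject_id[keep], x$subjects$group[keep],
         x$subjects$age[keep], x$subjects$sex[keep], vols, rs)
}

#' Write a cohort to delimited text
#'
#' Layout: header `subject_id,group,age,sex` followed by one column per
#' region label; one row per subject; UTF-8, decimal point `.`.
#'
#' @param x a [cohort()].
#' @param path output file path.
#' @param sep field separator, `","` (default) or `"\t"`.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(x, path, sep = ",") {
  stopifnot(inherits(x, "cohort"))
  df <- cbind(x$subjects,
              as.data.frame(x$volumes, check.names = FALSE))
  write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a cohort from delimited text
#'
#' Expects the layout written by [write_cohort()]: columns `subject_id`,
#' `group`, `age`, `sex`, then one numeric column per region. The separator
#' (comma or tab) is auto-detected from the header line.
#'
#' @param path input file path.
#' @param regions optional character vector selecting (and ordering) the
#'   region columns to use; defaults to every column after `sex`.
#' @param name name for the resulting region set.
#' @return A [cohort()].
#' @export
read_cohort <- function(path, regions = NULL, name = "custom") {
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  df <- read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                   stringsAsFactors = FALSE, quote = "", comment.char = "")
  required <- c("subject_id", "group", "age", "sex")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0)
    stop("cohort file is missing required column(s): ",
         paste(missing, collapse = ", "))
  region_cols <- setdiff(names(df), required)
  if (!is.null(regions)) {
    absent <- setdiff(regions, region_cols)
    if (length(absent) > 0)
      stop("region column(s) not in cohort file: ",
           paste(absent, collapse = ", "))
    region_cols <- regions
  }
  if (length(region_cols) < 3L)
    stop("cohort file must contain at least 3 region columns")
  vols <- as.matrix(df[, region_cols, drop = FALSE])
  if (!is.numeric(vols)) {
    nonnum <- region_cols[!vapply(df[region_cols], is.numeric, logical(1))]
    stop("non-numeric volume column(s): ", paste(nonnum, collapse = ", "))
  }
  cohort(df$subject_id, df$group, df$age, df$sex, vols,
         region_set(region_cols, name = name))
}
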