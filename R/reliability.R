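# Repeatability and group statistics for radius measurements.
#
# A measurement table is a long-format data frame with one row per
# subject x structure x repeat and mm radius columns whole_mm, proximal_mm,
# middle_mm, distal_mm (plus optional sex, age, observer). The reliability
# metric is the coefficient of variation of the repeated measurements of one
# quantity; group summaries are sample mean and SD (n - 1 denominator,
# verified against the packaged reference table).

radius_parts <- c("whole", "proximal", "middle", "distal")
radius_cols <- paste0(radius_parts, "_mm")

check_measurement_table <- function(table) {
  if (!is.data.frame(table) || nrow(table) == 0L)
    stop("measurement table must be a non-empty data frame")
  missing_cols <- setdiff(radius_cols, names(table))
  if (length(missing_cols))
    stop("measurement table lacks columns: ", paste(missing_cols, collapse = ", "))
  if (any(!is.na(as.matrix(table[radius_cols])) &
          as.matrix(table[radius_cols]) <= 0))
    stop("radii must be positive")
  table
}

#' Coefficient of variation
#'
#' Sample standard deviation (n - 1 denominator) divided by the mean.
#'
#' @param values Numeric vector of at least two positive values.
#' @return The CV (dimensionless ratio, `>= 0`).
#' @examples
#' coefficient_of_variation(c(100, 110, 120)) # 10 / 110
#' @export
coefficient_of_variation <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 2L) stop("CV needs at least 2 values")
  if (any(!is.finite(values))) stop("CV: non-finite values")
  m <- mean(values)
  if (m <= 0) stop("CV undefined: mean must be positive")
  sd(values) / m
}

#' Group means and standard deviations of radius measurements
#'
#' Sample mean and SD (n - 1) of each radius column per group. A group with
#' a single row gets `NA` SD; empty factor combinations are omitted (with a
#' warning when they were explicitly requested through factor levels).
#'
#' @param table A measurement table (see module description).
#' @param by Character vector of grouping column names; empty for a pooled
#'   summary of all rows.
#' @return A data frame in long part-wise format: grouping columns, `part`,
#'   `n`, `mean`, `sd`.
#' @export
aggregate_groups <- function(table, by = character()) {
  table <- check_measurement_table(table)
  if (length(by)) {
    missing_by <- setdiff(by, names(table))
    if (length(missing_by))
      stop("unknown grouping columns: ", paste(missing_by, collapse = ", "))
    groups <- interaction(table[by], drop = FALSE, sep = "\r")
    if (any(table(groups) == 0L))
      warning("empty groups omitted from the summary")
    groups <- droplevels(groups)
  } else {
    groups <- factor(rep("all", nrow(table)))
  }
  out <- list()
  for (g in levels(groups)) {
    rows <- table[groups == g, , drop = FALSE]
    for (part in radius_parts) {
      v <- rows[[paste0(part, "_mm")]]
      v <- v[!is.na(v)]
      rec <- data.frame(part = part, n = length(v),
                        mean = if (length(v)) mean(v) else NA_real_,
                        sd = if (length(v) >= 2L) sd(v) else NA_real_,
                        stringsAsFactors = FALSE)
      if (length(by)) {
        keys <- strsplit(g, "\r", fixed = TRUE)[[1L]]
        for (i in seq_along(by)) rec[[by[i]]] <- keys[i]
        rec <- rec[c(by, "part", "n", "mean", "sd")]
      }
      out[[length(out) + 1L]] <- rec
    }
  }
  do.call(rbind, out)
}

#' Two-group comparison of radii
#'
#' Welch's two-sample t-test (unequal variances, two-sided). The degenerate
#' case of two constant equal groups returns `t = 0`, `p = 1`.
#'
#' @param a,b Numeric vectors, each of length `>= 2`.
#' @param paired Paired test instead of Welch's unpaired (requires equal
#'   lengths).
#' @return A list with `t`, `p_value`, `mean_a`, `mean_b`, `method`.
#' @export
compare_groups <- function(a, b, paired = FALSE) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 2L || length(b) < 2L)
    stop("each group needs at least 2 values")
  if (var(a) == 0 && var(b) == 0) {
    if (mean(a) == mean(b))
      return(list(t = 0, p_value = 1, mean_a = mean(a), mean_b = mean(b),
                  method = "degenerate (both groups constant)"))
    return(list(t = Inf * sign(mean(a) - mean(b)), p_value = 0,
                mean_a = mean(a), mean_b = mean(b),
                method = "degenerate (both groups constant)"))
  }
  tt <- t.test(a, b, paired = paired, var.equal = FALSE)
  list(t = unname(tt$statistic), p_value = tt$p.value,
       mean_a = mean(a), mean_b = mean(b), method = tt$method)
}

#' Repeatability report: coefficients of variation of repeated measurements
#'
#' One CV per (subject, structure, part) across the repeats, plus the
#' minimum, maximum and mean CV over all such triplets.
#'
#' @param table A measurement table; every (subject, structure) group must
#'   hold at least two repeats.
#' @return An object of class `reliability_report`: data frame `cv` (columns
#'   `subject`, `structure`, `part`, `n_repeats`, `cv`) and `summary`
#'   (`min`, `max`, `mean`).
#' @export
reliability_report <- function(table) {
  table <- check_measurement_table(table)
  if (!all(c("subject", "structure") %in% names(table)))
    stop("measurement table needs subject and structure columns")
  key <- interaction(table$subject, table$structure, drop = TRUE, sep = "\r")
  recs <- list()
  for (g in levels(key)) {
    rows <- table[key == g, , drop = FALSE]
    if (nrow(rows) < 2L)
      stop("each (subject, structure) group needs at least 2 repeats: ",
           gsub("\r", "/", g, fixed = TRUE))
    for (part in radius_parts) {
      recs[[length(recs) + 1L]] <- data.frame(
        subject = rows$subject[1L], structure = rows$structure[1L],
        part = part, n_repeats = nrow(rows),
        cv = coefficient_of_variation(rows[[paste0(part, "_mm")]]),
        stringsAsFactors = FALSE)
    }
  }
  cv <- do.call(rbind, recs)
  structure(list(cv = cv,
                 summary = c(min = min(cv$cv), max = max(cv$cv),
                             mean = mean(cv$cv))),
            class = "reliability_report")
}

#' @export
print.reliability_report <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<reliability_report> %d CVs over %d subject/structure groups\n",
              nrow(x$cv), nrow(unique(x$cv[c("subject", "structure")]))))
  cat(sprintf("  CV min %.3f, max %.3f, mean %.3f\n",
              s[["min"]], s[["max"]], s[["mean"]]))
  invisible(x)
}
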