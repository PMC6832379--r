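# Packaged reference dataset: per-subject radii (mm) from a ten-radiograph
# lateral-view validation series (five women, five men; each value the
# rounded average of three repeated measurements of the cortical outline
# "outer" or medullary canal "inner").
#
# The source table prints its "Proximal"/"Distal" columns interchanged
# relative to the study's pooled summary table: the pooled means reconcile
# only when the printed "proximal" columns are read as distal radii and vice
# versa (printed proximal-outer pools to 452 mm, which the summary table
# reports as the *distal* outline radius). The canonical labeling applies
# that swap; `labels = "printed"` returns the columns exactly as printed.

#' Load the packaged per-subject reference radii
#'
#' Per-subject mm radii of the cortical outline and medullary canal of ten
#' femora (five women, five men), in long measurement-table format suitable
#' for [aggregate_groups()] and [compare_groups()].
#'
#' @param labels `"canonical"` (default) resolves the proximal/distal
#'   column-label discrepancy of the printed source table against its pooled
#'   summary (see the package vignette); `"printed"` keeps the labels exactly
#'   as printed.
#' @return A data frame with columns `subject`, `age`, `sex`, `structure`
#'   (`"outline"`/`"canal"`), `whole_mm`, `proximal_mm`, `middle_mm`,
#'   `distal_mm`.
#' @export
load_reference_radii <- function(labels = c("canonical", "printed")) {
  labels <- match.arg(labels)
  path <- system.file("extdata", "femur_radii_reference.csv",
                      package = "fembow", mustWork = TRUE)
  wide <- read.csv(path, stringsAsFactors = FALSE)
  long <- do.call(rbind, lapply(c(outer = "outline", inner = "canal"), function(st) {
    suffix <- names(which(c(outer = "outline", inner = "canal") == st))
    data.frame(subject = wide$subject, age = wide$age, sex = wide$sex,
               structure = st,
               whole_mm = wide[[paste0("whole_", suffix)]],
               proximal_mm = wide[[paste0("proximal_", suffix)]],
               middle_mm = wide[[paste0("middle_", suffix)]],
               distal_mm = wide[[paste0("distal_", suffix)]],
               stringsAsFactors = FALSE)
  }))
  rownames(long) <- NULL
  if (labels == "canonical") {
    tmp <- long$proximal_mm
    long$proximal_mm <- long$distal_mm
    long$distal_mm <- tmp
  }
  long
}
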