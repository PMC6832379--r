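# Annotation and measurement file formats.
#
# Annotations are JSON (schema "fembow-annotation/1"): image reference
# (optional), pixel spacing, magnification, the four traced border polylines
# and the three operator-marked points, plus observer/repeat/subject
# metadata. Measurements are CSV rows mirroring as.data.frame() of a
# radius_measurement.

ANNOTATION_SCHEMA <- "fembow-annotation/1"

validation_error <- function(msg) {
  stop(errorCondition(msg, class = c("annotation_validation_error", "error")))
}

#' Assemble an annotation document
#'
#' @param outline,canal `border_pair`s of the traced borders.
#' @param p1,p2,p3 Operator-marked points (distal cortical junctions and
#'   lesser-trochanter base).
#' @param pixel_spacing mm per pixel (`> 0`).
#' @param magnification Projection magnification factor.
#' @param image Optional path of the source radiograph.
#' @param subject,sex,age,observer,repeat_index Metadata.
#' @return A list of class `annotation` following the packaged JSON schema.
#' @export
annotation_document <- function(outline, canal, p1, p2, p3,
                                pixel_spacing, magnification = 1,
                                image = NULL, subject = NA_character_,
                                sex = NA_character_, age = NA_real_,
                                observer = NA_character_,
                                repeat_index = NA_integer_) {
  doc <- list(schema = ANNOTATION_SCHEMA,
              image = image,
              pixel_spacing = pixel_spacing,
              magnification = magnification,
              subject = list(id = subject, sex = sex, age = age),
              observer = observer,
              repeat_index = repeat_index,
              borders = list(outline_upper = unname(outline$upper),
                             outline_lower = unname(outline$lower),
                             canal_upper = unname(canal$upper),
                             canal_lower = unname(canal$lower)),
              landmarks = list(p1 = as.numeric(p1), p2 = as.numeric(p2),
                               p3 = as.numeric(p3)))
  class(doc) <- "annotation"
  validate_annotation(doc)
}

#' Validate an annotation document
#'
#' Checks the schema tag, the presence and shape of the four borders and
#' three marked points, and positivity of the calibration fields; errors
#' name the offending field.
#'
#' @param doc An annotation list.
#' @return The validated document (invisibly classed `annotation`).
#' @export
validate_annotation <- function(doc) {
  if (!is.list(doc)) validation_error("annotation must be a list")
  if (is.null(doc$schema) || !startsWith(doc$schema, "fembow-annotation/"))
    validation_error("missing or unrecognized field: schema")
  if (is.null(doc$pixel_spacing) || !is.numeric(doc$pixel_spacing) ||
      doc$pixel_spacing <= 0)
    validation_error("missing or invalid field: pixel_spacing (mm/px > 0)")
  if (is.null(doc$magnification) || !is.numeric(doc$magnification) ||
      doc$magnification <= 0)
    validation_error("missing or invalid field: magnification")
  for (b in c("outline_upper", "outline_lower", "canal_upper", "canal_lower")) {
    m <- doc$borders[[b]]
    if (is.null(m))
      validation_error(paste0("missing border: borders.", b))
    if (!is.matrix(m) || ncol(m) != 2L || nrow(m) < 2L)
      validation_error(paste0("invalid border (need an n x 2 matrix, n >= 2): borders.", b))
  }
  for (p in c("p1", "p2", "p3")) {
    v <- doc$landmarks[[p]]
    if (is.null(v) || length(v) != 2L || !all(is.finite(v)))
      validation_error(paste0("missing or invalid landmark: landmarks.", p))
  }
  class(doc) <- "annotation"
  invisible(doc)
}

#' Write an annotation document to JSON
#'
#' @param doc An annotation (see [annotation_document()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(doc, path) {
  validate_annotation(doc)
  jsonlite::write_json(unclass(doc), path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(path)
}

#' Read and validate an annotation JSON file
#'
#' @param path File path.
#' @return A validated `annotation` list; border polylines as matrices.
#' @export
read_annotation <- function(path) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  doc <- jsonlite::fromJSON(path, simplifyMatrix = TRUE)
  for (b in names(doc$borders))
    if (!is.null(doc$borders[[b]]))
      doc$borders[[b]] <- matrix(as.numeric(doc$borders[[b]]), ncol = 2L,
                                 dimnames = list(NULL, c("x", "y")))
  for (p in names(doc$landmarks))
    doc$landmarks[[p]] <- as.numeric(doc$landmarks[[p]])
  doc <- validate_annotation(doc)
  doc
}

#' Write / read a measurement table as CSV
#'
#' @param table A measurement table data frame.
#' @param path File path.
#' @return `write_measurements()` returns `path` invisibly;
#'   `read_measurements()` the validated data frame.
#' @export
write_measurements <- function(table, path) {
  check_measurement_table(table)
  write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_measurements
#' @export
read_measurements <- function(path) {
  if (!file.exists(path)) stop("measurement file not found: ", path)
  tab <- read.csv(path, stringsAsFactors = FALSE)
  if (nrow(tab) == 0L) validation_error("measurement CSV is empty")
  check_measurement_table(tab)
}
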