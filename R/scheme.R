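#' The 15-label annotation scheme for the fetal four-chamber view
#'
#' The standard annotation protocol for the four-chamber plane labels 13
#' anatomical structures (cardiac chambers, septa, ventricular walls, lungs,
#' descending aorta, spine, ribs) plus two area annotations (heart area,
#' thorax area) used for the cardiothoracic ratio. Background is id 0 and is
#' never part of the scheme.
#'
#' @param path Optional path to a JSON scheme file of `{"name": id}` pairs.
#'   When `NULL` the default scheme (ids 1..15 in protocol order) is returned.
#' @return A `label_scheme` object: a named integer vector mapping label name
#'   to positive integer id.
#' @examples
#' sch <- label_scheme()
#' sch[["Spine"]]
#' @export
label_scheme <- function(path = NULL) {
  if (is.null(path)) {
    ids <- seq_along(.fcv_label_names)
    names(ids) <- .fcv_label_names
    return(structure(as.integer(ids), names = names(ids), class = "label_scheme"))
  }
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!length(raw) || is.null(names(raw)) || any(!nzchar(names(raw)))) {
    stop("scheme file must be a JSON object of {\"name\": id} pairs: ", path)
  }
  ids <- as.integer(unlist(raw))
  names(ids) <- names(raw)
  validate_scheme(structure(ids, class = "label_scheme"))
}

# Protocol order; comparisons elsewhere are case-insensitive.
.fcv_label_names <- c(
  "Left Atrium", "Left Ventricle", "Right Atrium", "Right Ventricle",
  "Interventricular Septum", "Interatrial Septum",
  "Left Ventricular Wall", "Right Ventricular Wall",
  "Left Lung", "Right Lung", "Descending Aorta", "Spine", "RIB",
  "Heart Area", "Thorax Area"
)

validate_scheme <- function(scheme) {
  if (!inherits(scheme, "label_scheme")) stop("not a label_scheme")
  if (length(scheme) != 15L) {
    stop("scheme must have exactly 15 non-background entries, got ", length(scheme))
  }
  if (anyDuplicated(scheme)) stop("scheme ids must be unique")
  if (any(scheme <= 0L)) stop("scheme ids must be positive (0 is background)")
  missing <- setdiff(tolower(.fcv_label_names), tolower(names(scheme)))
  if (length(missing)) {
    stop("scheme is missing required labels: ", paste(missing, collapse = ", "))
  }
  scheme
}

#' Write a label scheme to a JSON file
#'
#' @param scheme A `label_scheme`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_label_scheme <- function(scheme, path) {
  validate_scheme(scheme)
  obj <- as.list(stats::setNames(as.integer(scheme), names(scheme)))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

# Resolve a label name case-insensitively to its id.
scheme_id <- function(scheme, label_name) {
  hit <- match(tolower(label_name), tolower(names(scheme)))
  if (is.na(hit)) {
    stop("unknown label name: '", label_name, "' (scheme has: ",
         paste(names(scheme), collapse = ", "), ")")
  }
  unname(scheme[hit])
}

#' @export
print.label_scheme <- function(x, ...) {
  cat("<label_scheme> 15 labels (background = 0)\n")
  for (i in seq_along(x)) cat(sprintf("  %2d  %s\n", x[i], names(x)[i]))
  invisible(x)
}
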