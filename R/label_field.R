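#' Label set
#'
#' An ordered set of integer label identifiers. The first label is
#' conventionally the background, the second the lesion.
#'
#' @param labels integer vector of at least two distinct natural numbers.
#' @return an object of class `label_set`.
#' @export
label_set <- function(labels = c(0L, 1L)) {
  labels <- as.integer(labels)
  if (length(labels) < 2L) stopf("a label set needs at least 2 labels")
  if (anyDuplicated(labels)) stopf("labels must be distinct")
  if (any(labels < 0L)) stopf("labels must be natural numbers")
  structure(list(labels = labels), class = "label_set")
}

#' Per-pixel label field
#'
#' A length-`height * width` vector of labels in row-major pixel order
#' (pixel i sits at row `floor((i-1)/width)+1`, column `((i-1) %% width)+1`).
#'
#' @param labels integer vector of labels.
#' @param height,width grid dimensions, `height * width == length(labels)`.
#' @param labelset the [label_set] the entries are drawn from.
#' @return an object of class `label_field`.
#' @export
label_field <- function(labels, height, width, labelset = label_set()) {
  labels <- as.integer(labels)
  if (length(labels) != height * width)
    stopf("label vector has %d entries; expected %d x %d = %d",
          length(labels), height, width, height * width)
  if (!all(labels %in% labelset$labels))
    stopf("label field contains values outside the label set")
  structure(list(labels = labels, height = height, width = width,
                 labelset = labelset),
            class = "label_field")
}

#' @export
print.label_field <- function(x, ...) {
  tab <- table(x$labels)
  cat(sprintf("<label_field %d x %d: %s>\n", x$height, x$width,
              paste(sprintf("%s=%d", names(tab), tab), collapse = ", ")))
  invisible(x)
}

#' Read a label mask from a single-channel PNG
#'
#' Pixels with value >= 0.5 (e.g. 255 in an 8-bit file) map to the second
#' label of `labelset` (lesion), the rest to the first (background).
#'
#' @param path file path.
#' @param labelset a binary [label_set].
#' @return a [label_field].
#' @export
read_mask_png <- function(path, labelset = label_set()) {
  if (!file.exists(path)) stopf("mask file not found: %s", path)
  px <- png::readPNG(path)
  if (length(dim(px)) == 3L) px <- px[, , 1]
  lab <- ifelse(px >= 0.5, labelset$labels[2], labelset$labels[1])
  label_field(matrix_to_field(lab), nrow(px), ncol(px), labelset)
}

#' Write a binary label mask as a single-channel PNG
#'
#' The second label of the field's label set is written as white (255),
#' everything else as black (0).
#'
#' @param field a [label_field] over a binary label set.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_mask_png <- function(field, path) {
  stopifnot(inherits(field, "label_field"))
  pos <- field$labelset$labels[2]
  M <- field_to_matrix(as.numeric(field$labels == pos),
                       field$height, field$width)
  png::writePNG(M, path)
  invisible(path)
}
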