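#' Build a cell annotation table
#'
#' An annotation table records one object per row as a continuous (row, col)
#' center (0-based pixel coordinates), a positive radius in pixels, and
#' optional class label and ground-truth object id. The Gaussian standard
#' deviation used throughout the package is `radius / 3`.
#'
#' @param row,col numeric vectors of center coordinates (0-based, sub-pixel
#'   allowed). `row` runs across the channel (lateral), `col` along the flow.
#' @param radius positive numeric vector of object radii in pixels.
#' @param class optional character vector of class labels.
#' @param object_id optional integer vector of ground-truth identities.
#' @return a `data.frame` with columns `row`, `col`, `radius`, `class`,
#'   `object_id`.
#' @export
annotations <- function(row = numeric(), col = numeric(), radius = numeric(),
                        class = NA_character_, object_id = NA_integer_) {
  n <- length(row)
  ann <- data.frame(
    row = as.numeric(row), col = as.numeric(col), radius = as.numeric(radius),
    class = rep_len(as.character(class), n),
    object_id = rep_len(as.integer(object_id), n),
    stringsAsFactors = FALSE
  )
  validate_annotations(ann)
  ann
}

#' @rdname annotations
#' @param ann an annotation `data.frame`.
#' @export
validate_annotations <- function(ann) {
  stopifnot(is.data.frame(ann),
            all(c("row", "col", "radius") %in% names(ann)))
  if (nrow(ann) > 0 && any(!is.finite(ann$radius) | ann$radius <= 0))
    stop("annotation radii must be positive and finite (sigma = radius/3 > 0)")
  invisible(ann)
}

#' Read / write annotation tables
#'
#' CSV layout: `frame,object_id,row,col,radius,class`. `frame` may be absent
#' for single-frame tables.
#'
#' @param path CSV file path.
#' @export
read_annotations <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_annotations(df)
  df
}

#' @rdname read_annotations
#' @param ann annotation table.
#' @export
write_annotations <- function(ann, path) {
  utils::write.csv(ann, path, row.names = FALSE)
  invisible(path)
}
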