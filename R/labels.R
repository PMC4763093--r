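# Face label masks: the per-face segmentation that separates living tissue
# from non-living contact surfaces (break surfaces, bases, repair patches)
# and the surrounding environment.

#' The closed set of face label classes
#' @return `c("living", "nonliving_contact", "background")`.
#' @export
label_classes <- function() c("living", "nonliving_contact", "background")

#' Face label mask
#'
#' A partition of a mesh's faces into living tissue, non-living contact
#' surface and background classes. Effective surface area (ESA) is the area
#' of the `living` faces only; total surface area (TSA) includes everything
#' kept after segmentation from the environment.
#'
#' @param labels character vector, one class per face, values in
#'   [label_classes()].
#' @return An object of class `coral_labels`.
#' @export
face_labels <- function(labels) {
  labels <- as.character(labels)
  bad <- !(labels %in% label_classes())
  if (any(bad))
    stop("unknown label class(es): ",
         paste(unique(labels[bad]), collapse = ", "), call. = FALSE)
  structure(list(labels = labels), class = "coral_labels")
}

#' @export
print.coral_labels <- function(x, ...) {
  tb <- table(factor(x$labels, levels = label_classes()))
  cat("<coral_labels>", paste(names(tb), tb, sep = " = ", collapse = ", "),
      "\n")
  invisible(x)
}

check_labels <- function(mask, mesh) {
  if (!inherits(mask, "coral_labels"))
    stop("mask must be a coral_labels object", call. = FALSE)
  if (length(mask$labels) != n_faces(mesh))
    stop("mask covers ", length(mask$labels), " faces but mesh has ",
         n_faces(mesh), call. = FALSE)
  invisible(mask)
}

#' Read / write a face label mask as CSV
#'
#' The on-disk format is a two-column CSV `face_index,class` with one header
#' line and 0-based face indices (the convention of the mesh tools the OBJ
#' files come from); indices are converted to 1-based on read. Every face of
#' the associated mesh must be covered exactly once.
#'
#' @param path CSV file path.
#' @param n_faces number of faces of the associated mesh.
#' @return `read_labels`: a [face_labels()] mask.
#' @export
read_labels <- function(path, n_faces) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("face_index", "class") %in% names(df)))
    stop("label CSV must have columns face_index,class", call. = FALSE)
  idx <- as.integer(df$face_index) + 1L
  if (anyNA(idx) || any(idx < 1L | idx > n_faces))
    stop("face_index out of range [0, ", n_faces - 1L, "]", call. = FALSE)
  if (anyDuplicated(idx))
    stop("duplicate face_index entries", call. = FALSE)
  if (length(idx) != n_faces)
    stop("label CSV covers ", length(idx), " of ", n_faces, " faces",
         call. = FALSE)
  labels <- character(n_faces)
  labels[idx] <- df$class
  face_labels(labels)
}

#' @rdname read_labels
#' @param mask a [face_labels()] mask.
#' @export
write_labels <- function(mask, path) {
  df <- data.frame(face_index = seq_along(mask$labels) - 1L,
                   class = mask$labels)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
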