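# Scale calibration: convert arbitrary model units to centimetres using
# landmark pairs on an imaged reference object (a 23 cm folding ruler or a
# ColorChecker Passport placed next to the colony).

#' Scale reference from landmark point pairs
#'
#' Each pair is two model-space landmark points a known physical distance
#' apart, digitised on the reference object visible in the reconstruction.
#'
#' @param pairs data frame with numeric columns `ax, ay, az, bx, by, bz,
#'   known_length_cm`, one row per landmark pair.
#' @param source provenance of the reference object.
#' @return An object of class `coral_scale_ref`.
#' @export
scale_reference <- function(pairs,
                            source = c("custom", "ruler_23cm", "colorchecker")) {
  source <- match.arg(source)
  pairs <- as.data.frame(pairs)
  need <- c("ax", "ay", "az", "bx", "by", "bz", "known_length_cm")
  if (!all(need %in% names(pairs)))
    stop("pairs must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  if (nrow(pairs) < 1L) stop("at least one landmark pair is required",
                             call. = FALSE)
  num <- as.matrix(pairs[need])
  if (!all(is.finite(num))) stop("non-finite landmark coordinates",
                                 call. = FALSE)
  if (any(pairs$known_length_cm <= 0))
    stop("known_length_cm must be positive", call. = FALSE)
  structure(list(pairs = pairs[need], source = source),
            class = "coral_scale_ref")
}

#' Read a scale reference from CSV or JSON
#'
#' CSV: columns `ax,ay,az,bx,by,bz,known_length_cm`. JSON: an object with a
#' `pairs` array of such records and an optional `source` string.
#'
#' @param path file path (`.csv` or `.json`).
#' @return A [scale_reference()].
#' @export
read_scale_reference <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    scale_reference(as.data.frame(obj$pairs),
                    source = if (!is.null(obj$source)) obj$source else "custom")
  } else {
    scale_reference(utils::read.csv(path))
  }
}

#' Fit the model-to-centimetre scale factor
#'
#' The factor is the mean over landmark pairs of known physical length over
#' model-space distance. The coefficient of variation of the per-pair ratios
#' is returned as a quality flag: a CV above `cv_warn` (default 5%) raises a
#' warning, since it indicates inconsistent landmarking or a distorted
#' reconstruction, but is not an error.
#'
#' @param ref a [scale_reference()].
#' @param cv_warn CV threshold (fraction) above which to warn.
#' @return A list with `factor` (cm per model unit), `cv` (coefficient of
#'   variation across pairs; 0 for a single pair) and `n_pairs`.
#' @export
fit_scale <- function(ref, cv_warn = 0.05) {
  stopifnot(inherits(ref, "coral_scale_ref"))
  p <- ref$pairs
  d <- sqrt((p$ax - p$bx)^2 + (p$ay - p$by)^2 + (p$az - p$bz)^2)
  if (any(d == 0))
    stop("landmark pair(s) with zero model-space distance: ",
         paste(which(d == 0), collapse = ", "), call. = FALSE)
  ratio <- p$known_length_cm / d
  factor <- mean(ratio)
  cv <- if (length(ratio) > 1L) stats::sd(ratio) / factor else 0
  if (cv > cv_warn)
    warning(sprintf("scale ratios vary by CV = %.1f%% (> %.1f%%); check %s",
                    100 * cv, 100 * cv_warn, "landmarks"), call. = FALSE)
  list(factor = factor, cv = cv, n_pairs = length(ratio))
}

#' Calibrate a mesh to centimetres
#'
#' Multiplies all vertex coordinates by the fitted scale factor and stamps
#' the mesh units as cm. Surface areas then scale by `factor^2` and volumes
#' by `factor^3`.
#'
#' @param mesh a [coral_mesh()].
#' @param factor positive scale factor (cm per model unit), e.g.
#'   `fit_scale(ref)$factor`.
#' @return The calibrated mesh with `units = "cm"`.
#' @export
apply_scale <- function(mesh, factor) {
  if (!is.numeric(factor) || length(factor) != 1L || !is.finite(factor) ||
      factor <= 0)
    stop("scale factor must be a positive number", call. = FALSE)
  mesh <- scale_mesh(mesh, factor)
  mesh$units <- "cm"
  mesh
}
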