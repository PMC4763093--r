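# Frame selection for structure-from-motion input: score the sharpness of
# video-derived still frames and pick a well-spaced, sharp subset under the
# reconstruction service's image ceiling (70 images per model).

# Read an image file as a grayscale matrix in [0, 1]. PNG natively; TIFF
# when the tiff package is installed.
read_frame_gray <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = {
      if (!requireNamespace("tiff", quietly = TRUE))
        stop("reading TIFF frames requires the tiff package", call. = FALSE)
      tiff::readTIFF(path)
    },
    stop("unsupported frame format: .", ext, call. = FALSE))
  if (length(dim(img)) == 3L) {
    if (dim(img)[3L] >= 3L)
      img <- 0.299 * img[, , 1L] + 0.587 * img[, , 2L] + 0.114 * img[, , 3L]
    else
      img <- img[, , 1L]
  }
  img
}

# 5-point Laplacian of a matrix (interior only, no padding).
laplacian <- function(img) {
  nr <- nrow(img)
  nc <- ncol(img)
  if (nr < 3L || nc < 3L)
    stop("frame too small for sharpness scoring (< 3 px)", call. = FALSE)
  c0 <- img[2:(nr - 1L), 2:(nc - 1L)]
  img[1:(nr - 2L), 2:(nc - 1L)] + img[3:nr, 2:(nc - 1L)] +
    img[2:(nr - 1L), 1:(nc - 2L)] + img[2:(nr - 1L), 3:nc] - 4 * c0
}

#' Sharpness of a single frame
#'
#' Variance of the Laplacian of the grayscale image — the standard focus
#' measure: in-focus frames have strong high-frequency content, defocused
#' or motion-blurred frames do not. A constant frame scores exactly 0.
#'
#' @param path image file path (PNG, or TIFF with the tiff package).
#' @return Non-negative sharpness score (dimensionless).
#' @export
frame_sharpness <- function(path) {
  resp <- laplacian(read_frame_gray(path))
  mean((resp - mean(resp))^2)
}

#' Score all frames of a directory
#'
#' Scores every PNG/TIFF frame by [frame_sharpness()]. Frame ordinals are
#' parsed from trailing digits of the file names (zero-padded ordinals as
#' produced by frame extractors); files without digits are numbered by
#' position. Unreadable images are skipped with a warning and recorded.
#'
#' @param dir directory of frames.
#' @param pattern file-name regexp (default PNG/TIFF).
#' @return A data frame with columns `frame_id`, `file`, `sharpness`,
#'   `selected` (all `FALSE`; see [select_frames()]), plus an attribute
#'   `skipped` listing unreadable files.
#' @export
score_frames <- function(dir, pattern = "\\.(png|tif|tiff)$") {
  files <- sort(list.files(dir, pattern = pattern, ignore.case = TRUE))
  if (length(files) == 0L)
    stop("no readable frames in ", dir, call. = FALSE)
  ids <- suppressWarnings(
    as.integer(sub(".*?(\\d+)\\.[A-Za-z]+$", "\\1", files)))
  ids[is.na(ids)] <- seq_along(files)[is.na(ids)]
  sharp <- rep(NA_real_, length(files))
  skipped <- character(0)
  for (i in seq_along(files)) {
    s <- tryCatch(frame_sharpness(file.path(dir, files[i])),
                  error = function(e) NA_real_)
    if (is.na(s)) skipped <- c(skipped, files[i]) else sharp[i] <- s
  }
  if (length(skipped))
    warning(length(skipped), " unreadable frame(s) skipped: ",
            paste(utils::head(skipped, 3L), collapse = ", "), call. = FALSE)
  ok <- !is.na(sharp)
  out <- data.frame(frame_id = ids[ok], file = files[ok],
                    sharpness = sharp[ok], selected = FALSE,
                    stringsAsFactors = FALSE)
  out <- out[order(out$frame_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  out
}

#' Select sharp, well-spaced frames under an image ceiling
#'
#' Greedy selection: frames are visited in decreasing sharpness (ties broken
#' by lower frame ordinal) and accepted while the selection stays under
#' `cap` and the ordinal distance to every already-selected frame is at
#' least `min_spacing`. The default cap of 70 is the reconstruction
#' service's per-model image limit; the spacing knob suppresses near-
#' duplicate consecutive video frames. Fully deterministic.
#'
#' @param scores data frame from [score_frames()] (needs `frame_id` and
#'   `sharpness`).
#' @param cap maximum number of selected frames (default 70).
#' @param min_spacing minimum ordinal distance between selected frames
#'   (default 1 = adjacent allowed).
#' @return `scores` with the `selected` column set.
#' @export
select_frames <- function(scores, cap = 70L, min_spacing = 1L) {
  stopifnot(cap >= 1L, min_spacing >= 1L)
  ord <- order(-scores$sharpness, scores$frame_id)
  chosen <- integer(0)
  for (i in ord) {
    if (length(chosen) >= cap) break
    id <- scores$frame_id[i]
    if (all(abs(id - chosen) >= min_spacing)) chosen <- c(chosen, id)
  }
  scores$selected <- scores$frame_id %in% chosen
  scores
}

#' Write a frame-selection manifest CSV
#'
#' Columns `frame_id, file, sharpness, selected`, preceded by a comment
#' header recording the selection parameters for provenance.
#'
#' @param scores data frame from [select_frames()].
#' @param path output CSV path.
#' @param cap,min_spacing the parameters used, echoed into the header.
#' @return `path`, invisibly.
#' @export
write_frame_manifest <- function(scores, path, cap = 70L, min_spacing = 1L) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(sprintf(
    "# coralmesh %s frame manifest (cap = %d, min_spacing = %d)",
    as.character(utils::packageVersion("coralmesh")), cap, min_spacing), con)
  df <- scores[c("frame_id", "file", "sharpness", "selected")]
  df$sharpness <- formatC(df$sharpness, format = "g", digits = 10)
  utils::write.table(df, con, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Generate synthetic test frames
#'
#' Writes a stack of checkerboard PNG frames with per-frame Gaussian blur,
#' emulating a video sweep that drifts in and out of focus. Useful for
#' exercising the scoring and selection stages without real footage.
#'
#' @param dir output directory (created if needed).
#' @param n number of frames.
#' @param size image side length in pixels.
#' @param cell checkerboard cell size in pixels.
#' @param sigmas numeric vector recycled over frames: Gaussian blur sigma
#'   per frame (0 = sharp).
#' @return Invisibly, the written file paths.
#' @export
synthetic_frames <- function(dir, n = 20L, size = 64L, cell = 8L,
                             sigmas = 0) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  base <- checkerboard(size, cell)
  sigmas <- rep_len(sigmas, n)
  paths <- character(n)
  for (i in seq_len(n)) {
    img <- if (sigmas[i] > 0) gaussian_blur(base, sigmas[i]) else base
    paths[i] <- file.path(dir, sprintf("frame_%04d.png", i))
    png::writePNG(img, paths[i])
  }
  invisible(paths)
}

#' Checkerboard test pattern
#' @param size side length in pixels.
#' @param cell cell size in pixels.
#' @return `size x size` matrix of 0/1 values.
#' @export
checkerboard <- function(size = 64L, cell = 8L) {
  idx <- (seq_len(size) - 1L) %/% cell
  outer(idx, idx, function(a, b) as.numeric((a + b) %% 2L))
}

#' Gaussian blur of a grayscale image
#'
#' Separable Gaussian convolution with replicated edges; kernel radius
#' `ceiling(3 * sigma)`.
#'
#' @param img numeric matrix.
#' @param sigma standard deviation in pixels (> 0).
#' @return Blurred matrix of the same size.
#' @export
gaussian_blur <- function(img, sigma) {
  stopifnot(sigma > 0)
  r <- ceiling(3 * sigma)
  k <- stats::dnorm(-r:r, sd = sigma)
  k <- k / sum(k)
  pad_conv <- function(m) {
    # replicate-pad rows, convolve columns of the padded matrix with k
    top <- m[rep(1L, r), , drop = FALSE]
    bot <- m[rep(nrow(m), r), , drop = FALSE]
    mp <- rbind(top, m, bot)
    out <- matrix(0, nrow(m), ncol(m))
    for (j in seq_along(k))
      out <- out + k[j] * mp[j:(j + nrow(m) - 1L), , drop = FALSE]
    out
  }
  t(pad_conv(t(pad_conv(img))))
}
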