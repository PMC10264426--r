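#' Fundus image container
#'
#' A `fundus_image` is a plain list holding an `H x W x 3` numeric pixel array
#' with values in `[0, 1]`, an optional grade label, an id string, and (for
#' synthetic images) a data frame of ground-truth lesion records. Pixels are
#' stored row-major in the usual R array sense: `pixels[i, j, c]` is row `i`
#' (top to bottom), column `j` (left to right), channel `c` (R, G, B).
#'
#' @param pixels numeric `H x W x 3` array with finite values in `[0, 1]`.
#' @param label optional grade name (see [grade_levels()]).
#' @param id identifier string.
#' @param lesions optional data frame of lesion records
#'   (`type`, `row`, `col`, `radius`).
#' @return an object of class `fundus_image`.
#' @export
fundus_image <- function(pixels, label = NULL, id = "img", lesions = NULL) {
  if (!is.array(pixels) || length(dim(pixels)) != 3L || dim(pixels)[3] != 3L)
    stop("pixels must be an H x W x 3 array")
  if (!all(is.finite(pixels)))
    stop("pixels must be finite")
  if (min(pixels) < 0 || max(pixels) > 1)
    stop("pixels must lie in [0, 1]")
  if (!is.null(label)) label <- as.character(grade_factor(label))
  if (is.null(lesions))
    lesions <- data.frame(type = character(), row = numeric(),
                          col = numeric(), radius = numeric())
  structure(list(pixels = pixels, label = label, id = id, lesions = lesions),
            class = "fundus_image")
}

#' @export
print.fundus_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<fundus_image '%s'> %d x %d x %d, label = %s, %d lesion(s)\n",
              x$id, d[1], d[2], d[3],
              if (is.null(x$label)) "<none>" else x$label,
              nrow(x$lesions)))
  invisible(x)
}

#' @export
dim.fundus_image <- function(x) dim(x$pixels)

as_pixels <- function(x) {
  if (inherits(x, "fundus_image")) x$pixels else x
}

#' Read and write fundus images
#'
#' PNG input/output for fundus images. JPEG and TIFF files are read through
#' EBImage; writing always produces 8-bit RGB PNG.
#'
#' @param path file path.
#' @param label,id passed to [fundus_image()].
#' @return `read_fundus_png()` returns a `fundus_image`;
#'   `write_fundus_png()` returns `path` invisibly.
#' @export
read_fundus_png <- function(path, label = NULL, id = NULL) {
  if (is.null(id)) id <- tools::file_path_sans_ext(basename(path))
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    px <- png::readPNG(path)
  } else {
    img <- EBImage::readImage(path)
    px <- ebimage_to_pixels(img)
  }
  if (length(dim(px)) == 2L) px <- array(rep(px, 3L), c(dim(px), 3L))
  if (dim(px)[3] > 3L) px <- px[, , 1:3, drop = FALSE]
  fundus_image(pmin(pmax(px, 0), 1), label = label, id = id)
}

#' @rdname read_fundus_png
#' @param image a `fundus_image` or `H x W x 3` array.
#' @export
write_fundus_png <- function(image, path) {
  px <- as_pixels(image)
  # quantize to 8-bit so on-disk representation is the canonical one
  px <- round(pmin(pmax(px, 0), 1) * 255) / 255
  png::writePNG(px, target = path)
  invisible(path)
}

# EBImage stores Color images as x (width) by y (height); our arrays are
# H x W (row = y). Convert by transposing the two spatial dimensions.
pixels_to_ebimage <- function(px) {
  EBImage::Image(aperm(px, c(2L, 1L, 3L)), colormode = "Color")
}

ebimage_to_pixels <- function(img) {
  a <- EBImage::imageData(img)
  if (length(dim(a)) == 2L) t(a) else aperm(a, c(2L, 1L, 3L))
}

#' Bilinear image resizing
#'
#' Resamples an `H x W x 3` pixel array (or `fundus_image`) to a new spatial
#' size with bilinear interpolation. Used to build the low- (224 x 224) and
#' high-resolution (448 x 448) reconstruction targets of the scale-adaptive
#' auto-encoder.
#'
#' @param image a `fundus_image` or pixel array.
#' @param height,width target spatial size in pixels.
#' @return an `height x width x 3` array in `[0, 1]`.
#' @export
resize_bilinear <- function(image, height, width) {
  px <- as_pixels(image)
  out <- ebimage_to_pixels(EBImage::resize(pixels_to_ebimage(px),
                                           w = width, h = height,
                                           filter = "bilinear"))
  pmin(pmax(out, 0), 1)
}

#' Spatial transforms used for augmentation
#'
#' `flip_horizontal()` mirrors left-right, `flip_vertical()` mirrors
#' top-bottom, and `rotate_image()` rotates about the image center by an
#' arbitrary angle, keeping the original frame size and filling exposed
#' corners with black.
#'
#' @param image a `fundus_image` or pixel array.
#' @param degrees rotation angle in degrees (counter-clockwise).
#' @return a pixel array of the same shape as the input.
#' @export
flip_horizontal <- function(image) {
  px <- as_pixels(image)
  px[, rev(seq_len(dim(px)[2])), , drop = FALSE]
}

#' @rdname flip_horizontal
#' @export
flip_vertical <- function(image) {
  px <- as_pixels(image)
  px[rev(seq_len(dim(px)[1])), , , drop = FALSE]
}

#' @rdname flip_horizontal
#' @export
rotate_image <- function(image, degrees) {
  px <- as_pixels(image)
  d <- dim(px)
  img <- EBImage::rotate(pixels_to_ebimage(px), degrees,
                         filter = "bilinear",
                         output.dim = c(d[2], d[1]), bg.col = 0)
  out <- ebimage_to_pixels(img)
  pmin(pmax(out, 0), 1)
}
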