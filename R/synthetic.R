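#' Configuration for the synthetic fundus generator
#'
#' The generator emulates the gross appearance of a color fundus photograph —
#' a warm-toned circular retina disc on a dark background, an optic-disc
#' highlight and dark curvilinear vessels — plus grade-conditional lesions:
#' small bright yellowish drusen-like spots for intermediate AMD, one large
#' pale depigmented patch for geographic atrophy, and dark red
#' hemorrhage/fluid blobs for wet AMD. Lesion morphology is a synthetic
#' stand-in chosen so that grades are separable by image content; it is not a
#' clinical simulation.
#'
#' @param n_per_grade images generated per grade (default 216, the balanced
#'   per-grade count of the cohort the pipeline is sized for).
#' @param size_range integer vector `(min_h, min_w, max_h, max_w)`; image
#'   heights and widths are drawn uniformly within it. Minimum dimensions must
#'   be at least 224 and maxima at most 2224 x 1888; the default spans the
#'   size range of the modelled cohort (547 x 491 to 2224 x 1888).
#' @param lesion_params per-grade lesion settings; see Details. Partial lists
#'   are merged over the defaults.
#' @param seed integer seed; an identical config and seed reproduces the
#'   output set bit for bit.
#'
#' @details `lesion_params` is a list with entries
#' \describe{
#'   \item{INTERMEDIATE}{`spot_count` (length-2 range, default 10..30),
#'     `spot_radius` (fraction of disc radius, default 0.02..0.045),
#'     `spot_intensity` (additive brightness, default 0.45)}
#'   \item{GA}{`patch_radius` (fraction of disc radius, default 0.25..0.4),
#'     `patch_lightening` (default 0.3)}
#'   \item{WET}{`blob_count` (default 2..6), `blob_radius` (fraction of disc
#'     radius, default 0.06..0.14), `blob_darkness` (default 0.5)}
#' }
#' @return a `synthetic_config` list.
#' @export
synthetic_config <- function(n_per_grade = 216L,
                             size_range = c(547L, 491L, 2224L, 1888L),
                             lesion_params = list(),
                             seed = 0L) {
  if (n_per_grade < 1L) stop("n_per_grade must be positive")
  size_range <- as.integer(size_range)
  if (length(size_range) != 4L) stop("size_range must be (min_h, min_w, max_h, max_w)")
  if (size_range[1] < 224L || size_range[2] < 224L)
    stop("minimum image dimensions must be at least 224 px")
  if (size_range[3] > 2224L || size_range[4] > 1888L)
    stop("maximum image dimensions must be at most 2224 x 1888 px")
  if (size_range[3] < size_range[1] || size_range[4] < size_range[2])
    stop("size_range maxima must not be below minima")
  defaults <- list(
    INTERMEDIATE = list(spot_count = c(10L, 30L), spot_radius = c(0.02, 0.045),
                        spot_intensity = 0.45),
    GA   = list(patch_radius = c(0.25, 0.4), patch_lightening = 0.3),
    WET  = list(blob_count = c(2L, 6L), blob_radius = c(0.06, 0.14),
                blob_darkness = 0.5)
  )
  for (g in names(lesion_params)) {
    if (!g %in% names(defaults)) stop("unknown lesion_params grade: ", g)
    defaults[[g]] <- utils::modifyList(defaults[[g]], lesion_params[[g]])
  }
  structure(list(n_per_grade = as.integer(n_per_grade),
                 size_range = size_range,
                 lesion_params = defaults,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

# additive soft disc: gaussian-edged circle, vectorized over the pixel grid
soft_disc <- function(h, w, cr, cc, radius, softness = 1.5) {
  rr <- matrix(seq_len(h), h, w)
  cc_ <- matrix(seq_len(w), h, w, byrow = TRUE)
  d <- sqrt((rr - cr)^2 + (cc_ - cc)^2)
  1 / (1 + exp((d - radius) / softness))
}

#' Generate a single synthetic fundus image
#'
#' Draws a fundus-like image of the requested size with a retina disc of
#' radius about 45\% of the smaller dimension, an optic-disc highlight, at
#' least three vessel-like dark random-walk curves, and lesions conditioned on
#' `grade` (see [synthetic_config()]). Ground-truth lesion coordinates are
#' recorded in the returned object's `lesions` element.
#'
#' @param grade one of `"NORMAL"`, `"INTERMEDIATE"`, `"GA"`, `"WET"`.
#' @param height,width image size in pixels (positive; at least 224 to be
#'   usable by the scale-adaptive network).
#' @param rng_seed integer seed; identical calls are bit-identical.
#' @param lesion_params per-grade lesion settings as in [synthetic_config()].
#' @param id id string for the image.
#' @return a [fundus_image()] with the grade label and lesion records.
#' @examples
#' img <- generate_fundus("INTERMEDIATE", 300, 300, rng_seed = 7)
#' nrow(img$lesions)  # drusen-like spots, between 10 and 30
#' @export
generate_fundus <- function(grade, height, width, rng_seed = 0L,
                            lesion_params = synthetic_config()$lesion_params,
                            id = NULL) {
  grade <- as.character(grade_factor(grade))
  height <- as.integer(height); width <- as.integer(width)
  if (is.na(height) || is.na(width) || height <= 0L || width <= 0L)
    stop("height and width must be positive integers")
  if (is.null(id)) id <- sprintf("%s_%dx%d_s%d", tolower(grade), height, width, rng_seed)

  old <- local_rng(rng_seed)
  on.exit(restore_rng(old), add = TRUE)

  h <- height; w <- width
  cr <- h / 2 + stats::runif(1, -0.02, 0.02) * h
  cc <- w / 2 + stats::runif(1, -0.02, 0.02) * w
  disc_r <- 0.45 * min(h, w)

  disc <- soft_disc(h, w, cr, cc, disc_r, softness = 0.02 * disc_r)
  # radial shading: slightly darker toward the rim
  rr <- matrix(seq_len(h), h, w)
  ccm <- matrix(seq_len(w), h, w, byrow = TRUE)
  d <- sqrt((rr - cr)^2 + (ccm - cc)^2) / disc_r
  shade <- 1 - 0.25 * pmin(d, 1)^2

  base_rgb <- c(0.78, 0.38, 0.14) * stats::runif(1, 0.9, 1.1)
  px <- array(0.02, c(h, w, 3L))
  for (ch in 1:3)
    px[, , ch] <- px[, , ch] + disc * shade * min(base_rgb[ch], 1)

  # optic disc: bright yellowish highlight offset along the horizontal axis
  od_c <- cc + sample(c(-1, 1), 1) * stats::runif(1, 0.45, 0.6) * disc_r
  od_r <- cr + stats::runif(1, -0.1, 0.1) * disc_r
  od <- soft_disc(h, w, od_r, od_c, 0.12 * disc_r, softness = 0.03 * disc_r)
  od_gain <- c(0.2, 0.45, 0.35)
  for (ch in 1:3) px[, , ch] <- px[, , ch] + od * od_gain[ch] * disc

  # vessels: dark red random walks radiating from the optic disc
  n_vessels <- sample(3:6, 1)
  vessel <- matrix(0, h, w)
  for (v in seq_len(n_vessels)) {
    ang <- stats::runif(1, 0, 2 * pi)
    pos <- c(od_r, od_c)
    step <- 0.012 * disc_r
    for (s in seq_len(220)) {
      ang <- ang + stats::rnorm(1, 0, 0.25)
      pos <- pos + step * c(sin(ang), cos(ang))
      if (sqrt((pos[1] - cr)^2 + (pos[2] - cc)^2) > 0.92 * disc_r) break
      r0 <- max(1L, round(pos[1])); c0 <- max(1L, round(pos[2]))
      if (r0 > h || c0 > w) break
      wdt <- max(1L, round(0.012 * disc_r * (1 - s / 260)))
      ri <- max(1L, r0 - wdt):min(h, r0 + wdt)
      ci <- max(1L, c0 - wdt):min(w, c0 + wdt)
      vessel[ri, ci] <- pmax(vessel[ri, ci], 0.8)
    }
  }
  for (ch in 1:3)
    px[, , ch] <- px[, , ch] - vessel * disc * c(0.25, 0.22, 0.08)[ch]

  lesions <- data.frame(type = character(), row = numeric(),
                        col = numeric(), radius = numeric())
  add_lesion <- function(type, r0, c0, rad) {
    lesions <<- rbind(lesions, data.frame(type = type, row = r0,
                                          col = c0, radius = rad))
  }
  rand_in_disc <- function(max_frac = 0.75) {
    th <- stats::runif(1, 0, 2 * pi)
    rd <- disc_r * max_frac * sqrt(stats::runif(1))
    c(cr + rd * sin(th), cc + rd * cos(th))
  }

  if (grade == "INTERMEDIATE") {
    p <- lesion_params$INTERMEDIATE
    n_spots <- sample(p$spot_count[1]:p$spot_count[2], 1)
    for (s in seq_len(n_spots)) {
      ctr <- rand_in_disc(0.7)
      rad <- disc_r * stats::runif(1, p$spot_radius[1], p$spot_radius[2])
      m <- soft_disc(h, w, ctr[1], ctr[2], rad, softness = max(0.5, 0.3 * rad))
      gain <- p$spot_intensity * c(0.9, 0.85, 0.35)
      for (ch in 1:3) px[, , ch] <- px[, , ch] + m * gain[ch]
      add_lesion("drusen", ctr[1], ctr[2], rad)
    }
  } else if (grade == "GA") {
    p <- lesion_params$GA
    ctr <- rand_in_disc(0.35)
    rad <- disc_r * stats::runif(1, p$patch_radius[1], p$patch_radius[2])
    m <- soft_disc(h, w, ctr[1], ctr[2], rad, softness = 0.1 * rad)
    gain <- p$patch_lightening * c(0.6, 0.9, 1.1)
    for (ch in 1:3) px[, , ch] <- px[, , ch] + m * gain[ch]
    add_lesion("atrophy", ctr[1], ctr[2], rad)
  } else if (grade == "WET") {
    p <- lesion_params$WET
    n_blobs <- sample(p$blob_count[1]:p$blob_count[2], 1)
    for (s in seq_len(n_blobs)) {
      ctr <- rand_in_disc(0.6)
      rad <- disc_r * stats::runif(1, p$blob_radius[1], p$blob_radius[2])
      m <- soft_disc(h, w, ctr[1], ctr[2], rad, softness = 0.2 * rad)
      gain <- p$blob_darkness * c(0.55, 0.85, 0.3)
      for (ch in 1:3) px[, , ch] <- px[, , ch] - m * gain[ch]
      add_lesion("hemorrhage", ctr[1], ctr[2], rad)
    }
  }

  # mild sensor noise, then clip to the valid range
  px <- px + array(stats::rnorm(h * w * 3L, 0, 0.01), c(h, w, 3L))
  px <- pmin(pmax(px, 0), 1)
  fundus_image(px, label = grade, id = id, lesions = lesions)
}

#' Generate a labelled synthetic dataset on disk
#'
#' Writes `n_per_grade` 8-bit RGB PNG files per grade, with sizes drawn
#' uniformly from the configured range, plus a CSV manifest with columns
#' `id,filename,grade,height,width`. The whole set is a deterministic
#' function of the config (including its seed).
#'
#' @param config a [synthetic_config()].
#' @param out_dir output directory (created if missing).
#' @return the manifest as a data frame (invisibly also written to
#'   `manifest.csv` in `out_dir`).
#' @export
generate_dataset <- function(config, out_dir) {
  stopifnot(inherits(config, "synthetic_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir) || file.access(out_dir, 2L) != 0L)
    stop("output directory is not writable: ", out_dir)

  old <- local_rng(config$seed)
  on.exit(restore_rng(old), add = TRUE)

  grades <- grade_levels()
  sr <- config$size_range
  rows <- vector("list", 4L * config$n_per_grade)
  k <- 0L
  for (g in grades) {
    for (i in seq_len(config$n_per_grade)) {
      h <- sample(sr[1]:sr[3], 1)
      w <- sample(sr[2]:sr[4], 1)
      img_seed <- sample.int(.Machine$integer.max, 1)
      id <- sprintf("%s_%03d", tolower(g), i)
      img <- generate_fundus(g, h, w, rng_seed = img_seed,
                             lesion_params = config$lesion_params, id = id)
      fn <- paste0(id, ".png")
      write_fundus_png(img, file.path(out_dir, fn))
      k <- k + 1L
      rows[[k]] <- data.frame(id = id, filename = fn, grade = g,
                              height = h, width = w)
    }
  }
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE, quote = FALSE)
  manifest
}

#' Read a dataset manifest
#'
#' @param path path to a `manifest.csv` written by [generate_dataset()], or a
#'   directory containing one.
#' @return the manifest data frame with an attribute `dir` giving the image
#'   directory.
#' @export
read_manifest <- function(path) {
  if (dir.exists(path)) path <- file.path(path, "manifest.csv")
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "filename", "grade", "height", "width")
  if (!all(need %in% names(m)))
    stop("manifest must have columns ", paste(need, collapse = ","))
  attr(m, "dir") <- dirname(normalizePath(path))
  m
}
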