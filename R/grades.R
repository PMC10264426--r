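#' AMD grade labels
#'
#' The four-grade AMD scale used throughout the package: a normal (no-AMD)
#' retina, intermediate dry AMD, geographic atrophy (GA, late dry AMD) and
#' wet (neovascular) AMD. The canonical ordering `NORMAL`, `INTERMEDIATE`,
#' `GA`, `WET` maps onto one-hot indices 0..3 and is used for every label
#' vector, confusion matrix and softmax output in the package. An alternative
#' ordering can be supplied wherever labels are consumed, but the default is
#' this one.
#'
#' @param order character vector giving an alternative permutation of the four
#'   grade names; defaults to the canonical order.
#' @return `grade_levels()` returns the ordered character vector of grade
#'   names; `grade_factor()` returns a factor with those levels.
#' @examples
#' grade_levels()
#' grade_index("GA")   # 2 (zero-based one-hot index)
#' @export
grade_levels <- function(order = NULL) {
  canonical <- c("NORMAL", "INTERMEDIATE", "GA", "WET")
  if (is.null(order)) return(canonical)
  order <- toupper(order)
  if (length(order) != 4L || !setequal(order, canonical))
    stop("grade order must be a permutation of ", paste(canonical, collapse = ", "))
  order
}

#' @rdname grade_levels
#' @param x character or factor vector of grade names.
#' @export
grade_factor <- function(x, order = NULL) {
  lev <- grade_levels(order)
  x <- toupper(as.character(x))
  bad <- setdiff(unique(x), lev)
  if (length(bad))
    stop("unknown grade label(s): ", paste(bad, collapse = ", "))
  factor(x, levels = lev)
}

#' @rdname grade_levels
#' @export
grade_index <- function(x, order = NULL) {
  as.integer(grade_factor(x, order)) - 1L
}

#' @rdname grade_levels
#' @param i zero-based one-hot index in 0..3.
#' @export
grade_from_index <- function(i, order = NULL) {
  lev <- grade_levels(order)
  i <- as.integer(i)
  if (any(i < 0L | i > 3L)) stop("grade index must be in 0..3")
  lev[i + 1L]
}

#' One-hot encode grade labels
#'
#' @param x character or factor vector of grade names.
#' @param order optional alternative grade ordering.
#' @return an `length(x) x 4` 0/1 matrix with one 1 per row.
#' @export
grade_one_hot <- function(x, order = NULL) {
  f <- grade_factor(x, order)
  m <- matrix(0, length(f), 4L, dimnames = list(NULL, levels(f)))
  m[cbind(seq_along(f), as.integer(f))] <- 1
  m
}
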