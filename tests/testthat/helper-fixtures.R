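# Shared fixtures, generated once per test run. Sizes are kept small so the
# whole suite stays CPU-friendly; larger geometries are exercised in the
# dedicated shape tests.

fixture_env <- new.env()

# a small balanced image set (2 per grade) at mixed sizes >= 224
fixture_images <- function() {
  if (is.null(fixture_env$imgs)) {
    grades <- rep(grade_levels(), each = 2)
    sizes <- rbind(c(224, 224), c(232, 240), c(240, 224), c(224, 248),
                   c(236, 236), c(224, 232), c(248, 224), c(228, 244))
    fixture_env$imgs <- lapply(seq_along(grades), function(i)
      generate_fundus(grades[i], sizes[i, 1], sizes[i, 2], rng_seed = 400 + i))
  }
  fixture_env$imgs
}

# a tiny SA architecture used where only mechanics (not quality) matter
tiny_sa <- function(seed = 0) {
  build_sa(sa_architecture(filters = c(4L, 6L), branch_filters = c(4L, 4L)),
           seed = seed)
}

random_image <- function(h, w, seed = 1) {
  withr::with_seed(seed, array(runif(h * w * 3), c(h, w, 3)))
}
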