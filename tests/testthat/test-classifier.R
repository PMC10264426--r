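test_that("the classifier graph ends in 4 softmax units with normalized output", {
  clf <- build_classifier("TINY", head_config(c(8L, 8L, 8L)), seed = 0)
  img <- random_image(224, 224, seed = 1)
  pred <- predict_grade(clf, NULL, img)
  expect_length(pred$probs, 4L)
  expect_equal(sum(pred$probs), 1, tolerance = 1e-5)
  expect_true(all(pred$probs >= 0))
  expect_true(pred$label %in% grade_levels())
})

test_that("head parameter counts follow the closed-form arithmetic", {
  # widths (a, b, c) on an F-dim pooled feature:
  # (Fa + a + 4a) + (ab + b + 4b) + (bc + c + 4c) + (4c + 4),
  # batch norm contributing 4 parameters per unit (2 trainable + 2 stats)
  clf <- build_classifier("TINY", head_config(c(8L, 8L, 8L)), seed = 0)
  F_ <- clf$feature_dim
  a <- 8; b <- 8; c_ <- 8
  expected <- (F_ * a + a + 4 * a) + (a * b + b + 4 * b) +
    (b * c_ + c_ + 4 * c_) + (4 * c_ + 4)
  expect_identical(clf$param_counts$head_total, as.numeric(expected))
  # trainable excludes the 2 running-stat entries per batch-norm unit
  expect_identical(clf$param_counts$head_trainable,
                   as.numeric(expected - 2 * (a + b + c_)))
})

test_that("seed-fixed builds give identical head weights; unknown backbones fail", {
  a <- build_classifier("TINY", seed = 3)
  b <- build_classifier("TINY", seed = 3)
  expect_identical(fundusSA:::collect_params(a$head_layers),
                   fundusSA:::collect_params(b$head_layers))
  expect_error(build_classifier("ALEXNET"), "configuration error")
  expect_error(head_config(c(10, 10)), "exactly 3")
})

test_that("resnet50 builds and forwards a 224 image to 4 normalized probabilities", {
  clf <- build_classifier("RESNET50", head_config(c(16L, 16L, 16L)), seed = 0)
  expect_identical(clf$feature_dim, 2048L)
  pred <- predict_grade(clf, NULL, random_image(224, 224, seed = 4))
  expect_equal(sum(pred$probs), 1, tolerance = 1e-5)
})

test_that("augmentation quadruples an image and flips are involutions", {
  px <- random_image(64, 48, seed = 5)
  out <- augment(px)
  expect_length(out, 4L)
  expect_identical(flip_horizontal(flip_horizontal(px)), px)
  expect_identical(flip_vertical(flip_vertical(px)), px)
  # rotation keeps the frame size
  expect_identical(dim(out[[2]]), dim(px))
  # all copies carry the same label distribution implicitly (same image)
  expect_identical(out[[1]], px)
})

test_that("stratified split reproduces the 70/15/15 arithmetic at 216 per grade", {
  manifest <- data.frame(
    id = sprintf("img%04d", 1:864),
    grade = rep(grade_levels(), each = 216),
    stringsAsFactors = FALSE)
  sp <- stratified_split(manifest, c(0.70, 0.15, 0.15), seed = 1)
  n_train <- sum(sp$split == "train")
  expect_true(n_train %in% c(604L, 605L))
  per_grade <- table(sp$grade[sp$split == "train"])
  expect_true(all(per_grade >= 151 & per_grade <= 152))
  # proportions preserved within one sample per grade
  expect_true(all(abs(per_grade - 0.7 * 216) <= 1))
  # partition is exact
  expect_identical(sort(unique(sp$split)), c("test", "train", "val"))
  expect_identical(nrow(sp), 864L)
})

test_that("reduce-on-plateau halts improvement-free runs into strict decay", {
  st <- plateau_init(0.001, factor = 0.1, patience = 1)
  st <- plateau_update(st, 1.0)  # first observation sets the best
  lrs <- numeric(4)
  for (i in 1:4) {
    st <- plateau_update(st, 1.0)  # frozen metric
    lrs[i] <- st$lr
  }
  expect_true(all(diff(lrs) < 0))
  expect_equal(lrs[1], 1e-4)
  # an improving metric keeps the rate
  st2 <- plateau_init(0.001, factor = 0.1, patience = 2)
  for (m in c(1.0, 0.9, 0.8)) st2 <- plateau_update(st2, m)
  expect_equal(st2$lr, 0.001)
})

test_that("the head trains downhill on seeded synthetic images and beats chance", {
  imgs <- fixture_images()
  manifest <- data.frame(
    id = vapply(imgs, `[[`, "", "id"),
    filename = NA_character_,
    grade = vapply(imgs, `[[`, "", "label"),
    height = NA_integer_, width = NA_integer_,
    stringsAsFactors = FALSE)
  manifest$split <- "train"  # tiny set: train on everything
  cfg <- clf_train_config(backbone = "TINY", epochs = 6, batch_size = 8,
                          initial_lr = 0.01, head = head_config(c(16L, 16L, 16L)),
                          seed = 0)
  fit <- train_classifier(manifest, NULL, cfg, images = imgs)
  h <- fit$history
  tr <- h[h$split == "train", ]
  expect_lt(tr$loss[nrow(tr)], tr$loss[1])
  expect_gt(tr$accuracy[nrow(tr)], 0.25)
  expect_identical(names(h), c("epoch", "split", "loss", "accuracy", "lr"))
})

test_that("prediction ties resolve to the lowest grade index", {
  clf <- build_classifier("TINY", head_config(c(4L, 4L, 4L)), seed = 0)
  # zero the output layer so all logits tie exactly
  params <- fundusSA:::collect_params(clf$head_layers)
  params$head_out.W[] <- 0
  params$head_out.b[] <- 0
  clf$head_layers <- fundusSA:::assign_params(clf$head_layers, params)
  pred <- predict_grade(clf, NULL, random_image(224, 224, seed = 6))
  expect_equal(unname(pred$probs), rep(0.25, 4), tolerance = 1e-12)
  expect_identical(pred$label, "NORMAL")
  # a bias toward the third unit predicts GA
  params$head_out.b[3] <- 5
  clf$head_layers <- fundusSA:::assign_params(clf$head_layers, params)
  expect_identical(predict_grade(clf, NULL, random_image(224, 224, seed = 6))$label,
                   "GA")
})

test_that("a missing grade in the training split raises a stratification error", {
  manifest <- data.frame(id = c("a", "b"), filename = NA, grade = c("NORMAL", "GA"),
                         height = NA, width = NA, split = c("train", "test"))
  expect_error(train_classifier(manifest, NULL, clf_train_config(backbone = "TINY")),
               "stratification")
})
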