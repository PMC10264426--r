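#' Default run configuration
#'
#' The nested configuration binding the whole pipeline: synthetic data
#' generation (`synth`), scale-adaptive training (`sa`), classifier training
#' (`clf`) and evaluation (`eval`), plus one global seed from which every
#' stage derives its own seed deterministically. Defaults mirror the
#' published training recipes (Adam 0.001 / 100 epochs / batch 1 for the
#' auto-encoder with loss weights 0.25 and 0.075; SGD from 0.001 with
#' reduce-on-plateau, 300 epochs, batch 64, 70/30 split for the classifier).
#'
#' @return a nested list of configuration sections.
#' @export
default_run_config <- function() {
  list(
    seed = 0L,
    synth = list(
      n_per_grade = 216L,
      size_range = c(547L, 491L, 2224L, 1888L)
    ),
    sa = list(
      arch = list(latent_grid = c(112L, 112L), kernel = 3L,
                  filters = c(16L, 32L), branch_filters = c(16L, 16L)),
      train = list(optimizer = "ADAM", learning_rate = 0.001,
                   epochs = 100L, batch_size = 1L, max_images = NULL),
      loss = list(high_loss = "PSEUDO_HUBER", low_loss = "LOG_COSH",
                  w_high = 0.25, w_low = 0.075, delta = 1.0)
    ),
    clf = list(
      backbone = "RESNET50", pretrained = FALSE, optimizer = "SGD",
      initial_lr = 0.001,
      plateau = list(factor = 0.1, patience = 10L, min_lr = 1e-6),
      epochs = 300L, batch_size = 64L, split = c(0.70, 0.15, 0.15),
      head = list(dense_widths = c(1024L, 512L, 256L), dropout_rate = 0.5),
      augmentation = list(rotation_deg = 50, hflip = TRUE, vflip = TRUE)
    ),
    eval = list(k = c(10L, 5L, 3L), cv_epochs = 5L, output_dir = "runs")
  )
}

# recursive merge that rejects keys absent from the defaults, reporting the
# offending key by its dotted path
merge_config <- function(defaults, user, path = character()) {
  if (is.null(user)) return(defaults)
  if (!is.list(user) || !is.list(defaults)) return(user)
  for (key in names(user)) {
    here <- paste(c(path, key), collapse = ".")
    if (!key %in% names(defaults))
      stop("unknown configuration key: ", here)
    if (is.null(user[[key]])) next  # YAML null: keep the default
    if (is.list(defaults[[key]]) && !is.null(names(defaults[[key]]))) {
      defaults[[key]] <- merge_config(defaults[[key]], user[[key]],
                                      c(path, key))
    } else {
      defaults[[key]] <- user[[key]]
    }
  }
  defaults
}

validate_run_config <- function(cfg) {
  chk <- function(ok, key, msg) if (!ok) stop("invalid value for ", key, ": ", msg)
  chk(cfg$sa$train$learning_rate >= 0, "sa.train.learning_rate", "must be nonnegative")
  chk(cfg$sa$loss$w_high > 0, "sa.loss.w_high", "must be positive")
  chk(cfg$sa$loss$w_low > 0, "sa.loss.w_low", "must be positive")
  chk(cfg$sa$loss$delta > 0, "sa.loss.delta", "must be positive")
  chk(toupper(cfg$sa$loss$high_loss) %in%
        c("MSE", "MSLE", "PSEUDO_HUBER", "LOG_COSH"),
      "sa.loss.high_loss", "unknown loss name")
  chk(toupper(cfg$sa$loss$low_loss) %in%
        c("MSE", "MSLE", "PSEUDO_HUBER", "LOG_COSH"),
      "sa.loss.low_loss", "unknown loss name")
  chk(toupper(cfg$clf$backbone) %in% backbone_names(),
      "clf.backbone", "unknown backbone")
  chk(cfg$clf$initial_lr > 0, "clf.initial_lr", "must be positive")
  chk(abs(sum(cfg$clf$split) - 1) < 1e-8, "clf.split", "fractions must sum to 1")
  chk(cfg$synth$n_per_grade >= 1, "synth.n_per_grade", "must be positive")
  chk(all(cfg$eval$k >= 2), "eval.k", "fold counts must be >= 2")
  cfg
}

#' Read, validate and write run configurations
#'
#' `parse_run_config()` reads a YAML file, fills every missing key with its
#' documented default, rejects unknown keys by name, and validates values
#' (e.g. negative learning rates or loss weights, unknown enum names). An
#' empty file yields the full default configuration.
#' `serialize_run_config()` writes a configuration back to YAML;
#' serializing a parsed file and re-parsing it is the identity.
#'
#' @param path YAML file path.
#' @return the validated configuration list.
#' @export
parse_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  user <- yaml::read_yaml(path)
  cfg <- merge_config(default_run_config(), user)
  validate_run_config(cfg)
}

#' @rdname parse_run_config
#' @param config a configuration list.
#' @export
serialize_run_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

config_to_sa <- function(cfg) {
  list(arch = sa_architecture(cfg$sa$arch$latent_grid, cfg$sa$arch$kernel,
                              cfg$sa$arch$filters, cfg$sa$arch$branch_filters),
       train = sa_train_config(cfg$sa$train$optimizer,
                               cfg$sa$train$learning_rate,
                               cfg$sa$train$epochs, cfg$sa$train$batch_size,
                               loss = sa_loss_config(cfg$sa$loss$high_loss,
                                                     cfg$sa$loss$low_loss,
                                                     cfg$sa$loss$w_high,
                                                     cfg$sa$loss$w_low,
                                                     cfg$sa$loss$delta),
                               seed = derive_seed(cfg$seed, 2L)))
}

config_to_clf <- function(cfg) {
  clf_train_config(backbone = cfg$clf$backbone, pretrained = cfg$clf$pretrained,
                   optimizer = cfg$clf$optimizer,
                   initial_lr = cfg$clf$initial_lr, plateau = cfg$clf$plateau,
                   epochs = cfg$clf$epochs, batch_size = cfg$clf$batch_size,
                   split = cfg$clf$split,
                   augmentation = augmentation_spec(
                     cfg$clf$augmentation$rotation_deg,
                     cfg$clf$augmentation$hflip, cfg$clf$augmentation$vflip),
                   head = head_config(cfg$clf$head$dense_widths,
                                      cfg$clf$head$dropout_rate),
                   seed = derive_seed(cfg$seed, 4L))
}
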