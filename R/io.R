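#' Read and write half-images as plain PGM
#'
#' Contrast images are stored as portable graymaps (plain text, magic `P2`):
#' background 128, dark dots 0, bright dots 255. The mapping is lossless for
#' ternary contrast images.
#'
#' @param img An integer contrast matrix with values in `{-1, 0, +1}`.
#' @param path File path.
#' @return `read_pgm()` returns an integer contrast matrix; `write_pgm()`
#'   returns `path` invisibly.
#' @export
write_pgm <- function(img, path) {
  gray <- matrix(c(0L, 128L, 255L)[img + 2L], nrow(img), ncol(img))
  lines <- c("P2", sprintf("%d %d", ncol(img), nrow(img)), "255",
             apply(gray, 1, paste, collapse = " "))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_pgm
#' @export
read_pgm <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines)]
  if (lines[1] != "P2") abort("only plain (P2) PGM files are supported")
  vals <- scan(text = paste(lines[-1], collapse = " "), what = integer(),
               quiet = TRUE)
  w <- vals[1]; h <- vals[2]; maxval <- vals[3]
  px <- vals[-(1:3)]
  if (length(px) != w * h) abort("corrupt PGM: pixel count mismatch")
  contrast <- integer(length(px))
  contrast[px < maxval / 3] <- -1L
  contrast[px > 2 * maxval / 3] <- 1L
  matrix(contrast, h, w, byrow = TRUE)
}

#' Export and import a stereo pair
#'
#' Writes `<stem>_left.pgm`, `<stem>_right.pgm` and, when the pair carries a
#' generating spec, a `<stem>_spec.yml` sidecar from which the stimulus can
#' be regenerated.
#'
#' @param pair A `stereo_pair`.
#' @param stem Output path stem.
#' @return `export_stereo_pair()` returns the written paths invisibly;
#'   `import_stereo_pair()` returns a `stereo_pair`.
#' @export
export_stereo_pair <- function(pair, stem) {
  paths <- c(left = paste0(stem, "_left.pgm"),
             right = paste0(stem, "_right.pgm"))
  write_pgm(pair$left, paths[["left"]])
  write_pgm(pair$right, paths[["right"]])
  if (!is.null(pair$spec)) {
    sidecar <- paste0(stem, "_spec.yml")
    yaml::write_yaml(unclass(pair$spec), sidecar)
    paths <- c(paths, spec = sidecar)
  }
  invisible(paths)
}

#' @rdname export_stereo_pair
#' @export
import_stereo_pair <- function(stem) {
  pair <- stereo_pair(read_pgm(paste0(stem, "_left.pgm")),
                      read_pgm(paste0(stem, "_right.pgm")))
  sidecar <- paste0(stem, "_spec.yml")
  if (file.exists(sidecar))
    pair$spec <- do.call(rds_spec, yaml::read_yaml(sidecar))
  pair
}

#' Write a result table as delimited text
#'
#' @param x A tibble or any result object with a [tidy()] method.
#' @param path Output path.
#' @param sep Field separator.
#' @return `path`, invisibly.
#' @export
write_result_tsv <- function(x, path, sep = "\t") {
  df <- if (inherits(x, c("tuning_curve", "psychometric_curve",
                          "operator_distribution"))) tidy(x)
        else as.data.frame(x)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Experiment configuration
#'
#' A flat key-value parameter set, serialized as YAML, covering stimulus
#' geometry, decision stage, Gabor detectors, analysis grids and the seed.
#' Defaults are the package's standard study conditions. Unknown keys are an
#' error, so a typo cannot silently change an experiment.
#'
#' @return `default_config()`: a named list of class `experiment_config`.
#' @export
default_config <- function() {
  structure(list(
    center_size = 32L, surround_size = 34L, dot_density = 0.25,
    binocular_correlation = 1, stimulus_disparity = -2L,
    image_size = 24L, dot_size = 8L, dot_disparity = -8L,
    frames_per_trial = 16L, noise_sigma = NA_real_,
    trials_per_side = 30L, n_blocks = 20L,
    gabor_sigma = 0.05, gabor_freq = 10, pixel_pitch = 0.0175,
    gabor_amplitude = 14,
    c_min = -1, c_max = 1, c_step = 0.1,
    rho_min = 0.05, rho_max = 1, rho_step = 0.05,
    n_patterns = 1000L, n_runs = 200L,
    n_frames = 1000L, disparity_range = 4L,
    seed = 1L), class = "experiment_config")
}

#' @rdname default_config
#' @param path YAML file path.
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  cfg <- default_config()
  unknown <- setdiff(names(vals), names(cfg))
  if (length(unknown))
    abort(paste0("unknown config keys: ", paste(unknown, collapse = ", ")))
  cfg[names(vals)] <- vals
  cfg
}

#' @rdname default_config
#' @param cfg An `experiment_config`.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

config_hash <- function(cfg) rlang::hash(unclass(cfg))
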