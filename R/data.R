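#' Construct one multivariate time-series instance
#'
#' @param instance_id Character scalar identifier.
#' @param channels List of numeric vectors, all of one common length
#'   (within an instance every sensor shares the time axis).
#' @param label Class label, 0 (normal) or 1 (abnormal).
#' @return An `mts_instance` list with fields `instance_id`, `channels`,
#'   `label`.
#' @export
mts_instance <- function(instance_id, channels, label) {
  if (!is.list(channels) || length(channels) < 1L)
    stop("channels must be a non-empty list of numeric vectors", call. = FALSE)
  lens <- lengths(channels)
  if (length(unique(lens)) != 1L)
    stop(sprintf("instance '%s': channels have unequal lengths (%s)",
                 instance_id, paste(lens, collapse = ", ")), call. = FALSE)
  if (!label %in% c(0, 1)) stop("label must be 0 or 1", call. = FALSE)
  structure(list(instance_id = as.character(instance_id),
                 channels = lapply(channels, as.numeric),
                 label = as.integer(label)),
            class = "mts_instance")
}

#' Construct a multivariate time-series dataset
#'
#' @param instances List of [mts_instance()] objects, all with the same
#'   number of channels (lengths may differ across instances).
#' @param name Dataset name.
#' @return An `mts_dataset` list with fields `instances`, `m`, `name`.
#' @export
mts_dataset <- function(instances, name = "dataset") {
  if (!is.list(instances) || length(instances) < 1L)
    stop("empty dataset: no instances", call. = FALSE)
  ms <- vapply(instances, function(i) length(i$channels), integer(1))
  if (length(unique(ms)) != 1L)
    stop("all instances must have the same number of channels", call. = FALSE)
  structure(list(instances = instances, m = ms[1], name = name),
            class = "mts_dataset")
}

#' @export
print.mts_dataset <- function(x, ...) {
  lens <- vapply(x$instances, function(i) length(i$channels[[1]]), integer(1))
  labs <- dataset_labels(x)
  cat(sprintf("<mts_dataset> '%s': %d instances, %d channel(s), lengths %d-%d, labels 0/1 = %d/%d\n",
              x$name, length(x$instances), x$m, min(lens), max(lens),
              sum(labs == 0), sum(labs == 1)))
  invisible(x)
}

#' Extract the label vector of a dataset
#' @param dataset An `mts_dataset`.
#' @return Integer vector of 0/1 labels, one per instance.
#' @export
dataset_labels <- function(dataset) {
  vapply(dataset$instances, `[[`, integer(1), "label")
}

#' Read a dataset from the long CSV interchange format
#'
#' The canonical on-disk format is a comma-delimited file with header
#' `instance_id,channel,t,value,label`: one row per (instance, channel,
#' timestep), `t` 1-based and consecutive within each (instance, channel).
#' Channel lengths must agree within an instance; labels must be constant
#' per instance and binary.
#'
#' @param path CSV file path.
#' @param name Dataset name (defaults to the file name).
#' @return An `mts_dataset`.
#' @export
read_long_csv <- function(path, name = basename(path)) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  required <- c("instance_id", "channel", "t", "value", "label")
  if (!all(required %in% names(df)))
    stop("long CSV must have columns instance_id, channel, t, value, label",
         call. = FALSE)
  if (any(is.na(df$label)))
    stop("missing label in long CSV", call. = FALSE)
  ids <- unique(df$instance_id)
  instances <- lapply(ids, function(id) {
    sub <- df[df$instance_id == id, , drop = FALSE]
    lab <- unique(sub$label)
    if (length(lab) != 1L)
      stop(sprintf("instance '%s' has conflicting labels", id), call. = FALSE)
    chans <- lapply(split(sub, sub$channel), function(s) {
      s <- s[order(s$t), , drop = FALSE]
      if (!identical(as.integer(s$t), seq_len(nrow(s))))
        stop(sprintf("instance '%s': t must be 1-based consecutive", id),
             call. = FALSE)
      s$value
    })
    lens <- lengths(chans)
    if (length(unique(lens)) != 1L)
      stop(sprintf("instance '%s': ragged channels (lengths %s)",
                   id, paste(lens, collapse = ", ")), call. = FALSE)
    mts_instance(id, unname(chans), lab)
  })
  mts_dataset(instances, name = name)
}

#' Write a dataset in the long CSV interchange format
#'
#' @param dataset An `mts_dataset`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_long_csv <- function(dataset, path) {
  rows <- lapply(dataset$instances, function(inst) {
    Tn <- length(inst$channels[[1]])
    do.call(rbind, lapply(seq_along(inst$channels), function(c) {
      data.frame(instance_id = inst$instance_id, channel = c, t = seq_len(Tn),
                 value = inst$channels[[c]], label = inst$label)
    }))
  })
  write.csv(do.call(rbind, rows), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a dataset stored as one whitespace-delimited matrix per instance
#'
#' Each file holds `T` rows by `m` columns (one column per sensor) and the
#' label is encoded in the file name suffix `_normal` / `_abnormal`
#' (e.g. `w007_abnormal.txt`). All files must agree on the column count.
#'
#' @param directory Directory containing the instance files.
#' @param pattern File name pattern (default `\\.txt$`).
#' @return An `mts_dataset`.
#' @export
read_instance_matrices <- function(directory, pattern = "\\.txt$") {
  files <- sort(list.files(directory, pattern = pattern, full.names = TRUE))
  if (length(files) == 0L)
    stop("empty dataset: no instance files in ", directory, call. = FALSE)
  instances <- lapply(files, function(f) {
    base <- sub("\\.[^.]*$", "", basename(f))
    lab <- if (grepl("_abnormal$", base)) 1L
           else if (grepl("_normal$", base)) 0L
           else stop("file name must end in _normal or _abnormal: ", basename(f),
                     call. = FALSE)
    mat <- as.matrix(read.table(f, header = FALSE))
    mts_instance(sub("_(normal|abnormal)$", "", base),
                 lapply(seq_len(ncol(mat)), function(c) unname(mat[, c])), lab)
  })
  ms <- vapply(instances, function(i) length(i$channels), integer(1))
  if (length(unique(ms)) != 1L)
    stop("inconsistent column counts across instance files", call. = FALSE)
  mts_dataset(instances, name = basename(directory))
}

#' Write a dataset as per-instance matrix files
#'
#' Inverse of [read_instance_matrices()].
#' @param dataset An `mts_dataset`.
#' @param directory Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_instance_matrices <- function(dataset, directory) {
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  for (inst in dataset$instances) {
    suffix <- if (inst$label == 1L) "abnormal" else "normal"
    mat <- do.call(cbind, inst$channels)
    write.table(mat, file.path(directory,
                               sprintf("%s_%s.txt", inst$instance_id, suffix)),
                row.names = FALSE, col.names = FALSE)
  }
  invisible(directory)
}

#' Configuration for the synthetic wafer-like generator
#'
#' Defaults mirror the shape of the six-sensor wafer benchmark: per-instance
#' lengths drawn uniformly from 104..198 time steps, channels sharing one
#' length within an instance, and an abnormal class marked by a downward
#' level shift plus two transient spikes on top of a smooth low-frequency
#' baseline.
#'
#' @param n_instances Number of instances to generate.
#' @param m Number of sensor channels per instance.
#' @param length_range Integer pair `(Tmin, Tmax)`, `Tmin >= 8`.
#' @param spike_amplitude Height of each transient spike added to abnormal
#'   instances (same units as the baseline, whose amplitude is about 1).
#' @param level_shift Downward level shift applied to abnormal instances.
#' @param noise_sd Standard deviation of the additive Gaussian noise.
#' @param n_spikes Number of spikes per abnormal channel.
#' @param class_balance Fraction of instances labelled 0 (normal), in (0, 1).
#' @param seed Integer seed; one seed yields one bit-stable dataset.
#' @return A `synth_config` list.
#' @export
synth_config <- function(n_instances = 120L, m = 6L,
                         length_range = c(104L, 198L),
                         spike_amplitude = 2, level_shift = 1,
                         noise_sd = 0.1, n_spikes = 2L,
                         class_balance = 0.5, seed = 1L) {
  cfg <- list(n_instances = as.integer(n_instances), m = as.integer(m),
              length_range = as.integer(length_range),
              spike_amplitude = spike_amplitude, level_shift = level_shift,
              noise_sd = noise_sd, n_spikes = as.integer(n_spikes),
              class_balance = class_balance, seed = as.integer(seed))
  if (cfg$n_instances < 2L || cfg$m < 1L)
    stop("need n_instances >= 2 and m >= 1", call. = FALSE)
  if (length(cfg$length_range) != 2L || cfg$length_range[1] < 8L ||
      cfg$length_range[1] > cfg$length_range[2])
    stop("length_range must be (Tmin, Tmax) with 8 <= Tmin <= Tmax", call. = FALSE)
  if (cfg$class_balance <= 0 || cfg$class_balance >= 1)
    stop("class_balance must lie strictly between 0 and 1", call. = FALSE)
  if (cfg$noise_sd < 0 || cfg$spike_amplitude < 0 || cfg$n_spikes < 0L)
    stop("noise_sd, spike_amplitude and n_spikes must be non-negative", call. = FALSE)
  structure(cfg, class = "synth_config")
}

# Evaluate `expr` under set.seed(seed) without disturbing the caller's RNG.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Generate a synthetic wafer-like dataset
#'
#' Each channel is a smooth low-frequency sinusoid (random amplitude, phase
#' and period) plus Gaussian noise. Abnormal instances (label 1) additionally
#' receive a downward level shift of `level_shift` on every channel and
#' `n_spikes` transient three-sample spikes of height `spike_amplitude` at
#' random positions, emulating the "low values with two obvious spikes"
#' signature of faulty wafer runs. Lengths are drawn uniformly from
#' `length_range` per instance and shared by all channels of that instance.
#' The dataset is a deterministic function of `config$seed`.
#'
#' @param config A [synth_config()].
#' @return An `mts_dataset` with exactly
#'   `round(n_instances * class_balance)` normal instances.
#' @export
generate_synthetic <- function(config = synth_config()) {
  if (!inherits(config, "synth_config"))
    stop("config must be created by synth_config()", call. = FALSE)
  n0 <- round(config$n_instances * config$class_balance)
  labels <- integer(config$n_instances)
  labels[seq_len(config$n_instances) > n0] <- 1L
  with_seed(config$seed, {
    instances <- lapply(seq_len(config$n_instances), function(i) {
      Tn <- sample(seq(config$length_range[1], config$length_range[2]), 1L)
      tt <- seq_len(Tn)
      channels <- lapply(seq_len(config$m), function(ch) {
        amp <- runif(1, 0.6, 1.2)
        period <- runif(1, Tn / 3, Tn)
        phase <- runif(1, 0, 2 * pi)
        x <- amp * sin(2 * pi * tt / period + phase) +
          rnorm(Tn, sd = config$noise_sd)
        if (labels[i] == 1L) {
          x <- x - config$level_shift
          if (config$n_spikes > 0L && config$spike_amplitude > 0) {
            pos <- sample(seq(3L, Tn - 2L), config$n_spikes)
            for (p in pos) {   # three-sample triangular spike
              x[p] <- x[p] + config$spike_amplitude
              x[p - 1L] <- x[p - 1L] + config$spike_amplitude / 2
              x[p + 1L] <- x[p + 1L] + config$spike_amplitude / 2
            }
          }
        }
        x
      })
      mts_instance(sprintf("synth%04d", i), channels, labels[i])
    })
    mts_dataset(instances, name = "synthetic")
  })
}
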