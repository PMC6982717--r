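#' Stratified k-fold split
#'
#' Partitions `1..n` into `k` disjoint folds, stratified by label so every
#' fold carries both classes whenever possible; fold sizes differ by at most
#' one. Deterministic given `seed`.
#'
#' @param labels Label vector, length `n`.
#' @param k Number of folds, `2 <= k <= n`.
#' @param seed Integer seed.
#' @return List of `k` integer index vectors (disjoint, covering `1..n`).
#' @export
kfold_split <- function(labels, k, seed = 1L) {
  n <- length(labels)
  if (k < 2L || k > n) stop("need 2 <= k <= n", call. = FALSE)
  folds <- vector("list", k)
  with_seed(seed, {
    cursor <- 0L   # deal classes consecutively so overall sizes stay balanced
    for (cls in unique(labels)) {
      idx <- which(labels == cls)
      idx <- idx[sample.int(length(idx))]
      for (j in seq_along(idx)) {
        f <- (cursor %% k) + 1L
        folds[[f]] <- c(folds[[f]], idx[j])
        cursor <- cursor + 1L
      }
    }
  })
  lapply(folds, sort)
}

#' Define an experimental condition
#'
#' @param encoder `"GASF"`, `"GADF"` or `"MTF"`.
#' @param architecture `"simple"` or `"vgg16"`.
#' @param order Concatenation order: an explicit permutation of `1..m`, or
#'   `NULL` for the identity.
#' @param image_size Encoder output size `n` (images are `n x n` per channel).
#' @param bins MTF quantile bin count.
#' @return A `condition` list.
#' @export
condition <- function(encoder = c("GASF", "GADF", "MTF"),
                      architecture = c("simple", "vgg16"),
                      order = NULL, image_size = 128L, bins = 8L) {
  encoder <- match.arg(toupper(encoder), c("GASF", "GADF", "MTF"))
  architecture <- match.arg(architecture)
  structure(list(encoder = encoder, architecture = architecture,
                 order = if (is.null(order)) NULL else as.integer(order),
                 image_size = as.integer(image_size), bins = as.integer(bins)),
            class = "condition")
}

#' Encode an instance as a concatenated RGB image
#'
#' Per channel: rescale to `[0,1]`, resample to `image_size`, encode with the
#' condition's field method, render through the rainbow colormap; then
#' channel-split concatenate in the condition's order.
#'
#' @param instance An `mts_instance`.
#' @param cond A [condition()].
#' @return A `concat_image` array `(n * m) x n x 3`.
#' @export
encode_instance <- function(instance, cond) {
  images <- lapply(instance$channels, function(x)
    colormap_rainbow(encode_series(x, cond$encoder, cond$image_size, cond$bins)))
  ord <- if (is.null(cond$order)) seq_along(images) else cond$order
  concat_rgb(images, ord)
}

#' Encode a whole dataset as a 4-D image batch
#'
#' @param dataset An `mts_dataset`.
#' @param cond A [condition()].
#' @return Array `(n * m, n, 3, N)` of concatenated images.
#' @export
encode_dataset <- function(dataset, cond) {
  as_image_batch(lapply(dataset$instances, encode_instance, cond = cond))
}

#' Run one condition under repeated stratified k-fold cross-validation
#'
#' For each repeat the instances are split into `k` stratified folds; for
#' each fold a fresh network is trained on the remaining `k - 1` folds and
#' evaluated on the held-out fold with [error_rate()]. All seeds derive from
#' `base_seed`, so a run is exactly replayable. The per-repeat means of the
#' fold errors are the sampling unit used by the comparison tests.
#'
#' @param dataset An `mts_dataset` containing both classes.
#' @param cond A [condition()].
#' @param tconf A [train_config()] (its `seed` is overridden fold by fold).
#' @param repeats Number of cross-validation repetitions.
#' @param k Number of folds.
#' @param base_seed Integer base seed for fold assignment and training.
#' @return An `experiment_result` with `error_rates` (repeats x folds
#'   matrix), `repeat_means`, `mean_error`, `condition` and `seeds`.
#' @export
run_condition <- function(dataset, cond, tconf = train_config(),
                          repeats = 20L, k = 5L, base_seed = 1L) {
  labels <- dataset_labels(dataset)
  if (length(unique(labels)) < 2L)
    stop("dataset must contain both classes", call. = FALSE)
  X <- encode_dataset(dataset, cond)
  n <- dim(X)[4]
  arch <- build_architecture(cond$architecture,
                             input_shape = c(3L, dim(X)[1], dim(X)[2]))
  errs <- matrix(NA_real_, repeats, k)
  seeds <- matrix(NA_integer_, repeats, k)
  for (r in seq_len(repeats)) {
    folds <- kfold_split(labels, k, seed = base_seed + 1000L * r)
    for (f in seq_len(k)) {
      test_idx <- folds[[f]]
      train_idx <- setdiff(seq_len(n), test_idx)
      if (length(unique(labels[train_idx])) < 2L)
        stop("stratification error: single-class training fold", call. = FALSE)
      seed_rf <- (base_seed * 7919L + r * 101L + f) %% .Machine$integer.max
      tc <- tconf
      tc$seed <- as.integer(seed_rf)
      model <- train_convnet(arch, X[, , , train_idx, drop = FALSE],
                             labels[train_idx], tc)
      pred <- predict(model, X[, , , test_idx, drop = FALSE])
      errs[r, f] <- error_rate(pred, labels[test_idx])
      seeds[r, f] <- seed_rf
    }
  }
  repeat_means <- rowMeans(errs)
  structure(list(condition = cond, error_rates = errs,
                 repeat_means = repeat_means,
                 mean_error = mean(repeat_means),
                 seeds = seeds, base_seed = base_seed, k = k,
                 repeats = repeats),
            class = "experiment_result")
}

#' @export
print.experiment_result <- function(x, ...) {
  cat(sprintf("<experiment_result> %s / %s: mean error %.2f%% over %d repeat(s) x %d fold(s)\n",
              x$condition$encoder, x$condition$architecture, x$mean_error,
              x$repeats, x$k))
  invisible(x)
}

#' Dunn post-hoc pairwise rank test
#'
#' Rank-based pairwise comparisons between groups following a Kruskal-Wallis
#' omnibus test. Uses mean ranks over the pooled sample with the standard tie
#' correction; `z[i, j] = (rbar_i - rbar_j) / sd_ij` and two-sided normal
#' p-values. When all observations are identical the variance vanishes and
#' every p-value is reported as 1.
#'
#' @param samples Named list of numeric vectors (one per group).
#' @return A `dunn_test` list with matrices `z`, `p` (raw, symmetric, unit
#'   diagonal) and `p_holm` (Holm-adjusted off-diagonals).
#' @export
dunn_test <- function(samples) {
  g <- length(samples)
  if (g < 2L) stop("need at least two groups", call. = FALSE)
  nms <- names(samples)
  if (is.null(nms)) nms <- paste0("group", seq_len(g))
  pooled <- unlist(samples, use.names = FALSE)
  N <- length(pooled)
  rk <- rank(pooled)
  sizes <- lengths(samples)
  grp <- rep(seq_len(g), sizes)
  rbar <- tapply(rk, grp, mean)
  ties <- table(pooled)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  var_base <- N * (N + 1) / 12 - tie_term
  z <- p <- matrix(0, g, g, dimnames = list(nms, nms))
  diag(p) <- 1
  for (i in seq_len(g - 1)) for (j in (i + 1):g) {
    v <- var_base * (1 / sizes[i] + 1 / sizes[j])
    zij <- if (v <= 0) 0 else (rbar[i] - rbar[j]) / sqrt(v)
    z[i, j] <- zij; z[j, i] <- -zij
    p[i, j] <- p[j, i] <- 2 * stats::pnorm(-abs(zij))
  }
  upper <- upper.tri(p)
  p_holm <- p
  p_holm[upper] <- stats::p.adjust(p[upper], method = "holm")
  p_holm[lower.tri(p_holm)] <- t(p_holm)[lower.tri(p_holm)]
  structure(list(z = z, p = p, p_holm = p_holm, sizes = sizes),
            class = "dunn_test")
}

#' Compare encoders with the Dunn post-hoc test
#'
#' Takes the results of the same protocol run under different field encoders
#' and compares their per-repeat mean error rates pairwise.
#'
#' @param results List of `experiment_result`s (typically GASF, GADF, MTF).
#' @return A `dunn_test` object; group names are the encoder names.
#' @export
compare_encoders <- function(results) {
  samples <- lapply(results, `[[`, "repeat_means")
  names(samples) <- vapply(results, function(r) r$condition$encoder, character(1))
  sizes <- lengths(samples)
  if (length(unique(sizes)) != 1L)
    warning("unequal numbers of repeats across conditions", call. = FALSE)
  dunn_test(samples)
}

#' Compare concatenation orders with Wilcoxon signed-rank tests
#'
#' Error-rate samples are paired by (repeat, fold) position, so the same
#' folds and training seeds underlie each member of a pair. If every paired
#' difference is zero the comparison is degenerate and its p-value is
#' reported as 1.
#'
#' @param results List of >= 2 `experiment_result`s run with identical
#'   protocol seeds but different concatenation orders.
#' @param names Optional group names.
#' @return A list with the symmetric `p` matrix (unit diagonal) and a logical
#'   `degenerate` matrix flagging all-zero-difference pairs.
#' @export
compare_orders <- function(results, names = NULL) {
  g <- length(results)
  if (g < 2L) stop("need at least two order conditions", call. = FALSE)
  if (is.null(names)) names <- paste0("order", seq_len(g))
  samples <- lapply(results, function(r) as.vector(r$error_rates))
  if (length(unique(lengths(samples))) != 1L)
    stop("results must share the same repeats x folds layout", call. = FALSE)
  p <- matrix(1, g, g, dimnames = list(names, names))
  degenerate <- matrix(FALSE, g, g, dimnames = list(names, names))
  for (i in seq_len(g - 1)) for (j in (i + 1):g) {
    d <- samples[[i]] - samples[[j]]
    if (all(d == 0)) {
      degenerate[i, j] <- degenerate[j, i] <- TRUE
      p[i, j] <- p[j, i] <- 1
    } else {
      w <- suppressWarnings(stats::wilcox.test(samples[[i]], samples[[j]],
                                               paired = TRUE, exact = FALSE))
      p[i, j] <- p[j, i] <- w$p.value
    }
  }
  list(p = p, degenerate = degenerate)
}

#' Compare architectures with the Kruskal-Wallis test
#'
#' @param ... Two or more numeric vectors of per-repeat mean error rates
#'   (or `experiment_result`s, whose `repeat_means` are used), one per
#'   architecture.
#' @return The `htest` object from [stats::kruskal.test()].
#' @export
compare_architectures <- function(...) {
  groups <- lapply(list(...), function(x)
    if (inherits(x, "experiment_result")) x$repeat_means else as.numeric(x))
  if (length(groups) < 2L)
    stop("need at least two architectures to compare", call. = FALSE)
  if (any(lengths(groups) < 2L))
    stop("each group needs at least 2 observations", call. = FALSE)
  stats::kruskal.test(groups)
}

#' Write experiment results and comparisons to disk
#'
#' Produces `results.csv` (one row per repeat x fold with the condition
#' fields) and `summary.txt` (per-condition means, five-number summaries and
#' any p-value tables). Re-running on the same inputs reproduces the files
#' byte for byte.
#'
#' @param results List of `experiment_result`s (possibly empty).
#' @param comparisons Optional named list of comparison objects
#'   ([dunn_test()], [compare_orders()] output, or `htest`).
#' @param dir Output directory (created if needed).
#' @return Paths of the written files, invisibly.
#' @export
report_results <- function(results, comparisons = list(), dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(results, function(r) {
    idx <- expand.grid(fold = seq_len(ncol(r$error_rates)),
                       rep = seq_len(nrow(r$error_rates)))
    data.frame(encoder = r$condition$encoder,
               architecture = r$condition$architecture,
               order = paste(if (is.null(r$condition$order)) "identity"
                             else r$condition$order, collapse = "-"),
               image_size = r$condition$image_size,
               repeat_ = idx$rep, fold = idx$fold,
               error_rate = r$error_rates[cbind(idx$rep, idx$fold)])
  })
  csv <- if (length(rows)) do.call(rbind, rows)
    else data.frame(encoder = character(0), architecture = character(0),
                    order = character(0), image_size = integer(0),
                    repeat_ = integer(0), fold = integer(0),
                    error_rate = numeric(0))
  csv_path <- file.path(dir, "results.csv")
  write.csv(csv, csv_path, row.names = FALSE, quote = FALSE)

  txt_path <- file.path(dir, "summary.txt")
  con <- file(txt_path, open = "wt")
  on.exit(close(con))
  for (r in results) {
    fv <- stats::fivenum(as.vector(r$error_rates))
    writeLines(sprintf(
      "%s / %s: mean %.3f%% | min %.3f q1 %.3f med %.3f q3 %.3f max %.3f",
      r$condition$encoder, r$condition$architecture, r$mean_error,
      fv[1], fv[2], fv[3], fv[4], fv[5]), con)
  }
  for (nm in names(comparisons)) {
    writeLines(c("", sprintf("== %s ==", nm)), con)
    cmp <- comparisons[[nm]]
    pm <- if (inherits(cmp, "dunn_test")) cmp$p
          else if (is.list(cmp) && !is.null(cmp$p)) cmp$p else NULL
    if (!is.null(pm)) {
      writeLines(capture.output(print(round(pm, 4))), con)
    } else if (inherits(cmp, "htest")) {
      writeLines(sprintf("%s: p = %.4g", cmp$method, cmp$p.value), con)
    }
  }
  invisible(c(csv_path, txt_path))
}
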