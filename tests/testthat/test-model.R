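test_that("pooling arithmetic halves spatial dims through the stack", {
  a <- build_architecture("simple", c(3, 768, 128))
  pools <- Filter(function(l) l$type == "pool", a$layers)
  expect_identical(pools[[2]]$out_shape[2:3], c(192L, 32L))
  v <- build_architecture("vgg16", c(3, 256, 128))
  vpools <- Filter(function(l) l$type == "pool", v$layers)
  expect_length(vpools, 5)
  expect_identical(vpools[[5]]$out_shape[2:3], c(8L, 4L))
  expect_error(build_architecture("simple", c(3, 10, 10)), "shape error")
})

test_that("architectures match their published structure", {
  a <- build_architecture("simple", c(3, 96, 32))
  types <- vapply(a$layers, `[[`, character(1), "type")
  expect_identical(sum(types == "conv"), 2L)
  expect_identical(sum(types == "pool"), 2L)
  expect_identical(sum(types == "fc"), 1L)
  expect_true(all(vapply(Filter(function(l) l$type == "conv", a$layers),
                         `[[`, integer(1), "kernel") == 5L))
  v <- build_architecture("vgg16", c(3, 96, 32))
  vtypes <- vapply(v$layers, `[[`, character(1), "type")
  expect_identical(sum(vtypes == "conv"), 13L)
  expect_identical(sum(vtypes == "pool"), 5L)
  expect_identical(sum(vtypes == "fc"), 3L)
  expect_true(all(vapply(Filter(function(l) l$type == "conv", v$layers),
                         `[[`, integer(1), "kernel") == 3L))
})

test_that("vgg16 capacity dwarfs the simple net and its first FC layer count
           matches the canonical figure for six-sensor 128-pixel input", {
  simple <- build_architecture("simple", c(3, 768, 128))
  vgg <- build_architecture("vgg16", c(3, 768, 128))
  expect_gt(param_count(vgg) / param_count(simple), 100)
  fc_layers <- Filter(function(l) l$type == "fc", vgg$layers)
  fc1 <- fc_layers[[1]]
  expect_equal(fc1$d_in * fc1$d_out + fc1$d_out, 201330688)
})

test_that("error_rate implements (1 - correct/N) * 100", {
  expect_equal(error_rate(c(1, 1, 0, 1), c(1, 1, 1, 1)), 25)
  expect_equal(error_rate(1:5, 1:5), 0)
  expect_equal(error_rate(c(0, 1), c(1, 0)), 100)
  expect_error(error_rate(c(0, 1), c(1)), "equal length")
})

test_that("training learns a separable fixture to zero training error", {
  d <- separable_dataset(n = 30, m = 2, seed = 11)
  labs <- dataset_labels(d)
  X <- encode_dataset(d, condition("GASF", image_size = 16))
  arch <- build_architecture("simple", c(3, 32, 16))
  model <- train_convnet(arch, X, labs,
                         quick_config(seed = 5, max_epochs = 40, patience = 10))
  expect_lte(model$stopped_epoch, 40L)
  expect_identical(nrow(model$history), model$stopped_epoch)
  expect_equal(error_rate(predict(model, X), labs), 0)
})

test_that("training is deterministic given the seed", {
  d <- separable_dataset(n = 20, m = 2, seed = 13)
  labs <- dataset_labels(d)
  X <- encode_dataset(d, condition("GADF", image_size = 16))
  arch <- build_architecture("simple", c(3, 32, 16))
  m1 <- train_convnet(arch, X, labs, quick_config(seed = 9, max_epochs = 5))
  m2 <- train_convnet(arch, X, labs, quick_config(seed = 9, max_epochs = 5))
  expect_identical(m1$history, m2$history)
  expect_identical(predict(m1, X), predict(m2, X))
  m3 <- train_convnet(arch, X, labs, quick_config(seed = 10, max_epochs = 5))
  expect_false(identical(m1$history, m3$history))
})

test_that("contradictory duplicate labels force chance-level training error", {
  set.seed(17)
  img <- array(runif(16 * 16 * 3), c(16, 16, 3))
  X <- array(rep(img, 20), c(16, 16, 3, 20))
  labs <- rep(c(0L, 1L), 10)
  arch <- build_architecture("simple", c(3, 16, 16))
  model <- train_convnet(arch, X, labs,
                         train_config(max_epochs = 10, patience = 3,
                                      validation_fraction = 0.2, seed = 3))
  expect_equal(error_rate(predict(model, X), labs), 50)
})

test_that("epoch bounds and degenerate inputs are enforced", {
  d <- separable_dataset(n = 12, m = 1, seed = 19)
  labs <- dataset_labels(d)
  X <- encode_dataset(d, condition("GASF", image_size = 16))
  arch <- build_architecture("simple", c(3, 16, 16))
  m <- train_convnet(arch, X, labs,
                     train_config(max_epochs = 1, patience = 1, seed = 1))
  expect_identical(m$stopped_epoch, 1L)
  expect_error(train_convnet(arch, X, rep(0L, 12), train_config(seed = 1)),
               "both classes")
  expect_error(train_convnet(arch, X[, , , 1:5, drop = FALSE], labs,
                             train_config(seed = 1)), "one label per image")
  expect_error(train_config(patience = 0), "patience")
  expect_error(train_config(validation_fraction = 0.7), "validation_fraction")
})

test_that("predict handles empty input, single images and shape mismatch", {
  d <- separable_dataset(n = 12, m = 1, seed = 23)
  labs <- dataset_labels(d)
  X <- encode_dataset(d, condition("GASF", image_size = 16))
  arch <- build_architecture("simple", c(3, 16, 16))
  model <- train_convnet(arch, X, labs, quick_config(max_epochs = 3))
  expect_identical(predict(model, list()), integer(0))
  one <- predict(model, X[, , , 1, drop = FALSE])
  expect_length(one, 1)
  expect_true(one %in% c(0L, 1L))
  expect_error(predict(model, array(0, c(8, 8, 3, 2))), "input shape")
})

test_that("score ties break toward class zero", {
  arch <- build_architecture("simple", c(3, 16, 16))
  model <- structure(list(arch = arch,
                          params = asNamespace("mtsimage")$init_params(arch, 1),
                          input_offset = 0.5), class = "trained_model")
  # zero out the FC layer: all scores identical -> tie -> class 0
  nl <- length(model$params)
  model$params[[nl]]$W[] <- 0
  model$params[[nl]]$b[] <- 0
  X <- array(runif(16 * 16 * 3 * 4), c(16, 16, 3, 4))
  expect_identical(predict(model, X), rep(0L, 4))
})

test_that("checkpoints reload and reproduce predictions bit-identically", {
  d <- separable_dataset(n = 12, m = 1, seed = 29)
  labs <- dataset_labels(d)
  X <- encode_dataset(d, condition("MTF", image_size = 16))
  arch <- build_architecture("simple", c(3, 16, 16))
  model <- train_convnet(arch, X, labs, quick_config(max_epochs = 4))
  path <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(model, path)
  back <- load_checkpoint(path)
  expect_identical(predict(back, X), predict(model, X))
  saveRDS(1:3, path)
  expect_error(load_checkpoint(path), "checkpoint")
})
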