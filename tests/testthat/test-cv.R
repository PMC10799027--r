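test_that("stratified folds balance 2 classes over 4 folds exactly", {
  labels <- rep(c("a", "b"), 4)
  folds <- stratified_kfold(labels, k = 4, seed = 1)
  for (f in 1:4) {
    expect_identical(sort(labels[folds == f]), c("a", "b"))
  }
})

test_that("stratified folds partition, balance within one, and are seed-deterministic", {
  set.seed(77)
  for (rep in 1:10) {
    n_cls <- sample(2:5, 1)
    labels <- sample(letters[seq_len(n_cls)],
                     size = sample(20:60, 1), replace = TRUE)
    k <- sample(2:4, 1)
    while (any(table(labels) < k)) {
      labels <- c(labels, letters[seq_len(n_cls)])
    }
    folds <- stratified_kfold(labels, k = k, seed = rep)
    # partition: every index in exactly one fold
    expect_true(all(folds %in% seq_len(k)))
    expect_length(folds, length(labels))
    # per-class fold sizes differ by at most one
    for (cls in unique(labels)) {
      sizes <- tabulate(folds[labels == cls], nbins = k)
      expect_lte(max(sizes) - min(sizes), 1)
    }
    expect_identical(folds, stratified_kfold(labels, k = k, seed = rep))
    expect_false(identical(folds,
                           stratified_kfold(labels, k = k, seed = rep + 500)) &&
                   rep == 1)
  }
  expect_error(stratified_kfold(c("a", "a", "a", "b"), k = 4), "fewer than")
})

test_that("confusion metrics follow the standard definitions", {
  counts <- matrix(c(50, 10, 5, 35), 2, 2, byrow = TRUE,
                   dimnames = list(c("x", "y"), c("x", "y")))
  met <- confusion_metrics(counts)
  expect_equal(unname(met$recall["x"]), 50 / 60)
  expect_equal(unname(met$precision["x"]), 50 / 55)
  expect_equal(unname(met$f1["x"]),
               2 * (50 / 55) * (50 / 60) / (50 / 55 + 50 / 60))
  expect_equal(met$average_accuracy, mean(c(50 / 60, 35 / 40)))
  expect_equal(rowSums(met$confusion), c(x = 1, y = 1), tolerance = 1e-12)

  ident <- diag(3); dimnames(ident) <- list(letters[1:3], letters[1:3])
  met2 <- confusion_metrics(ident)
  expect_equal(unname(met2$recall), rep(1, 3))
  expect_equal(unname(met2$f1), rep(1, 3))
  expect_equal(met2$average_accuracy, 1)

  holey <- matrix(c(2, 0, 0, 0), 2, 2)
  met3 <- confusion_metrics(holey)
  expect_equal(unname(met3$recall[2]), 0)
  expect_length(met3$zero_denominator, 1)

  expect_error(confusion_metrics(matrix(1, 2, 3)), "square")
  expect_error(confusion_metrics(matrix(-1, 2, 2)), "non-negative")
})

test_that("perfectly separable classes cross-validate to the identity confusion", {
  cl <- gaussian_clouds(n_per_class = 16, d = 8, sep = 40,
                        classes = c("healthy", "cancer"))
  ds <- spectral_dataset(seq(800, 814, 2), cl$x, cl$labels,
                         sprintf("s%02d", seq_along(cl$labels)))
  rep <- cross_validate(ds, n_components = 5, k = 4, seed = 3)
  expect_equal(unname(rep$confusion), diag(2), tolerance = 1e-12)
  expect_equal(rep$average_accuracy, 1)
})

test_that("permuted labels classify at chance", {
  set.seed(55)
  accs <- sapply(1:10, function(s) {
    x <- matrix(rnorm(48 * 30), 48, 30)
    labels <- rep(c("a", "b"), 24)[sample.int(48)]
    ds <- spectral_dataset(seq_len(30), x, labels, sprintf("p%02d", 1:48))
    cross_validate(ds, n_components = 10, k = 4, seed = s)$average_accuracy
  })
  expect_lt(abs(mean(accs) - 0.5), 0.08)
})

test_that("cross-validation is deterministic and leakage-free", {
  cfg <- two_class_config(seed = 9, n_per_stage = 24, grid_step = 25,
                          noise_sd = 0.05)
  ds <- generate_dataset(cfg, two_class_bands(0.3))$dataset
  a <- cross_validate(ds, n_components = 8, k = 4, seed = 2)
  b <- cross_validate(ds, n_components = 8, k = 4, seed = 2)
  expect_identical(a$counts, b$counts)
  expect_identical(a$fold_assignments, b$fold_assignments)

  # no leakage: the models predicting fold f are fitted without fold f's
  # rows, so corrupting one spectrum cannot change the predictions of its
  # fold-mates
  corrupt <- ds
  victim <- 5
  corrupt$matrix[victim, ] <- corrupt$matrix[victim, ] + 100
  cc <- cross_validate(corrupt, n_components = 8, k = 4, seed = 2)
  expect_identical(cc$fold_assignments, a$fold_assignments)
  mates <- setdiff(which(a$fold_assignments == a$fold_assignments[victim]),
                   victim)
  expect_identical(cc$predictions$predicted[mates],
                   a$predictions$predicted[mates])
})

test_that("cv reports export to files with row-normalized confusion", {
  cl <- gaussian_clouds(n_per_class = 8, d = 4, sep = 10,
                        classes = c("u", "v"))
  ds <- spectral_dataset(seq(1, 7, 2), cl$x, cl$labels,
                         sprintf("e%02d", 1:16))
  rep <- cross_validate(ds, n_components = 3, k = 4, seed = 1)
  dir <- withr::local_tempdir()
  export_cv_report(rep, dir)
  expect_true(all(file.exists(file.path(
    dir, c("confusion.csv", "counts.csv", "metrics.json",
           "predictions.csv")))))
  met <- jsonlite::read_json(file.path(dir, "metrics.json"))
  expect_equal(met$average_accuracy, rep$average_accuracy)
})
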