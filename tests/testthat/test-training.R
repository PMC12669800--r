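test_that("p-affinity transform evaluates -log10 of molar values", {
  expect_equal(paffinity(1.0), 0.0)
  expect_equal(paffinity(1e-6), 6.0)
  expect_equal(paffinity(5e-8), 7.30103, tolerance = 1e-5)
  expect_error(paffinity(0), "positive")
  expect_error(paffinity(-1e-9), "positive")
})

test_that("focal loss reduces to scaled cross-entropy at gamma = 0", {
  set.seed(1)
  p <- runif(50, 0.05, 0.95)
  y <- rbinom(50, 1, 0.3)
  expect_equal(focal_loss(p, y, alpha = 0.5, gamma = 0),
               0.5 * bce_loss(p, y), tolerance = 1e-9)
})

test_that("focal loss matches hand evaluation and limits", {
  expect_equal(focal_loss(0.9, 1, alpha = 0.25, gamma = 2),
               0.25 * 0.1^2 * (-log(0.9)), tolerance = 1e-12)
  expect_lt(focal_loss(rep(1 - 1e-7, 10), rep(1, 10)), 1e-10)
  expect_warning(focal_loss(c(0.5, 1.2), c(1, 1)), "clipped")
})

test_that("focal loss never exceeds the class-weighted cross-entropy", {
  set.seed(2)
  p <- runif(200, 0.01, 0.99)
  y <- rbinom(200, 1, 0.5)
  for (gamma in c(0.5, 1, 2, 5)) {
    pt <- ifelse(y == 1, p, 1 - p)
    w <- ifelse(y == 1, 0.25, 0.75)
    per_focal <- -w * (1 - pt)^gamma * log(pt)
    per_wbce <- -w * log(pt)
    expect_true(all(per_focal <= per_wbce + 1e-12))
  }
})

test_that("classification metrics match closed-form confusion counts", {
  perfect <- compute_metrics(c(0.9, 0.8, 0.1, 0.2), c(1, 1, 0, 0),
                             "occurrence")
  expect_equal(perfect$MCC, 1)
  expect_equal(perfect$F1, 1)
  expect_equal(perfect$AUROC, 1)
  expect_equal(perfect$AUPRC, 1)
  # TP = TN = FP = FN = 1
  m <- compute_metrics(c(0.9, 0.9, 0.1, 0.1), c(1, 0, 0, 1), "site")
  expect_equal(m$MCC, 0)
  expect_equal(m$F1, 0.5)
  expect_equal(m$Accuracy, 0.5)
  expect_equal(m$Specificity, 0.5)
})

test_that("regression metrics are exact for identical predictions", {
  y <- c(4.2, 6.8, 5.5, 7.1)
  m <- compute_metrics(y, y, "affinity")
  expect_equal(m$RMSE, 0)
  expect_equal(m$MAE, 0)
  expect_equal(m$Pearson, 1)
  expect_equal(m$Spearman, 1)
})

test_that("single-class labels give a missing AUROC", {
  m <- compute_metrics(c(0.2, 0.6, 0.9), c(1, 1, 1), "occurrence")
  expect_true(is.na(m$AUROC))
})

test_that("AUROC matches brute-force pairwise counting on 200 cases", {
  set.seed(33)
  for (case in 1:200) {
    n <- sample(6:25, 1)
    scores <- round(runif(n), 1)  # coarse rounding forces ties
    labels <- rbinom(n, 1, 0.4)
    if (sum(labels) == 0 || sum(labels) == n) next
    expect_equal(auroc(scores, labels), brute_auroc(scores, labels),
                 tolerance = 1e-9)
  }
})

test_that("AUPRC matches frozen reference values with ties", {
  s1 <- c(.9, .8, .8, .6, .5, .4, .35, .3, .2, .1)
  y1 <- c(1, 1, 0, 1, 0, 0, 0, 1, 0, 0)
  expect_equal(auprc(s1, y1), 0.7291666666666666, tolerance = 1e-9)
  s2 <- c(.1, .9, .3, .7, .7, .7, .2, .05)
  y2 <- c(0, 1, 0, 1, 1, 0, 0, 0)
  expect_equal(auprc(s2, y2), 0.8333333333333333, tolerance = 1e-9)
})

test_that("dataset splits are disjoint, exhaustive, ratio-faithful", {
  s <- split_dataset(1:10, seed = 1)
  expect_equal(lengths(s), c(train = 7L, val = 1L, test = 2L))
  big <- split_dataset(seq_len(13920), seed = 2)
  expect_equal(lengths(big), c(train = 9744L, val = 1392L, test = 2784L))
  all_idx <- sort(c(big$train, big$val, big$test))
  expect_equal(all_idx, seq_len(13920))
  expect_identical(split_dataset(1:100, seed = 7),
                   split_dataset(1:100, seed = 7))
  expect_false(identical(split_dataset(1:100, seed = 7),
                         split_dataset(1:100, seed = 8)))
  expect_error(split_dataset(1:2), "at least 3")
})

test_that("site label files align with residue order", {
  st <- make_toy_protein(20, seed = 4)
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(character(0), f)
  expect_equal(read_site_labels(f, st), integer(20))
  writeLines(c("A:3", "A:11", "A:17"), f)
  lab <- read_site_labels(f, st)
  expect_equal(which(lab == 1), c(3L, 11L, 17L))
  writeLines(c("A:3", "A:11", "B:99"), f)
  expect_error(read_site_labels(f, st, strict = TRUE), "absent")
  expect_warning(lab2 <- read_site_labels(f, st, strict = FALSE),
                 "skipping")
  expect_equal(sum(lab2), 2L)
})

test_that("a short training run reduces the loss and stays finite", {
  cfg <- tiny_cfg(epochs = 15L, seed = 3L)
  ds <- get_fix("occ_small", function() {
    make_task_dataset("occurrence", 4, seed = 50, config = tiny_cfg())
  })
  m <- train_task("occurrence", ds, cfg)
  expect_s3_class(m, "tribind_model")
  expect_true(all(is.finite(m$history)))
  expect_lt(tail(m$history, 1), m$history[1])
})

test_that("validation-based early stopping retains the best parameters", {
  cfg <- tiny_cfg(epochs = 25L, patience = 3L, seed = 4L)
  ds <- get_fix("occ_small", function() {
    make_task_dataset("occurrence", 4, seed = 50, config = tiny_cfg())
  })
  m <- train_task("occurrence", ds[1:3], cfg, val_dataset = ds[4])
  expect_true(length(m$history) <= 25L)
})

test_that("checkpoints round-trip parameters and configuration", {
  cfg <- tiny_cfg(epochs = 2L)
  ds <- get_fix("occ_small", function() {
    make_task_dataset("occurrence", 4, seed = 50, config = tiny_cfg())
  })
  m <- train_task("occurrence", ds, cfg)
  f <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(m, f)
  m2 <- load_checkpoint(f)
  expect_equal(m2$params, m$params)
  expect_equal(m2$config$h1, cfg$h1)
  expect_equal(predict_dataset("occurrence", ds, m2$params, m2$config),
               predict_dataset("occurrence", ds, m$params, m$config))
})
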