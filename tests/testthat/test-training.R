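# Splitting, preprocessing, schedule, model assembly, training loop.

fake_records <- function(n_patients, scans = 3L) {
  data.frame(patient_id = rep(sprintf("P%02d", seq_len(n_patients)),
                              each = scans),
             label = "X", stringsAsFactors = FALSE)
}

test_that("45 patients at k = 5 give 9-patient folds split 27/9/9", {
  rec <- fake_records(45L)
  plan <- make_splits(rec, k = 5L, scheme = "3:1:1", seed = 4L)
  expect_equal(unname(table(plan$fold_of_patient)), rep(9L, 5L),
               ignore_attr = TRUE)
  for (r in 1:5) {
    idx <- split_records(plan, rec, r)
    pat <- function(i) unique(rec$patient_id[i])
    expect_length(pat(idx$train), 27L)
    expect_length(pat(idx$val), 9L)
    expect_length(pat(idx$test), 9L)
  }
})

test_that("split plans are deterministic and patient-disjoint", {
  rec <- fake_records(23L)
  p1 <- make_splits(rec, k = 5L, seed = 99L)
  p2 <- make_splits(rec, k = 5L, seed = 99L)
  expect_identical(p1$fold_of_patient, p2$fold_of_patient)
  p3 <- make_splits(rec, k = 5L, seed = 100L)
  expect_false(identical(p1$fold_of_patient, p3$fold_of_patient))

  for (scheme in c("3:1:1", "one-train")) {
    plan <- make_splits(rec, k = 5L, scheme = scheme, seed = 7L)
    for (r in seq_len(plan$k)) {
      idx <- split_records(plan, rec, r)
      pats <- lapply(idx, function(i) unique(rec$patient_id[i]))
      expect_length(intersect(pats$train, pats$val), 0L)
      expect_length(intersect(pats$train, pats$test), 0L)
      expect_length(intersect(pats$val, pats$test), 0L)
      expect_setequal(unlist(pats), unique(rec$patient_id))
    }
  }
})

test_that("degenerate deals and undersized cohorts are handled", {
  rec <- fake_records(10L)
  plan <- make_splits(rec, k = 10L, scheme = "one-train", seed = 1L)
  idx <- split_records(plan, rec, 3L)
  expect_length(unique(rec$patient_id[idx$train]), 1L)
  expect_error(make_splits(fake_records(4L), k = 5L), "distinct patients")
})

test_that("learning rate follows the closed-form step decay", {
  expect_equal(lr_schedule(0), 3e-4)
  expect_equal(lr_schedule(9), 3e-4)
  expect_equal(lr_schedule(10), 3e-5)
  expect_equal(lr_schedule(25), 3e-4 * 0.1^2)
  e <- 0:49
  expect_equal(lr_schedule(e), 3e-4 * 0.1^(e %/% 10))
})

test_that("preprocessing standardizes and resizes as specified", {
  img <- matrix(0.42, 40, 40)
  out <- preprocess_image(img, mean = 0.42, std = 0.1, size = 32L)
  expect_identical(dim(out), c(32L, 32L))
  expect_equal(max(abs(out)), 0)

  big <- matrix(runif(512 * 496), 512, 496)
  expect_identical(dim(preprocess_image(big, 0.5, 0.25)), c(224L, 224L))

  expect_error(preprocess_image(img, 0, 0), "degenerate")
  expect_error(preprocess_image(matrix(0, 4, 4), 0, 1), "at least 8x8")
})

test_that("upsampling resize matches the per-pixel bilinear oracle", {
  cb <- matrix(c(0, 1, 1, 0), 2, 2)
  got <- resize_bilinear(cb, 224, 224)
  ref <- naive_bilinear(cb, 224, 224)
  expect_lt(max(abs(got - ref)), 1e-4)
  # downscaling a constant image is exact
  expect_equal(max(abs(resize_bilinear(matrix(0.7, 100, 80), 32, 24) - 0.7)),
               0, tolerance = 1e-12)
})

test_that("zero requested epochs returns the initialized model and empty log", {
  set.seed(40)
  cfg <- tiny_cfg()
  x <- array(rnorm(6 * 1 * 32 * 32), c(6, 1, 32, 32))
  y <- rep(1:3, 2)
  fit <- train_model(x, y, 1:4, 5:6, cfg, train_config(max_epochs = 0L))
  expect_equal(nrow(fit$log), 0L)
  expect_s3_class(fit$model, "hctnet_model")
})

test_that("ablation modes assemble the documented module sets", {
  cfg <- hctnet_config("full")
  manifests <- lapply(ns$ABLATION_MODES, function(m) {
    cfg$ablation_mode <- m
    param_manifest(assemble_model(cfg, seed = 1L))
  })
  names(manifests) <- ns$ABLATION_MODES
  # monotone assembly: full includes everything llfe_vit has
  expect_true(all(manifests$llfe_vit$name %in% manifests$full$name))
  # vit_only on 224x224 with P = 16: N = 196 tokens -> 197 position rows
  vit <- assemble_model(hctnet_config("full", ablation_mode = "vit_only"),
                        seed = 1L)
  expect_equal(nrow(vit$params$t_branch$embed$Epos), 197L)
  # concat head consumes both branches: input width 2D
  cc <- assemble_model(hctnet_config("full",
                                     ablation_mode = "llfe_vit_cbranch_concat"),
                       seed = 1L)
  expect_equal(nrow(cc$params$head$W), 2L * 384L)
  expect_error(hctnet_config("full", ablation_mode = "bogus"),
               "valid modes")
})

test_that("training is deterministic given the seed and reduces the loss", {
  set.seed(41)
  cfg <- tiny_cfg()
  x <- array(rnorm(24 * 1 * 32 * 32), c(24, 1, 32, 32))
  y <- rep(1:3, 8)
  # separable signal: class-specific mean shift in a corner
  for (i in seq_along(y)) x[i, 1, 1:8, 1:8] <- x[i, 1, 1:8, 1:8] + y[i]
  tc <- train_config(batch_size = 8L, max_epochs = 3L, seed = 5L)
  f1 <- train_model(x, y, 1:18, 19:24, cfg, tc)
  f2 <- train_model(x, y, 1:18, 19:24, cfg, tc)
  expect_equal(f1$log$train_loss, f2$log$train_loss, tolerance = 1e-12)
  expect_lt(f1$log$train_loss[3], f1$log$train_loss[1])
  expect_equal(f1$log$lr, rep(3e-4, 3))
})

test_that("the fitted classifier round-trips through predict and checkpoints", {
  set.seed(42)
  d <- generate_oct_dataset(synth_spec(2L, 4L, image_size = 32L,
                                       class_set = "3class", seed = 3L))
  cfg <- tiny_cfg()
  fit <- hctnet_fit(d$images, d$records$label, config = cfg,
                    tcfg = train_config(batch_size = 8L, max_epochs = 2L,
                                        seed = 1L),
                    patient_id = d$records$patient_id)
  pr <- predict(fit, d$images, type = "prob")
  expect_identical(dim(pr), c(24L, 3L))
  expect_lt(max(abs(rowSums(pr) - 1)), 1e-6)
  cl <- predict(fit, d$images)
  expect_s3_class(cl, "factor")
  expect_identical(levels(cl), sort(unique(d$records$label)))

  ck <- file.path(tempdir(), "ck.rds")
  hctnet_save(fit$model, ck)
  expect_true(file.exists(paste0(ck, ".manifest.json")))
  m2 <- hctnet_load(ck)
  expect_equal(param_manifest(m2), param_manifest(fit$model))
  unlink(c(ck, paste0(ck, ".manifest.json")))
})
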