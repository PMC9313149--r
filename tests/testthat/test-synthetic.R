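# Synthetic layered-phantom OCT generator.

test_that("generation is deterministic and respects the configured counts", {
  sp <- synth_spec(3L, 4L, image_size = 48L, seed = 11L)
  d1 <- generate_oct_dataset(sp)
  d2 <- generate_oct_dataset(sp)
  expect_identical(d1$images, d2$images)
  expect_identical(d1$records, d2$records)

  sp3 <- synth_spec(15L, 20L, image_size = 48L, class_set = "3class",
                    seed = 2L)
  d3 <- generate_oct_dataset(sp3)
  expect_equal(nrow(d3$records), 900L)
  expect_equal(length(unique(d3$records$patient_id)), 45L)
  # label balance matches the spec exactly
  expect_equal(unname(table(d3$records$label)), rep(300L, 3L),
               ignore_attr = TRUE)
  expect_true(all(d3$images >= 0 & d3$images <= 1))
})

test_that("DME pockets are darker than the surrounding bands", {
  sp <- synth_spec(4L, 3L, image_size = 64L, keep_masks = TRUE,
                   seed = 21L)
  d <- generate_oct_dataset(sp)
  idx <- which(d$records$label == "DME")
  diffs <- vapply(idx, function(i) {
    pocket <- d$lesion_masks[[i]]
    band <- d$band_masks[[i]] & !pocket
    mean(d$images[i, , ][band]) - mean(d$images[i, , ][pocket])
  }, numeric(1))
  expect_true(all(diffs > 0.1))
})

test_that("scans within a patient correlate more than across patients", {
  sp <- synth_spec(6L, 4L, image_size = 48L, seed = 31L)
  d <- generate_oct_dataset(sp)
  n <- nrow(d$records)
  flat <- matrix(d$images, n)
  cc <- suppressWarnings(cor(t(flat)))
  same <- outer(d$records$patient_id, d$records$patient_id, `==`)
  diag(same) <- NA
  intra <- mean(cc[same & !is.na(same)])
  inter <- mean(cc[!same & !is.na(same)])
  expect_gt(intra, inter)
})

test_that("nearest-centroid audit sits between chance and perfection", {
  d <- generate_oct_dataset(synth_spec(6L, 6L, image_size = 48L,
                                       seed = 41L))
  aud <- class_separability_audit(d)
  expect_gt(aud$accuracy, aud$chance)
  expect_lt(aud$accuracy, 1)

  # zero contrast removes every class cue: accuracy collapses to chance
  d0 <- generate_oct_dataset(synth_spec(6L, 6L, image_size = 48L,
                                        contrast = 0, seed = 41L))
  aud0 <- class_separability_audit(d0)
  expect_lt(abs(aud0$accuracy - aud0$chance), 0.15)

  # separability grows with lesion contrast
  dh <- generate_oct_dataset(synth_spec(6L, 6L, image_size = 48L,
                                        contrast = 2.5, seed = 41L))
  expect_gte(class_separability_audit(dh)$accuracy, aud0$accuracy)
})

test_that("PNG serialization round-trips through the manifest convention", {
  d <- generate_oct_dataset(synth_spec(2L, 2L, image_size = 32L,
                                       class_set = "3class", seed = 51L))
  dir <- file.path(tempdir(), "synthpng")
  unlink(dir, recursive = TRUE)
  manifest <- write_oct_dataset(d, dir)
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  m2 <- read_manifest(file.path(dir, "manifest.csv"))
  expect_equal(m2$patient_id, d$records$patient_id)
  imgs <- load_manifest_images(m2, dir)
  expect_length(imgs, nrow(d$records))
  expect_lt(max(abs(imgs[[1]] - d$images[1, , ])), 1 / 255)

  disc <- discover_dataset(dir, patient_pattern = "^([A-Za-z]+-P[0-9]+)-")
  expect_equal(nrow(disc), nrow(d$records))
  expect_setequal(unique(disc$label), unique(d$records$label))
  unlink(dir, recursive = TRUE)
})
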