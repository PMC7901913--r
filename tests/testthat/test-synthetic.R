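test_that("prototype generation is deterministic and matches digit-image statistics", {
  sp <- synthetic_spec(n_classes = 5, seed = 7)
  p1 <- make_prototypes(sp)
  p2 <- make_prototypes(sp)
  expect_identical(p1, p2)
  expect_length(p1, 5)
  for (p in p1) {
    expect_true(is.integer(p))
    expect_true(all(p >= 0 & p <= 255))
    expect_equal(dim(p), c(28, 28))
  }
  # sparse bright strokes: most of the image is near-black background
  bg <- vapply(p1, function(p) mean(p < 16), numeric(1))
  expect_true(all(bg >= 0.6))
  # prototypes are mutually distinguishable
  flat <- vapply(p1, as.vector, numeric(784))
  cc <- stats::cor(flat); diag(cc) <- 0
  expect_lt(max(cc), sp$cor_ceiling)
})

test_that("infeasible separability constraints raise a generation error", {
  sp <- synthetic_spec(n_classes = 2, image_size = 1, cor_ceiling = 0,
                       seed = 1)
  expect_error(make_prototypes(sp, max_retries = 5), "correlation")
})

test_that("sampled datasets are balanced, valid 8-bit and deterministic", {
  sp <- synthetic_spec(n_classes = 10, n_train = 100, seed = 3)
  pr <- make_prototypes(sp)
  ds <- sample_dataset(sp, 100, pr)
  expect_equal(nrow(ds), 100)
  expect_true(all(ds$label %in% 0:9))
  expect_true(all(table(ds$label) %in% 9:11))
  for (img in ds$image[1:10]) {
    expect_true(is.integer(img))
    expect_true(all(img >= 0 & img <= 255))
  }
  ds2 <- sample_dataset(sp, 100, pr)
  expect_identical(ds, ds2)
  # independent splits differ
  ds3 <- sample_dataset(sp, 100, pr, split_seed_offset = 1L)
  expect_false(identical(ds$image, ds3$image))
})

test_that("without jitter and noise every sample equals its prototype", {
  sp <- synthetic_spec(n_classes = 3, n_train = 12, jitter_px = 0,
                       jitter_deg = 0, noise_sigma = 0, seed = 5)
  pr <- make_prototypes(sp)
  ds <- sample_dataset(sp, 12, pr)
  for (k in seq_len(12)) {
    expect_identical(ds$image[[k]], pr[[ds$label[k] + 1L]])
  }
})

test_that("IDX containers round-trip and reject malformed headers", {
  sp <- synthetic_spec(n_classes = 3, n_train = 6, seed = 2)
  ds <- sample_dataset(sp, 6)

  fi <- withr::local_tempfile(fileext = ".idx3-ubyte")
  fl <- withr::local_tempfile(fileext = ".idx1-ubyte")
  write_idx(ds$image, fi)
  write_idx(ds$label, fl)
  expect_identical(read_idx(fi), ds$image)
  expect_identical(read_idx(fl), as.integer(ds$label))

  # byte-level header check: images magic then big-endian dims
  hdr <- readBin(fi, "raw", 16)
  expect_identical(hdr[1:4], as.raw(c(0, 0, 8, 3)))
  expect_identical(hdr[5:8], as.raw(c(0, 0, 0, 6)))
  expect_identical(hdr[9:12], as.raw(c(0, 0, 0, 28)))
  expect_identical(readBin(fl, "raw", 4), as.raw(c(0, 0, 8, 1)))

  bad <- withr::local_tempfile()
  writeBin(as.raw(c(0xde, 0xad, 0xbe, 0xef, 0, 0, 0, 1)), bad)
  expect_error(read_idx(bad), "magic")

  trunc <- withr::local_tempfile()
  writeBin(readBin(fi, "raw", 40), trunc)
  expect_error(read_idx(trunc), "truncated")
})

test_that("a linear classifier separates the synthetic classes from raw pixels", {
  ds <- small_dataset(n_train = 250, n_test = 80)
  flat <- function(d) t(vapply(d$image, as.vector, numeric(784))) / 255
  x_tr <- flat(ds$train); y_tr <- ds$train$label
  x_te <- flat(ds$test); y_te <- ds$test$label
  # one-vs-all ridge regression on indicators: a plain linear decision rule
  classes <- sort(unique(y_tr))
  y_ind <- outer(y_tr, classes, "==") * 1
  xtx <- crossprod(x_tr) + diag(1e-1, ncol(x_tr))
  beta <- solve(xtx, crossprod(x_tr, y_ind))
  pred <- classes[max.col(x_te %*% beta)]
  expect_gte(mean(pred == y_te), 0.9)
})
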