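test_that("Laplacian kernels are zero-sum and null constants", {
  for (nb in c(4, 8)) {
    k <- laplacianKernel(nb)
    expect_equal(dim(k), c(3L, 3L))
    expect_equal(sum(k), 0)
    flat <- matrix(17, 6, 6)
    expect_true(all(convolveImage(flat, k) == 0))
  }
  expect_error(laplacianKernel(6), class = "cropheight_input_error")
})

test_that("Laplacian response matches the discrete second-difference sum", {
  img <- matrix(0, 5, 5)
  img[3, 3] <- 10
  resp <- convolveImage(img, laplacianKernel(4))
  # direct d2/dx2 + d2/dy2 at interior pixels
  manual <- matrix(0, 5, 5)
  for (y in 2:4) for (x in 2:4)
    manual[y, x] <- img[y, x - 1] + img[y, x + 1] + img[y - 1, x] +
      img[y + 1, x] - 4 * img[y, x]
  expect_equal(resp[2:4, 2:4], manual[2:4, 2:4])
})

test_that("directional kernels behave like axis derivatives", {
  kx <- directionalKernel("x")
  expect_equal(sum(kx), 0)
  expect_equal(directionalKernel("y"), t(kx))
  # antisymmetric about the centre column
  expect_equal(kx[, 1], -kx[, 3])

  constAlongX <- matrix(rep(1:8, times = 6), 8, 6)  # varies only in y
  expect_true(all(convolveImage(constAlongX, kx) == 0))

  step <- cbind(matrix(0, 7, 4), matrix(100, 7, 4))  # vertical step at col 4|5
  resp <- abs(convolveImage(step, kx))
  expect_true(all(apply(resp[2:6, ], 1, which.max) %in% c(4, 5)))

  expect_error(directionalKernel("z"), class = "cropheight_input_error")
})

test_that("marker kernel has the prescribed size and column structure", {
  for (w in c(3, 5, 7, 9)) {
    k <- modifiedKernel(w)
    expect_equal(dim(k), c(2 * w + 1, 2 * w + 1))
    colVals <- k[1, ]
    expect_equal(k, matrix(rep(colVals, each = nrow(k)), nrow(k)))  # constant columns
    signs <- sign(colVals)
    flank <- (w + 1) / 2
    expect_equal(signs, c(rep(1, flank), rep(-1, w), rep(1, flank)))
    expect_true(all(rowSums(k) == 0))
    expect_equal(k, k[, ncol(k):1])  # mirror symmetric about the centre line
  }
  expect_error(modifiedKernel(4), class = "cropheight_input_error")
  expect_error(modifiedKernel(1), class = "cropheight_input_error")
})

test_that("convolveImage matches a brute-force placement loop", {
  set.seed(5)
  img <- matrix(runif(16, -10, 10), 4, 4)
  k <- matrix(runif(9, -2, 2), 3, 3)
  expect_equal(convolveImage(img, k), bruteCorrelate(img, k), tolerance = 1e-12)

  img2 <- matrix(runif(7 * 9), 7, 9)
  k2 <- modifiedKernel(3)
  expect_equal(convolveImage(img2, k2), bruteCorrelate(img2, k2), tolerance = 1e-10)
})

test_that("identity kernel reproduces the input; oversized kernels are rejected", {
  ident <- matrix(0, 3, 3); ident[2, 2] <- 1
  set.seed(8)
  img <- matrix(runif(30), 5, 6)
  expect_equal(convolveImage(img, ident), img)
  expect_error(convolveImage(matrix(1, 2, 2), modifiedKernel(3)),
               class = "cropheight_input_error")
})

test_that("zero-sum kernels are invariant to intensity offsets", {
  set.seed(13)
  for (k in list(laplacianKernel(4), laplacianKernel(8),
                 directionalKernel("x"), modifiedKernel(3), modifiedKernel(5))) {
    img <- matrix(runif(15 * 14, 0, 255), 15, 14)
    shift <- runif(1, -100, 100)
    expect_equal(convolveImage(img + shift, k), convolveImage(img, k),
                 tolerance = 1e-9)
  }
})

test_that("marker kernel peaks on a dark stripe of matching width", {
  set.seed(21)
  for (w in c(3, 5)) {
    width <- 41
    img <- matrix(200 + rnorm(31 * width, 0, 5), 31, width)  # bright field
    centre <- 21
    cols <- (centre - (w - 1) / 2):(centre + (w - 1) / 2)
    img[, cols] <- -150 + rnorm(31 * w, 0, 5)  # dark stripe, excess-green polarity
    resp <- convolveImage(img, modifiedKernel(w))
    interior <- (w + 2):(31 - w - 1)
    expect_true(all(apply(resp[interior, ], 1, which.max) == centre))
  }
})

test_that("kernels round-trip through the plain-text format", {
  k <- modifiedKernel(5)
  path <- withr::local_tempfile(fileext = ".txt")
  writeKernel(k, path)
  expect_equal(readKernel(path), unname(k))
})
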