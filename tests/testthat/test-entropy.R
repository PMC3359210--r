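test_that("histograms count every pixel and normalize", {
  h <- intensity_histogram(matrix(c(0, 0, 255, 255), 2, 2))
  expect_equal(h$p[1], 0.5)
  expect_equal(h$p[256], 0.5)
  expect_equal(sum(h$p), 1, tolerance = 1e-12)
  expect_length(h$counts, 256)

  h7 <- intensity_histogram(matrix(7, 3, 3))
  expect_equal(h7$p[8], 1)

  set.seed(1)
  m <- matrix(sample(0:255, 300, TRUE), 15, 20)
  expect_equal(sum(intensity_histogram(m)$counts), 300)
  expect_error(intensity_histogram(matrix(numeric(0), 0, 0)), "empty")
  expect_error(intensity_histogram(matrix(1.5, 2, 2)), "integers")
})

test_that("criterion values match hand computation on a two-point histogram", {
  p <- numeric(256); p[c(1, 256)] <- 0.5
  # both classes are single occupied bins: normalized class entropies are 0
  expect_equal(entropy_criterion(p, 100), 0)
  # printed Eq.-style algebra: -log(.5)-log(.5) - 2 * (.5*log 2)*.5
  expect_equal(entropy_criterion(p, 100, "printed"),
               2 * log(2) - 0.5 * log(2), tolerance = 1e-12)
  # degenerate split: everything in class A
  expect_identical(entropy_criterion(p, 255), -Inf)
  expect_identical(entropy_criterion(p, 255, "printed"), -Inf)
})

test_that("criterion is symmetric for a uniform histogram", {
  p <- rep(1 / 256, 256)
  H <- vapply(0:255, function(j) entropy_criterion(p, j), 0)
  for (j in 0:254)
    expect_equal(H[j + 1], H[254 - j + 1], tolerance = 1e-10)
})

test_that("threshold argmax equals the brute-force criterion scan", {
  set.seed(99)
  for (crit in c("kapur", "printed")) {
    for (trial in 1:100) {
      p <- random_histogram(64, sample(2:64, 1))
      tr <- max_entropy_threshold(p, criterion = crit)
      expect_identical(tr$cutoff, brute_force_jstar(p, crit))
      expect_equal(tr$max_entropy, max(tr$criterion_curve))
    }
  }
})

test_that("bimodal mass ties break to the smallest cutoff", {
  p <- numeric(256); p[51] <- 0.5; p[201] <- 0.5   # bins 50 and 200
  tr <- max_entropy_threshold(p)
  expect_equal(tr$cutoff, 50L)
})

test_that("dark blobs on a bright background are recovered exactly", {
  set.seed(42)
  ch <- matrix(sample(215:225, 64 * 64, TRUE), 64, 64)
  blob <- matrix(FALSE, 64, 64)
  blob[10:25, 10:25] <- TRUE; blob[40:55, 30:50] <- TRUE
  ch[blob] <- sample(25:35, sum(blob), TRUE)
  tr <- max_entropy_threshold(intensity_histogram(ch))
  expect_gte(tr$cutoff, 35); expect_lt(tr$cutoff, 215)
  mask <- binarize(ch, tr)
  expect_identical(mask == 0L, blob)
})

test_that("degenerate histograms are flagged, not fatal", {
  tr <- max_entropy_threshold(intensity_histogram(matrix(17, 4, 4)))
  expect_true(tr$degenerate)
  expect_equal(tr$cutoff, 17L)
})

test_that("empty bins beyond the occupied range do not move the cutoff", {
  set.seed(5)
  p <- c(random_histogram(64, 20), numeric(192))
  expect_identical(max_entropy_threshold(p)$cutoff,
                   max_entropy_threshold(p[1:64])$cutoff)
})

test_that("binarization uses the foreground-low coding", {
  expect_identical(binarize(matrix(c(10, 200), 1, 2), 100),
                   matrix(c(0L, 255L), 1, 2))
  ch <- matrix(sample(1:255, 25, TRUE), 5, 5)
  expect_true(all(binarize(ch, 255) == 0L))
  expect_true(all(binarize(ch, 0) == 255L))
  m <- binarize(ch, 128)
  expect_true(all(m %in% c(0L, 255L)))
  expect_equal(sum(m == 0L) + sum(m == 255L), 25L)
})

test_that("multistage segmentation recovers the dark population", {
  set.seed(7)
  n <- 128 * 128
  lab <- sample(1:3, n, TRUE, prob = c(0.2, 0.3, 0.5))
  v <- pmin(255L, pmax(0L,
        as.integer(round(rnorm(n, c(40, 140, 240)[lab], 8)))))
  ch <- matrix(v, 128, 128)
  ms <- multistage_segment(ch)
  expect_false(ms$degenerate)
  pred <- ms$mask == 0L
  truth <- matrix(lab == 1, 128, 128)
  dice <- 2 * sum(pred & truth) / (sum(pred) + sum(truth))
  expect_gte(dice, 0.95)
  # the layers partition the image
  expect_true(all(ms$layers >= 0 & ms$layers <= length(ms$boundaries)))
  expect_equal(length(ms$layers), n)
})

test_that("a constant image yields a degenerate empty segmentation", {
  ms <- multistage_segment(matrix(130, 16, 16))
  expect_true(ms$degenerate)
  expect_true(all(ms$mask == 255L))
})

test_that("multistage collapses to the single-stage threshold when all
          values sit in one quarter", {
  set.seed(12)
  v <- pmin(63, pmax(0, c(round(rnorm(2000, 10, 3)),
                          round(rnorm(2096, 50, 3)))))
  ch <- matrix(v, 64, 64)
  ms <- multistage_segment(ch)
  tr <- max_entropy_threshold(intensity_histogram(ch), 0, 63)
  expect_identical(ms$mask, binarize(ch, tr))
})

test_that("mode filter removes isolated pixels, keeps solid regions", {
  m <- matrix(255L, 15, 15); m[8, 8] <- 0L
  expect_true(all(mode_filter(m, 3) == 255L))

  # fully-foreground mask: clipped corner windows still vote foreground
  solid <- matrix(0L, 20, 20)
  expect_identical(mode_filter(solid, 3), solid)

  # embedded square: interior untouched
  emb <- matrix(255L, 30, 30); emb[6:25, 6:25] <- 0L
  out <- mode_filter(emb, 3)
  expect_true(all(out[10:21, 10:21] == 0L))
})

test_that("mode filter equals the brute-force window vote", {
  set.seed(21)
  for (trial in 1:6) {
    r <- sample(1:3, 1)
    m <- matrix(ifelse(runif(20 * 17) < runif(1), 0L, 255L), 20, 17)
    expect_identical(mode_filter(m, r), mode_filter_oracle(m, r))
  }
  # checkerboard stress case
  cb <- matrix(ifelse((row(matrix(0, 8, 8)) + col(matrix(0, 8, 8))) %% 2 == 0,
                      0L, 255L), 8, 8)
  expect_identical(mode_filter(cb, 3), mode_filter_oracle(cb, 3))
})

test_that("mode filter is idempotent on locally homogeneous masks", {
  # a half-plane has a clear majority in every (clipped) window, so it is
  # a fixed point of the filter, hence trivially idempotent
  half <- matrix(255L, 40, 40); half[, 1:20] <- 0L
  expect_identical(mode_filter(half, 2), half)
  expect_identical(mode_filter(mode_filter(half, 2), 2), half)
})
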