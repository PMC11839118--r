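test_that("transcript rasterization bins by floor and conserves counts", {
  tr <- data.frame(x = c(1, 5, 15), y = c(1, 5, 2), gene = "A")
  r <- rasterize_transcripts(tr, resolution_um = 10, gene_order = "A")
  expect_equal(r$values[1, 1, 1], 2)
  expect_equal(r$values[2, 1, 1], 1)
  expect_equal(sum(r$values), nrow(tr))

  set.seed(4)
  n <- 10000
  tr2 <- data.frame(x = runif(n, 0, 300), y = runif(n, 0, 200),
                    gene = sample(c("A", "B", "C"), n, replace = TRUE))
  r2 <- rasterize_transcripts(tr2, 10, gene_order = c("A", "B", "C"))
  expect_equal(sum(r2$values), n)
  # naive per-pixel double-loop oracle
  oracle <- array(0, dim(r2$values))
  for (g in 1:3) {
    sub <- tr2[tr2$gene == c("A", "B", "C")[g], ]
    for (i in seq_len(nrow(sub)))
      oracle[floor(sub$x[i] / 10) + 1, floor(sub$y[i] / 10) + 1, g] <-
        oracle[floor(sub$x[i] / 10) + 1, floor(sub$y[i] / 10) + 1, g] + 1
  }
  expect_identical(r2$values, oracle)
})

test_that("rasterization rejects unknown genes and empty input", {
  tr <- data.frame(x = 1, y = 1, gene = "Z")
  expect_error(rasterize_transcripts(tr, 10, gene_order = c("A", "B")), "Z")
  expect_error(rasterize_transcripts(tr[0, ], 10), "empty")
})

test_that("transcript segmentation applies the 10-transcript rule", {
  v <- array(0, c(4, 1, 1))
  v[, 1, 1] <- c(3, 9, 10, 50)
  r <- sample_raster(v, "s")
  seg <- segment_foreground(r, "transcript")
  expect_equal(as.vector(seg$foreground), c(FALSE, FALSE, TRUE, TRUE))
  # all-background raster is fully zeroed
  v2 <- array(2, c(3, 3, 1))
  seg2 <- segment_foreground(sample_raster(v2, "s"), "transcript")
  expect_true(all(seg2$values == 0))
})

test_that("Otsu matches an exhaustive between-class-variance scan", {
  bcv_scan <- function(x, thresholds) {
    # oracle: maximize between-class variance directly on the data
    best <- -Inf; arg <- NA
    for (t in thresholds) {
      lo <- x[x <= t]; hi <- x[x > t]
      if (!length(lo) || !length(hi)) next
      v <- length(lo) / length(x) * length(hi) / length(x) *
        (mean(lo) - mean(hi))^2
      if (v > best) { best <- v; arg <- t }
    }
    arg
  }
  x <- c(0, 0, 0, 10, 10, 10)
  thr <- otsu_threshold(x)
  expect_equal(sum(x > thr), 3)
  expect_equal(sum(x > bcv_scan(x, seq(0, 10, length.out = 257))), 3)
  for (seed in 1:5) {
    set.seed(seed)
    x <- c(rnorm(300, 1, 0.5), rnorm(200, 6, 1))
    thr <- otsu_threshold(x)
    edges <- seq(min(x), max(x), length.out = 257)
    oracle <- bcv_scan(x, edges[-c(1, 257)])
    # same partition of the data
    expect_equal(sum(x > thr), sum(x > oracle))
  }
  expect_error(otsu_threshold(rep(3, 10)), "degenerate")
})

test_that("log-normalization follows the median-ratio formula", {
  mk <- function(vals) {
    v <- array(0, c(length(vals) / 2, 1, 2))
    v[, 1, ] <- matrix(vals, ncol = 2, byrow = TRUE)
    sample_raster(v, "s", foreground = matrix(TRUE, dim(v)[1], 1))
  }
  # three pixels with totals {2,4,6} -> q = 4; pixel (2,2) -> (log2, log2)
  r <- mk(c(1, 1, 2, 2, 3, 3))
  norm <- lognormalize_pixels(list(r), "intensity")
  expect_equal(norm$q, 4)
  expect_equal(norm$pixels[2, ], c(log(2), log(2)))
  # zero entry with eps = 1: pixel (4,0), q = 4 -> (log 4, log eps)
  r2 <- mk(c(4, 0, 1, 3, 2, 2))
  norm2 <- lognormalize_pixels(list(r2), "intensity", eps = 1)
  expect_equal(norm2$pixels[1, ], c(log(4), log(1)))
  # transcript counts: zero maps to 0 (log1p-style)
  norm3 <- lognormalize_pixels(list(mk(c(4, 0, 1, 3, 2, 2))), "transcript")
  expect_equal(norm3$pixels[1, 2], 0)
})

test_that("rescaling the dataset shifts normalized values by log(c) only", {
  # q, the numerator and the total all scale by c, so the ratio q*p/total
  # scales by c and the log shifts additively; PCA centering removes the
  # shift downstream, so meta-markers are scale-invariant
  set.seed(1)
  v <- array(rexp(5 * 4 * 3) + 0.5, c(5, 4, 3))
  r1 <- sample_raster(v, "a", foreground = matrix(TRUE, 5, 4))
  r2 <- sample_raster(v * 7.3, "a", foreground = matrix(TRUE, 5, 4))
  n1 <- lognormalize_pixels(list(r1), "intensity")
  n2 <- lognormalize_pixels(list(r2), "intensity")
  expect_equal(n2$pixels, n1$pixels + log(7.3), tolerance = 1e-12)
  m1 <- compute_metamarkers(n1, K = 2)
  m2 <- compute_metamarkers(n2, K = 2)
  expect_equal(abs(m1$scores), abs(m2$scores), tolerance = 1e-8)
})

test_that("meta-marker computation obeys the K rule and PCA identities", {
  set.seed(2)
  mkr <- function(M) {
    v <- array(rexp(6 * 6 * M) + 0.2, c(6, 6, M))
    sample_raster(v, "s", foreground = matrix(TRUE, 6, 6))
  }
  norm7 <- lognormalize_pixels(list(mkr(7)), "intensity")
  mm7 <- compute_metamarkers(norm7)
  expect_equal(mm7$K, 5)  # fewer than 10 markers -> K = 5
  norm12 <- lognormalize_pixels(list(mkr(12)), "intensity")
  expect_equal(compute_metamarkers(norm12)$K, 10)
  expect_error(compute_metamarkers(norm7, K = 9), "exceeds")

  # full-rank PCA: projection is a rotation; reconstruction exact
  norm3 <- lognormalize_pixels(list(mkr(3)), "intensity")
  mm3 <- compute_metamarkers(norm3, K = 3)
  rec <- mm3$scores %*% t(mm3$loadings)
  cent <- sweep(norm3$pixels, 2, mm3$center)
  expect_equal(rec, unname(cent), tolerance = 1e-10)
})

test_that("an isolated pixel is its own meta-pixel", {
  v <- array(0, c(7, 7, 2))
  v[4, 4, ] <- c(3, 5)
  fg <- matrix(FALSE, 7, 7); fg[4, 4] <- TRUE
  r <- sample_raster(v, "s", foreground = fg)
  norm <- lognormalize_pixels(list(r), "intensity")
  field <- matrix(NA_real_, 49, 2)
  field[4 + 3 * 7, ] <- norm$pixels[1, ]
  meta <- vima:::.metapixel_field(field, 7, 7)
  expect_equal(meta[1, ], norm$pixels[1, ])
})

test_that("batch correction removes per-sample offsets and standardizes", {
  set.seed(9)
  n <- 3000
  base <- matrix(rnorm(n * 3), n, 3)
  z1 <- base[seq_len(n / 2), ]
  z2 <- sweep(base[(n / 2 + 1):n, ], 2, c(2, -1, 0.5), "+")
  Z <- rbind(z1, z2)
  ids <- rep(c("a", "b"), each = n / 2)
  zc <- correct_batch(Z, ids, standardize = FALSE)
  gap <- abs(colMeans(zc[ids == "a", ]) - colMeans(zc[ids == "b", ]))
  expect_lt(max(gap), 0.1)

  # identical samples: output ~ standardized input
  Zi <- rbind(base, base)
  zi <- correct_batch(Zi, rep(c("a", "b"), each = n))
  expect_equal(zi, apply(scale(Zi), 2, vima:::.std_pop), tolerance = 0.05)

  # standardization contract
  zs <- correct_batch(Z, ids)
  expect_lt(max(abs(colMeans(zs))), 1e-6)
  expect_lt(max(abs(apply(zs, 2, function(x) mean((x - mean(x))^2)) - 1)),
            1e-6)
})

test_that("single-sample correction is a warned pass-through", {
  set.seed(1)
  Z <- matrix(rnorm(300), 100, 3)
  expect_warning(zc <- correct_batch(Z, rep("a", 100)), "single sample")
  expect_equal(zc, unname(apply(scale(Z), 2, vima:::.std_pop)),
               tolerance = 1e-10)
})

test_that("patch extraction follows the stride grid and tissue filter", {
  K <- 2
  field <- structure(list(sample_id = "s",
                          values = array(rnorm(120 * 120 * K),
                                         c(120, 120, K)),
                          foreground = matrix(TRUE, 120, 120)),
                     class = "metamarker_field")
  ps <- extract_patches(field, side_px = 40, stride_px = 10)
  expect_equal(length(ps), 81)  # ((120-40)/10 + 1)^2
  expect_true(all(ps$anchors %% 10 == 0))
  expect_true(all(ps$tissue_fraction == 1))

  # a patch with 15% tissue is discarded
  fg <- matrix(FALSE, 40, 50)
  fg[, 1:10] <- TRUE  # left patch has 25%... make second patch sparse
  field2 <- structure(list(sample_id = "s",
                           values = array(1, c(40, 50, 1)) *
                             as.vector(fg),
                           foreground = fg),
                      class = "metamarker_field")
  ps2 <- extract_patches(field2, side_px = 40, stride_px = 10,
                         min_tissue = 0.2)
  expect_equal(nrow(ps2$anchors), 1)
  expect_equal(ps2$tissue_fraction, 0.25)

  fg3 <- matrix(FALSE, 40, 40); fg3[, 1:6] <- TRUE  # 15% tissue
  field3 <- structure(list(sample_id = "s",
                           values = array(0, c(40, 40, 1)),
                           foreground = fg3),
                      class = "metamarker_field")
  expect_error(extract_patches(field3, 40, 10, 0.2), "no patch")
})

test_that("metadata validation flags schema problems", {
  expect_error(sample_metadata(data.frame(sample_id = "a", phenotype = 1)),
               "donor_id")
  expect_error(sample_metadata(data.frame(sample_id = c("a", "a"),
                                          donor_id = "d", phenotype = 1)),
               "duplicate")
  md <- sample_metadata(data.frame(sample_id = c("a", "b"),
                                   donor_id = c("d1", "d1"),
                                   phenotype = c("ctl", "case")))
  expect_equal(sort(md$phenotype), c(0, 1))
})
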