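toy_series <- function(frames, times) {
  rdm_series(array(unlist(frames), dim = c(dim(frames[[1]]), length(frames))),
             times, kind = "decoding_accuracy")
}

test_that("sliding-window smoothing averages neighbors and preserves the mean", {
  m1 <- matrix(c(0, 1, 1, 0), 2, 2)
  m2 <- matrix(c(0, 2, 2, 0), 2, 2)
  m3 <- matrix(c(0, 6, 6, 0), 2, 2)
  ser <- toy_series(list(m1, m2, m3), times = c(0, 5, 10))
  sm <- smooth_series(ser, window_ms = 15) # 3-sample window at 5 ms step
  expect_equal(sm$values[1, 2, 2], (1 + 2 + 6) / 3) # center = mean of three
  expect_equal(sm$values[1, 2, 1], (1 + 2) / 2)     # truncated edge
  # entrywise series mean is preserved up to edge truncation (O(w/n))
  long <- toy_series(lapply(sin(seq(0, 3, length.out = 60)) + 2, function(v) {
    matrix(c(0, v, v, 0), 2, 2)
  }), times = seq(0, by = 5, length.out = 60))
  lsm <- smooth_series(long, 15)
  expect_equal(mean(lsm$values[1, 2, ]), mean(long$values[1, 2, ]),
               tolerance = 0.01)
  # window of one sample is the identity
  expect_equal(smooth_series(ser, window_ms = 5)$values, ser$values)
  # constant series unchanged
  cs <- toy_series(list(m1, m1, m1), c(0, 5, 10))
  expect_equal(smooth_series(cs, 15)$values, cs$values)
  expect_error(smooth_series(ser, window_ms = 1), "one time step")
})

test_that("MDS embeds equidistant and planar configurations faithfully", {
  # 3 equidistant conditions -> equilateral triangle
  eq <- rdm(matrix(1, 3, 3) - diag(3))
  fr <- mds_frame(eq)
  d <- dist(cbind(fr$dim1, fr$dim2))
  expect_equal(max(d) / min(d), 1, tolerance = 1e-6)
  expect_equal(colMeans(cbind(fr$dim1, fr$dim2)), c(0, 0),
               tolerance = 1e-10) # centered
  expect_lt(attr(fr, "stress"), 1e-6)

  # distances of points already in a plane are recovered
  set.seed(19)
  pts <- matrix(rnorm(16), 8, 2)
  pr <- mds_frame(rdm(as.matrix(dist(pts))))
  got <- as.matrix(dist(cbind(pr$dim1, pr$dim2)))
  want <- as.matrix(dist(pts))
  expect_equal(got[lower.tri(got)], want[lower.tri(want)], tolerance = 1e-6)

  # negative (cross-validated) dissimilarities are shifted, not fatal
  neg <- matrix(rnorm(25, 1), 5, 5); neg <- (neg + t(neg)) / 2
  neg[1, 2] <- neg[2, 1] <- -0.4
  expect_s3_class(mds_frame(rdm(neg)), "mds_frame")
  expect_warning(mds_frame(rdm(matrix(0, 3, 3))), "degenerate")

  # deterministic
  expect_identical(mds_frame(rdm(as.matrix(dist(pts)))), pr)
})

test_that("frame alignment is rigid and stabilizes a static series", {
  set.seed(20)
  pts <- matrix(rnorm(12), 6, 2)
  d <- as.matrix(dist(pts))
  ser <- toy_series(list(d, d, d), c(0, 5, 10))
  mv <- mds_series(ser)
  # static series -> identical frames after alignment
  f1 <- mv[mv$time == 0, c("dim1", "dim2")]
  f3 <- mv[mv$time == 10, c("dim1", "dim2")]
  expect_equal(as.matrix(f3), as.matrix(f1), tolerance = 1e-8,
               ignore_attr = TRUE)
  # alignment never changes within-frame pairwise distances
  for (tt in unique(mv$time)) {
    fr <- mv[mv$time == tt, ]
    got <- as.matrix(dist(cbind(fr$dim1, fr$dim2)))
    raw <- mds_frame(rdm(d))
    want <- as.matrix(dist(cbind(raw$dim1, raw$dim2)))
    expect_equal(got[lower.tri(got)], want[lower.tri(want)],
                 tolerance = 1e-8)
  }
  expect_error(mds_series(toy_series(list(matrix(0, 1, 1)), 0)),
               "two conditions")
})

test_that("an emerging vertical organization becomes visible in MDS frames", {
  set <- tiny_set()
  same_v <- outer(set$vertical, set$vertical, `==`)
  base <- matrix(0.5, 12, 12)
  late <- ifelse(same_v, 0.5, 0.95) # vertical split after "onset"
  diag(base) <- diag(late) <- 0
  ser <- toy_series(list(base, base, late, late), c(150, 175, 200, 225))
  mv <- mds_series(ser, set = set)
  ratio <- function(fr) {
    co <- as.matrix(fr[, c("dim1", "dim2")])
    dd <- as.matrix(dist(co))
    mean(dd[!same_v & upper.tri(dd)]) / mean(dd[same_v & upper.tri(dd)])
  }
  r_pre <- ratio(mv[mv$time == 150, ])
  r_post <- ratio(mv[mv$time == 225, ])
  expect_lt(r_pre, 1.2)   # no vertical clustering before
  expect_gt(r_post, 1.5)  # clear between/within separation after
})

test_that("mds_movie writes frame images and a coordinate table", {
  set <- tiny_set()
  d <- as.matrix(dist(matrix(rnorm(24), 12, 2)))
  ser <- toy_series(list(d, d), c(0, 5))
  out <- withr::local_tempdir()
  mv <- mds_movie(ser, out_dir = out, set = set)
  expect_true(file.exists(file.path(out, "coordinates.csv")))
  expect_true(all(file.exists(file.path(out, c("frame_0001.png",
                                               "frame_0002.png")))))
  back <- utils::read.csv(file.path(out, "coordinates.csv"))
  expect_equal(nrow(back), 24)
  expect_equal(back$dim1, mv$dim1, tolerance = 1e-12)
})
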