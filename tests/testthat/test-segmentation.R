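# Thresholding, contour tracing, RDP simplification, mask smoothing.

test_that("thresholding separates dark roots from a bright backlight", {
  expect_false(any(threshold_image(matrix(255, 4, 4), 128)))
  expect_true(all(threshold_image(matrix(0, 4, 4), 128)))
  img <- matrix(250, 3, 3); img[2, 2] <- 10
  m <- threshold_image(img, 128)
  expect_identical(which(m), 5L)  # center pixel only
  # per-pixel comparison oracle on a random image
  set.seed(42)
  img <- matrix(sample(0:255, 400, replace = TRUE), 20, 20)
  expect_identical(threshold_image(img, 97), img < 97)
  expect_identical(threshold_image(img, 97, invert = TRUE), img >= 97)
})

test_that("a single pixel yields one outer contour of length 1", {
  m <- mask_from_pixels(cbind(3L, 4L), 6, 6)
  cons <- extract_contours(m)
  expect_length(cons, 1L)
  expect_identical(cons[[1L]]$kind, "outer")
  expect_identical(nrow(cons[[1L]]$points), 1L)
  expect_identical(cons[[1L]]$points[1L, ], c(row = 3L, col = 4L))
})

test_that("a filled 5x5 square traces its 16 border pixels", {
  m <- matrix(FALSE, 9, 9); m[3:7, 3:7] <- TRUE
  cons <- extract_contours(m)
  expect_length(cons, 1L)
  ring <- cons[[1L]]$points
  expect_identical(nrow(ring), 16L)
  # the ring visits exactly the border pixels of the square
  border <- which(m, arr.ind = TRUE)
  border <- border[border[, 1L] %in% c(3L, 7L) | border[, 2L] %in% c(3L, 7L), ]
  expect_setequal(paste(ring[, 1L], ring[, 2L]),
                  paste(border[, 1L], border[, 2L]))
  # consecutive points are 8-adjacent, ring closes
  steps <- abs(diff(rbind(ring, ring[1L, , drop = FALSE])))
  expect_true(all(pmax(steps[, 1L], steps[, 2L]) == 1L))
})

test_that("an enclosed background pixel produces a hole contour", {
  m <- matrix(FALSE, 9, 9); m[3:7, 3:7] <- TRUE; m[5, 5] <- FALSE
  cons <- extract_contours(m)
  kinds <- vapply(cons, function(cn) cn$kind, "")
  expect_identical(sort(kinds), c("hole", "outer"))
  hole <- cons[[which(kinds == "hole")]]$points
  # hole ring: foreground pixels adjacent to (5, 5), consecutively 8-adjacent
  expect_gte(nrow(hole), 4L)
  expect_true(all(abs(hole[, 1L] - 5L) <= 1L & abs(hole[, 2L] - 5L) <= 1L))
  expect_true(all(mapply(function(i, j) m[i, j], hole[, 1L], hole[, 2L])))
  steps <- abs(diff(rbind(hole, hole[1L, , drop = FALSE])))
  expect_true(all(pmax(steps[, 1L], steps[, 2L]) == 1L))
  # outer and hole rings have opposite orientations (signed shoelace)
  signed <- function(p) {
    x <- p[, 2L]; y <- p[, 1L]; j <- c(2:nrow(p), 1L)
    sum(x * y[j] - x[j] * y) / 2
  }
  expect_lt(signed(cons[[which(kinds == "hole")]]$points) *
            signed(cons[[which(kinds == "outer")]]$points), 0)
})

test_that("one outer contour per 8-connected component", {
  set.seed(7)
  for (rep in 1:5) {
    m <- random_mask(15, 15, 0.35)
    cons <- extract_contours(m)
    n_out <- sum(vapply(cons, function(cn) cn$kind, "") == "outer")
    expect_identical(n_out, max(oracle_label(m, 8L)))
  }
})

test_that("RDP collapses collinear points and keeps true corners", {
  pts <- cbind(0, 0:9)
  expect_equal(simplify_contour(pts, 2), pts[c(1L, 10L), ])
  # L-shaped path: corner must be retained (max chord distance ~ 7.07)
  L <- rbind(cbind(0:10 * 0, 0:10), cbind(1:10, 10))
  out <- simplify_contour(L, 2)
  expect_true(any(out[, 1L] == 0 & out[, 2L] == 10))
  expect_identical(nrow(out), 3L)
  # every input point lies within epsilon of the simplified polyline
  for (eps in c(0.5, 2, 5)) {
    set.seed(eps * 10)
    walk <- cbind(cumsum(sample(c(-1L, 0L, 1L), 40, TRUE)),
                  cumsum(sample(c(0L, 1L), 40, TRUE)))
    out <- simplify_contour(walk, eps)
    keep_idx <- match(paste(out[, 1L], out[, 2L]),
                      paste(walk[, 1L], walk[, 2L]))
    expect_false(any(is.na(keep_idx)))  # vertices are a subsequence
    maxd <- 0
    for (i in seq_len(length(keep_idx) - 1L)) {
      span <- keep_idx[i]:keep_idx[i + 1L]
      d <- crownpheno:::point_segment_dist(
        walk[span, , drop = FALSE], walk[keep_idx[i], ], walk[keep_idx[i + 1L], ])
      maxd <- max(maxd, d)
    }
    expect_lte(maxd, eps)
  }
})

test_that("RDP removes single-pixel jags of amplitude up to 2", {
  pts <- cbind(c(rep(0L, 5L), 1L, rep(0L, 5L)), 0:10)  # one 1-px jag
  out <- simplify_contour(pts, 2)
  expect_equal(out, pts[c(1L, 11L), ])
})

test_that("smoothing is a fixed point on rectangles and removes bumps", {
  m <- matrix(FALSE, 12, 15); m[4:9, 3:12] <- TRUE
  expect_identical(smooth_mask(m, 2), m)
  # a one-pixel bump on an edge is shaved off
  b <- m; b[3, 7] <- TRUE
  expect_identical(smooth_mask(b, 2), m)
  # empty in, empty out
  e <- matrix(FALSE, 5, 5)
  expect_identical(smooth_mask(e, 2), e)
})

test_that("smoothing preserves components and hole structure", {
  m <- matrix(FALSE, 24, 24)
  m[3:12, 3:12] <- TRUE        # square with a 4x4 hole
  m[6:9, 6:9] <- FALSE
  m[16:21, 12:18] <- TRUE      # second solid component
  sm <- smooth_mask(m, 2)
  expect_identical(max(oracle_label(sm, 8L)), 2L)
  expect_identical(oracle_holes(sm)$holes, 1L)
})

test_that("smoothing barely changes realistic crown silhouettes", {
  # root widths of ~1.3-2 mm at the field camera scale (~12.8 px/mm)
  syn <- make_synthetic_crown(n_laterals = 10, seed = 5,
                              width_range_px = c(16, 26),
                              height = 600, width = 480)
  raw <- threshold_image(syn$image, 128)
  sm <- smooth_mask(raw, 2)
  jac <- sum(sm & raw) / sum(sm | raw)
  expect_gte(jac, 0.95)
})

test_that("smoothing reduces skeleton end points on jagged edges", {
  # rectangle with noisy single-pixel edge jags
  set.seed(9)
  m <- matrix(FALSE, 40, 120)
  m[15:24, 10:110] <- TRUE
  jag_cols <- sample(12:108, 30)
  m[cbind(14L, jag_cols)] <- TRUE
  m[cbind(25L, sample(12:108, 30))] <- TRUE
  tips_of <- function(mask) {
    count_tips(build_topology(extract_skeleton(mask)))
  }
  expect_lte(tips_of(smooth_mask(m, 2)), tips_of(m))
})
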