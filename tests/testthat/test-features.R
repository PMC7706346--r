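# The 27 phenes: counting, extent, areas, diameters, lengths, holes,
# orientation.

test_that("root count profile matches a direct scan oracle", {
  m <- matrix(FALSE, 8, 7)
  m[2:7, 3] <- TRUE                       # solid vertical bar
  expect_identical(root_count_profile(m), rep(1L, 6L))
  m2 <- m; m2[2:7, 6] <- TRUE             # two disjoint bars
  expect_identical(root_count_profile(m2), rep(2L, 6L))
  # row pattern bg,fg,fg,bg,fg -> 2 transitions
  m3 <- matrix(FALSE, 1, 5); m3[1, c(2, 3, 5)] <- TRUE
  expect_identical(root_count_profile(m3), 2L)
  # foreground starting at column 1 counts as a transition
  m4 <- matrix(FALSE, 1, 4); m4[1, 1:2] <- TRUE
  expect_identical(root_count_profile(m4), 1L)
  set.seed(31)
  for (rep in 1:5) {
    m <- random_mask(12, 12, 0.4)
    if (!any(m)) next
    rows <- range(which(rowSums(m) > 0))
    expect_identical(root_count_profile(m),
                     oracle_row_transitions(m)[rows[1]:rows[2]])
  }
})

test_that("median and maximum roots follow the sort oracle", {
  expect_equal(median_max_roots(rep(1L, 5L)), list(median = 1, maximum = 1L))
  expect_equal(median_max_roots(c(1L, 1L, 3L, 5L, 5L)),
               list(median = 3, maximum = 5L))
  expect_equal(median_max_roots(c(2L, 4L)), list(median = 3, maximum = 4L))
  expect_equal(median_max_roots(integer(0)), list(median = 0, maximum = 0L))
})

test_that("extent metrics are bounding-box spans", {
  s <- mask_from_pixels(cbind(4L, 5L), 9, 9)
  expect_equal(extent_metrics(s),
               list(maximum_width = 1L, depth = 1L, width_to_depth_ratio = 1))
  m <- matrix(FALSE, 14, 9); m[3:12, 4:6] <- TRUE   # 10 rows x 3 cols
  expect_equal(extent_metrics(m),
               list(maximum_width = 3L, depth = 10L,
                    width_to_depth_ratio = 0.3))
  e <- matrix(FALSE, 3, 3)
  expect_equal(extent_metrics(e),
               list(maximum_width = 0L, depth = 0L, width_to_depth_ratio = 0))
})

test_that("area metrics match hull, shoelace and chain-walk oracles", {
  m <- matrix(FALSE, 14, 14); m[3:12, 3:12] <- TRUE  # 10x10 square
  a <- area_metrics(m)
  expect_identical(a$network_area, 100L)
  expect_equal(a$convex_area, 81)       # hull of pixel centers spans 9x9
  expect_equal(a$perimeter, 36)
  expect_equal(a$solidity, 100 / 81)
  # single pixel: degenerate hull
  s <- mask_from_pixels(cbind(2L, 2L), 4, 4)
  as <- area_metrics(s)
  expect_identical(as$network_area, 1L)
  expect_equal(as$convex_area, 0)
  expect_equal(as$solidity, 0)
  expect_equal(as$perimeter, 0)
  # L-shaped hexomino: convex area against an independent gift-wrap hull
  L <- mask_from_pixels(rbind(c(2L, 2L), c(3L, 2L), c(4L, 2L),
                              c(4L, 3L), c(4L, 4L), c(3L, 3L)), 6, 6)
  aL <- area_metrics(L)
  expect_identical(aL$network_area, 6L)
  expect_equal(aL$convex_area,
               oracle_convex_area_wrap(which(L, arr.ind = TRUE)))
  # random blobs: convex area equals the gift-wrap + shoelace oracle
  set.seed(17)
  for (rep in 1:6) {
    m <- random_mask(12, 12, 0.3)
    if (sum(m) < 3) next
    expect_equal(area_metrics(m)$convex_area,
                 oracle_convex_area_wrap(which(m, arr.ind = TRUE)))
  }
})

test_that("diameter metrics follow the histogram and sort oracles", {
  mk_skel <- function(radii) {
    n <- length(radii)
    S <- matrix(FALSE, 3, n + 2L)
    R <- matrix(0, 3, n + 2L)
    if (n) {
      S[2, 2:(n + 1L)] <- TRUE
      R[2, 2:(n + 1L)] <- radii
    }
    crownpheno:::new_skeleton(S, R)
  }
  one <- diameter_metrics(mk_skel(1), c(3, 5))
  expect_equal(one$average_diameter, 2)
  expect_equal(one$median_diameter, 2)
  expect_equal(one$maximum_diameter, 2)
  expect_equal(one$volume, pi)
  expect_equal(one$surface_area, 2 * pi)
  ten <- diameter_metrics(mk_skel(rep(2, 10)), c(3, 5))
  expect_equal(unname(ten$frequencies), c(0, 1, 0))
  mix <- diameter_metrics(mk_skel(c(1, 1, 3)), c(3, 5))
  expect_equal(mix$median_diameter, 2)
  expect_equal(mix$maximum_diameter, 6)
  empty <- diameter_metrics(mk_skel(numeric(0)), c(3, 5))
  expect_equal(empty$maximum_diameter, 0)
  expect_equal(unname(empty$frequencies), c(0, 0, 0))
})

test_that("diameter bins are half-open with an inclusive top bin", {
  S <- matrix(FALSE, 3, 6); S[2, 2:5] <- TRUE
  R <- matrix(0, 3, 6); R[2, 2:5] <- c(1.5, 1.5, 2.5, 4)  # diam 3, 3, 5, 8
  dm <- diameter_metrics(crownpheno:::new_skeleton(S, R), c(3, 5))
  # 3 falls in the medium bin, 5 in the coarse bin
  expect_equal(unname(dm$frequencies), c(0, 0.5, 0.5))
  expect_equal(sum(dm$frequencies), 1)
})

test_that("total root length sums chain steps once per edge", {
  S <- matrix(FALSE, 5, 13); S[3, 2:12] <- TRUE    # 11-pixel horizontal
  expect_equal(total_root_length(build_topology(S)), 10)
  D <- matrix(FALSE, 13, 13)
  for (k in 0:10) D[2 + k, 2 + k] <- TRUE          # 11-pixel diagonal
  expect_equal(total_root_length(build_topology(D)), 10 * sqrt(2))
  # Y with three 10-step arms
  Y <- matrix(FALSE, 25, 25)
  Y[2:12, 13] <- TRUE
  for (k in 1:10) { Y[12 + k, 13 - k] <- TRUE; Y[12 + k, 13 + k] <- TRUE }
  expect_equal(total_root_length(build_topology(Y)), 10 + 20 * sqrt(2))
  # oracle: sum over segments of independently computed chain lengths
  g <- build_topology(Y)
  expect_equal(total_root_length(g),
               sum(vapply(g$segments, oracle_chain_length, 0)))
})

test_that("lower root area counts pixels below the widest point", {
  # 3-px-wide bar over rows 2..12, widened to 5 px at row 5 only
  m <- matrix(FALSE, 14, 9); m[2:12, 4:6] <- TRUE; m[5, 3:7] <- TRUE
  skel <- extract_skeleton(m)
  px <- skeleton_pixels(skel)
  expect_equal(max(px$radius), skel$radius[5, 5])
  expect_equal(lower_root_area(m, skel), sum(m[6:14, ]))
  # max-radius pixel on the last foreground row -> 0
  m2 <- matrix(FALSE, 8, 9); m2[7, 2:8] <- TRUE
  sk2 <- extract_skeleton(m2)
  expect_equal(lower_root_area(m2, sk2), 0L)
  # uniform bar: all radii tie; tie rule picks the topmost skeleton row
  m3 <- matrix(FALSE, 12, 7); m3[3:10, 3:5] <- TRUE
  sk3 <- extract_skeleton(m3)
  px3 <- skeleton_pixels(sk3)
  top <- min(px3$row[px3$radius == max(px3$radius)])
  expect_equal(lower_root_area(m3, sk3), sum(m3[(top + 1):12, ]))
})

test_that("hole metrics equal the flood-fill oracle", {
  solid <- matrix(TRUE, 6, 6)
  expect_equal(hole_metrics(solid), list(holes = 0L, average_hole_size = 0))
  sq <- matrix(FALSE, 7, 7); sq[2:6, 2:6] <- TRUE; sq[4, 4] <- FALSE
  expect_equal(hole_metrics(sq), list(holes = 1L, average_hole_size = 1))
  ring <- matrix(FALSE, 12, 18)
  ring[3:9, 3:9] <- TRUE; ring[5:7, 5:7] <- FALSE   # 3x3 hole
  ring[4:8, 12:16] <- TRUE                          # separate solid blob
  expect_equal(hole_metrics(ring), list(holes = 1L, average_hole_size = 9))
  set.seed(23)
  for (rep in 1:6) {
    m <- random_mask(15, 15, 0.55)
    expect_equal(hole_metrics(m), oracle_holes(m))
  }
})

test_that("orientation of straight lines is exact", {
  H <- matrix(FALSE, 9, 60); H[5, 3:58] <- TRUE
  gh <- build_topology(H)
  oh <- orientation_metrics(crownpheno:::new_skeleton(H, H * 1), gh, 40L)
  expect_equal(oh$average_root_orientation, 0, tolerance = 1e-9)
  expect_equal(unname(oh$frequencies), c(1, 0, 0))
  V <- matrix(FALSE, 60, 9); V[3:58, 5] <- TRUE
  gv <- build_topology(V)
  ov <- orientation_metrics(crownpheno:::new_skeleton(V, V * 1), gv, 40L)
  expect_equal(ov$average_root_orientation, 90, tolerance = 1e-9)
  expect_equal(unname(ov$frequencies), c(0, 0, 1))
  D <- matrix(FALSE, 60, 60)
  for (k in 0:50) D[5 + k, 5 + k] <- TRUE
  gd <- build_topology(D)
  od <- orientation_metrics(crownpheno:::new_skeleton(D, D * 1), gd, 40L)
  expect_equal(od$average_root_orientation, 45, tolerance = 1e-9)
  # 45 degrees falls in the medium bin [30, 60)
  expect_equal(unname(od$frequencies), c(0, 1, 0))
})

test_that("angle bins are half-open with 90 in the steep bin", {
  # bin edges: 30 -> medium, 60 -> steep, 90 -> steep
  S1 <- matrix(FALSE, 3, 3); S1[2, 2] <- TRUE
  g1 <- build_topology(S1)
  o <- orientation_metrics(crownpheno:::new_skeleton(S1, S1 * 1), g1, 40L)
  expect_equal(unname(o$frequencies), c(1, 0, 0))  # isolated pixel: 0 deg
  expect_equal(sum(o$frequencies), 1)
})

test_that("profile summaries are invariant to mirror and translation", {
  set.seed(41)
  for (rep in 1:4) {
    m <- random_mask(10, 14, 0.35)
    if (!any(m)) next
    base <- median_max_roots(root_count_profile(m))
    mirrored <- m[, ncol(m):1]
    shifted <- cbind(matrix(FALSE, nrow(m), 3), m)
    expect_equal(median_max_roots(root_count_profile(mirrored)), base)
    expect_equal(median_max_roots(root_count_profile(shifted)), base)
  }
})

test_that("an empty image assembles an all-zero feature row", {
  res <- analyze_image(matrix(250, 20, 20), crown_config(), "blank")
  f <- res$features
  for (nm in setdiff(crownpheno:::feature_names(), "computational_time"))
    expect_equal(f[[nm]], 0, info = nm)
})

test_that("a vertical bar yields an internally consistent feature row", {
  img <- matrix(245, 40, 21); img[4:36, 9:13] <- 15
  f <- analyze_image(img, crown_config(), "bar")$features
  expect_equal(f$maximum_number_of_roots, 1)
  expect_equal(f$median_number_of_roots, 1)
  expect_equal(f$number_of_root_tips, 2)
  expect_equal(f$depth, 33)
  expect_equal(f$maximum_width, 5)
  expect_equal(f$width_to_depth_ratio, 5 / 33)
  expect_equal(f$network_area, 33 * 5)
  expect_equal(f$holes, 0)
  expect_gte(f$steep_angle_frequency, 0.9)
  expect_equal(f$shallow_angle_frequency +
               f$medium_angle_frequency + f$steep_angle_frequency, 1)
  expect_equal(f$fine_diameter_frequency +
               f$medium_diameter_frequency + f$coarse_diameter_frequency, 1)
})
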