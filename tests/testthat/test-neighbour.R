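snap_of <- function(xyz, venus, control = NULL) {
  tibble::tibble(nucleus_id = sprintf("n%02d", seq_len(nrow(xyz))),
                 x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                 venus = venus,
                 control = control %||% rep(1000, nrow(xyz)))
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("nearest neighbours match brute-force distances", {
  sn <- snap_of(cbind(c(0, 3), 0, 0), c(10, 20))
  pr <- nearest_neighbour_pairs(sn)
  expect_equal(pr$id2, rev(pr$id1))
  expect_equal(pr$distance, c(3, 3))

  # collinear nuclei at 0, 1, 3
  sn2 <- snap_of(cbind(c(0, 1, 3), 0, 0), c(1, 2, 3))
  pr2 <- nearest_neighbour_pairs(sn2)
  expect_equal(pr2$id2, c("n02", "n01", "n02"))
})

test_that("pairing is invariant under rigid transforms", {
  set.seed(2)
  xyz <- matrix(runif(60, 0, 50), ncol = 3)
  sn <- snap_of(xyz, runif(20, 1, 100))
  pr <- nearest_neighbour_pairs(sn)
  th <- 0.7
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  sn2 <- snap_of(xyz %*% R + 13, sn$venus)
  pr2 <- nearest_neighbour_pairs(sn2)
  expect_equal(pr$id2, pr2$id2)
  expect_equal(pr$distance, pr2$distance, tolerance = 1e-9)
})

test_that("ordered intensity ratios follow arithmetic and scaling rules", {
  sn <- snap_of(cbind(c(0, 1, 10, 11), 0, 0), c(10, 5, 8, 2))
  pr <- nearest_neighbour_pairs(sn)
  # directed pairs: (10,5), (5,10), (8,2), (2,8) -> ordered ratios 2,2,4,4
  expect_equal(pair_intensity_ratio(pr), 3)
  sn2 <- sn; sn2$venus <- sn$venus * 7
  expect_equal(pair_intensity_ratio(nearest_neighbour_pairs(sn2)), 3)
  # identical neighbours give exactly 1
  sn3 <- snap_of(cbind(c(0, 1, 10, 11), 0, 0), rep(6, 4))
  expect_equal(pair_intensity_ratio(nearest_neighbour_pairs(sn3)), 1)
  # signed convention cancels
  expect_equal(pair_intensity_ratio(pr, convention = "signed"),
               mean(c(2, 0.5, 4, 0.25)))
})

test_that("pair correlation is 1 for identical channels and near 0 for independence", {
  gen <- generate_snapshot(n_nuclei = 300, rho = 0.999, seed = 3)
  pr <- nearest_neighbour_pairs(gen$snapshot)
  expect_gt(pair_correlation(pr), 0.9)

  rs <- sapply(1:5, function(s) {
    g <- generate_snapshot(n_nuclei = 2000, rho = 0, seed = s)
    pair_correlation(nearest_neighbour_pairs(g$snapshot))
  })
  expect_true(all(abs(rs) < 0.1))

  # salt-and-pepper anti-correlation is negative and inflates ratios
  gneg <- generate_snapshot(n_nuclei = 1000, rho = -0.6, seed = 9)
  gpos <- generate_snapshot(n_nuclei = 1000, rho = 0.9, seed = 9)
  pneg <- nearest_neighbour_pairs(gneg$snapshot)
  ppos <- nearest_neighbour_pairs(gpos$snapshot)
  expect_lt(pair_correlation(pneg), 0)
  expect_gt(pair_intensity_ratio(pneg), pair_intensity_ratio(ppos))
})

test_that("venus-positive fraction responds to the background threshold", {
  gen <- generate_snapshot(n_nuclei = 500, positive_fraction = 1, seed = 4)
  expect_equal(as.numeric(venus_positive_fraction(gen$snapshot,
                                                  gen$background)), 1)
  dim_snap <- gen$snapshot
  dim_snap$venus <- rep_len(gen$background, nrow(dim_snap)) * 0.2
  expect_equal(as.numeric(venus_positive_fraction(dim_snap,
                                                  gen$background)), 0)
  # 60% positives at 5x background recovered within 0.03
  gmix <- generate_snapshot(n_nuclei = 2000, positive_fraction = 0.6,
                            level_positive = 500, bg_level = 100, seed = 6)
  f <- venus_positive_fraction(gmix$snapshot, gmix$background)
  expect_equal(as.numeric(f), 0.6, tolerance = 0.05)
  expect_error(venus_positive_fraction(gmix$snapshot[0, ], gmix$background),
               "empty")
})

test_that("persistent close pairs threshold on the mean 3D distance", {
  t <- seq(0, 5, by = 0.5)
  mk <- function(id, x) tibble::tibble(cell_id = id, time = t, x = x,
                                       y = 0, z = 0,
                                       signal = 1, control = 1)
  near <- dplyr::bind_rows(mk("a", 0), mk("b", 10))
  expect_equal(nrow(persistent_close_pairs(near)), 1)
  far <- dplyr::bind_rows(mk("a", 0), mk("b", 20))
  expect_equal(nrow(persistent_close_pairs(far)), 0)
  # oscillating 10 <-> 22 with mean 16: rejected
  osc <- dplyr::bind_rows(mk("a", 0),
                          mk("b", rep(c(10, 22), length.out = length(t))))
  expect_equal(mean(abs(osc$x[osc$cell_id == "b"])), 16, tolerance = 0.6)
  expect_equal(nrow(persistent_close_pairs(osc)), 0)
  # no temporal overlap: skipped silently
  b2 <- mk("b", 1); b2$time <- b2$time + 100
  expect_equal(nrow(persistent_close_pairs(dplyr::bind_rows(mk("a", 0), b2))),
               0)
})
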