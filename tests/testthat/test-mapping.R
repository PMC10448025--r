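test_that("mapping pins every source knot to its target node", {
  src <- random_landmarks(1)
  tgt <- default_scale_nodes()
  m <- build_mapping(src, tgt)
  expect_equal(map_forward(m, src), tgt, tolerance = 1e-12)
  # midpoint of adjacent knots maps to midpoint of adjacent nodes
  mid <- (src[4] + src[5]) / 2
  expect_equal(map_forward(m, mid), (tgt[4] + tgt[5]) / 2,
               tolerance = 1e-12)
})

test_that("inputs beyond the outermost landmarks follow the terminal slope", {
  src <- random_landmarks(2)
  tgt <- default_scale_nodes()
  m <- build_mapping(src, tgt)
  slope_hi <- (tgt[11] - tgt[10]) / (src[11] - src[10])
  overshoot <- 37.5
  expect_equal(map_forward(m, src[11] + overshoot),
               100 + slope_hi * overshoot, tolerance = 1e-12)
  slope_lo <- (tgt[2] - tgt[1]) / (src[2] - src[1])
  expect_equal(map_forward(m, src[1] - 5), 1 - slope_lo * 5,
               tolerance = 1e-12)
})

test_that("coincident landmarks merge; fully flat images are unmappable", {
  src <- c(2, 2, 2, 4, 5, 6, 7, 8, 9, 10, 11)
  tgt <- default_scale_nodes()
  m <- build_mapping(src, tgt)
  # merged knot carries the mean of the three coincident targets
  expect_equal(map_forward(m, 2), mean(tgt[1:3]), tolerance = 1e-12)
  expect_equal(map_forward(m, 11), 100)
  expect_error(build_mapping(rep(3, 11), tgt), "unmappable")
})

test_that("window/limit conversions are exact algebraic inverses", {
  expect_equal(limits_from_window(400, 800), data.frame(LW = 0, UW = 800))
  expect_equal(limits_from_window(50, 20), data.frame(LW = 40, UW = 60))
  expect_equal(window_from_limits(0, 800), data.frame(WL = 400, WW = 800))
  expect_error(limits_from_window(10, 0), "WW must be > 0")
  expect_error(window_from_limits(5, 5), "UW > LW")
  set.seed(4)
  WL <- runif(100, -500, 3000); WW <- runif(100, 1e-3, 4000)
  lim <- limits_from_window(WL, WW)
  back <- window_from_limits(lim$LW, lim$UW)
  expect_equal(back$WL, WL)
  expect_equal(back$WW, WW)
})

test_that("standardization through a mapping matches limit-wise interpolation", {
  src <- random_landmarks(5)
  tgt <- sort(runif(11, 1, 100)); tgt[1] <- 1; tgt[11] <- 100
  m <- build_mapping(src, tgt)
  WL <- mean(src[c(3, 8)]); WW <- src[8] - src[3]
  got <- standardize_window(WL, WW, m)
  # oracle: interpolate each limit by explicit search over segments
  interp <- function(x) {
    if (x <= src[1]) return(tgt[1] + (x - src[1]) *
                              (tgt[2] - tgt[1]) / (src[2] - src[1]))
    if (x >= src[11]) return(tgt[11] + (x - src[11]) *
                               (tgt[11] - tgt[10]) / (src[11] - src[10]))
    k <- max(which(src <= x))
    if (k == 11) k <- 10
    tgt[k] + (x - src[k]) * (tgt[k + 1] - tgt[k]) / (src[k + 1] - src[k])
  }
  sLW <- interp(WL - WW / 2); sUW <- interp(WL + WW / 2)
  expect_equal(got$WL, (sLW + sUW) / 2, tolerance = 1e-12)
  expect_equal(got$WW, sUW - sLW, tolerance = 1e-12)
})

test_that("identity and linear maps act as expected on windows", {
  nodes <- default_scale_nodes()
  ident <- build_mapping(nodes, nodes)
  got <- standardize_window(42, 37, ident)
  expect_equal(got$WL, 42)
  expect_equal(got$WW, 37)
  doubling <- build_mapping(nodes, 2 * nodes)
  got2 <- standardize_window(42, 37, doubling)
  expect_equal(got2$WL, 84)
  expect_equal(got2$WW, 74)
})

test_that("standardize then destandardize is the identity (property)", {
  for (seed in 1:20) {
    set.seed(seed)
    src <- sort(runif(11, 5, 3000))
    tgt <- c(1, sort(runif(9, 2, 99)), 100)
    m <- build_mapping(src, tgt)
    # windows inside the hull and spilling past it
    WL <- runif(5, src[2], src[10])
    WW <- runif(5, 1, 3 * (src[11] - src[1]))
    sw <- standardize_window(WL, WW, m)
    back <- destandardize_window(sw$WL, sw$WW, m)
    expect_equal(back$WL, WL, tolerance = 1e-8)
    expect_equal(back$WW, WW, tolerance = 1e-8)
    expect_true(all(sw$WW > 0))
    # monotonicity inside the hull
    xs <- sort(runif(50, src[1], src[11]))
    ys <- map_forward(m, xs)
    expect_true(all(diff(ys) >= 0))
    expect_equal(map_inverse(m, ys), xs, tolerance = 1e-9)
  }
})
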