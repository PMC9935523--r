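# simulate a Gaussian random field with an exponential covariance so the
# variogram fit can be checked against known generating parameters
simulate_gaussian_field <- function(x, y, psill, range, nugget = 0,
                                    mean = 0, seed = 1) {
  set.seed(seed)
  d <- as.matrix(dist(cbind(x, y)))
  C <- psill * exp(-d / range) + diag(nugget, nrow(d))
  L <- chol(C + diag(1e-10, nrow(d)))
  mean + as.vector(t(L) %*% rnorm(nrow(d)))
}

test_that("WLS variogram fitting recovers exact model values", {
  # feed the fitter noiseless model evaluations: the weighted
  # least-squares machinery must return the generating parameters
  h <- seq(20, 600, length.out = 15)
  for (model in c("exponential", "spherical", "gaussian")) {
    truth <- list(nugget = 0.5, psill = 3, range = 180)
    emp <- data.frame(dist = h,
                      gamma = soilrisk:::vgm_value(h, model, truth$nugget,
                                                   truth$psill,
                                                   truth$range),
                      n = rep(50, length(h)))
    fit <- soilrisk:::fit_variogram(emp, model)
    expect_equal(fit$nugget, truth$nugget, tolerance = 0.02)
    expect_equal(fit$psill, truth$psill, tolerance = 0.02)
    expect_equal(fit$range, truth$range, tolerance = 0.05)
  }
})

test_that("variogram fit recovers parameters from simulated fields", {
  # a single realization carries large sampling variability in its
  # empirical variogram, so the recovery band is wide: total sill and
  # range within a factor of the truth, averaged over realizations
  n <- 180
  ratio_sill <- ratio_range <- numeric(5)
  for (k in 1:5) {
    set.seed(40 + k)
    x <- runif(n, 0, 1000); y <- runif(n, 0, 1000)
    z <- simulate_gaussian_field(x, y, psill = 4, range = 80,
                                 seed = 400 + k)
    m <- fit_interpolator(data.frame(x = x, y = y, value = z),
                          interpolator_config("ordinary_kriging",
                                              model = "exponential",
                                              nugget = 0))
    ratio_sill[k] <- m$variogram$psill / 4
    ratio_range[k] <- m$variogram$range / 80
  }
  expect_lt(abs(mean(ratio_sill) - 1), 0.35)
  expect_lt(abs(mean(ratio_range) - 1), 0.5)
})

test_that("constant fields degenerate gracefully", {
  df <- data.frame(x = runif(8, 0, 100), y = runif(8, 0, 100), value = 5)
  expect_warning(m <- fit_interpolator(
    df, interpolator_config("ordinary_kriging")), "constant")
  g <- predict_grid(m, raster_spec(0, 0, 20, 5, 5))
  expect_true(all(g$values[is.finite(g$values)] == 5))
  # IDW needs no fitting and also reproduces the constant
  mi <- fit_interpolator(df, interpolator_config("idw"))
  expect_null(mi$variogram)
  gi <- predict_grid(mi, raster_spec(0, 0, 20, 5, 5))
  expect_equal(gi$values[is.finite(gi$values)],
               rep(5, sum(is.finite(gi$values))))
})

test_that("duplicate sample locations are averaged with a message", {
  df <- data.frame(x = c(1, 1, 2, 3, 4, 5), y = c(1, 1, 2, 3, 4, 5),
                   value = c(2, 4, 1, 1, 1, 1))
  expect_message(m <- fit_interpolator(df, interpolator_config("idw")),
                 "duplicate")
  expect_equal(nrow(m$data), 5)
  expect_equal(m$data$z[m$data$x == 1], 3)
})

test_that("kriging with zero nugget interpolates exactly at samples", {
  set.seed(13)
  n <- 25
  df <- data.frame(x = runif(n, 0, 500), y = runif(n, 0, 500),
                   value = rnorm(n))
  cfg <- interpolator_config("ordinary_kriging", nugget = 0,
                             radius = 1000)
  m <- fit_interpolator(df, cfg)
  p <- soilrisk:::predict_points(m, df$x, df$y)
  expect_equal(p$pred, df$value, tolerance = 1e-8)
})

test_that("ordinary kriging weights sum to one", {
  set.seed(14)
  n <- 12
  df <- data.frame(x = runif(n, 0, 300), y = runif(n, 0, 300),
                   value = rnorm(n, 10, 2))
  m <- fit_interpolator(df, interpolator_config("ordinary_kriging",
                                                radius = 1000))
  px <- runif(20, 0, 300); py <- runif(20, 0, 300)
  p <- soilrisk:::predict_points(m, px, py, details = TRUE)
  for (w in p$weights) expect_equal(sum(w), 1, tolerance = 1e-8)
})

test_that("IDW predictions are convex combinations of neighbour values", {
  set.seed(15)
  n <- 40
  df <- data.frame(x = runif(n, 0, 400), y = runif(n, 0, 400),
                   value = runif(n, 2, 9))
  m <- fit_interpolator(df, interpolator_config("idw", radius = 1e4,
                                                max_neighbours = n))
  p <- soilrisk:::predict_points(m, runif(50, 0, 400), runif(50, 0, 400))
  expect_true(all(p$pred >= min(df$value) - 1e-12))
  expect_true(all(p$pred <= max(df$value) + 1e-12))
})

test_that("cells beyond the search radius are nodata", {
  df <- data.frame(x = rep(50, 5) + 0:4, y = rep(50, 5), value = 1:5)
  m <- fit_interpolator(df, interpolator_config("idw", radius = 30))
  g <- predict_grid(m, raster_spec(0, 0, cellsize = 10, ncols = 30,
                                   nrows = 10))
  cx <- 0 + (seq_len(30) - 0.5) * 10
  far <- cx > 120   # > 30 m from every sample
  expect_true(all(is.na(g$values[, far])))
  expect_true(any(is.finite(g$values)))
  expect_warning(predict_grid(m, raster_spec(5000, 5000, 10, 4, 4)),
                 "nodata")
})

test_that("predictions are invariant under coordinate translation", {
  set.seed(16)
  n <- 20
  df <- data.frame(x = runif(n, 0, 200), y = runif(n, 0, 200),
                   value = rnorm(n, 5))
  shift <- c(1234.5, -987.6)
  df2 <- transform(df, x = x + shift[1], y = y + shift[2])
  for (method in c("idw", "ordinary_kriging")) {
    cfg <- interpolator_config(method, radius = 500)
    m1 <- fit_interpolator(df, cfg)
    m2 <- fit_interpolator(df2, cfg)
    px <- runif(10, 0, 200); py <- runif(10, 0, 200)
    p1 <- soilrisk:::predict_points(m1, px, py)
    p2 <- soilrisk:::predict_points(m2, px + shift[1], py + shift[2])
    expect_equal(p1$pred, p2$pred, tolerance = 1e-8)
  }
})

test_that("cross-validation behaves on constant and noise fields", {
  set.seed(17)
  const <- data.frame(x = runif(20, 0, 100), y = runif(20, 0, 100),
                      value = 7)
  cv <- cross_validate(const, interpolator_config("idw", radius = 1000))
  expect_equal(cv$rmse, 0)
  # white noise: LOO RMSE close to the noise standard deviation
  n <- 200
  noise <- data.frame(x = runif(n, 0, 1000), y = runif(n, 0, 1000),
                      value = rnorm(n, 0, 2))
  cvn <- cross_validate(noise, interpolator_config("idw", radius = 1e4))
  expect_lt(abs(cvn$rmse - 2) / 2, 0.25)
  cvn2 <- cross_validate(noise, interpolator_config("idw", radius = 1e4))
  expect_identical(cvn$rmse, cvn2$rmse)
  expect_error(cross_validate(const[1:5, ],
                              interpolator_config("idw")), "at least 10")
})

test_that("ESRI ASCII grids round-trip through the standard header", {
  df <- data.frame(x = runif(12, 0, 100), y = runif(12, 0, 100),
                   value = runif(12, 1, 3))
  m <- fit_interpolator(df, interpolator_config("idw", radius = 500))
  g <- predict_grid(m, raster_spec(0, 0, cellsize = 25, ncols = 4,
                                   nrows = 3))
  path <- tempfile(fileext = ".asc")
  write_esri_ascii(g, path)
  lines <- readLines(path)
  expect_match(lines[1], "^ncols 4$")
  expect_match(lines[2], "^nrows 3$")
  expect_match(lines[3], "^xllcorner 0$")
  expect_match(lines[4], "^yllcorner 0$")
  expect_match(lines[5], "^cellsize 25$")
  expect_match(lines[6], "^NODATA_value -9999$")
  body <- read.table(text = lines[-(1:6)])
  expect_equal(dim(as.matrix(body)), c(3, 4))
  vals <- as.matrix(body)
  vals[vals == -9999] <- NA
  expect_equal(unname(vals), unname(g$values), tolerance = 1e-6)
})

test_that("fixture hotspots show up in the interpolated index surface", {
  sv <- fixture_towns()
  sg <- sv[sv$town == "Sharyn Gol", ]
  surf <- ipin_surface(sg, config = interpolator_config("idw"),
                       cellsize = 100)
  sp <- surf$raster$spec
  cx <- sp$xll + (seq_len(sp$ncols) - 0.5) * sp$cellsize
  cy <- sp$yll + (sp$nrows - seq_len(sp$nrows) + 0.5) * sp$cellsize
  xs <- matrix(rep(cx, each = sp$nrows), nrow = sp$nrows)
  ys <- matrix(rep(cy, times = sp$ncols), nrow = sp$nrows)
  d_east <- sqrt((xs - 2800)^2 + (ys - 1200)^2)
  v <- surf$raster$values
  near <- v[d_east < 400 & is.finite(v)]
  far <- v[d_east > 1500 & is.finite(v)]
  expect_gt(mean(near), mean(far))
})
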