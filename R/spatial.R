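#' Raster grid specification
#'
#' Regular grid definition in planar metres, lower-left anchored, matching
#' the ESRI ASCII grid header convention.
#'
#' @param xll,yll Coordinates of the lower-left corner of the grid (m).
#' @param cellsize Cell size in metres (default 10, the conventional
#'   output resolution for town-scale pollution maps).
#' @param ncols,nrows Grid dimensions (>= 1).
#' @param nodata Value written for cells with no prediction.
#' @return Object of class `raster_spec`.
#' @export
raster_spec <- function(xll, yll, cellsize = 10, ncols, nrows,
                        nodata = -9999) {
  stopifnot(is.finite(xll), is.finite(yll), cellsize > 0,
            ncols >= 1, nrows >= 1)
  structure(list(xll = xll, yll = yll, cellsize = cellsize,
                 ncols = as.integer(ncols), nrows = as.integer(nrows),
                 nodata = nodata),
            class = "raster_spec")
}

#' Raster specification covering a set of samples
#'
#' @param samples Data frame with `x`, `y`.
#' @param cellsize Cell size, metres.
#' @param pad Margin added around the sample extent, metres.
#' @return A [raster_spec()].
#' @export
raster_for_samples <- function(samples, cellsize = 10, pad = 0) {
  stopifnot(all(c("x", "y") %in% names(samples)))
  xr <- range(samples$x) + c(-pad, pad)
  yr <- range(samples$y) + c(-pad, pad)
  raster_spec(xll = xr[1], yll = yr[1], cellsize = cellsize,
              ncols = max(1L, ceiling(diff(xr) / cellsize)),
              nrows = max(1L, ceiling(diff(yr) / cellsize)))
}

#' Interpolator configuration
#'
#' Settings for spatial interpolation of point observations: inverse
#' distance weighting (`idw`) or ordinary kriging (`ordinary_kriging`)
#' with a classical semivariogram model fitted by weighted least squares.
#' Prediction uses a circular search neighbourhood (default radius 500 m);
#' cells with no observation inside the radius stay nodata.
#'
#' @param method `"idw"` or `"ordinary_kriging"`.
#' @param radius Search radius, metres (> 0).
#' @param power IDW distance-decay exponent (> 0).
#' @param model Semivariogram model: `"spherical"`, `"exponential"` or
#'   `"gaussian"`.
#' @param nugget,sill,range Optional fixed variogram parameters; left NULL
#'   they are estimated from the data (`sill` is the partial sill;
#'   `range` the model's distance parameter).
#' @param n_bins Number of distance bins of the empirical semivariogram
#'   (>= 8).
#' @param min_neighbours,max_neighbours Neighbour count bounds per
#'   prediction location.
#' @return Object of class `interpolator_config`.
#' @export
interpolator_config <- function(method = c("idw", "ordinary_kriging"),
                                radius = 500, power = 2,
                                model = c("exponential", "spherical",
                                          "gaussian"),
                                nugget = NULL, sill = NULL, range = NULL,
                                n_bins = 12, min_neighbours = 1,
                                max_neighbours = 16) {
  method <- match.arg(method)
  model <- match.arg(model)
  stopifnot(radius > 0, power > 0, n_bins >= 8,
            min_neighbours >= 1, max_neighbours >= min_neighbours)
  if (!is.null(nugget) && !is.null(sill) && (sill < 0 || nugget < 0)) {
    stop("variogram requires sill >= 0 and nugget >= 0", call. = FALSE)
  }
  structure(list(method = method, radius = radius, power = power,
                 model = model, nugget = nugget, sill = sill,
                 range = range, n_bins = n_bins,
                 min_neighbours = min_neighbours,
                 max_neighbours = max_neighbours),
            class = "interpolator_config")
}

# semivariogram model value at distances h
vgm_value <- function(h, model, nugget, psill, range) {
  g <- switch(model,
    exponential = psill * (1 - exp(-h / range)),
    gaussian    = psill * (1 - exp(-(h / range)^2)),
    spherical   = ifelse(h < range,
                         psill * (1.5 * h / range - 0.5 * (h / range)^3),
                         psill))
  ifelse(h > 0, nugget + g, 0)
}

# empirical semivariogram on n_bins equal-width distance bins up to cutoff
empirical_variogram <- function(x, y, z, n_bins, cutoff = NULL) {
  d <- as.matrix(stats::dist(cbind(x, y)))
  iu <- which(upper.tri(d), arr.ind = TRUE)
  h <- d[iu]
  g <- 0.5 * (z[iu[, 1]] - z[iu[, 2]])^2
  if (is.null(cutoff)) cutoff <- max(h) * 0.67
  keep <- h <= cutoff & h > 0
  h <- h[keep]; g <- g[keep]
  bin <- cut(h, seq(0, cutoff, length.out = n_bins + 1),
             include.lowest = TRUE)
  out <- data.frame(dist = as.numeric(tapply(h, bin, mean)),
                    gamma = as.numeric(tapply(g, bin, mean)),
                    n = as.integer(tapply(h, bin, length)))
  out[!is.na(out$dist), ]
}

# WLS variogram fit (weights = pair counts); parameters named in `fixed`
# are held at the given values during optimisation
fit_variogram <- function(emp, model, fixed = list()) {
  sill0 <- max(emp$gamma)
  par0 <- c(nugget = 0.1 * sill0 + 1e-12, psill = 0.9 * sill0 + 1e-12,
            range = max(emp$dist) / 3)
  lower <- c(nugget = 0, psill = 1e-12, range = max(emp$dist) * 1e-4)
  upper <- c(nugget = 10 * sill0 + 1, psill = 10 * sill0 + 1,
             range = 2 * max(emp$dist))
  fx <- c(nugget = fixed$nugget, psill = fixed$sill, range = fixed$range)
  free <- setdiff(names(par0), names(fx))
  full <- function(p_free) {
    p <- c(p_free, fx)[c("nugget", "psill", "range")]
    names(p) <- c("nugget", "psill", "range")
    p
  }
  obj <- function(p_free) {
    p <- full(p_free)
    g <- vgm_value(emp$dist, model, p[["nugget"]], p[["psill"]],
                   p[["range"]])
    sum(emp$n * (emp$gamma - g)^2)
  }
  if (length(free) == 0) return(as.list(fx[c("nugget", "psill", "range")]))
  # multi-start on the range axis: the WLS surface has local minima with
  # near-zero range (pure-nugget look-alikes)
  best <- NULL
  for (r0 in max(emp$dist) * c(1 / 20, 1 / 6, 1 / 3, 2 / 3)) {
    p0 <- par0[free]
    if ("range" %in% free) p0["range"] <- r0
    fit <- stats::optim(p0, obj, method = "L-BFGS-B",
                        lower = lower[free], upper = upper[free])
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  as.list(full(best$par))
}

#' Fit a spatial interpolator to point observations
#'
#' For IDW no fitting is done beyond validating the data. For ordinary
#' kriging, the empirical semivariogram is computed on at least 8 distance
#' bins and the configured model fitted by weighted least squares (weights
#' proportional to pair counts); any of nugget/sill/range given in the
#' config is held fixed. Duplicate coordinates are averaged with a
#' message. A constant field degenerates kriging; the fit then falls back
#' to a constant surface with a warning.
#'
#' @param samples Data frame with `x`, `y` and the observed variable.
#' @param config An [interpolator_config()].
#' @param value Name of the observation column (default `"value"`).
#' @return Object of class `soil_interpolator` holding the (deduplicated)
#'   data, the config and, for kriging, the fitted variogram
#'   (`$variogram$nugget/psill/range`, plus `$empirical`).
#' @export
fit_interpolator <- function(samples, config = interpolator_config(),
                             value = "value") {
  stopifnot(inherits(config, "interpolator_config"))
  if (!all(c("x", "y", value) %in% names(samples))) {
    stop("'samples' needs columns x, y and '", value, "'", call. = FALSE)
  }
  df <- data.frame(x = samples$x, y = samples$y, z = samples[[value]])
  df <- df[is.finite(df$x) & is.finite(df$y) & is.finite(df$z), ]
  if (nrow(df) < 5) stop("need at least 5 samples with finite ",
                         "coordinates and values", call. = FALSE)
  key <- paste(df$x, df$y)
  if (anyDuplicated(key)) {
    message(sum(duplicated(key)), " duplicate location(s) averaged")
    df <- do.call(rbind, lapply(split(df, key), function(p) {
      data.frame(x = p$x[1], y = p$y[1], z = mean(p$z))
    }))
  }
  out <- list(data = df, config = config, constant = NULL, variogram = NULL)
  if (stats::var(df$z) < .Machine$double.eps) {
    if (config$method == "ordinary_kriging") {
      warning("all values identical; kriging degenerates to a constant ",
              "surface", call. = FALSE)
      out$constant <- df$z[1]
    }
  } else if (config$method == "ordinary_kriging") {
    emp <- empirical_variogram(df$x, df$y, df$z, config$n_bins)
    fixed <- list(nugget = config$nugget, sill = config$sill,
                  range = config$range)
    out$variogram <- fit_variogram(emp, config$model, fixed)
    out$empirical <- emp
  }
  structure(out, class = "soil_interpolator")
}

#' @export
print.soil_interpolator <- function(x, ...) {
  cat(sprintf("Spatial interpolator: %s, %d points, radius %g m\n",
              x$config$method, nrow(x$data), x$config$radius))
  if (!is.null(x$variogram)) {
    cat(sprintf("  %s variogram: nugget %.4g, psill %.4g, range %.4g m\n",
                x$config$model, x$variogram$nugget, x$variogram$psill,
                x$variogram$range))
  }
  if (!is.null(x$constant)) cat("  constant surface:", x$constant, "\n")
  invisible(x)
}

# predict at arbitrary points; details = TRUE also returns the kriging /
# IDW weights of the last point (for diagnostics on small instances)
predict_points <- function(model, px, py, details = FALSE) {
  stopifnot(inherits(model, "soil_interpolator"))
  cfg <- model$config
  df <- model$data
  n <- length(px)
  pred <- rep(NA_real_, n)
  pvar <- rep(NA_real_, n)
  wlist <- if (details) vector("list", n) else NULL
  for (i in seq_len(n)) {
    d <- sqrt((df$x - px[i])^2 + (df$y - py[i])^2)
    nb <- which(d <= cfg$radius)
    if (length(nb) < cfg$min_neighbours) next
    if (length(nb) > cfg$max_neighbours) {
      nb <- nb[order(d[nb])[seq_len(cfg$max_neighbours)]]
    }
    if (!is.null(model$constant)) {
      pred[i] <- model$constant; pvar[i] <- 0
      if (details) wlist[[i]] <- rep(1 / length(nb), length(nb))
      next
    }
    dn <- d[nb]; zn <- df$z[nb]
    hit <- which(dn < 1e-9)
    if (length(hit) > 0) {
      # coincides with an observation: exact interpolation
      pred[i] <- zn[hit[1]]
      pvar[i] <- if (cfg$method == "ordinary_kriging")
        (model$variogram$nugget %||% 0) else 0
      if (details) {
        w <- numeric(length(nb)); w[hit[1]] <- 1; wlist[[i]] <- w
      }
      next
    }
    if (cfg$method == "idw") {
      w <- dn^(-cfg$power)
      w <- w / sum(w)
      pred[i] <- sum(w * zn); pvar[i] <- NA_real_
    } else {
      vg <- model$variogram
      G <- vgm_value(as.matrix(stats::dist(cbind(df$x[nb], df$y[nb]))),
                    cfg$model, vg$nugget, vg$psill, vg$range)
      g0 <- vgm_value(dn, cfg$model, vg$nugget, vg$psill, vg$range)
      m <- length(nb)
      A <- rbind(cbind(G, 1), c(rep(1, m), 0))
      sol <- tryCatch(solve(A, c(g0, 1)),
                      error = function(e) {
                        solve(A + diag(1e-10, m + 1), c(g0, 1))
                      })
      w <- sol[seq_len(m)]
      pred[i] <- sum(w * zn)
      pvar[i] <- max(0, sum(w * g0) + sol[m + 1])
    }
    if (details) wlist[[i]] <- w
  }
  out <- list(pred = pred, var = pvar)
  if (details) out$weights <- wlist
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Predict onto a regular raster
#'
#' Evaluates a fitted interpolator at every cell centre of a raster grid.
#' Cells with no observation inside the search radius are set to the
#' raster's nodata value. For ordinary kriging a prediction-variance
#' raster is returned as well; with a zero nugget the surface passes
#' exactly through the observations.
#'
#' @param model A fitted [fit_interpolator()] result.
#' @param rspec A [raster_spec()].
#' @return List of class `soil_raster`: `values` (nrows x ncols matrix,
#'   row 1 = northernmost row, ESRI ASCII order), `variance` (same shape,
#'   kriging only) and `spec`.
#' @export
predict_grid <- function(model, rspec) {
  stopifnot(inherits(rspec, "raster_spec"))
  cx <- rspec$xll + (seq_len(rspec$ncols) - 0.5) * rspec$cellsize
  cy <- rspec$yll + (rspec$nrows - seq_len(rspec$nrows) + 0.5) *
    rspec$cellsize
  px <- rep(cx, times = rspec$nrows)
  py <- rep(cy, each = rspec$ncols)
  res <- predict_points(model, px, py)
  vals <- matrix(res$pred, nrow = rspec$nrows, ncol = rspec$ncols,
                 byrow = TRUE)
  if (all(is.na(vals))) {
    warning("raster does not overlap the data within the search radius; ",
            "all cells nodata", call. = FALSE)
  }
  vr <- matrix(res$var, nrow = rspec$nrows, ncol = rspec$ncols,
               byrow = TRUE)
  structure(list(values = vals,
                 variance = if (model$config$method == "ordinary_kriging")
                   vr else NULL,
                 spec = rspec),
            class = "soil_raster")
}

#' Leave-one-out cross-validation of an interpolator
#'
#' Predicts every sample from all the others under the given
#' configuration and summarises the errors.
#'
#' @inheritParams fit_interpolator
#' @return List: `me` (mean error), `rmse`, `n_predicted`, and `details`
#'   (per-sample observed/predicted). Samples with no neighbour inside
#'   the radius are excluded from the summary.
#' @export
cross_validate <- function(samples, config = interpolator_config(),
                           value = "value") {
  if (!all(c("x", "y", value) %in% names(samples))) {
    stop("'samples' needs columns x, y and '", value, "'", call. = FALSE)
  }
  n <- nrow(samples)
  if (n < 10) stop("cross-validation needs at least 10 samples",
                   call. = FALSE)
  obs <- samples[[value]]
  pred <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    m <- fit_interpolator(samples[-i, , drop = FALSE], config, value)
    pred[i] <- predict_points(m, samples$x[i], samples$y[i])$pred
  }
  ok <- !is.na(pred)
  err <- pred[ok] - obs[ok]
  list(me = mean(err), rmse = sqrt(mean(err^2)),
       n_predicted = sum(ok),
       details = data.frame(x = samples$x, y = samples$y, observed = obs,
                            predicted = pred))
}

#' Write a raster as an ESRI ASCII grid
#'
#' Plain-text grid with the standard six-line header
#' (ncols/nrows/xllcorner/yllcorner/cellsize/NODATA_value) followed by the
#' rows from north to south.
#'
#' @param raster A `soil_raster` from [predict_grid()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_esri_ascii <- function(raster, path) {
  stopifnot(inherits(raster, "soil_raster"))
  sp <- raster$spec
  v <- raster$values
  v[is.na(v)] <- sp$nodata
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", sp$ncols),
    sprintf("nrows %d", sp$nrows),
    sprintf("xllcorner %.10g", sp$xll),
    sprintf("yllcorner %.10g", sp$yll),
    sprintf("cellsize %.10g", sp$cellsize),
    sprintf("NODATA_value %.10g", sp$nodata)
  ), con)
  utils::write.table(format(v, trim = TRUE, digits = 8), con,
                     row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Interpolated pollution-index surface for one town
#'
#' Convenience wrapper of the compute-then-interpolate workflow: computes
#' the per-sample integrated Nemerow index, fits the configured
#' interpolator and predicts onto a raster covering the town, returning
#' the index surface together with its severity-class raster.
#'
#' @param samples Soil-sample data frame for one town (finite `x`, `y`).
#' @param guideline Guideline set or built-in name for the index.
#' @param metals Metals entering the index.
#' @param config An [interpolator_config()].
#' @param cellsize Raster cell size, metres.
#' @return List: `raster` (`soil_raster` of IPI_N), `classes` (integer
#'   matrix, 1 = safe ... 5 = heavy, NA outside the search radius),
#'   `model`, `per_sample`.
#' @export
ipin_surface <- function(samples, guideline = "mns2019",
                         metals = c("Cd", "Cu", "Pb", "Zn"),
                         config = interpolator_config("ordinary_kriging"),
                         cellsize = 10) {
  check_samples(samples, require_coords = TRUE)
  ix <- survey_ipin(samples, guideline, metals)
  pts <- merge(ix$per_sample[, c("sample_id", "ipin")],
               samples[, c("sample_id", "x", "y")], by = "sample_id")
  names(pts)[names(pts) == "ipin"] <- "value"
  model <- fit_interpolator(pts, config)
  grid <- predict_grid(model, raster_for_samples(pts, cellsize))
  cls <- grid$values
  cls[] <- NA_integer_
  ok <- is.finite(grid$values)
  cls[ok] <- as.integer(classify_ipin(pmax(0, grid$values[ok])))
  list(raster = grid, classes = cls, model = model,
       per_sample = ix$per_sample)
}
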