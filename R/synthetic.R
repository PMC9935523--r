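#' Hexagonal sampling network inside a rectangle
#'
#' Generates a regular triangular (hexagonal-packing) lattice of sampling
#' points clipped to a bounding box, with the lattice pitch chosen by
#' bisection so that exactly `n_target` points remain. When a pitch yields
#' more points than requested, the surplus points closest to the box
#' boundary are dropped, ties broken deterministically by (y, x) order.
#' The lattice is anchored at the box centroid, so `n_target = 1` returns
#' the centroid itself.
#'
#' @param bbox Numeric vector `c(xmin, ymin, xmax, ymax)` in metres;
#'   must have positive area.
#' @param n_target Number of points required (>= 1).
#' @return Data frame with columns `x`, `y` (n_target rows, ordered by
#'   (y, x)).
#' @examples
#' nrow(hex_grid_points(c(0, 0, 1000, 800), 48))
#' @export
hex_grid_points <- function(bbox, n_target) {
  stopifnot(length(bbox) == 4, is.finite(bbox))
  xmin <- bbox[1]; ymin <- bbox[2]; xmax <- bbox[3]; ymax <- bbox[4]
  if (xmax <= xmin || ymax <= ymin) {
    stop("'bbox' must have positive area", call. = FALSE)
  }
  if (n_target < 1) stop("'n_target' must be >= 1", call. = FALSE)
  area <- (xmax - xmin) * (ymax - ymin)

  lattice <- function(pitch) {
    # triangular lattice: row spacing pitch*sqrt(3)/2, alternate rows
    # offset by pitch/2; anchored at the centroid
    cx <- (xmin + xmax) / 2; cy <- (ymin + ymax) / 2
    dy <- pitch * sqrt(3) / 2
    jmax <- ceiling((ymax - ymin) / (2 * dy)) + 1
    imax <- ceiling((xmax - xmin) / (2 * pitch)) + 1
    pts <- do.call(rbind, lapply(seq(-jmax, jmax), function(j) {
      xs <- cx + (seq(-imax, imax) + (j %% 2) / 2) * pitch
      cbind(x = xs, y = cy + j * dy)
    }))
    keep <- pts[, "x"] >= xmin & pts[, "x"] <= xmax &
            pts[, "y"] >= ymin & pts[, "y"] <= ymax
    pts[keep, , drop = FALSE]
  }

  # nominal pitch for a hexagonal packing of n_target points in `area`
  p0 <- sqrt(2 * area / (sqrt(3) * n_target))
  lo <- p0 / 8; hi <- p0 * 8
  if (nrow(lattice(lo)) < n_target) {
    lo <- p0 / 64
    if (nrow(lattice(lo)) < n_target) {
      stop("'n_target' exceeds the achievable lattice density", call. = FALSE)
    }
  }
  for (k in seq_len(64)) {
    mid <- (lo + hi) / 2
    if (nrow(lattice(mid)) >= n_target) lo <- mid else hi <- mid
  }
  pts <- lattice(lo)
  if (nrow(pts) > n_target) {
    bdist <- pmin(pts[, "x"] - xmin, xmax - pts[, "x"],
                  pts[, "y"] - ymin, ymax - pts[, "y"])
    ord <- order(bdist, pts[, "y"], pts[, "x"])
    drop <- ord[seq_len(nrow(pts) - n_target)]
    pts <- pts[-drop, , drop = FALSE]
  }
  pts <- pts[order(pts[, "y"], pts[, "x"]), , drop = FALSE]
  data.frame(x = unname(pts[, "x"]), y = unname(pts[, "y"]))
}

#' Specify a synthetic town survey
#'
#' Describes one town of a synthetic soil survey: its extent, the number
#' of samples on the hexagonal network, the target arithmetic mean and
#' coefficient of variation of each metal's lognormal concentration
#' distribution, and optional pollution hotspots applied as multiplicative
#' distance-decaying enrichment.
#'
#' @param name Town name.
#' @param bbox Bounding box `c(xmin, ymin, xmax, ymax)`, metres.
#' @param n_samples Number of samples (>= 1).
#' @param means Named numeric vector of target arithmetic means, mg/kg,
#'   strictly positive; names from [soil_metals()].
#' @param cv Coefficient of variation of each metal's lognormal
#'   distribution (>= 0; 0 gives the degenerate constant-at-mean limit).
#' @param hotspots List of hotspots, each `list(x =, y =, radius =,
#'   enrich =)` with `enrich` a named multiplier vector (>= 1) applied
#'   with linear decay from the centre to the radius.
#' @param seed Integer seed making the simulated survey reproducible.
#' @return Object of class `town_spec`.
#' @export
town_spec <- function(name, bbox, n_samples, means, cv = 0.5,
                      hotspots = list(), seed = 1L) {
  stopifnot(is.character(name), n_samples >= 1)
  check_metals(names(means))
  if (any(!is.finite(means)) || any(means <= 0)) {
    stop("'means' must be finite and strictly positive", call. = FALSE)
  }
  if (!is.finite(cv) || cv < 0) {
    stop("'cv' must be non-negative (moment matching is unsolvable ",
         "otherwise)", call. = FALSE)
  }
  for (h in hotspots) {
    stopifnot(is.finite(h$x), is.finite(h$y), h$radius > 0)
    if (any(h$enrich < 1)) stop("hotspot enrichment must be >= 1",
                                call. = FALSE)
  }
  structure(list(name = name, bbox = bbox, n_samples = n_samples,
                 means = means, cv = cv, hotspots = hotspots,
                 seed = as.integer(seed)),
            class = "town_spec")
}

hotspot_factor <- function(x, y, hotspots, metal) {
  f <- rep(1, length(x))
  for (h in hotspots) {
    e <- h$enrich[metal]
    if (is.na(e)) next
    d <- sqrt((x - h$x)^2 + (y - h$y)^2)
    w <- pmax(0, 1 - d / h$radius)      # linear decay to the radius
    f <- f * (1 + (e - 1) * w)
  }
  f
}

#' Simulate a town survey
#'
#' Draws sample locations on the hexagonal network and i.i.d. lognormal
#' concentrations per metal, with the lognormal parameters solved from the
#' target arithmetic mean m and coefficient of variation cv
#' (sigma^2 = log(1 + cv^2), mu = log m - sigma^2/2, so E X = m exactly).
#' Hotspot enrichment is applied multiplicatively afterwards. The result
#' is fully reproducible from the spec's integer seed.
#'
#' @param spec A [town_spec()].
#' @param seed Optional override of `spec$seed`.
#' @return Soil-sample data frame: `sample_id`, `town`, `x`, `y` and one
#'   column per metal (mg/kg).
#' @examples
#' sp <- town_spec("Demo", c(0, 0, 2000, 1500), 20,
#'                 means = c(Cd = 0.9, Pb = 30), seed = 7)
#' head(simulate_survey(sp))
#' @export
simulate_survey <- function(spec, seed = spec$seed) {
  stopifnot(inherits(spec, "town_spec"))
  pts <- hex_grid_points(spec$bbox, spec$n_samples)
  out <- data.frame(
    sample_id = sprintf("%s-%03d", toupper(substr(spec$name, 1, 3)),
                        seq_len(spec$n_samples)),
    town = spec$name, x = pts$x, y = pts$y,
    stringsAsFactors = FALSE
  )
  set.seed(seed, kind = "Mersenne-Twister")
  sigma2 <- log(1 + spec$cv^2)
  for (m in names(spec$means)) {
    mu <- log(spec$means[[m]]) - sigma2 / 2
    v <- if (sigma2 == 0) rep(spec$means[[m]], spec$n_samples)
         else stats::rlnorm(spec$n_samples, meanlog = mu,
                            sdlog = sqrt(sigma2))
    out[[m]] <- v * hotspot_factor(out$x, out$y, spec$hotspots, m)
  }
  out
}

# Rescale v so that sum equals target_sum while no element exceeds cap.
# Capped elements are frozen and the remainder rescaled exactly; iterates
# until no new element hits the cap.
cap_rescale <- function(v, target_sum, cap) {
  if (length(v) * cap < target_sum) {
    stop("cap_rescale: target sum not attainable under the cap",
         call. = FALSE)
  }
  capped <- rep(FALSE, length(v))
  out <- v
  repeat {
    s <- (target_sum - sum(out[capped])) / sum(v[!capped])
    out[!capped] <- s * v[!capped]
    newly <- !capped & out > cap
    if (!any(newly)) break
    out[newly] <- cap
    capped <- capped | newly
  }
  out
}

#' Built-in three-town fixture survey
#'
#' A deterministic synthetic survey emulating the design of a three-town
#' coal-mining survey: 48 (Baganuur), 50 (Nalaikh) and 44 (Sharyn Gol)
#' composite topsoil samples — 142 in total — on hexagonal networks, with
#' right-skewed Cd/Cu/Pb/Zn concentrations whose town arithmetic means are
#' post-scaled to equal the reference town means exactly
#' (Baganuur 0.87/13.6/29.6/51.7, Nalaikh 1.21/13.8/36.4/73.7, Sharyn Gol
#' 1.46/22.1/69.0/87.6 mg/kg for Cd/Cu/Pb/Zn). Town-centre hotspots
#' (all towns) and an eastern mining-waste gradient (Sharyn Gol) provide
#' spatial structure. Exactly one Cu concentration (Baganuur) and three Pb
#' concentrations (Sharyn Gol) exceed the Mongolian permissible values;
#' the exceedances are injected at hotspot-adjacent samples and the
#' remaining samples compensatorily rescaled (capped just below the
#' threshold) so the exact town means are preserved.
#'
#' @param seed Integer seed; the default gives the canonical fixture.
#' @param cv Lognormal coefficient of variation before rescaling.
#' @return Soil-sample data frame with 142 rows.
#' @examples
#' sv <- fixture_towns()
#' table(sv$town)
#' @export
fixture_towns <- function(seed = 142L, cv = 0.5) {
  mns <- builtin_guidelines()$mns2019$thresholds
  towns <- list(
    town_spec("Baganuur", c(0, 0, 3600, 2700), 48,
              means = c(Cd = 0.87, Cu = 13.6, Pb = 29.6, Zn = 51.7),
              cv = cv,
              hotspots = list(list(x = 1800, y = 1350, radius = 800,
                                   enrich = c(Cd = 1.6, Cu = 1.8, Pb = 1.6,
                                              Zn = 1.6))),
              seed = seed),
    town_spec("Nalaikh", c(0, 0, 3800, 2700), 50,
              means = c(Cd = 1.21, Cu = 13.8, Pb = 36.4, Zn = 73.7),
              cv = cv,
              hotspots = list(list(x = 1900, y = 1350, radius = 700,
                                   enrich = c(Cd = 1.4, Cu = 1.4, Pb = 1.4,
                                              Zn = 1.4))),
              seed = seed + 1L),
    town_spec("Sharyn Gol", c(0, 0, 2800, 2400), 44,
              means = c(Cd = 1.46, Cu = 22.1, Pb = 69.0, Zn = 87.6),
              cv = cv,
              hotspots = list(
                list(x = 1400, y = 1200, radius = 600,
                     enrich = c(Cd = 1.4, Cu = 1.4, Pb = 1.4, Zn = 1.4)),
                list(x = 2800, y = 1200, radius = 1000,
                     enrich = c(Cd = 2.0, Cu = 2.0, Pb = 2.0, Zn = 2.0))),
              seed = seed + 2L)
  )
  # MNS exceedances to inject: (town, metal, values as multiples of the
  # permissible content), placed at the samples nearest the listed hotspot
  inject <- list(
    list(town = "Baganuur", metal = "Cu", ratios = 1.10,
         at = c(1800, 1350)),
    list(town = "Sharyn Gol", metal = "Pb", ratios = c(1.05, 1.15, 1.30),
         at = c(2800, 1200))
  )
  surveys <- lapply(towns, simulate_survey)
  for (k in seq_along(surveys)) {
    sv <- surveys[[k]]
    spec <- towns[[k]]
    for (m in names(spec$means)) {
      thr <- mns[[m]]
      target_sum <- spec$means[[m]] * nrow(sv)
      inj <- Filter(function(z) z$town == spec$name && z$metal == m, inject)
      exceed_idx <- integer(0)
      if (length(inj) == 1) {
        z <- inj[[1]]
        d <- sqrt((sv$x - z$at[1])^2 + (sv$y - z$at[2])^2)
        exceed_idx <- order(d)[seq_along(z$ratios)]
        sv[[m]][exceed_idx] <- z$ratios * thr
        target_sum <- target_sum - sum(sv[[m]][exceed_idx])
      }
      rest <- setdiff(seq_len(nrow(sv)), exceed_idx)
      sv[[m]][rest] <- cap_rescale(sv[[m]][rest], target_sum, 0.98 * thr)
    }
    surveys[[k]] <- sv
  }
  out <- do.call(rbind, surveys)
  row.names(out) <- NULL
  out
}
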