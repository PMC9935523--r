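# Reference town-mean concentrations (mg/kg) for the three coal-mining
# towns, and the published average risk values recomputed throughout the
# suite.

town_means <- function() {
  data.frame(
    town = c("Baganuur", "Nalaikh", "Sharyn Gol"),
    Cd = c(0.87, 1.21, 1.46),
    Cu = c(13.6, 13.8, 22.1),
    Pb = c(29.6, 36.4, 69.0),
    Zn = c(51.7, 73.7, 87.6),
    stringsAsFactors = FALSE
  )
}

# Published average risk table (3 s.f., scientific notation): one row per
# town x receptor x metal with HQ via ingestion, HQ via dermal contact,
# HI and (Cd, Pb only) CR.
published_risk <- function() {
  rows <- rbind(
    c("Baganuur",   "adult", "Cd", 1.28e-3, 3.90e-4, 1.67e-3, 6.59e-6),
    c("Baganuur",   "child", "Cd", 1.05e-2, 1.68e-3, 1.21e-2, 1.35e-5),
    c("Nalaikh",    "adult", "Cd", 1.79e-3, 5.44e-4, 2.33e-3, 9.19e-6),
    c("Nalaikh",    "child", "Cd", 1.46e-2, 2.34e-3, 1.69e-2, 1.88e-5),
    c("Sharyn Gol", "adult", "Cd", 2.15e-3, 6.55e-4, 2.81e-3, 1.11e-5),
    c("Sharyn Gol", "child", "Cd", 1.76e-2, 2.82e-3, 2.04e-2, 2.26e-5),
    c("Baganuur",   "adult", "Cu", 5.03e-4, 5.11e-6, 5.09e-4, NA),
    c("Baganuur",   "child", "Cu", 4.12e-3, 2.20e-5, 4.14e-3, NA),
    c("Nalaikh",    "adult", "Cu", 5.09e-4, 5.16e-6, 5.14e-4, NA),
    c("Nalaikh",    "child", "Cu", 4.16e-3, 2.22e-5, 4.18e-3, NA),
    c("Sharyn Gol", "adult", "Cu", 8.16e-4, 8.28e-6, 8.24e-4, NA),
    c("Sharyn Gol", "child", "Cu", 6.67e-3, 3.56e-5, 6.71e-3, NA),
    c("Baganuur",   "adult", "Pb", 1.25e-2, 2.53e-4, 1.27e-2, 1.27e-7),
    c("Baganuur",   "child", "Pb", 1.02e-1, 1.09e-3, 1.03e-1, 2.60e-7),
    c("Nalaikh",    "adult", "Pb", 1.53e-2, 3.12e-4, 1.57e-2, 1.57e-7),
    c("Nalaikh",    "child", "Pb", 1.25e-1, 1.34e-3, 1.27e-1, 3.20e-7),
    c("Sharyn Gol", "adult", "Pb", 2.91e-2, 5.91e-4, 2.97e-2, 2.97e-7),
    c("Sharyn Gol", "child", "Pb", 2.38e-1, 2.54e-3, 2.40e-1, 6.07e-7),
    c("Baganuur",   "adult", "Zn", 2.54e-4, 3.87e-6, 2.58e-4, NA),
    c("Baganuur",   "child", "Zn", 2.08e-3, 1.66e-5, 2.10e-3, NA),
    c("Nalaikh",    "adult", "Zn", 3.62e-4, 5.52e-6, 3.68e-4, NA),
    c("Nalaikh",    "child", "Zn", 2.96e-3, 2.37e-5, 2.99e-3, NA),
    c("Sharyn Gol", "adult", "Zn", 4.31e-4, 6.56e-6, 4.37e-4, NA),
    c("Sharyn Gol", "child", "Zn", 3.52e-3, 2.82e-5, 3.55e-3, NA)
  )
  out <- data.frame(town = rows[, 1], receptor = rows[, 2],
                    metal = rows[, 3],
                    hq_ing = as.numeric(rows[, 4]),
                    hq_derm = as.numeric(rows[, 5]),
                    hi = as.numeric(rows[, 6]),
                    cr = as.numeric(rows[, 7]),
                    stringsAsFactors = FALSE)
  out
}

# small random survey for property tests
random_survey <- function(n = 20, towns = c("A", "B"), seed = 1) {
  set.seed(seed)
  data.frame(
    sample_id = sprintf("S%03d", seq_len(n)),
    town = sample(towns, n, replace = TRUE),
    x = runif(n, 0, 1000), y = runif(n, 0, 1000),
    Cd = rlnorm(n, log(0.8), 0.5),
    Cu = rlnorm(n, log(15), 0.5),
    Pb = rlnorm(n, log(30), 0.5),
    Zn = rlnorm(n, log(60), 0.5),
    stringsAsFactors = FALSE
  )
}

rel_err <- function(got, want) abs(got - want) / abs(want)
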