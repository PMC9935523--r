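#' Construct an exposure scenario
#'
#' Bundle of receptor-specific exposure parameters for the soil ingestion
#' and dermal contact pathways of a deterministic US-EPA-style risk
#' assessment.
#'
#' @param receptor Receptor label, e.g. `"adult"` or `"child"`.
#' @param IngR Soil ingestion rate, mg/day.
#' @param EF Exposure frequency, days/year.
#' @param ED Exposure duration, years.
#' @param BW Body weight, kg.
#' @param SA Exposed skin surface area, cm^2.
#' @param AF Soil-to-skin adherence factor, mg/cm^2.
#' @param LT Lifetime, years (sets the carcinogenic averaging time).
#' @param AT_nc Averaging time for non-carcinogenic effects, days; defaults
#'   to `ED * 365`.
#' @param AT_ca Averaging time for carcinogenic effects, days; defaults to
#'   `LT * 365`.
#' @return Object of class `exposure_scenario`.
#' @export
exposure_scenario <- function(receptor, IngR, EF, ED, BW, SA, AF, LT = 70,
                              AT_nc = ED * 365, AT_ca = LT * 365) {
  vals <- c(IngR = IngR, EF = EF, ED = ED, BW = BW, SA = SA, AF = AF,
            LT = LT, AT_nc = AT_nc, AT_ca = AT_ca)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all exposure parameters must be finite and strictly positive",
         call. = FALSE)
  }
  structure(c(list(receptor = receptor), as.list(vals)),
            class = "exposure_scenario")
}

#' @export
print.exposure_scenario <- function(x, ...) {
  cat(sprintf(paste0("Exposure scenario '%s': IngR %g mg/d, EF %g d/y, ",
                     "ED %g y, BW %g kg,\n  SA %g cm2, AF %g mg/cm2, ",
                     "AT_nc %g d, AT_ca %g d\n"),
              x$receptor, x$IngR, x$EF, x$ED, x$BW, x$SA, x$AF,
              x$AT_nc, x$AT_ca))
  invisible(x)
}

#' Built-in adult and child exposure scenarios
#'
#' Default receptor parameterisation: an adult (soil ingestion 100 mg/day,
#' exposure 350 days/year over 24 years, body weight 65.0 kg, skin area
#' 4350 cm^2, adherence 0.07 mg/cm^2) and a child (200 mg/day, 350
#' days/year over 6 years, 15.9 kg, 1600 cm^2, 0.20 mg/cm^2). The body
#' weights reflect Mongolian adults and, for children, values used in
#' neighbouring China. Non-carcinogenic averaging time is ED x 365 (8760 /
#' 2190 days); carcinogenic averaging time is LT x 365 = 25550 days with a
#' 70-year lifetime for both receptors.
#'
#' @return Named list of two [exposure_scenario()] objects (`adult`,
#'   `child`).
#' @export
builtin_scenarios <- function() {
  list(
    adult = exposure_scenario("adult", IngR = 100, EF = 350, ED = 24,
                              BW = 65.0, SA = 4350, AF = 0.07, LT = 70),
    child = exposure_scenario("child", IngR = 200, EF = 350, ED = 6,
                              BW = 15.9, SA = 1600, AF = 0.20, LT = 70)
  )
}

#' Built-in toxicity profile
#'
#' Oral and dermal reference doses (RfD, mg/(kg day)), dermal absorption
#' fraction (ABS) and — for the carcinogens Cd and Pb — the oral slope
#' factor (SF, (mg/(kg day))^-1) for the four routinely measured metals.
#' Values can be overridden or extended by passing a modified copy of this
#' data frame wherever a `tox` argument is accepted.
#'
#' @return Data frame with columns `metal`, `rfd_ing`, `rfd_derm`, `abs`,
#'   `sf_ing` (NA where the metal is not treated as a carcinogen).
#' @export
builtin_toxicity <- function() {
  data.frame(
    metal   = c("Cd", "Cu", "Pb", "Zn"),
    rfd_ing  = c(1.00e-3, 4.00e-2, 3.50e-3, 3.00e-1),
    rfd_derm = c(1.00e-5, 1.20e-2, 5.25e-4, 6.00e-2),
    abs      = c(0.001, 0.001, 0.001, 0.001),
    sf_ing   = c(1.50e+1, NA, 8.50e-3, NA),
    stringsAsFactors = FALSE
  )
}

tox_row <- function(tox, metal) {
  i <- match(metal, tox$metal)
  if (is.na(i)) stop("no toxicity values for metal '", metal, "'",
                     call. = FALSE)
  tox[i, ]
}

pick_at <- function(s, averaging = c("nc", "ca")) {
  averaging <- match.arg(averaging)
  if (averaging == "nc") s$AT_nc else s$AT_ca
}

#' Average daily dose via soil ingestion
#'
#' ADD_ing = C_soil x IngR x EF x ED / (BW x AT) x 1e-6, in mg/(kg day);
#' the 1e-6 factor converts mg/kg soil to kg/mg intake. `averaging`
#' selects the non-carcinogenic (`"nc"`, AT = ED x 365) or carcinogenic
#' (`"ca"`, AT = LT x 365) averaging time.
#'
#' @param c_soil Soil concentration, mg/kg dry soil, non-negative
#'   (vectorised).
#' @param scenario An [exposure_scenario()].
#' @param averaging `"nc"` or `"ca"`.
#' @return Dose(s) in mg/(kg day).
#' @examples
#' add_ingestion(0.87, builtin_scenarios()$adult, "nc")  # 1.283e-06
#' @export
add_ingestion <- function(c_soil, scenario, averaging = c("nc", "ca")) {
  stopifnot(inherits(scenario, "exposure_scenario"))
  if (any(c_soil < 0, na.rm = TRUE)) stop("'c_soil' must be non-negative",
                                          call. = FALSE)
  at <- pick_at(scenario, averaging)
  c_soil * scenario$IngR * scenario$EF * scenario$ED /
    (scenario$BW * at) * 1e-6
}

#' Average daily dose via dermal contact
#'
#' ADD_derm = C_soil x SA x AF x ABS x EF x ED / (BW x AT) x 1e-6, in
#' mg/(kg day).
#'
#' @inheritParams add_ingestion
#' @param abs Dermal absorption fraction, in (0, 1].
#' @return Dose(s) in mg/(kg day).
#' @examples
#' add_dermal(0.87, builtin_scenarios()$adult, abs = 0.001, "nc")
#' @export
add_dermal <- function(c_soil, scenario, abs, averaging = c("nc", "ca")) {
  stopifnot(inherits(scenario, "exposure_scenario"))
  if (any(c_soil < 0, na.rm = TRUE)) stop("'c_soil' must be non-negative",
                                          call. = FALSE)
  if (!is.finite(abs) || abs <= 0 || abs > 1) {
    stop("'abs' must lie in (0, 1]", call. = FALSE)
  }
  at <- pick_at(scenario, averaging)
  c_soil * scenario$SA * scenario$AF * abs * scenario$EF * scenario$ED /
    (scenario$BW * at) * 1e-6
}

#' Hazard quotients and hazard index for one metal
#'
#' HQ_ing = ADD_ing / RfD_ing and HQ_derm = ADD_derm / RfD_derm at the
#' non-carcinogenic averaging time; HI is their sum over the two exposure
#' pathways considered (ingestion and dermal contact). HI > 1 flags the
#' probability of non-carcinogenic adverse health effects.
#'
#' @inheritParams add_ingestion
#' @param metal Metal symbol with an entry in `tox`.
#' @param tox Toxicity table as from [builtin_toxicity()].
#' @return List `hq_ing`, `hq_derm`, `hi`, `hi_exceeds_1` (vectorised over
#'   `c_soil`).
#' @examples
#' hazard_index(0.87, "Cd", builtin_scenarios()$adult)
#' @export
hazard_index <- function(c_soil, metal, scenario, tox = builtin_toxicity()) {
  tr <- tox_row(tox, metal)
  if (is.na(tr$rfd_ing)) stop("missing ingestion RfD for metal '", metal,
                              "'", call. = FALSE)
  if (is.na(tr$rfd_derm)) stop("missing dermal RfD for metal '", metal,
                               "'", call. = FALSE)
  hq_ing <- add_ingestion(c_soil, scenario, "nc") / tr$rfd_ing
  hq_derm <- add_dermal(c_soil, scenario, tr$abs, "nc") / tr$rfd_derm
  hi <- hq_ing + hq_derm
  list(hq_ing = hq_ing, hq_derm = hq_derm, hi = hi, hi_exceeds_1 = hi > 1)
}

#' Carcinogenic risk for one metal
#'
#' CR = ADD_ing(carcinogenic averaging) x SF_ing: the incremental lifetime
#' cancer probability via soil ingestion, the only pathway with a slope
#' factor in the built-in profile. Calling this for a metal without a
#' slope factor is an error, never silently zero.
#'
#' @inheritParams hazard_index
#' @return List `cr` and `cr_category` (see [cr_category()]).
#' @examples
#' carcinogenic_risk(0.87, "Cd", builtin_scenarios()$child)
#' @export
carcinogenic_risk <- function(c_soil, metal, scenario,
                              tox = builtin_toxicity()) {
  tr <- tox_row(tox, metal)
  if (is.na(tr$sf_ing)) {
    stop("metal '", metal, "' has no ingestion slope factor in this ",
         "toxicity profile (not treated as a carcinogen)", call. = FALSE)
  }
  cr <- add_ingestion(c_soil, scenario, "ca") * tr$sf_ing
  list(cr = cr, cr_category = cr_category(cr))
}

#' Regulatory carcinogenic-risk category
#'
#' `virtually_safe` for CR <= 1e-6, `acceptable` in (1e-6, 1e-4) (the
#' acceptable total risk range for regulatory purposes), `unacceptable`
#' for CR >= 1e-4.
#'
#' @param cr Numeric vector of non-negative risks.
#' @return Factor with levels `virtually_safe < acceptable < unacceptable`.
#' @export
cr_category <- function(cr) {
  if (any(!is.finite(cr)) || any(cr < 0)) {
    stop("'cr' must be finite and non-negative", call. = FALSE)
  }
  cls <- ifelse(cr <= 1e-6, "virtually_safe",
         ifelse(cr < 1e-4, "acceptable", "unacceptable"))
  factor(cls, levels = c("virtually_safe", "acceptable", "unacceptable"),
         ordered = TRUE)
}

#' Full risk table per town, receptor and metal
#'
#' Runs the hazard and carcinogenic-risk calculations for every
#' combination of town, receptor and metal and returns one table in the
#' conventional layout of deterministic soil risk assessments: HQ via
#' ingestion, HQ via dermal contact, HI and (where a slope factor exists)
#' CR with its category.
#'
#' Input can be either per-sample survey data (each town's risks are then
#' averages of per-sample risks) or a table of town-mean concentrations
#' (`means = TRUE`). Because every dose is linear in concentration the
#' two conventions agree exactly.
#'
#' @param data Data frame: per-sample survey (columns `sample_id`, `town`,
#'   metals) or per-town means (column `town` plus metal columns) with
#'   `means = TRUE`.
#' @param scenarios List of [exposure_scenario()] objects; default
#'   [builtin_scenarios()].
#' @param tox Toxicity table; default [builtin_toxicity()].
#' @param metals Metals to assess; default intersection of `tox$metal`
#'   with the data's metal columns.
#' @param means Set `TRUE` when `data` holds town-mean concentrations.
#' @return Data frame of class `risk_table`: `town`, `receptor`, `metal`,
#'   `mean_conc`, `hq_ing`, `hq_derm`, `hi`, `cr`, `cr_category` (NA for
#'   non-carcinogens).
#' @examples
#' tm <- data.frame(town = "Baganuur", Cd = 0.87, Cu = 13.6,
#'                  Pb = 29.6, Zn = 51.7)
#' risk_table(tm, means = TRUE)
#' @export
risk_table <- function(data, scenarios = builtin_scenarios(),
                       tox = builtin_toxicity(), metals = NULL,
                       means = FALSE) {
  if (!is.data.frame(data) || nrow(data) == 0) {
    stop("'data' must be a non-empty data frame", call. = FALSE)
  }
  if (!"town" %in% names(data)) stop("missing 'town' column", call. = FALSE)
  if (is.null(metals)) metals <- intersect(tox$metal, names(data))
  check_metals(metals)
  if (length(metals) == 0) stop("no assessable metal columns in 'data'",
                                call. = FALSE)
  towns <- unique(data$town)
  town_means <- do.call(rbind, lapply(towns, function(tn) {
    rows <- data[data$town == tn, metals, drop = FALSE]
    if (means && nrow(rows) != 1L) {
      stop("with means = TRUE, expected one row per town", call. = FALSE)
    }
    colMeans(as.matrix(rows), na.rm = TRUE)
  }))
  out <- do.call(rbind, lapply(towns, function(tn) {
    do.call(rbind, lapply(names(scenarios), function(r) {
      s <- scenarios[[r]]
      do.call(rbind, lapply(metals, function(m) {
        cm <- town_means[match(tn, towns), m]
        h <- hazard_index(cm, m, s, tox)
        has_sf <- !is.na(tox_row(tox, m)$sf_ing)
        cr <- if (has_sf) carcinogenic_risk(cm, m, s, tox) else NULL
        data.frame(town = tn, receptor = r, metal = m, mean_conc = cm,
                   hq_ing = h$hq_ing, hq_derm = h$hq_derm, hi = h$hi,
                   cr = if (has_sf) cr$cr else NA_real_,
                   cr_category = if (has_sf) as.character(cr$cr_category)
                                 else NA_character_,
                   stringsAsFactors = FALSE)
      }))
    }))
  }))
  row.names(out) <- NULL
  class(out) <- c("risk_table", class(out))
  out
}

#' @export
print.risk_table <- function(x, ...) {
  y <- as.data.frame(x)
  for (cl in c("hq_ing", "hq_derm", "hi", "cr")) {
    y[[cl]] <- ifelse(is.na(y[[cl]]), "", sprintf("%.2e", y[[cl]]))
  }
  y$mean_conc <- sprintf("%.3g", y$mean_conc)
  print(y, row.names = FALSE)
  invisible(x)
}
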