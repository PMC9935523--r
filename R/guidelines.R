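#' Metal(loid)s recognised by the package
#'
#' The closed set of element symbols accepted in concentration columns and
#' guideline sets: the four metals determined in every sample of a typical
#' urban topsoil survey (Cd, Cu, Pb, Zn) plus the four metal(loid)s commonly
#' screened in sample subsets (As, Cr, Hg, Ni).
#'
#' @return Character vector of the eight element symbols.
#' @export
soil_metals <- function() {
  c("Cd", "Cu", "Pb", "Zn", "As", "Cr", "Hg", "Ni")
}

check_metals <- function(metals, context = "metal") {
  bad <- setdiff(metals, soil_metals())
  if (length(bad) > 0) {
    stop(sprintf("unknown %s symbol(s): %s (known: %s)", context,
                 paste(bad, collapse = ", "),
                 paste(soil_metals(), collapse = ", ")), call. = FALSE)
  }
  invisible(metals)
}

#' Construct a guideline set
#'
#' A guideline set is a named collection of regulatory soil concentration
#' thresholds (mg/kg dry soil), one per metal, with a kind describing its
#' regulatory meaning: a `permissible` value (national standard), a `target`
#' value (sustainable soil quality) or an `intervention` value (serious
#' contamination requiring remediation).
#'
#' @param name Short identifier for the set.
#' @param kind One of `"permissible"`, `"target"`, `"intervention"`.
#' @param thresholds Named numeric vector, names from [soil_metals()],
#'   values strictly positive thresholds in mg/kg dry soil.
#' @return An object of class `guideline_set`.
#' @examples
#' guideline_set("example", "permissible", c(Cd = 3, Pb = 100))
#' @export
guideline_set <- function(name, kind = c("permissible", "target", "intervention"),
                          thresholds) {
  kind <- match.arg(kind)
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (is.null(names(thresholds)) || any(!nzchar(names(thresholds)))) {
    stop("'thresholds' must be a fully named numeric vector", call. = FALSE)
  }
  check_metals(names(thresholds), context = "threshold")
  if (anyDuplicated(names(thresholds))) {
    stop("a metal appears more than once in guideline set '", name, "'",
         call. = FALSE)
  }
  if (any(!is.finite(thresholds)) || any(thresholds <= 0)) {
    stop("all thresholds in guideline set '", name,
         "' must be finite and strictly positive", call. = FALSE)
  }
  structure(list(name = name, kind = kind,
                 thresholds = thresholds[order(match(names(thresholds),
                                                     soil_metals()))]),
            class = "guideline_set")
}

#' @export
print.guideline_set <- function(x, ...) {
  cat(sprintf("Guideline set '%s' (%s values, mg/kg dry soil)\n", x$name, x$kind))
  print(x$thresholds)
  invisible(x)
}

#' Built-in regulatory guideline sets
#'
#' Returns the three guideline sets used throughout the package:
#' \describe{
#'   \item{`mns2019`}{Permissible metal(loid) contents of the Mongolian
#'     soil-quality standard MNS 5850:2019.}
#'   \item{`dsg_target`}{Dutch Soil Guideline target values.}
#'   \item{`dsg_intervention`}{Dutch Soil Guideline intervention values.}
#' }
#' The built-ins are constructed afresh on each call and are therefore
#' immutable; user-supplied sets can be used anywhere a `guideline_set`
#' is accepted (see [read_guideline_config()]).
#'
#' @return Named list of three [guideline_set()] objects.
#' @examples
#' builtin_guidelines()$mns2019$thresholds[["Cd"]]   # 3 mg/kg
#' @export
builtin_guidelines <- function() {
  list(
    mns2019 = guideline_set("mns2019", "permissible",
      c(As = 20, Cd = 3, Cr = 150, Cu = 100, Hg = 2, Ni = 150, Pb = 100,
        Zn = 300)),
    dsg_target = guideline_set("dsg_target", "target",
      c(As = 29, Cd = 0.8, Cr = 100, Cu = 36, Hg = 0.3, Ni = 35, Pb = 85,
        Zn = 140)),
    dsg_intervention = guideline_set("dsg_intervention", "intervention",
      c(As = 55, Cd = 12, Cr = 380, Cu = 190, Hg = 10, Ni = 210, Pb = 530,
        Zn = 720))
  )
}

resolve_guideline <- function(guideline) {
  if (inherits(guideline, "guideline_set")) return(guideline)
  if (is.character(guideline) && length(guideline) == 1L) {
    builtins <- builtin_guidelines()
    if (guideline %in% names(builtins)) return(builtins[[guideline]])
    stop("unknown built-in guideline '", guideline, "'; available: ",
         paste(names(builtins), collapse = ", "), call. = FALSE)
  }
  stop("'guideline' must be a guideline_set or a built-in name", call. = FALSE)
}

metal_columns <- function(samples) {
  intersect(soil_metals(), names(samples))
}

check_samples <- function(samples, require_coords = FALSE) {
  if (!is.data.frame(samples) || nrow(samples) == 0) {
    stop("'samples' must be a non-empty data frame of soil samples",
         call. = FALSE)
  }
  needed <- c("sample_id", "town")
  missing <- setdiff(needed, names(samples))
  if (length(missing) > 0) {
    stop("missing mandatory column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  mets <- metal_columns(samples)
  if (length(mets) == 0) stop("no metal concentration columns found",
                              call. = FALSE)
  for (m in mets) {
    v <- samples[[m]]
    if (any(v < 0, na.rm = TRUE)) {
      bad <- samples$sample_id[which(v < 0)[1]]
      stop(sprintf("negative %s concentration in sample '%s'", m, bad),
           call. = FALSE)
    }
  }
  if (require_coords) {
    if (!all(c("x", "y") %in% names(samples)) ||
        any(!is.finite(samples$x)) || any(!is.finite(samples$y))) {
      stop("finite 'x' and 'y' coordinates are required for spatial operations",
           call. = FALSE)
    }
  }
  invisible(samples)
}

#' Screen one soil sample against a guideline set
#'
#' Computes, for every metal present in the sample, the concentration /
#' threshold ratio and an exceedance flag. Exceedance is strict
#' (`ratio > 1`): a concentration exactly at the threshold is compliant.
#' Metals measured in the sample but absent from the guideline set (and
#' metals with a missing concentration) are retained with
#' `evaluable = FALSE`, never silently dropped.
#'
#' @param sample A one-row data frame (or list coercible to one) with
#'   `sample_id` and metal concentration columns in mg/kg.
#' @param guideline A [guideline_set()] or built-in name (`"mns2019"`,
#'   `"dsg_target"`, `"dsg_intervention"`).
#' @return Data frame with one row per metal present in the sample:
#'   `sample_id`, `metal`, `conc`, `threshold`, `ratio`, `exceeded`,
#'   `evaluable`.
#' @examples
#' s <- data.frame(sample_id = "BGN-001", town = "Baganuur",
#'                 Cd = 0.87, Cu = 13.6, Pb = 29.6, Zn = 51.7)
#' screen_sample(s, "mns2019")
#' @export
screen_sample <- function(sample, guideline) {
  guideline <- resolve_guideline(guideline)
  sample <- as.data.frame(sample, stringsAsFactors = FALSE)
  if (nrow(sample) != 1L) stop("'sample' must be a single sample (one row)",
                               call. = FALSE)
  mets <- metal_columns(sample)
  if (length(mets) == 0) stop("sample has no metal concentration columns",
                              call. = FALSE)
  conc <- vapply(mets, function(m) as.numeric(sample[[m]]), numeric(1))
  if (any(conc < 0, na.rm = TRUE)) {
    stop("negative concentration in sample '", sample$sample_id, "'",
         call. = FALSE)
  }
  if (!any(mets %in% names(guideline$thresholds) & !is.na(conc))) {
    stop("no metal of the sample has a threshold in guideline set '",
         guideline$name, "'", call. = FALSE)
  }
  thr <- guideline$thresholds[mets]
  ratio <- unname(conc / thr)
  evaluable <- !is.na(conc) & !is.na(thr)
  out <- data.frame(
    sample_id = sample$sample_id,
    metal = mets,
    conc = unname(conc),
    threshold = unname(thr),
    ratio = ifelse(evaluable, ratio, NA_real_),
    exceeded = ifelse(evaluable, ratio > 1, NA),
    evaluable = evaluable,
    stringsAsFactors = FALSE, row.names = NULL
  )
  out
}

#' Classify concentrations on the Dutch Soil Guideline scale
#'
#' Assigns each metal of each sample to `below_target`,
#' `target_to_intervention` or `above_intervention` using the built-in (or
#' supplied) Dutch target and intervention values; metals without a
#' concentration or without both thresholds are `not_evaluable`. The class
#' is `above_intervention` exactly when the concentration strictly exceeds
#' the intervention value.
#'
#' @param samples Soil-sample data frame (see [read_samples()]).
#' @param target,intervention Guideline sets; default the built-in Dutch
#'   values.
#' @return Data frame `sample_id`, `town`, `metal`, `conc`, `dsg_class`.
#' @export
dsg_classify <- function(samples, target = "dsg_target",
                         intervention = "dsg_intervention") {
  check_samples(samples)
  target <- resolve_guideline(target)
  intervention <- resolve_guideline(intervention)
  mets <- metal_columns(samples)
  out <- do.call(rbind, lapply(mets, function(m) {
    conc <- samples[[m]]
    tt <- target$thresholds[m]
    ti <- intervention$thresholds[m]
    cls <- rep("not_evaluable", length(conc))
    ok <- !is.na(conc) & !is.na(tt) & !is.na(ti)
    cls[ok & conc > ti] <- "above_intervention"
    cls[ok & conc > tt & conc <= ti] <- "target_to_intervention"
    cls[ok & conc <= tt] <- "below_target"
    data.frame(sample_id = samples$sample_id, town = samples$town,
               metal = m, conc = conc, dsg_class = cls,
               stringsAsFactors = FALSE)
  }))
  row.names(out) <- NULL
  out
}

#' Screen a survey against a guideline set
#'
#' Aggregates [screen_sample()] over all samples: per metal the number of
#' evaluable samples, the number of strict exceedances and the maximum
#' ratio, with a per-town breakdown. Samples with a missing concentration
#' for a metal are excluded from that metal's counts (`n_missing` records
#' how many).
#'
#' @inheritParams dsg_classify
#' @param guideline A [guideline_set()] or built-in name.
#' @return List of class `screening_summary` with components
#'   `per_metal`, `per_town` (data frames) and `results` (the stacked
#'   per-sample [screen_sample()] rows).
#' @examples
#' sv <- fixture_towns()
#' screen_survey(sv, "mns2019")$per_metal
#' @export
screen_survey <- function(samples, guideline) {
  check_samples(samples)
  guideline <- resolve_guideline(guideline)
  res <- do.call(rbind, lapply(seq_len(nrow(samples)), function(i) {
    r <- screen_sample(samples[i, , drop = FALSE], guideline)
    r$town <- samples$town[i]
    r
  }))
  eval_res <- res[res$evaluable, , drop = FALSE]
  agg <- function(df, by) {
    parts <- split(df, df[by], drop = TRUE)
    out <- do.call(rbind, lapply(parts, function(p) {
      key <- p[1, by, drop = FALSE]
      cbind(key, data.frame(
        n_evaluated = nrow(p),
        n_exceeding = sum(p$exceeded),
        max_ratio = max(p$ratio)))
    }))
    row.names(out) <- NULL
    out
  }
  per_metal <- agg(eval_res, "metal")
  per_metal <- per_metal[order(match(per_metal$metal, soil_metals())), ]
  n_missing <- vapply(per_metal$metal, function(m)
    sum(res$metal == m & !res$evaluable), integer(1))
  per_metal$n_missing <- unname(n_missing)
  per_town <- agg(eval_res, c("town", "metal"))
  per_town <- per_town[order(per_town$town,
                             match(per_town$metal, soil_metals())), ]
  row.names(per_metal) <- row.names(per_town) <- NULL
  structure(list(guideline = guideline$name, per_metal = per_metal,
                 per_town = per_town, results = res),
            class = "screening_summary")
}

#' @export
print.screening_summary <- function(x, ...) {
  cat(sprintf("Survey screening against '%s' (%d samples)\n",
              x$guideline, length(unique(x$results$sample_id))))
  print(x$per_metal, row.names = FALSE)
  invisible(x)
}
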