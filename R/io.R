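#' Read a soil-sample survey from CSV
#'
#' Expects a header `sample_id,town,x,y` followed by metal concentration
#' columns (any subset of [soil_metals()]), concentrations in mg/kg dry
#' soil, empty cells meaning "not measured". Unparseable numeric cells
#' are turned into missing values with a warning naming the column;
#' duplicated sample ids are an error.
#'
#' @param path Path to the CSV file.
#' @return Soil-sample data frame.
#' @export
read_samples <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character",
                         check.names = FALSE, strip.white = TRUE)
  missing <- setdiff(c("sample_id", "town"), names(raw))
  if (length(missing) > 0) {
    stop("missing mandatory column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  unknown <- setdiff(names(raw),
                     c("sample_id", "town", "x", "y", soil_metals()))
  if (length(unknown) > 0) {
    warning("ignoring unrecognised column(s): ",
            paste(unknown, collapse = ", "), call. = FALSE)
    raw <- raw[, setdiff(names(raw), unknown), drop = FALSE]
  }
  if (anyDuplicated(raw$sample_id)) {
    stop("duplicated sample_id: ",
         paste(unique(raw$sample_id[duplicated(raw$sample_id)]),
               collapse = ", "), call. = FALSE)
  }
  for (cl in setdiff(names(raw), c("sample_id", "town"))) {
    v <- raw[[cl]]
    v[v == ""] <- NA
    num <- suppressWarnings(as.numeric(v))
    bad <- which(!is.na(v) & is.na(num))
    if (length(bad) > 0) {
      warning(sprintf("column %s: %d unparseable cell(s) treated as missing",
                      cl, length(bad)), call. = FALSE)
    }
    raw[[cl]] <- num
  }
  check_samples(raw)
  raw
}

#' Write a soil-sample survey to CSV
#'
#' @param samples Soil-sample data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_samples <- function(samples, path) {
  utils::write.csv(samples, path, row.names = FALSE, quote = FALSE,
                   na = "")
  invisible(path)
}

#' Read a guideline set from a key-value config file
#'
#' Plain-text config, one `metal = value` pair per line (`#` comments
#' allowed), optional `name = ...` and `kind = ...` entries. The
#' thresholds are merged over the chosen built-in base set, so a config
#' may override just one metal.
#'
#' @param path Path to the config file.
#' @param base Built-in set name to merge over, or NULL for no base.
#' @return A [guideline_set()].
#' @export
read_guideline_config <- function(path, base = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[nzchar(trimws(lines))])
  kv <- strsplit(lines, "\\s*=\\s*")
  bad <- lines[vapply(kv, length, integer(1)) != 2]
  if (length(bad) > 0) {
    stop("unparseable config line(s): ", paste(bad, collapse = "; "),
         call. = FALSE)
  }
  keys <- vapply(kv, `[`, "", 1)
  vals <- vapply(kv, `[`, "", 2)
  name <- if ("name" %in% keys) vals[keys == "name"][1] else
    basename(path)
  kind <- if ("kind" %in% keys) vals[keys == "kind"][1] else "permissible"
  keep <- !(keys %in% c("name", "kind"))
  thr <- suppressWarnings(as.numeric(vals[keep]))
  names(thr) <- keys[keep]
  if (any(is.na(thr))) {
    stop("non-numeric threshold(s) in ", path, call. = FALSE)
  }
  if (!is.null(base)) {
    basethr <- resolve_guideline(base)$thresholds
    merged <- basethr
    merged[names(thr)] <- thr
    thr <- merged
  }
  guideline_set(name, kind, thr)
}

#' Full assessment report for a survey
#'
#' Runs the complete assessment chain on one survey: guideline screening
#' (Mongolian permissible values plus Dutch target/intervention
#' classification), the per-sample and per-town integrated Nemerow
#' assessment, the human health risk table for both built-in receptors,
#' and the between-town comparisons. All tables are computed from the
#' same sample universe and the result is deterministic for a given
#' input.
#'
#' @param samples Soil-sample data frame.
#' @param guideline Guideline set (or name) for screening and indices.
#' @param metals Metals for the index and risk calculations.
#' @param scenarios Exposure scenarios; default [builtin_scenarios()].
#' @param tox Toxicity table; default [builtin_toxicity()].
#' @param maps If TRUE and coordinates are present, adds per-town
#'   interpolated index surfaces ([ipin_surface()]).
#' @param map_config Interpolator configuration for the maps.
#' @param map_cellsize Raster cell size for the maps, metres.
#' @return List of class `soilrisk_report`: `screening`, `dsg`,
#'   `indices`, `risk`, `comparison`, and optionally `maps` (one
#'   `ipin_surface()` result per town).
#' @examples
#' rep <- full_report(fixture_towns())
#' rep$indices$per_town
#' @export
full_report <- function(samples, guideline = "mns2019",
                        metals = c("Cd", "Cu", "Pb", "Zn"),
                        scenarios = builtin_scenarios(),
                        tox = builtin_toxicity(),
                        maps = FALSE,
                        map_config = interpolator_config("idw"),
                        map_cellsize = 50) {
  check_samples(samples)
  out <- list(
    screening = screen_survey(samples, guideline),
    dsg = dsg_classify(samples),
    indices = survey_ipin(samples, guideline, metals),
    risk = risk_table(samples, scenarios, tox,
                      metals = intersect(metals, tox$metal)),
    comparison = if (length(unique(samples$town)) >= 2)
      compare_towns_all(samples, metals) else NULL
  )
  if (maps) {
    out$maps <- lapply(split(samples, samples$town), function(sv) {
      ipin_surface(sv, guideline, metals, map_config, map_cellsize)
    })
  }
  structure(out, class = "soilrisk_report")
}

#' @export
print.soilrisk_report <- function(x, ...) {
  cat("== Guideline screening ==\n"); print(x$screening)
  cat("\n== Integrated Nemerow assessment ==\n"); print(x$indices)
  cat("\n== Human health risk ==\n"); print(x$risk)
  if (!is.null(x$comparison)) {
    cat("\n== Between-town comparisons ==\n")
    print(x$comparison, row.names = FALSE, digits = 4)
  }
  invisible(x)
}
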