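#' Single-metal pollution index
#'
#' PI = C / T, the ratio of a metal's soil concentration to its regulatory
#' permissible content. Dimensionless; vectorised over `conc` and
#' `threshold`.
#'
#' @param conc Concentration(s), mg/kg dry soil, non-negative.
#' @param threshold Permissible content(s), mg/kg dry soil, strictly
#'   positive.
#' @return Numeric vector of pollution indices.
#' @examples
#' pollution_index(0.87, 3)    # 0.29
#' pollution_index(69, 100)    # 0.69
#' @export
pollution_index <- function(conc, threshold) {
  if (any(!is.finite(threshold)) || any(threshold <= 0)) {
    stop("'threshold' must be finite and strictly positive", call. = FALSE)
  }
  if (any(is.finite(conc) & conc < 0)) {
    stop("'conc' must be non-negative", call. = FALSE)
  }
  conc / threshold
}

#' Integrated Nemerow pollution index
#'
#' Combines a set of per-metal pollution indices into the integrated
#' Nemerow index
#' \deqn{IPI_N = \sqrt{(PI_{avg}^2 + PI_{max}^2)/2},}
#' which up-weights the single worst pollutant relative to a plain mean.
#' By construction \eqn{PI_{max}/\sqrt{2} \le IPI_N \le PI_{max}} and
#' \eqn{IPI_N \ge PI_{avg}}.
#'
#' @param pi_values Non-empty numeric vector of finite, non-negative
#'   pollution indices (NA values are dropped).
#' @return List with `pi_avg`, `pi_max` and `ipin`.
#' @examples
#' integrated_nemerow(c(0.29, 0.136, 0.296, 0.17233))
#' @export
integrated_nemerow <- function(pi_values) {
  pi_values <- pi_values[!is.na(pi_values)]
  if (length(pi_values) == 0) {
    stop("'pi_values' must contain at least one non-missing value",
         call. = FALSE)
  }
  if (any(!is.finite(pi_values)) || any(pi_values < 0)) {
    stop("'pi_values' must be finite and non-negative", call. = FALSE)
  }
  pi_avg <- mean(pi_values)
  pi_max <- max(pi_values)
  list(pi_avg = pi_avg, pi_max = pi_max,
       ipin = sqrt((pi_avg^2 + pi_max^2) / 2))
}

ipin_class_levels <- c("safe", "precaution", "slight", "moderate", "heavy")

#' Classify integrated Nemerow index values
#'
#' Five-class severity scale: safe (IPI_N <= 0.7), precaution (0.7, 1),
#' slight pollution [1, 2), moderate pollution [2, 3), heavy pollution
#' (>= 3). The outer closures follow the published scale ("<= 0.7: safe",
#' ">= 3: heavy pollution"); interior boundaries are left-closed so the
#' partition is total and disjoint.
#'
#' @param ipin Numeric vector of non-negative index values.
#' @return Factor with levels `safe < precaution < slight < moderate <
#'   heavy`.
#' @examples
#' classify_ipin(c(0.26, 0.7, 1, 2.5, 3))
#' @export
classify_ipin <- function(ipin) {
  if (any(!is.finite(ipin)) || any(ipin < 0)) {
    stop("'ipin' must be finite and non-negative", call. = FALSE)
  }
  cls <- ifelse(ipin <= 0.7, "safe",
         ifelse(ipin < 1, "precaution",
         ifelse(ipin < 2, "slight",
         ifelse(ipin < 3, "moderate", "heavy"))))
  factor(cls, levels = ipin_class_levels, ordered = TRUE)
}

#' Per-sample and per-town integrated Nemerow assessment
#'
#' Computes per-metal pollution indices and the integrated Nemerow index
#' for every sample of a survey, plus two per-town aggregates: the
#' arithmetic mean of the per-sample IPI_N values (`mean_ipin`) and the
#' IPI_N evaluated at the town-mean concentrations (`ipin_of_means`). The
#' two differ in general because the index is nonlinear; both are reported
#' and classified.
#'
#' @param samples Soil-sample data frame (see [read_samples()]).
#' @param guideline A [guideline_set()] or built-in name; default the
#'   Mongolian permissible values.
#' @param metals Metals to include; default the four metals measured in
#'   every sample, `c("Cd", "Cu", "Pb", "Zn")`.
#' @return List of class `ipin_survey`: `per_sample` (sample_id, town,
#'   `pi_<metal>` columns, pi_avg, pi_max, ipin, ipin_class) and
#'   `per_town` (n, mean_ipin, mean_class, ipin_of_means, class_of_means).
#'   Samples missing any requested metal are skipped with a message.
#' @examples
#' sv <- fixture_towns()
#' survey_ipin(sv)$per_town
#' @export
survey_ipin <- function(samples, guideline = "mns2019",
                        metals = c("Cd", "Cu", "Pb", "Zn")) {
  check_samples(samples)
  check_metals(metals)
  guideline <- resolve_guideline(guideline)
  missing_thr <- setdiff(metals, names(guideline$thresholds))
  if (length(missing_thr) > 0) {
    stop("guideline set '", guideline$name, "' lacks threshold(s) for: ",
         paste(missing_thr, collapse = ", "), call. = FALSE)
  }
  missing_col <- setdiff(metals, names(samples))
  if (length(missing_col) > 0) {
    stop("survey lacks concentration column(s): ",
         paste(missing_col, collapse = ", "), call. = FALSE)
  }
  conc <- as.matrix(samples[, metals, drop = FALSE])
  usable <- stats::complete.cases(conc)
  if (sum(usable) == 0) stop("no sample has all requested metals measured",
                             call. = FALSE)
  if (any(!usable)) {
    message(sum(!usable), " sample(s) skipped: missing requested metal(s)")
  }
  conc <- conc[usable, , drop = FALSE]
  thr <- guideline$thresholds[metals]
  pim <- sweep(conc, 2, thr, "/")
  pi_avg <- rowMeans(pim)
  pi_max <- apply(pim, 1, max)
  ipin <- sqrt((pi_avg^2 + pi_max^2) / 2)
  per_sample <- data.frame(sample_id = samples$sample_id[usable],
                           town = samples$town[usable],
                           stringsAsFactors = FALSE)
  for (m in metals) per_sample[[paste0("pi_", m)]] <- unname(pim[, m])
  per_sample$pi_avg <- unname(pi_avg)
  per_sample$pi_max <- unname(pi_max)
  per_sample$ipin <- unname(ipin)
  per_sample$ipin_class <- classify_ipin(per_sample$ipin)

  towns <- split(seq_len(nrow(per_sample)), per_sample$town)
  per_town <- do.call(rbind, lapply(names(towns), function(tn) {
    idx <- towns[[tn]]
    mean_conc <- colMeans(conc[idx, , drop = FALSE])
    iom <- integrated_nemerow(pollution_index(mean_conc, thr))$ipin
    data.frame(town = tn, n = length(idx),
               mean_ipin = mean(per_sample$ipin[idx]),
               mean_class = classify_ipin(mean(per_sample$ipin[idx])),
               ipin_of_means = iom,
               class_of_means = classify_ipin(iom),
               stringsAsFactors = FALSE)
  }))
  row.names(per_town) <- NULL
  structure(list(guideline = guideline$name, metals = metals,
                 per_sample = per_sample, per_town = per_town),
            class = "ipin_survey")
}

#' @export
print.ipin_survey <- function(x, ...) {
  cat(sprintf("Integrated Nemerow assessment (%s; metals %s)\n",
              x$guideline, paste(x$metals, collapse = ", ")))
  print(x$per_town, row.names = FALSE, digits = 4)
  invisible(x)
}
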