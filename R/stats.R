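#' Normality-gated between-town comparison for one metal
#'
#' Tests whether a metal's concentrations differ between towns using the
#' two-stage procedure common in soil-survey work: each town's series is
#' first checked for normality with the Shapiro-Wilk test at P > 0.01;
#' if every town passes, a one-way ANOVA is used, otherwise the
#' nonparametric Kruskal-Wallis test. The gate is applied per metal per
#' town, never on pooled data.
#'
#' @param samples Soil-sample data frame (see [read_samples()]).
#' @param metal Metal symbol; must be a concentration column.
#' @param alpha Normality gate level (default 0.01).
#' @return List of class `town_comparison`: `metal`, `groups` (town, n,
#'   shapiro_p, normal), `test_used` (`"one_way_anova"` or
#'   `"kruskal_wallis"`), `statistic`, `df`, `p_value`.
#' @examples
#' sv <- fixture_towns()
#' compare_towns(sv, "Pb")
#' @export
compare_towns <- function(samples, metal, alpha = 0.01) {
  check_samples(samples)
  check_metals(metal)
  if (!metal %in% names(samples)) {
    stop("no concentration column for metal '", metal, "'", call. = FALSE)
  }
  df <- samples[!is.na(samples[[metal]]), c("town", metal)]
  groups <- split(df[[metal]], df$town)
  if (length(groups) < 2) stop("need at least 2 towns", call. = FALSE)
  ns <- vapply(groups, length, integer(1))
  small <- names(groups)[ns < 3]
  if (length(small) > 0) {
    stop("group(s) too small for the normality gate (< 3 samples): ",
         paste(small, collapse = ", "), call. = FALSE)
  }
  sw <- vapply(groups, function(v) {
    if (stats::sd(v) == 0) return(0)   # constant series cannot be normal
    stats::shapiro.test(v)$p.value
  }, numeric(1))
  normal <- sw > alpha
  gi <- data.frame(town = names(groups), n = unname(ns),
                   shapiro_p = unname(sw), normal = unname(normal),
                   stringsAsFactors = FALSE)
  vals <- df[[metal]]
  town <- factor(df$town)
  if (all(normal)) {
    fit <- stats::oneway.test(vals ~ town, var.equal = TRUE)
    res <- list(test_used = "one_way_anova",
                statistic = unname(fit$statistic),
                df = unname(fit$parameter), p_value = fit$p.value)
  } else {
    fit <- stats::kruskal.test(vals ~ town)
    res <- list(test_used = "kruskal_wallis",
                statistic = unname(fit$statistic),
                df = unname(fit$parameter), p_value = fit$p.value)
  }
  structure(c(list(metal = metal, groups = gi), res),
            class = "town_comparison")
}

#' @export
print.town_comparison <- function(x, ...) {
  cat(sprintf("%s between-town comparison: %s, statistic %.4g, p = %.4g\n",
              x$metal, x$test_used, x$statistic, x$p_value))
  print(x$groups, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Between-town comparisons for several metals
#'
#' @inheritParams compare_towns
#' @param metals Metal symbols (default all metal columns present).
#' @return Data frame: one row per metal with `test_used`, `statistic`,
#'   `p_value` and whether every town passed the normality gate.
#' @export
compare_towns_all <- function(samples, metals = NULL, alpha = 0.01) {
  if (is.null(metals)) metals <- metal_columns(samples)
  out <- do.call(rbind, lapply(metals, function(m) {
    cmp <- compare_towns(samples, m, alpha)
    data.frame(metal = m, test_used = cmp$test_used,
               statistic = cmp$statistic, p_value = cmp$p_value,
               all_normal = all(cmp$groups$normal),
               stringsAsFactors = FALSE)
  }))
  row.names(out) <- NULL
  out
}
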