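# Descriptive group comparisons, policy arithmetic, and national
# extrapolation. Monetary inputs are Pakistani rupees (Rs); conversion to
# US$ happens exactly once, inside extrapolate_national(), at the
# configured 2014 exchange rate.

#' Grouped descriptive table with two-sample tests
#'
#' Group means and SDs per variable, with each non-base group tested
#' against the base group: Welch t-tests for continuous variables,
#' chi-square tests for binary ones, significance stars at the 1/5/10%
#' two-sided levels. For the self-reported grouping, farmers answering
#' "don't know" (or not answering) are pooled with the non-adopters.
#'
#' @param records survey data.frame.
#' @param grouping `"self_reported"` (Bt believers vs the rest) or
#'   `"lab_category"` (non-Bt base vs weak-Bt and true-Bt, from
#'   `true_category` or via [classify_survey()]).
#' @param vars variables to summarise; defaults to the standard covariate
#'   and outcome set present in the data.
#' @return data.frame: one row per variable, per group `mean_*`/`sd_*`
#'   columns, and `p_*`/`stars_*` columns per non-base group. Groups with
#'   fewer than 2 observations get means but no tests.
#' @export
descriptive_table <- function(records,
                              grouping = c("self_reported", "lab_category"),
                              vars = NULL) {
  grouping <- match.arg(grouping)
  if (grouping == "self_reported") {
    g <- ifelse(records$belief == "bt", "bt_adopter", "non_adopter")
    base <- "non_adopter"
    levels_g <- c("non_adopter", "bt_adopter")
  } else {
    g <- if ("true_category" %in% names(records)) {
      records$true_category
    } else {
      classify_survey(records)
    }
    base <- "non_bt"
    levels_g <- c("non_bt", "weak_bt", "true_bt")
  }
  if (is.null(vars)) {
    candidates <- c("age", "education", "household_size", "off_farm",
                    "farm_size", "cotton_area", "bt_expression",
                    "pesticide_qty", "self_spray", "protective_gear",
                    "sc_habits", "dh", "qh")
    vars <- intersect(candidates, names(records))
  }
  levels_g <- intersect(levels_g, unique(g))
  others <- setdiff(levels_g, base)
  star <- function(p) {
    if (is.na(p)) "" else if (p < 0.01) "***" else if (p < 0.05) "**"
    else if (p < 0.10) "*" else ""
  }
  rows <- lapply(vars, function(v) {
    x <- records[[v]]
    row <- data.frame(variable = v)
    for (lev in levels_g) {
      xi <- x[g == lev]
      row[[paste0("mean_", lev)]] <- mean(xi)
      row[[paste0("sd_", lev)]] <- stats::sd(xi)
      row[[paste0("n_", lev)]] <- length(xi)
    }
    xb <- x[g == base]
    for (lev in others) {
      xi <- x[g == lev]
      p <- NA_real_
      if (length(xi) >= 2L && length(xb) >= 2L) {
        p <- if (is_binary_col(x)) {
          tab <- table(factor(g[g %in% c(base, lev)],
                              levels = c(base, lev)),
                       factor(x[g %in% c(base, lev)], levels = c(0, 1)))
          if (all(dim(tab) == c(2L, 2L)) && all(rowSums(tab) > 0) &&
              sum(tab) > 0 && length(unique(x[g %in% c(base, lev)])) > 1L) {
            suppressWarnings(stats::chisq.test(tab)$p.value)
          } else {
            1
          }
        } else if (stats::sd(xi) == 0 && stats::sd(xb) == 0) {
          if (mean(xi) == mean(xb)) 1 else 0
        } else {
          stats::t.test(xi, xb)$p.value
        }
      }
      row[[paste0("p_", lev)]] <- p
      row[[paste0("stars_", lev)]] <- star(p)
    }
    row
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Relative reduction of an effect against a baseline cost
#'
#' @param uame a (typically negative) unconditional marginal effect in Rs.
#' @param baseline positive baseline cost in Rs (the unconditional
#'   expected cost of illness).
#' @return list with `percent` (unrounded, `100 * |uame| / baseline`) and
#'   `display` (integer-percent string).
#' @examples
#' relative_reduction(-93.72, 292.34)$display  # "32%"
#' @export
relative_reduction <- function(uame, baseline) {
  check_positive(baseline, "baseline")
  pct <- 100 * abs(uame) / baseline
  list(percent = pct, display = paste0(round(pct), "%"))
}

#' National extrapolation of per-unit health-cost savings
#'
#' Multiplies a per-unit seasonal saving (Rs) by the national Bt cotton
#' area and converts the total to US$ exactly once. Defaults reflect the
#' study setting: 7.4 million acres under Bt cotton and the 2014 exchange
#' rate of 0.00995 US$ per Rs. The per-unit basis (per farmer-season vs per
#' acre) is the caller's explicit choice; the function only scales.
#'
#' @param per_unit_saving positive saving in Rs per unit.
#' @param national_area number of units nationally (default 7.4e6 acres).
#' @param exchange_rate US$ per Rs (default 0.00995).
#' @return list with `rs_total` (Rs) and `usd_total` (US$).
#' @examples
#' extrapolate_national(93.72)$rs_total / 1e6   # ~ 693.5 (million Rs)
#' extrapolate_national(93.91)$usd_total / 1e6  # ~ 6.92 (million US$)
#' @export
extrapolate_national <- function(per_unit_saving, national_area = 7.4e6,
                                 exchange_rate = 0.00995) {
  check_positive(per_unit_saving, "per_unit_saving", strict = FALSE)
  check_positive(national_area, "national_area", strict = FALSE)
  check_positive(exchange_rate, "exchange_rate")
  rs_total <- per_unit_saving * national_area
  list(rs_total = rs_total, usd_total = rs_total * exchange_rate)
}
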