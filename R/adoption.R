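# Lab-based adoption classification and belief-vs-lab misclassification.
# A farmer's plot is non-Bt when every strip test at 70 days after sowing is
# negative; with at least one positive strip, ELISA Bt toxin expression
# below the effectiveness threshold (default 1.90 ug/g) marks weakly
# performing Bt and expression at or above it marks true Bt.

#' Classify a farmer's lab-based Bt adoption category
#'
#' @param strip_results numeric/integer vector of 0/1 strip-test outcomes
#'   (one per tissue sample, 70 days after sowing); must be non-empty.
#' @param expression per-farmer ELISA Bt toxin expression (ug/g, >= 0).
#'   When several tested samples yield separate readings, aggregate them
#'   first (see [aggregate_expression()]); the default convention is the
#'   maximum across samples, mirroring the "at least one positive" logic of
#'   the strip rule.
#' @param threshold effectiveness threshold in ug/g (default 1.90).
#' @return list of class `btcoi_adoption` with `label` in
#'   `{"non_bt","weak_bt","true_bt"}` and `basis` describing the rule that
#'   fired.
#' @examples
#' classify_lab_adoption(c(0, 0), 0.5)$label   # "non_bt"
#' classify_lab_adoption(c(1, 0), 0.9)$label   # "weak_bt"
#' classify_lab_adoption(c(1, 1), 3.09)$label  # "true_bt"
#' @export
classify_lab_adoption <- function(strip_results, expression,
                                  threshold = 1.90) {
  if (length(strip_results) == 0L || all(is.na(strip_results))) {
    stop("no strip-test results supplied; classification is undefined",
         call. = FALSE)
  }
  if (!all(strip_results %in% c(0, 1))) {
    stop("strip results must be 0/1", call. = FALSE)
  }
  if (!is.numeric(expression) || length(expression) != 1L ||
      is.na(expression) || expression < 0) {
    stop("'expression' must be a single non-negative number", call. = FALSE)
  }
  check_positive(threshold, "threshold")
  if (sum(strip_results) == 0L) {
    label <- "non_bt"
    basis <- "strip_all_negative"
  } else if (expression < threshold) {
    label <- "weak_bt"
    basis <- "strip_positive_low_expression"
  } else {
    label <- "true_bt"
    basis <- "strip_positive_high_expression"
  }
  structure(list(label = label, basis = basis), class = "btcoi_adoption")
}

#' Aggregate several per-sample expression readings to one farmer value
#'
#' @param readings numeric vector of ELISA readings (ug/g).
#' @param method `"max"` (default; consistent with the at-least-one-positive
#'   strip rule) or `"mean"`.
#' @return single numeric value.
#' @export
aggregate_expression <- function(readings, method = c("max", "mean")) {
  method <- match.arg(method)
  readings <- readings[!is.na(readings)]
  if (length(readings) == 0L) stop("no expression readings", call. = FALSE)
  if (method == "max") max(readings) else mean(readings)
}

#' Vectorised lab classification for a survey table
#'
#' @param records survey data.frame with `strip_*` columns and a
#'   `bt_expression` column.
#' @param threshold effectiveness threshold (ug/g).
#' @return character vector of labels, one per row.
#' @export
classify_survey <- function(records, threshold = 1.90) {
  strip_cols <- grep("^strip_", names(records), value = TRUE)
  if (length(strip_cols) == 0L) {
    stop("no strip_* columns found in records", call. = FALSE)
  }
  strips <- as.matrix(records[strip_cols])
  any_pos <- rowSums(strips) > 0
  ifelse(!any_pos, "non_bt",
         ifelse(records$bt_expression < threshold, "weak_bt", "true_bt"))
}

belief_levels <- function() c("bt", "non_bt", "dont_know", "no_response")

#' Cross-tabulate self-reported adoption beliefs against strip outcomes
#'
#' Builds the belief (Bt / non-Bt / don't know / no response) by strip
#' outcome (all negative / at least one positive) table per province and
#' pooled, with per-cell counts and cell means of Bt toxin expression and
#' pesticide quantity. Records with an unknown belief code are excluded and
#' counted in the `n_excluded` attribute.
#'
#' @param records survey data.frame with `province`, `belief`, `strip_*`,
#'   `bt_expression`, `pesticide_qty` columns.
#' @return data.frame of class `btcoi_xtab` with columns `province`,
#'   `belief`, `strip_outcome`, `n`, `mean_bt_expression`,
#'   `mean_pesticide`.
#' @export
cross_tabulate <- function(records) {
  needed <- c("province", "belief", "bt_expression", "pesticide_qty")
  missing_cols <- setdiff(needed, names(records))
  if (length(missing_cols) > 0L) {
    stop("records lack column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  strip_cols <- grep("^strip_", names(records), value = TRUE)
  if (length(strip_cols) == 0L) {
    stop("no strip_* columns found in records", call. = FALSE)
  }
  known <- records$belief %in% belief_levels()
  n_excluded <- sum(!known)
  if (n_excluded > 0L) {
    message(n_excluded, " record(s) with unknown belief code excluded ",
            "from the cross-tabulation")
    records <- records[known, , drop = FALSE]
  }
  any_pos <- rowSums(as.matrix(records[strip_cols])) > 0
  records$strip_outcome <- ifelse(any_pos, "at_least_one_positive",
                                  "all_negative")
  tab_for <- function(df, prov) {
    cells <- expand.grid(belief = belief_levels(),
                         strip_outcome = c("all_negative",
                                           "at_least_one_positive"),
                         stringsAsFactors = FALSE)
    cells$province <- prov
    cells$n <- 0L
    cells$mean_bt_expression <- NA_real_
    cells$mean_pesticide <- NA_real_
    for (i in seq_len(nrow(cells))) {
      sel <- df$belief == cells$belief[i] &
        df$strip_outcome == cells$strip_outcome[i]
      cells$n[i] <- sum(sel)
      if (any(sel)) {
        cells$mean_bt_expression[i] <- mean(df$bt_expression[sel])
        cells$mean_pesticide[i] <- mean(df$pesticide_qty[sel])
      }
    }
    cells[c("province", "belief", "strip_outcome", "n",
            "mean_bt_expression", "mean_pesticide")]
  }
  provs <- sort(unique(records$province))
  out <- do.call(rbind, lapply(provs, function(p) {
    tab_for(records[records$province == p, , drop = FALSE], p)
  }))
  if (length(provs) > 1L) {
    out <- rbind(out, tab_for(records, "pooled"))
  }
  rownames(out) <- NULL
  attr(out, "n_excluded") <- n_excluded
  class(out) <- c("btcoi_xtab", "data.frame")
  out
}

#' Belief-vs-lab misclassification rates per province
#'
#' From a cross-tabulation, computes per province: `type1` = P(all strips
#' negative | belief = Bt), `type2` = P(at least one strip positive |
#' belief = non-Bt), `self_reported_adoption` = share reporting Bt,
#' `lab_adoption` = share with at least one positive strip, and
#' `incorrect_or_uncertain` = (type I count + type II count + don't-know
#' count) / province total. "No response" farmers enter the totals but are
#' not counted as uncertain. Rates with an empty denominator are reported
#' as `NA` (undefined), never as zero.
#'
#' @param xtab a [cross_tabulate()] result (or any data.frame with the same
#'   columns).
#' @return data.frame with one row per province (pooled row included when
#'   present), rates as fractions in `[0, 1]`.
#' @export
misclassification_rates <- function(xtab) {
  needed <- c("province", "belief", "strip_outcome", "n")
  if (!all(needed %in% names(xtab))) {
    stop("xtab lacks required columns", call. = FALSE)
  }
  one <- function(df) {
    total <- sum(df$n)
    cnt <- function(bel, outc = NULL) {
      sel <- df$belief %in% bel
      if (!is.null(outc)) sel <- sel & df$strip_outcome == outc
      sum(df$n[sel])
    }
    n_bt <- cnt("bt")
    n_nonbt <- cnt("non_bt")
    n_t1 <- cnt("bt", "all_negative")
    n_t2 <- cnt("non_bt", "at_least_one_positive")
    n_dk <- cnt("dont_know")
    data.frame(
      n = total,
      type1 = if (n_bt > 0) n_t1 / n_bt else NA_real_,
      type2 = if (n_nonbt > 0) n_t2 / n_nonbt else NA_real_,
      self_reported_adoption = if (total > 0) n_bt / total else NA_real_,
      lab_adoption = if (total > 0) {
        sum(df$n[df$strip_outcome == "at_least_one_positive"]) / total
      } else NA_real_,
      incorrect_or_uncertain = if (total > 0) {
        (n_t1 + n_t2 + n_dk) / total
      } else NA_real_)
  }
  provs <- unique(xtab$province)
  out <- do.call(rbind, lapply(provs, function(p) {
    cbind(province = p, one(xtab[xtab$province == p, , drop = FALSE]))
  }))
  rownames(out) <- NULL
  out
}

#' Published belief-by-strip cross-tabulation (Punjab and Sindh, 2013-14)
#'
#' Loads the published cross-tabulation of self-reported Bt adoption
#' against strip-test outcomes for the 564-farmer Pakistan cotton survey
#' (435 Punjab, 129 Sindh), including cell means of Bt toxin expression and
#' pesticide use. Shipped as a plain-text fixture; used to audit the
#' misclassification-rate calculations against the published percentages.
#'
#' @return data.frame in the [cross_tabulate()] layout (without the pooled
#'   rows).
#' @export
published_crosstab <- function() {
  path <- system.file("extdata", "pakistan_belief_lab_crosstab.csv",
                      package = "btcoi", mustWork = TRUE)
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  class(out) <- c("btcoi_xtab", "data.frame")
  out
}
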