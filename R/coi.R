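# Cost-of-illness accounting. Direct costs are the sum of self-treatment,
# physician consultation, medication, and travel expenses for acute
# pesticide-related symptoms; the indirect cost is work days lost valued at
# the farmer's wage. The treatment indicator dh is 1 exactly when any cost
# (monetary or time) was incurred, so a farmer who only lost work days
# still counts as treated. All amounts are in Pakistani rupees (Rs) per
# cotton season; the total is a lower bound on the true cost of ill health
# (intangible, nursing, chronic and worker-spillover costs are excluded).

direct_components <- function() {
  c("self_treatment", "consultation", "medication", "travel")
}

check_components <- function(c) {
  for (f in c(direct_components(), "days_lost")) {
    v <- c[[f]]
    if (is.null(v) || !is.numeric(v) || any(is.na(v))) {
      stop("cost component '", f, "' missing or non-numeric", call. = FALSE)
    }
    if (any(v < 0)) {
      stop("cost component '", f, "' is negative", call. = FALSE)
    }
  }
  invisible(c)
}

#' Direct treatment cost (Rs)
#'
#' Sum of the four direct components: self-treatment, consultation,
#' medication, and travel to and from health facilities.
#'
#' @param c list or data.frame with numeric fields `self_treatment`,
#'   `consultation`, `medication`, `travel` (vectors allowed).
#' @return numeric vector of direct costs in Rs.
#' @export
direct_cost <- function(c) {
  check_components(utils::modifyList(
    as.list(c)[intersect(names(c), direct_components())],
    list(days_lost = 0)))
  Reduce(`+`, lapply(direct_components(), function(f) {
    v <- c[[f]]
    if (is.null(v)) stop("cost component '", f, "' missing", call. = FALSE)
    v
  }))
}

#' Indirect cost of work days lost (Rs)
#'
#' Opportunity cost of work days lost to illness, valued at the farmer's
#' local wage rate: `days_lost * wage`.
#'
#' @param c list or data.frame with numeric fields `days_lost` and `wage`
#'   (Rs/day). A missing or non-positive wage with positive days lost is an
#'   error naming the offending record(s).
#' @return numeric vector of indirect costs in Rs.
#' @export
indirect_cost <- function(c) {
  days <- c[["days_lost"]]
  wage <- c[["wage"]]
  if (is.null(days) || !is.numeric(days) || any(is.na(days)) ||
      any(days < 0)) {
    stop("'days_lost' missing, non-numeric or negative", call. = FALSE)
  }
  if (is.null(wage)) wage <- rep(NA_real_, length(days))
  bad <- days > 0 & (is.na(wage) | wage <= 0)
  if (any(bad)) {
    stop("positive days_lost with missing or non-positive wage at ",
         "record(s): ", paste(utils::head(which(bad), 10L), collapse = ", "),
         call. = FALSE)
  }
  out <- ifelse(days > 0, days * wage, 0)
  out
}

#' Build the cost-of-illness outcome from components
#'
#' Combines direct and indirect costs into the seasonal outcome used by the
#' hurdle models: `qh = direct + indirect` and `dh = 1` iff `qh > 0`.
#' Work-time losses without any cash outlay therefore count as treatment.
#'
#' @param c list or data.frame with the component fields (see
#'   [direct_cost()] and [indirect_cost()]).
#' @return data.frame with columns `dh`, `direct`, `indirect`, `qh`.
#' @export
build_outcome <- function(c) {
  d <- direct_cost(c)
  i <- indirect_cost(c)
  qh <- d + i
  data.frame(dh = as.numeric(qh > 0), direct = d, indirect = i, qh = qh)
}

#' Append cost-of-illness columns to a survey table
#'
#' Convenience wrapper: computes [build_outcome()] from the survey's
#' component columns and appends `dh`, `direct`, `indirect`, `qh`
#' (replacing any existing columns of those names).
#'
#' @param records survey data.frame.
#' @return the survey with outcome columns appended.
#' @export
add_coi <- function(records) {
  out <- build_outcome(records)
  records[c("dh", "direct", "indirect", "qh")] <- out
  records
}
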