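.check_survival_records <- function(records) {
  stopifnot(is.data.frame(records),
            all(c("time", "event") %in% names(records)))
  if (nrow(records) == 0) stop("no survival records")
  if (any(!is.finite(records$time) | records$time <= 0))
    stop("follow-up times must be positive")
  records
}

#' Kaplan-Meier product-limit estimate
#'
#' Ties are handled by simultaneous events; subjects censored at an
#' event time are still counted at risk for that time.
#'
#' @param records data.frame with `time` (positive, months) and `event`
#'   (logical or 0/1; `TRUE` = death).
#' @return data.frame of class `km_curve`: `time` (distinct event times,
#'   ascending), `n_risk`, `n_event`, `survival` (probability just after
#'   each time).
#' @export
km_estimate <- function(records) {
  .check_survival_records(records)
  fit <- survival::survfit(
    survival::Surv(records$time, as.integer(records$event)) ~ 1)
  keep <- fit$n.event > 0
  out <- data.frame(time = fit$time[keep],
                    n_risk = fit$n.risk[keep],
                    n_event = fit$n.event[keep],
                    survival = fit$surv[keep])
  class(out) <- c("km_curve", "data.frame")
  out
}

#' Two-group log-rank test
#'
#' The standard observed-minus-expected chi-square with hypergeometric
#' variance accumulated over distinct event times; p from chi-square
#' with 1 degree of freedom.
#'
#' @param group_a,group_b data.frames with `time`, `event`.
#' @return list with `statistic`, `p_value`, `observed` and `expected`
#'   event counts per group (a first, b second).
#' @export
logrank_test <- function(group_a, group_b) {
  .check_survival_records(group_a)
  .check_survival_records(group_b)
  time <- c(group_a$time, group_b$time)
  event <- as.integer(c(group_a$event, group_b$event))
  if (sum(event) == 0)
    stop("log-rank test undefined with zero events")
  grp <- factor(rep(c("a", "b"), c(nrow(group_a), nrow(group_b))))
  sd <- survival::survdiff(survival::Surv(time, event) ~ grp)
  list(statistic = sd$chisq,
       p_value = stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE),
       observed = unname(sd$obs), expected = unname(sd$exp))
}

#' Expression-cutoff log-rank scan
#'
#' Reimplements the "scan" cut-off modus used to dichotomize a
#' continuous marker for Kaplan-Meier analysis: candidate cutoffs are
#' the midpoints between consecutive sorted distinct expression values;
#' each eligible cutoff (both groups at least `min_group_size`) is
#' scored with a log-rank test of expression >= cutoff (high) versus
#' below (low); the cutoff attaining the minimal p-value is chosen, with
#' ties broken towards the most balanced split. Because the minimum is
#' taken over many correlated tests, the reported minimum p-value is
#' anti-conservative and is flagged as such.
#'
#' @param records data.frame with `time`, `event`, `expression`.
#' @param min_group_size smallest admissible group (default 8).
#' @return list of class `scan_result`: `scan` (data.frame of `cutoff`,
#'   `n_high`, `n_low`, `statistic`, `p_value`), `chosen_cutoff`,
#'   `min_p`, `n_high`, `n_low`, `high_group_worse` (logical: fewer
#'   expected than observed events in the high group),
#'   `multiplicity_warning`.
#' @export
scan_cutoff <- function(records, min_group_size = 8) {
  .check_survival_records(records)
  if (!"expression" %in% names(records))
    stop("records must carry an expression column")
  expr <- records$expression
  vals <- sort(unique(expr[!is.na(expr)]))
  if (length(vals) < 2)
    stop("no valid cutoff: fewer than 2 distinct expression values")
  cand <- (vals[-1] + vals[-length(vals)]) / 2
  n_high <- vapply(cand, function(ct) sum(expr >= ct), integer(1))
  n_low <- length(expr) - n_high
  eligible <- n_high >= min_group_size & n_low >= min_group_size
  if (!any(eligible))
    stop("no valid cutoff: the group-size floor (", min_group_size,
         ") excludes every candidate")
  cand <- cand[eligible]; n_high <- n_high[eligible]; n_low <- n_low[eligible]
  res <- t(vapply(cand, function(ct) {
    hi <- expr >= ct
    lr <- logrank_test(records[hi, ], records[!hi, ])
    c(lr$statistic, lr$p_value, lr$observed[1] - lr$expected[1])
  }, numeric(3)))
  scan <- data.frame(cutoff = cand, n_high = n_high, n_low = n_low,
                     statistic = res[, 1], p_value = res[, 2])
  best_p <- min(scan$p_value)
  at_min <- which(scan$p_value <= best_p)
  if (length(at_min) > 1) {  # most balanced split, then lowest cutoff
    bal <- abs(scan$n_high[at_min] - scan$n_low[at_min])
    at_min <- at_min[bal == min(bal)]
  }
  pick <- at_min[1]
  structure(list(
    scan = scan,
    chosen_cutoff = scan$cutoff[pick],
    min_p = scan$p_value[pick],
    n_high = scan$n_high[pick], n_low = scan$n_low[pick],
    high_group_worse = res[pick, 3] > 0,
    multiplicity_warning = paste(
      "minimum p-value over", nrow(scan),
      "scanned cutoffs; anti-conservative under the null and not",
      "adjusted for multiple testing")),
    class = "scan_result")
}

#' @export
print.scan_result <- function(x, ...) {
  cat(sprintf(
    "cutoff scan: chosen cutoff %.4g (p = %.3g; high n = %d, low n = %d; high group %s)\n",
    x$chosen_cutoff, x$min_p, x$n_high, x$n_low,
    if (x$high_group_worse) "worse" else "better"))
  cat("note:", x$multiplicity_warning, "\n")
  invisible(x)
}

#' Stratified overall-survival scan report
#'
#' Runs [scan_cutoff()] once per stratum of the cohort, mirroring the
#' strata of the published overall-survival analysis: all patients,
#' MYCN-not-amplified, relapse/progression cases (all and
#' MYCN-not-amplified), localized stages with no MYCN amplification, and
#' metastatic cases. Strata that are empty or fail the group-size floor
#' are recorded as not evaluable rather than erroring.
#'
#' @param records data.frame with `time`, `event`, `expression`, and tag
#'   columns `mycn_status`, `stage_class` (`localized` / `metastatic`),
#'   `relapse_or_progression` (logical).
#' @param min_group_size forwarded to [scan_cutoff()].
#' @return data.frame: `stratum`, `n`, `evaluable`, `chosen_cutoff`,
#'   `min_p`, `n_high`, `n_low`, `high_group_worse`; the full
#'   `scan_result` objects are in `attr(, "scans")`.
#' @export
stratified_os_report <- function(records, min_group_size = 8) {
  strata <- list(
    all = rep(TRUE, nrow(records)),
    mycn_not_amplified = records$mycn_status != "amplified",
    relapse_or_progression = records$relapse_or_progression,
    relapse_mycn_not_amplified =
      records$relapse_or_progression & records$mycn_status != "amplified",
    localized_mycn_not_amplified =
      records$stage_class == "localized" & records$mycn_status != "amplified",
    metastatic = records$stage_class == "metastatic")
  scans <- list()
  rows <- lapply(names(strata), function(nm) {
    sel <- strata[[nm]] & !is.na(strata[[nm]])
    sub <- records[sel, , drop = FALSE]
    sc <- if (nrow(sub) > 0)
      tryCatch(scan_cutoff(sub, min_group_size), error = function(e) NULL)
    else NULL
    scans[[nm]] <<- sc
    if (is.null(sc))
      data.frame(stratum = nm, n = nrow(sub), evaluable = FALSE,
                 chosen_cutoff = NA_real_, min_p = NA_real_,
                 n_high = NA_integer_, n_low = NA_integer_,
                 high_group_worse = NA, stringsAsFactors = FALSE)
    else
      data.frame(stratum = nm, n = nrow(sub), evaluable = TRUE,
                 chosen_cutoff = sc$chosen_cutoff, min_p = sc$min_p,
                 n_high = sc$n_high, n_low = sc$n_low,
                 high_group_worse = sc$high_group_worse,
                 stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "scans") <- scans
  out
}

#' Export a Kaplan-Meier curve as TSV step coordinates
#'
#' @param curve a [km_estimate()] result.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_km_curve <- function(curve, path) {
  utils::write.table(as.data.frame(curve), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
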