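#' Convert first-order removal rate constants to half-lives
#'
#' DT50 = ln 2 / k. Applied samplewise to posterior draws; because the map
#' is strictly decreasing, the median of the DT50 samples equals
#' ln 2 / median(k samples).
#'
#' @param k removal rate constant(s) (1/h), strictly positive.
#' @return Half-life (hours), same length as `k`.
#' @examples
#' k_to_dt50(log(2))   # 1 h
#' k_to_dt50(0.001)    # ~693.1 h
#' @export
k_to_dt50 <- function(k) {
  if (any(!is.finite(k)) || any(k <= 0)) stop("k must be finite and > 0")
  log(2) / k
}

#' Detectability threshold on half-lives for one flowpath
#'
#' A removal rate is only measurable if it reduces the concentration over
#' the flowpath's median travel time by more than twice the measurement
#' precision (relative SD). The smallest detectable rate solves
#' \eqn{\exp(-k_{min}\tau) = 1 - 2\,\mathrm{relSD}}, giving the DT50
#' threshold
#' \deqn{DT50_{max} = \frac{\ln 2\,\tau}{-\ln(1 - 2\,\mathrm{relSD})}.}
#' Median half-lives above this threshold represent removal that is not
#' measurable and are masked as infinite (see [apply_inf_mask()]).
#'
#' @param rel_sd relative standard deviation of the measurement (fraction;
#'   requires `2 * rel_sd < 1`).
#' @param travel_time median travel time tau of the flowpath (h).
#' @return The DT50 threshold (h).
#' @examples
#' dt50_threshold(0.05, 11.5)  # ~75.7 h on the shortest flowpath
#' @export
dt50_threshold <- function(rel_sd, travel_time) {
  if (any(rel_sd <= 0) || any(2 * rel_sd >= 1))
    stop("rel_sd must satisfy 0 < 2*rel_sd < 1")
  if (any(travel_time <= 0)) stop("travel_time must be > 0")
  log(2) * travel_time / (-log(1 - 2 * rel_sd))
}

#' Posterior result for one compound on one flowpath
#'
#' One cell group of the wide results table: medians and IQRs of the retardation
#' coefficient, removal rate constant and half-life, plus the fit RMSE and
#' the detectability threshold applied.
#'
#' @param compound,flowpath identifiers.
#' @param R_median,R_iqr retardation posterior summaries (-).
#' @param k_median,k_iqr rate-constant posterior summaries (1/h).
#' @param dt50_median,dt50_iqr half-life posterior summaries (h).
#' @param rmse root mean square error of the posterior-median fit (ug/L).
#' @param threshold DT50 detectability threshold (h), or `NA`.
#' @param dt50_masked logical; set by [apply_inf_mask()].
#' @return An object of class `compound_flowpath_result`.
#' @export
compound_flowpath_result <- function(compound, flowpath,
                                     R_median, R_iqr, k_median, k_iqr,
                                     dt50_median = k_to_dt50(k_median),
                                     dt50_iqr = NA_real_,
                                     rmse = NA_real_, threshold = NA_real_,
                                     dt50_masked = FALSE) {
  structure(list(compound = compound, flowpath = flowpath,
                 R_median = R_median, R_iqr = R_iqr,
                 k_median = k_median, k_iqr = k_iqr,
                 dt50_median = dt50_median, dt50_iqr = dt50_iqr,
                 rmse = rmse, threshold = threshold,
                 dt50_masked = dt50_masked),
            class = "compound_flowpath_result")
}

#' Mask non-measurable half-lives as infinite
#'
#' If the median DT50 strictly exceeds the detectability threshold, the
#' half-life is reported as `Inf` and its IQR suppressed; a median exactly
#' at the threshold is left unchanged. Idempotent.
#'
#' @param result a [compound_flowpath_result()].
#' @param threshold DT50 threshold (h), e.g. from [dt50_threshold()].
#' @return The (possibly masked) `compound_flowpath_result`.
#' @export
apply_inf_mask <- function(result, threshold) {
  stopifnot(inherits(result, "compound_flowpath_result"), threshold > 0)
  result$threshold <- threshold
  if (!result$dt50_masked && result$dt50_median > threshold) {
    result$dt50_masked <- TRUE
    result$dt50_median <- Inf
    result$dt50_iqr <- NA_real_
  }
  result
}

#' Root mean square error of a fitted breakthrough curve
#'
#' Goodness-of-fit indicator: `sqrt(mean((obs - fit)^2))` with the model
#' evaluated at the posterior-median parameters and the observation times.
#'
#' @param observed an [observation_set()].
#' @param fitted a [breakthrough_curve()] covering the observation times, or
#'   a numeric vector of fitted values already at the observation times.
#' @return RMSE in ug/L.
#' @export
rmse <- function(observed, fitted) {
  stopifnot(inherits(observed, "observation_set"))
  if (length(observed$times) == 0L) stop("empty observation set")
  fit <- if (inherits(fitted, "breakthrough_curve")) {
    stats::approx(fitted$times, fitted$concentrations,
                  xout = observed$times, rule = 1)$y
  } else as.numeric(fitted)
  if (length(fit) != length(observed$times) || anyNA(fit))
    stop("fitted curve does not cover all observation times")
  sqrt(mean((observed$concentrations - fit)^2))
}

#' @rdname rmse
#' @param rmse_by_flowpath numeric vector of per-flowpath RMSEs for one
#'   compound.
#' @return `average_rmse()`: the arithmetic mean over flowpaths.
#' @export
average_rmse <- function(rmse_by_flowpath) {
  if (length(rmse_by_flowpath) == 0L) stop("no flowpath RMSEs supplied")
  mean(rmse_by_flowpath)
}

#' Assemble per-compound results into a results table
#'
#' Produces the wide summary layout with one row per compound: retardation
#' coefficient medians (IQRs) on flowpaths a--d, half-life medians (IQRs)
#' on a--d with masked entries rendered `"Inf"`, and the average RMSE over
#' flowpaths. Missing compound x flowpath entries are rendered as the
#' explicit gap marker `"--"` rather than silently dropped.
#'
#' @param results a list of [compound_flowpath_result()]s (any order), or
#'   the nested `results` produced by the fitting pipeline.
#' @param flowpaths flowpath ids defining the column order.
#' @return A data frame of class `results_table` with character columns
#'   `R_<fp>` and `DT50_<fp>` holding `"median (iqr)"` renderings to 3
#'   significant figures, and a numeric `RMSE_average` column. The
#'   unformatted numbers are kept in `attr(, "records")`.
#' @export
assemble_results_table <- function(results, flowpaths = c("a", "b", "c", "d")) {
  if (inherits(results, "compound_flowpath_result")) results <- list(results)
  stopifnot(all(vapply(results, inherits, logical(1), "compound_flowpath_result")))
  rec <- do.call(rbind, lapply(results, function(r)
    data.frame(compound = r$compound, flowpath = r$flowpath,
               R_median = r$R_median, R_iqr = r$R_iqr,
               dt50_median = r$dt50_median, dt50_iqr = r$dt50_iqr,
               rmse = r$rmse)))
  fmt <- function(med, iqr) {
    if (is.na(med)) return("--")
    if (is.infinite(med)) return("Inf")
    sprintf("%s (%s)", signif(med, 3), signif(iqr, 3))
  }
  compounds <- unique(rec$compound)
  rows <- lapply(compounds, function(cmp) {
    sub <- rec[rec$compound == cmp, ]
    cell <- function(fp, what) {
      i <- match(fp, sub$flowpath)
      if (is.na(i)) return("--")
      if (what == "R") fmt(sub$R_median[i], sub$R_iqr[i])
      else fmt(sub$dt50_median[i], sub$dt50_iqr[i])
    }
    out <- data.frame(Compound = cmp)
    for (fp in flowpaths) out[[paste0("R_", fp)]] <- cell(fp, "R")
    for (fp in flowpaths) out[[paste0("DT50_", fp)]] <- cell(fp, "DT50")
    out$RMSE_average <- signif(average_rmse(sub$rmse[!is.na(sub$rmse)]), 3)
    out
  })
  tab <- do.call(rbind, rows)
  attr(tab, "records") <- rec
  class(tab) <- c("results_table", class(tab))
  tab
}

#' Parse a rendered results-table cell back into numbers
#'
#' Inverts the `"median (iqr)"` / `"Inf"` / `"--"` rendering used by
#' [assemble_results_table()], so rendered tables round-trip.
#'
#' @param cell character vector of rendered cells.
#' @return A data frame with numeric columns `median` and `iqr` (`Inf` and
#'   `NA` as appropriate).
#' @export
parse_result_cell <- function(cell) {
  out <- data.frame(median = rep(NA_real_, length(cell)),
                    iqr = NA_real_)
  for (i in seq_along(cell)) {
    s <- trimws(cell[i])
    if (s == "--") next
    if (s == "Inf") { out$median[i] <- Inf; next }
    m <- regmatches(s, regexec("^([-0-9.eE+]+) \\(([-0-9.eE+]+)\\)$", s))[[1]]
    if (length(m) != 3L) stop("unparseable cell: ", s)
    out$median[i] <- as.numeric(m[2])
    out$iqr[i] <- as.numeric(m[3])
  }
  out
}
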