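#' Cohort-level summary report
#'
#' Aggregates pattern calls and breakpoint reports into the study-style
#' summary: counts per PEM pattern, proportions of
#' simple/complex/false/VNTR adjudications, the breakpoint feature table,
#' the SDP table, and (when truth is supplied) a confusion matrix of
#' generated versus called architecture codes.
#'
#' @param pattern_calls List of `pattern_call` objects (may be empty).
#' @param breakpoint_reports Optional list of `breakpoint_report`s.
#' @param truth Optional character vector of true architecture codes,
#'   parallel to `pattern_calls`.
#' @return List of class `cohort_report` with elements `pattern_counts`,
#'   `adjudication` (proportions summing to 1 over called loci),
#'   `n_no_call`, `breakpoints` (from [summarize_breakpoint_features()]),
#'   `sdp_table`, `confusion` (code x code matrix or NULL).
#' @export
report_cohort <- function(pattern_calls, breakpoint_reports = NULL,
                          truth = NULL) {
  pats <- vapply(pattern_calls, function(x)
    if (is.null(x$pattern)) "no_call" else x$pattern, "")
  called <- pats[pats != "no_call"]
  pattern_counts <- table(factor(called, levels = pem_pattern_table()$pattern))
  adjud <- if (length(called)) {
    prop.table(table(factor(pattern_complexity(called),
                            levels = c("simple", "complex", "false",
                                       "VNTR"))))
  } else table(factor(character(),
                      levels = c("simple", "complex", "false", "VNTR")))
  confusion <- NULL
  if (!is.null(truth)) {
    stopifnot(length(truth) == length(pattern_calls))
    called_code <- vapply(pattern_calls, function(x)
      if (is.null(x$code) || is.na(x$code)) "no_call" else x$code, "")
    confusion <- table(truth = factor(truth, levels = sv_codes()),
                       called = factor(called_code,
                                       levels = c(sv_codes(), "no_call")))
  }
  sdp_table <- do.call(rbind, lapply(breakpoint_reports, function(r)
    if (!is.null(r$sdp)) data.frame(id = r$id, sdp = format(r$sdp)) else NULL))
  structure(list(pattern_counts = pattern_counts,
                 adjudication = adjud,
                 n_no_call = sum(pats == "no_call"),
                 breakpoints = if (length(breakpoint_reports))
                   summarize_breakpoint_features(breakpoint_reports)
                 else NULL,
                 sdp_table = sdp_table,
                 confusion = confusion),
            class = "cohort_report")
}

#' @export
print.cohort_report <- function(x, ...) {
  cat("<cohort_report>\n  pattern counts:\n")
  print(x$pattern_counts[x$pattern_counts > 0])
  cat("  adjudication proportions:\n")
  print(round(x$adjudication, 3))
  if (x$n_no_call) cat("  no-calls:", x$n_no_call, "\n")
  if (!is.null(x$confusion)) {
    diag_frac <- sum(diag(x$confusion[, rownames(x$confusion)])) /
      max(1, sum(x$confusion))
    cat(sprintf("  confusion diagonal fraction: %.3f\n", diag_frac))
  }
  invisible(x)
}
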