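# internal helpers

#' Round half away from zero
#'
#' Commercial ("half-up") rounding used for all two-decimal display values;
#' `base::round()` rounds half to even, which would print 2.5 tie cases
#' differently from the published tables.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector rounded half away from zero.
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  # nudge by an ulp-scale epsilon so values that are decimally exact halves
  # (e.g. 0.575 stored as 0.57499999...) still round up
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

# status vocabulary used throughout; "DD" = data deficient
.statuses <- c("present", "absent", "DD")
.qualities <- c("H", "M", "L")

# quality grade -> numeric evidence weight (high = best = 0)
.quality_weight <- c(H = 0, M = 0.5, L = 1)

abort_bad_items <- function(bad, what) {
  rlang::abort(
    sprintf("unknown %s id(s): %s", what, paste(unique(bad), collapse = ", ")),
    class = "seamountEBSA_unknown_item"
  )
}

check_records_frame <- function(data) {
  req <- c("seamount", "domain", "item", "status", "quality")
  missing <- setdiff(req, names(data))
  if (length(missing) > 0) {
    rlang::abort(
      sprintf("record data must have columns %s; missing: %s",
              paste(req, collapse = ", "), paste(missing, collapse = ", ")),
      class = "seamountEBSA_bad_schema"
    )
  }
  bad <- setdiff(unique(data$status), .statuses)
  if (length(bad) > 0) {
    rlang::abort(
      sprintf("invalid status value(s): %s (allowed: %s)",
              paste(bad, collapse = ", "), paste(.statuses, collapse = ", ")),
      class = "seamountEBSA_bad_schema"
    )
  }
  bad <- setdiff(unique(data$quality[!is.na(data$quality)]), .qualities)
  if (length(bad) > 0) {
    rlang::abort(
      sprintf("invalid quality grade(s): %s (allowed: H, M, L)",
              paste(bad, collapse = ", ")),
      class = "seamountEBSA_bad_schema"
    )
  }
  invisible(data)
}
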