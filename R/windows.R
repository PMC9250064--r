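#' The five baseline extraction windows
#'
#' Closed integer intervals in days relative to the index date (day 0):
#' `day0 = [0, 0]`, `day_minus1 = [-1, -1]`, `short = [-30, -1]`,
#' `medium = [-180, -31]`, `long = [-450, -181]`. The short/medium/long
#' windows tile `[-450, -1]` without gaps; `day_minus1` deliberately overlaps
#' `short` — windows are independent extractions, not a partition.
#'
#' @return named list of length-2 integer vectors `c(lo, hi)`.
#' @export
default_windows <- function() {
  list(day0 = c(0L, 0L),
       day_minus1 = c(-1L, -1L),
       short = c(-30L, -1L),
       medium = c(-180L, -31L),
       long = c(-450L, -181L))
}

#' Validate a window set
#'
#' @param windows named list of closed integer intervals `c(lo, hi)`.
#' @return the window set, invisibly, or an error.
#' @export
validate_windows <- function(windows) {
  ck <- function(cond, msg) if (!cond) stop("invalid window set: ", msg, call. = FALSE)
  ck(is.list(windows) && length(windows) >= 1, "must be a non-empty list")
  nm <- names(windows)
  ck(!is.null(nm) && all(nzchar(nm)) && !anyDuplicated(nm), "windows must be uniquely named")
  for (w in windows) {
    ck(length(w) == 2 && is.numeric(w) && all(is.finite(w)) && w[1] <= w[2],
       "each window must be c(lo, hi) with lo <= hi")
  }
  invisible(windows)
}

#' Assign a day offset to its extraction windows
#'
#' Returns the names of every window whose closed interval contains the
#' offset (possibly none; day -1 falls in both `day_minus1` and `short`).
#'
#' @param offset integer day offset, `event_date - index_date`.
#' @param windows a window set, default [default_windows()].
#' @return character vector of window names (possibly empty).
#' @examples
#' assign_window(0)    # "day0"
#' assign_window(-1)   # "day_minus1" "short"
#' assign_window(-451) # character(0)
#' @export
assign_window <- function(offset, windows = default_windows()) {
  stopifnot(length(offset) == 1, is.finite(offset))
  validate_windows(windows)
  names(windows)[vapply(windows, function(w) offset >= w[1] && offset <= w[2],
                        logical(1))]
}
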