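#' TG-100-style ranking thresholds for severity, occurrence, and detection
#'
#' Returns the built-in threshold scales used to convert failure quantities
#' into integer ranks 1-10. Each scale is a strictly increasing vector of
#' nine upper bounds: rank r (1-9) is assigned to the smallest bound that is
#' greater than or equal to the quantity, and anything above the ninth bound
#' is rank 10. Exact boundary values map to the lower rank (bounds are
#' inclusive limits).
#'
#' Four criteria are provided:
#' \describe{
#'   \item{severity_ptv}{change in the percentage of PTV covered by the
#'     prescription dose, in percentage points}
#'   \item{severity_cord}{change in the maximum spinal-cord dose, in cGy}
#'   \item{occurrence}{fraction of observed time a parameter is out of
#'     tolerance, in percent}
#'   \item{detection}{fraction of observed time failures persist undetected,
#'     in percent}
#' }
#'
#' @return A named list of four numeric vectors (the nine upper bounds per
#'   criterion), with class \code{"rank_tables"}.
#' @seealso [rank_from_table()]
#' @export
#' @examples
#' tg100_rank_tables()$occurrence
rank_tables <- function() {
  structure(
    list(
      severity_ptv  = c(1, 2, 3, 4, 5, 10, 15, 20, 50),
      severity_cord = c(45, 90, 135, 180, 225, 450, 675, 900, 2250),
      occurrence    = c(0.01, 0.02, 0.05, 0.1, 0.2, 0.5, 1, 2, 5),
      detection     = c(0.01, 0.2, 0.5, 1, 2, 5, 10, 15, 20)
    ),
    class = "rank_tables"
  )
}

#' @rdname rank_tables
#' @export
tg100_rank_tables <- rank_tables

#' Validate a set of ranking tables
#'
#' @param tables a list of numeric threshold vectors, as from
#'   [rank_tables()] or a user-supplied replacement.
#' @return The tables, invisibly, after validation.
#' @keywords internal
validate_rank_tables <- function(tables) {
  required <- c("severity_ptv", "severity_cord", "occurrence", "detection")
  missing <- setdiff(required, names(tables))
  if (length(missing) > 0L) {
    stop("rank tables missing criteria: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  for (nm in required) {
    b <- tables[[nm]]
    if (length(b) != 9L) {
      stop("rank table '", nm, "' must have exactly 9 upper bounds",
           call. = FALSE)
    }
    if (any(diff(b) <= 0)) {
      stop("rank table '", nm, "' bounds must be strictly increasing",
           call. = FALSE)
    }
  }
  invisible(tables)
}

#' Convert a failure quantity to an integer rank
#'
#' Assigns the smallest rank whose upper bound is greater than or equal to
#' the quantity; quantities above the ninth bound receive rank 10. A quantity
#' exactly at a bound maps to the lower rank, because tolerances and
#' thresholds are stated as inclusive limits.
#'
#' @param quantity numeric vector of non-negative failure quantities, in the
#'   criterion's units (percent for occurrence/detection/PTV coverage, cGy
#'   for cord dose).
#' @param criterion one of \code{"severity_ptv"}, \code{"severity_cord"},
#'   \code{"occurrence"}, \code{"detection"}.
#' @param tables ranking tables; defaults to the built-in scales.
#' @return integer vector of ranks in 1-10, same length as \code{quantity}.
#' @export
#' @examples
#' rank_from_table(12, "severity_ptv")   # 7
#' rank_from_table(0.278, "occurrence")  # 6
rank_from_table <- function(quantity,
                            criterion = c("severity_ptv", "severity_cord",
                                          "occurrence", "detection"),
                            tables = rank_tables()) {
  criterion <- match.arg(criterion)
  validate_rank_tables(tables)
  if (any(!is.finite(quantity)) || any(quantity < 0)) {
    stop("quantity must be finite and non-negative", call. = FALSE)
  }
  bounds <- tables[[criterion]]
  # rank = 1 + number of bounds strictly below the quantity, capped at 10
  vapply(quantity, function(q) {
    r <- sum(bounds < q) + 1L
    min(r, 10L)
  }, integer(1))
}
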