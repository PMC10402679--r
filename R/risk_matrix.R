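#' Risk levels
#'
#' The three risk levels, totally ordered low < medium < high, rendered
#' green/yellow/red on plots.
#'
#' @return an ordered factor level set.
#' @keywords internal
risk_levels <- function() c("low", "medium", "high")

risk_factor <- function(x) {
  factor(x, levels = risk_levels(), ordered = TRUE)
}

#' Classify a failure mode's (S, O) pair into a risk level
#'
#' Applies the band rules of the 10x10 severity-by-occurrence risk matrix
#' adapted from the AIAG/VDA FMEA reference matrix, amended for TG-100's
#' instruction that very high severities deserve attention even when never
#' observed. The rules, in precedence order:
#' \enumerate{
#'   \item S = 1: low.
#'   \item O = 1: medium if S is 9 or 10, otherwise low.
#'   \item S in 2-5: medium if O + S is 9-10, high if O + S is 11-15,
#'     otherwise low.
#'   \item S in 6-10: medium if O + S is 9-11, high if O + S is 12-20,
#'     otherwise low.
#' }
#'
#' @param S,O integer vectors of ranks in 1-10 (recycled to a common
#'   length).
#' @return an ordered factor with levels low < medium < high.
#' @export
#' @examples
#' classify_risk(S = 3, O = 6)  # medium
#' classify_risk(S = 9, O = 1)  # medium: high severity never observed
classify_risk <- function(S, O) {
  n <- max(length(S), length(O))
  S <- rep_len(as.integer(S), n)
  O <- rep_len(as.integer(O), n)
  if (any(!S %in% 1:10) || any(!O %in% 1:10)) {
    stop("S and O ranks must be integers in 1-10", call. = FALSE)
  }
  out <- character(n)
  for (i in seq_len(n)) {
    s <- S[i]; o <- O[i]; t <- s + o
    out[i] <-
      if (s == 1L) {
        "low"
      } else if (o == 1L) {
        if (s >= 9L) "medium" else "low"
      } else if (s <= 5L) {
        if (t >= 9L && t <= 10L) "medium"
        else if (t >= 11L && t <= 15L) "high"
        else "low"
      } else {
        if (t >= 9L && t <= 11L) "medium"
        else if (t >= 12L && t <= 20L) "high"
        else "low"
      }
  }
  risk_factor(out)
}

#' Build the full 10x10 risk matrix
#'
#' Applies [classify_risk()] to all 100 (S, O) combinations.
#'
#' @return A 10x10 character matrix of class \code{"risk_matrix"}; rows are
#'   occurrence ranks (named O1-O10), columns severity ranks (S1-S10).
#' @export
#' @examples
#' rm <- build_risk_matrix()
#' table(rm)  # 32 low, 19 medium, 49 high
build_risk_matrix <- function() {
  m <- matrix(NA_character_, nrow = 10, ncol = 10,
              dimnames = list(paste0("O", 1:10), paste0("S", 1:10)))
  for (o in 1:10) {
    m[o, ] <- as.character(classify_risk(S = 1:10, O = o))
  }
  structure(m, class = c("risk_matrix", "matrix"))
}

#' @export
print.risk_matrix <- function(x, ...) {
  sym <- c(low = "L", medium = "M", high = "H")
  disp <- matrix(sym[unclass(x)], nrow = nrow(x), dimnames = dimnames(x))
  cat("10x10 risk matrix (severity along columns, occurrence along rows)\n")
  cat("L = low (green), M = medium (yellow), H = high (red)\n\n")
  # print occurrence from 10 down to 1 so low-occurrence rows sit at the
  # bottom, the usual orientation of a risk matrix
  print(disp[10:1, , drop = FALSE], quote = FALSE)
  counts <- table(risk_factor(unclass(x)))
  cat("\nlevels:", paste(names(counts), counts, sep = " = ",
                         collapse = ", "), "\n")
  invisible(x)
}

#' Look up risk levels in a prebuilt matrix
#'
#' @param matrix a \code{risk_matrix} from [build_risk_matrix()].
#' @param S,O integer ranks in 1-10.
#' @return an ordered factor of levels.
#' @keywords internal
lookup_risk <- function(matrix, S, O) {
  risk_factor(matrix[cbind(as.integer(O), as.integer(S))])
}

#' Recommend a QC test interval for one item
#'
#' Scans the item's failure modes from the shortest to the longest tested
#' interval and recommends the first interval classified medium risk: the
#' longest interval (least effort) that still sits at the edge of acceptable
#' risk. If no interval is medium and none is high, every tested interval is
#' acceptable and the longest is recommended (rule \code{longest_all_low}).
#' If a high-risk interval appears before any medium one, the longest
#' interval preceding the first high is recommended (rule
#' \code{last_before_high}). An item already at high risk under daily
#' testing cannot be scheduled on this grid and raises an error.
#'
#' @param item a single-row \code{qc_catalog} entry or an item_id.
#' @param profiles a data frame of \code{rank_profile} rows for this item,
#'   one per grid interval, all sharing one O rank.
#' @param matrix a \code{risk_matrix}; defaults to [build_risk_matrix()].
#' @param grid the \code{interval_grid} the profiles must cover.
#' @return A list of class \code{"frequency_recommendation"}: \code{item_id},
#'   \code{per_interval_levels} (data frame interval_days/S/O/level),
#'   \code{recommended_interval_days}, \code{candidates} (non-high
#'   intervals), \code{rule_applied}.
#' @export
recommend_frequency <- function(item, profiles,
                                matrix = build_risk_matrix(),
                                grid = interval_grid()) {
  id <- if (is.data.frame(item)) item$item_id[1] else as.integer(item)
  pr <- profiles[profiles$item_id == id, , drop = FALSE]
  pr <- pr[order(pr$interval_days), , drop = FALSE]
  if (anyDuplicated(pr$interval_days) ||
      !identical(as.integer(pr$interval_days),
                 as.integer(grid$interval_days))) {
    stop("profiles for item ", id, " must cover every grid interval ",
         "exactly once", call. = FALSE)
  }
  if (length(unique(pr$O)) != 1L) {
    stop("all failure modes of item ", id, " must share one O rank",
         call. = FALSE)
  }
  levels <- lookup_risk(matrix, S = pr$S, O = pr$O)
  trace <- data.frame(interval_days = pr$interval_days, S = pr$S, O = pr$O,
                      level = as.character(levels),
                      stringsAsFactors = FALSE)
  if (is.unsorted(as.integer(levels))) {
    warning("risk levels for item ", id,
            " are not monotone across intervals; scanning in grid order",
            call. = FALSE)
  }
  first_medium <- match("medium", trace$level)
  first_high <- match("high", trace$level)
  if (!is.na(first_high) && first_high == 1L) {
    stop("item ", id, " is already high risk at the shortest tested ",
         "interval; escalation beyond daily QC is needed", call. = FALSE)
  }
  if (!is.na(first_medium) && (is.na(first_high) ||
                               first_medium < first_high)) {
    rule <- "first_medium"
    rec <- trace$interval_days[first_medium]
  } else if (is.na(first_high)) {
    rule <- "longest_all_low"
    rec <- trace$interval_days[nrow(trace)]
  } else {
    rule <- "last_before_high"
    rec <- trace$interval_days[first_high - 1L]
  }
  structure(list(item_id = id, per_interval_levels = trace,
                 recommended_interval_days = as.integer(rec),
                 candidates = trace$interval_days[trace$level != "high"],
                 rule_applied = rule),
            class = "frequency_recommendation")
}

#' @export
print.frequency_recommendation <- function(x, ...) {
  cat("QC item", x$item_id, "- recommended interval:",
      x$recommended_interval_days, "days (rule:", x$rule_applied, ")\n")
  print(x$per_interval_levels, row.names = FALSE)
  invisible(x)
}

#' Render risk-matrix maps for a set of recommendations
#'
#' One grid per item: test interval on the vertical axis, severity rank on
#' the horizontal, each failure mode's cell colored by its risk level, the
#' recommended interval marked. Returns a text rendering and optionally
#' draws the grids on the current graphics device or into a PNG file.
#'
#' @param recommendations a list of \code{frequency_recommendation} objects.
#' @param file optional path to a PNG file; when given, the maps are drawn
#'   there instead of the active device.
#' @param draw logical; draw on the active device when no file is given.
#' @return Invisibly, a character vector of the text rendering (also usable
#'   via \code{cat}).
#' @export
render_rm_map <- function(recommendations, file = NULL, draw = is.null(file)) {
  if (length(recommendations) == 0L) {
    stop("no recommendations to render", call. = FALSE)
  }
  sym <- c(low = "L", medium = "M", high = "H")
  lines <- character(0)
  for (rec in recommendations) {
    tr <- rec$per_interval_levels
    lines <- c(lines,
               sprintf("QC item %d (O = %d), recommended D%d:",
                       rec$item_id, tr$O[1], rec$recommended_interval_days))
    header <- paste0("      ", paste(sprintf("S%-3d", 1:10), collapse = ""))
    lines <- c(lines, header)
    for (i in rev(seq_len(nrow(tr)))) {
      row <- rep(".", 10)
      row[tr$S[i]] <- sym[[tr$level[i]]]
      mark <- if (tr$interval_days[i] == rec$recommended_interval_days)
        " <-" else ""
      lines <- c(lines, sprintf("D%-4d %s%s", tr$interval_days[i],
                                paste(sprintf("%-4s", row), collapse = ""),
                                mark))
    }
    lines <- c(lines, "")
  }
  if (!is.null(file)) {
    grDevices::png(file, width = 480, height = 360 * length(recommendations))
    on.exit(grDevices::dev.off(), add = TRUE)
    draw <- TRUE
  }
  if (draw) {
    cols <- c(low = "#4daf4a", medium = "#ffd92f", high = "#e41a1c")
    old <- graphics::par(mfrow = c(length(recommendations), 1),
                         mar = c(4, 4, 2, 1))
    on.exit(graphics::par(old), add = TRUE)
    for (rec in recommendations) {
      tr <- rec$per_interval_levels
      n <- nrow(tr)
      graphics::plot(NULL, xlim = c(0.5, 10.5), ylim = c(0.5, n + 0.5),
                     xlab = "severity rank", ylab = "test interval",
                     yaxt = "n", xaxt = "n",
                     main = sprintf("QC item %d (O = %d)", rec$item_id,
                                    tr$O[1]))
      graphics::axis(1, at = 1:10)
      graphics::axis(2, at = seq_len(n), labels = paste0("D", tr$interval_days),
                     las = 1)
      for (i in seq_len(n)) {
        graphics::rect(tr$S[i] - 0.5, i - 0.5, tr$S[i] + 0.5, i + 0.5,
                       col = cols[[tr$level[i]]], border = "grey30")
      }
      irec <- match(rec$recommended_interval_days, tr$interval_days)
      graphics::points(tr$S[irec], irec, pch = 8, cex = 1.4)
    }
  }
  invisible(lines)
}
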