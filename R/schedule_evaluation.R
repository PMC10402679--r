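#' QC-schedule efficiency metric E = O/D
#'
#' E characterizes a schedule's ability to detect machine failures: the
#' occurrence rank over the detection rank. Larger values mean failures are
#' detected sooner relative to how often they occur. Computed from ranks,
#' matching how schedules are compared in practice; raw failure quantities
#' can be supplied instead via \code{raw = TRUE} for sensitivity analysis.
#'
#' @param O_rank,D_rank integer ranks in 1-10 (or, with \code{raw = TRUE},
#'   positive raw quantities on a common percent scale).
#' @param raw logical; skip the 1-10 range check and divide raw quantities.
#' @return numeric; the ratio O/D. Reporting convention is two decimals,
#'   half away from zero (see [format_efficiency()]).
#' @export
#' @examples
#' efficiency(2, 5)  # 0.4
efficiency <- function(O_rank, D_rank, raw = FALSE) {
  if (!raw && (any(!O_rank %in% 1:10) || any(!D_rank %in% 1:10))) {
    stop("O and D ranks must be integers in 1-10", call. = FALSE)
  }
  if (raw && any(O_rank <= 0 | D_rank <= 0)) {
    stop("raw quantities must be positive", call. = FALSE)
  }
  O_rank / D_rank
}

#' Format an efficiency value for reporting
#'
#' Two decimals, rounding half away from zero (2/6 reports as 0.33, 2/7 as
#' 0.29).
#'
#' @param E numeric efficiency values.
#' @return numeric, rounded to two decimals.
#' @export
format_efficiency <- function(E) {
  round_half_away(E * 100) / 100
}

#' Evaluate a schedule for a set of items
#'
#' @param item_id integer vector of items.
#' @param O_rank,D_rank integer rank vectors parallel to \code{item_id}.
#' @param label \code{"new"} or \code{"old"}.
#' @return A data frame of class \code{"schedule_evaluation"} with columns
#'   \code{item_id}, \code{label}, \code{O_rank}, \code{D_rank}, \code{E}.
#' @export
schedule_evaluation <- function(item_id, O_rank, D_rank,
                                label = c("new", "old")) {
  label <- match.arg(label)
  structure(
    data.frame(item_id = as.integer(item_id), label = label,
               O_rank = as.integer(O_rank), D_rank = as.integer(D_rank),
               E = efficiency(as.integer(O_rank), as.integer(D_rank)),
               stringsAsFactors = FALSE),
    class = c("schedule_evaluation", "data.frame")
  )
}

#' Compare a new QC schedule against the old one
#'
#' Per item, the verdict is \code{improved} when the new schedule's E
#' exceeds the old one's, \code{unchanged} when equal, and \code{worse}
#' otherwise.
#'
#' @param new,old \code{schedule_evaluation} data frames covering the same
#'   item set.
#' @return A data frame of class \code{"schedule_comparison"} with one row
#'   per item (O/D/E for both schedules and the verdict), plus a
#'   \code{"summary"} attribute of verdict counts.
#' @export
compare_schedules <- function(new, old) {
  if (!setequal(new$item_id, old$item_id) ||
      anyDuplicated(new$item_id) || anyDuplicated(old$item_id)) {
    stop("new and old schedules must cover the same items exactly once",
         call. = FALSE)
  }
  new <- new[order(new$item_id), , drop = FALSE]
  old <- old[match(new$item_id, old$item_id), , drop = FALSE]
  verdict <- ifelse(new$E > old$E, "improved",
                    ifelse(new$E == old$E, "unchanged", "worse"))
  out <- data.frame(item_id = new$item_id,
                    O_new = new$O_rank, D_new = new$D_rank,
                    E_new = format_efficiency(new$E),
                    O_old = old$O_rank, D_old = old$D_rank,
                    E_old = format_efficiency(old$E),
                    verdict = verdict, stringsAsFactors = FALSE)
  attr(out, "summary") <- table(factor(verdict, levels = c("improved",
                                                           "unchanged",
                                                           "worse")))
  class(out) <- c("schedule_comparison", "data.frame")
  out
}

#' @export
print.schedule_comparison <- function(x, ...) {
  cat("Schedule comparison (E = O/D; higher detects failures better)\n")
  print.data.frame(x, row.names = FALSE)
  s <- attr(x, "summary")
  cat("\n", paste(names(s), s, sep = ": ", collapse = ", "), "\n", sep = "")
  invisible(x)
}
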