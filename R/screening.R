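#' Visual-analog-scale response set for one participant
#'
#' Panel screening data: each participant rates five passion-fruit-juice
#' samples sweetened with graded sucrose concentrations (4.7, 7.05, 9.4,
#' 11.75 and 14.1 g/100 g) on a 9.0-cm visual analog scale whose centre
#' (4.5 cm) is defined as ideal sweetness.
#'
#' @param participant_id identifier.
#' @param concentrations sucrose concentrations in g/100 g; all five standard
#'   levels must be present exactly once (any order).
#' @param marks VAS mark positions in cm, within \[0, 9\], aligned with
#'   `concentrations`.
#' @return an object of class `vas_response`.
#' @export
vas_response <- function(participant_id, concentrations, marks) {
  std <- c(4.7, 7.05, 9.4, 11.75, 14.1)
  concentrations <- as.numeric(concentrations)
  marks <- as.numeric(marks)
  if (length(concentrations) != length(marks))
    input_error("vas_response", "concentrations and marks differ in length")
  missing <- std[!vapply(std, function(s) any(abs(concentrations - s) < 1e-9), logical(1))]
  if (length(missing) || length(concentrations) != 5)
    input_error("vas_response", "missing concentration %s",
                if (length(missing)) missing[1] else "(duplicates present)")
  if (any(marks < 0 | marks > 9))
    input_error("vas_response", "marks must lie within the 9-cm scale")
  ord <- order(concentrations)
  structure(list(participant_id = participant_id,
                 concentrations = concentrations[ord], marks = marks[ord]),
            class = "vas_response")
}

#' Eligibility decision for one participant
#'
#' A participant is eligible iff (a) the VAS marks are strictly increasing
#' with sucrose concentration (correct ordering of all five samples; ties
#' reject) and (b) the mark for the 9.4 g/100 g sample lies within
#' `tolerance` cm of `ideal_mark` (perceives 9.4 g/100 g as ideal sweetness).
#' `tolerance = Inf` reduces the rule to ordering only. The decision depends
#' only on the order pattern and the 9.4 mark, never on input row order.
#'
#' @param v a [vas_response()].
#' @param ideal_mark scale centre in cm (default 4.5).
#' @param tolerance allowed deviation of the 9.4 g/100 g mark from
#'   `ideal_mark`, cm (default 1.0; the source quantifies "around the centre"
#'   no further).
#' @return list with `eligible` (logical) and `reasons` (character vector of
#'   failed criteria, empty when eligible).
#' @export
screen_participant <- function(v, ideal_mark = 4.5, tolerance = 1.0) {
  stopifnot(inherits(v, "vas_response"))
  reasons <- character(0)
  if (any(diff(v$marks) <= 0))
    reasons <- c(reasons, "ordering criterion: marks not strictly increasing with concentration")
  mark94 <- v$marks[abs(v$concentrations - 9.4) < 1e-9]
  if (abs(mark94 - ideal_mark) > tolerance)
    reasons <- c(reasons, sprintf(
      "ideal-sweetness criterion: mark at 9.4 g/100 g is %.2f cm, outside %.2f +/- %.2f cm",
      mark94, ideal_mark, tolerance))
  list(eligible = length(reasons) == 0, reasons = reasons,
       participant_id = v$participant_id)
}

#' Screen a panel of participants from a CSV table
#'
#' Reads long-format responses (columns participant_id, concentration, mark)
#' and applies [screen_participant()] to each participant.
#'
#' @param path CSV path or a data.frame in the same layout.
#' @param ideal_mark,tolerance passed to [screen_participant()].
#' @return data.frame with columns participant_id, eligible, reasons.
#' @export
screen_panel <- function(path, ideal_mark = 4.5, tolerance = 1.0) {
  df <- if (is.data.frame(path)) path else read.csv(path, stringsAsFactors = FALSE)
  need <- c("participant_id", "concentration", "mark")
  if (!all(need %in% names(df)))
    input_error("screen_panel", "table must have columns %s", paste(need, collapse = ","))
  out <- lapply(split(df, df$participant_id), function(d) {
    r <- screen_participant(vas_response(d$participant_id[1], d$concentration, d$mark),
                            ideal_mark, tolerance)
    data.frame(participant_id = r$participant_id, eligible = r$eligible,
               reasons = paste(r$reasons, collapse = "; "),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
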