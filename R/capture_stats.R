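# Binomial capture-probability estimates.  Two bounds per condition:
# "lower" counts only outright captures, "upper" counts captures plus
# possible captures (the nucleotide straddling the N17 ring at the end of
# the run can still enter or escape, so the true entry probability lies
# between the two).

#' Capture probability with binomial standard error
#'
#' @param labels character vector of per-run outcome labels
#'   (`captured` / `possible` / `failed`) for one condition.
#' @param bound `"lower"` (captured only) or `"upper"`
#'   (captured + possible).
#' @return one-row data.frame with `bound`, `p` (fraction), `se`
#'   (binomial standard error, `sqrt(p(1-p)/n)`), `n`.
#' @export
capture_probability <- function(labels, bound = c("upper", "lower")) {
  bound <- match.arg(bound)
  n <- length(labels)
  if (n == 0L) stop("no outcomes supplied")
  bad <- setdiff(unique(labels), c("captured", "possible", "failed"))
  if (length(bad)) stop("unknown outcome label(s): ",
                        paste(bad, collapse = ", "))
  k <- if (bound == "lower") sum(labels == "captured")
       else sum(labels %in% c("captured", "possible"))
  p <- k / n
  data.frame(bound = bound, p = p, se = sqrt(p * (1 - p) / n), n = n)
}

#' Capture-probability table over a condition grid
#'
#' Groups an outcome table by condition and computes both probability
#' bounds.  Rows are tagged by series: `distance` for the on-axis study
#' (`translation == 0`) and `displacement` for the lateral study at the
#' displacement height (which includes the on-axis point at that height as
#' its zero-translation anchor).
#'
#' @param outcomes data.frame with columns `height`, `translation`,
#'   `orientation` and `label`.
#' @param displacement_height release height of the displacement study, nm.
#' @return data.frame with one row per (condition, orientation, bound):
#'   columns `height`, `translation`, `orientation`, `series`, `bound`,
#'   `p`, `se`, `n`, and `probability`/`probability_se` in percent.
#' @export
probability_table <- function(outcomes, displacement_height = 3.0) {
  stopifnot(all(c("height", "translation", "orientation", "label") %in%
                  names(outcomes)))
  key <- interaction(outcomes$height, outcomes$translation,
                     outcomes$orientation, drop = TRUE)
  rows <- lapply(split(outcomes, key), function(grp) {
    both <- rbind(capture_probability(grp$label, "lower"),
                  capture_probability(grp$label, "upper"))
    cbind(height = grp$height[1], translation = grp$translation[1],
          orientation = grp$orientation[1], both)
  })
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  tab$series <- ifelse(tab$translation == 0, "distance", "other")
  disp <- abs(tab$height - displacement_height) < 1e-9
  tab$series[disp & tab$translation > 0] <- "displacement"
  tab$probability <- 100 * tab$p
  tab$probability_se <- 100 * tab$se
  tab[order(tab$orientation, tab$series, tab$height, tab$translation,
            tab$bound), ]
}

#' Extract regression series from a probability table
#'
#' `height_series()` pulls the on-axis distance study (percent scale, with
#' binomial SEs) for one orientation and bound; `translation_series()`
#' pulls the lateral displacement study at the displacement height,
#' including its zero-translation anchor point.
#'
#' @param prob_table output of [probability_table()].
#' @param orientation `"up"` or `"down"`.
#' @param bound `"upper"` or `"lower"`.
#' @param displacement_height height of the displacement study, nm.
#' @return data.frame with `height` (or `translation`), `probability` and
#'   `se`, all in percent.
#' @export
height_series <- function(prob_table, orientation, bound = "upper") {
  s <- prob_table[prob_table$orientation == orientation &
                    prob_table$bound == bound &
                    prob_table$translation == 0, ]
  data.frame(height = s$height, probability = s$probability,
             se = s$probability_se)
}

#' @rdname height_series
#' @export
translation_series <- function(prob_table, orientation, bound = "upper",
                               displacement_height = 3.0) {
  s <- prob_table[prob_table$orientation == orientation &
                    prob_table$bound == bound &
                    abs(prob_table$height - displacement_height) < 1e-9, ]
  data.frame(translation = s$translation, probability = s$probability,
             se = s$probability_se)
}
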