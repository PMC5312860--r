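# Linear capture-probability model in release height and lateral
# translation:  p(%) = intercept - height_slope * h - translation_slope * t,
# with h and t in nm.  Height-only fits are ordinary least squares on the
# per-height probabilities; the translation series is first anchored so its
# zero-translation point equals the height model's prediction at the series
# height, then the translation slope is fitted with the intercept held at
# that prediction.

#' Construct a capture-probability model
#'
#' Prediction (percent) = `intercept - height_slope * h -
#' translation_slope * t`, with height `h` and translation `t` in nm.
#'
#' @param intercept probability (%) at height 0, translation 0.
#' @param height_slope loss of probability (% per nm) with release height.
#' @param translation_slope loss (% per nm) with lateral translation.
#' @param orientation optional phosphate orientation label (`up`/`down`).
#' @param metadata optional list of fit diagnostics.
#' @return object of class `capture_model`.
#' @export
capture_model <- function(intercept, height_slope, translation_slope = 0,
                          orientation = NA_character_, metadata = list()) {
  stopifnot(is.finite(intercept), is.finite(height_slope),
            is.finite(translation_slope))
  structure(list(intercept = intercept,
                 height_slope = height_slope,
                 translation_slope = translation_slope,
                 orientation = orientation,
                 metadata = metadata),
            class = "capture_model")
}

#' Reference capture models for wild-type alpha-hemolysin
#'
#' The published linear possible-capture models for a mononucleotide
#' released above the wild-type pore: phosphate-up, 72% - 16.5%/nm height
#' - 2.3%/nm translation; phosphate-down, 93% - 20.5%/nm height - 6.2%/nm
#' translation.  These serve as the default generating truth for the
#' Bernoulli outcome tier.
#'
#' @param include_translation if `FALSE`, return the height-only forms.
#' @return named list of `capture_model` objects (`up`, `down`).
#' @export
alpha_hemolysin_models <- function(include_translation = TRUE) {
  ts <- if (include_translation) c(up = 2.3, down = 6.2)
        else c(up = 0, down = 0)
  list(up = capture_model(72, 16.5, ts[["up"]], orientation = "up"),
       down = capture_model(93, 20.5, ts[["down"]], orientation = "down"))
}

#' Evaluate a capture model
#'
#' Returns the raw linear value, deliberately unclamped; values outside
#' \[0, 100\] are flagged via the `"out_of_range"` attribute (clamping to a
#' probability is the generator's job, not the model's).
#'
#' @param object a `capture_model`.
#' @param height release height above the K8 ring, nm (vectorised).
#' @param translation lateral translation, nm (vectorised).
#' @param ... unused.
#' @return predicted probability in percent.
#' @export
predict.capture_model <- function(object, height, translation = 0, ...) {
  if (any(height < 0)) stop("height must be non-negative")
  if (any(translation < 0)) stop("translation must be non-negative")
  p <- object$intercept - object$height_slope * height -
    object$translation_slope * translation
  if (any(p < 0 | p > 100)) attr(p, "out_of_range") <- TRUE
  p
}

#' Fit the height-only capture model
#'
#' Ordinary least squares of probability (%) on release height (nm),
#' reported in the subtractive form `intercept - height_slope * h`.  If the
#' points carry binomial standard errors (`se` column, %), the coefficient
#' standard errors propagated from them are recorded in the fit metadata
#' (`coef_se`); the fit itself stays unweighted unless `weighted = TRUE`.
#'
#' @param points data.frame with columns `height` (nm) and `probability`
#'   (%), optionally `se` (%).
#' @param orientation optional orientation label carried into the model.
#' @param weighted if `TRUE` and `se` is present, weight by `1/se^2`
#'   (points with `se == 0` get the largest finite weight present).
#' @return a `capture_model` with `translation_slope = 0`.
#' @export
fit_height_model <- function(points, orientation = NA_character_,
                             weighted = FALSE) {
  stopifnot(all(c("height", "probability") %in% names(points)))
  h <- points$height
  p <- points$probability
  if (length(unique(h)) < 2L)
    stop("need at least 2 distinct heights to fit a line")
  w <- NULL
  if (weighted) {
    if (!"se" %in% names(points)) stop("weighted fit requires an 'se' column")
    w <- 1 / pmax(points$se, min(points$se[points$se > 0]))^2
  }
  fit <- lm(p ~ h, weights = w)
  cf <- coef(fit)
  md <- list(n = length(h), rss = sum(residuals(fit)^2))
  if ("se" %in% names(points)) {
    # propagate the per-point binomial SEs through the OLS estimator
    hb <- mean(h)
    sxx <- sum((h - hb)^2)
    ci <- (h - hb) / sxx
    md$coef_se <- c(
      intercept = sqrt(sum((1 / length(h) - hb * ci)^2 * points$se^2)),
      height_slope = sqrt(sum(ci^2 * points$se^2)))
  }
  capture_model(intercept = unname(cf[1]), height_slope = unname(-cf[2]),
                translation_slope = 0, orientation = orientation,
                metadata = md)
}

#' Remove the height effect from a translation series
#'
#' The lateral-displacement study is run at one fixed release height.  To
#' isolate the translation effect, the whole series is shifted by a single
#' constant so that its zero-translation point equals the height model's
#' prediction at the series height.
#'
#' @param translation_points data.frame with columns `translation` (nm) and
#'   `probability` (%), optionally `se`; must contain a `translation == 0`
#'   row (the anchor).
#' @param height_model fitted height-only `capture_model`.
#' @param series_height release height of the displacement study, nm.
#' @return the input data.frame with `probability` shifted; the shift is
#'   recorded in `attr(, "shift")`.
#' @export
remove_height_effect <- function(translation_points, height_model,
                                 series_height = 3.0) {
  stopifnot(all(c("translation", "probability") %in%
                  names(translation_points)))
  at0 <- which(abs(translation_points$translation) < 1e-9)
  if (length(at0) == 0L)
    stop("translation series has no zero-translation anchor point")
  anchor <- predict(height_model, series_height, 0)
  shift <- as.numeric(anchor) - mean(translation_points$probability[at0])
  out <- translation_points
  out$probability <- out$probability + shift
  attr(out, "shift") <- shift
  out
}

#' Fit the combined height + translation capture model
#'
#' Intercept and height slope come from the height-only fit; the
#' translation slope is fitted to the height-adjusted displacement series
#' by least squares with the intercept fixed at the height model's
#' prediction for the series height.
#'
#' @param height_points data.frame (`height`, `probability`, optional `se`)
#'   for the on-axis distance study.
#' @param translation_points data.frame (`translation`, `probability`,
#'   optional `se`) for the displacement study at `series_height`.
#' @param orientation optional orientation label.
#' @param series_height release height of the displacement study, nm.
#' @param weighted passed to [fit_height_model()].
#' @param anchored if `FALSE`, fit the translation slope with a free
#'   intercept instead of pinning it at the height-model prediction
#'   (sensitivity analysis only; the anchoring step makes the pinned
#'   intercept the natural choice).
#' @return a `capture_model` with all three coefficients.
#' @export
fit_combined_model <- function(height_points, translation_points,
                               orientation = NA_character_,
                               series_height = 3.0, weighted = FALSE,
                               anchored = TRUE) {
  hm <- fit_height_model(height_points, orientation, weighted)
  adj <- remove_height_effect(translation_points, hm, series_height)
  anchor <- as.numeric(predict(hm, series_height, 0))
  t <- adj$translation
  if (anchored) {
    # least squares for p = anchor - s * t with the intercept pinned
    s <- sum(t * (anchor - adj$probability)) / sum(t^2)
  } else {
    s <- -unname(coef(lm(adj$probability ~ t))[2])
  }
  md <- hm$metadata
  md$n <- md$n + nrow(adj)
  md$rss <- md$rss + sum((anchor - s * t - adj$probability)^2)
  md$series_height <- series_height
  md$anchor_shift <- attr(adj, "shift")
  if ("se" %in% names(translation_points)) {
    # anchoring cancels the height-fit contribution: the fitted slope is
    # sum(t_i * (p0hat - p_ihat)) / sum(t^2) in terms of raw proportions
    se <- translation_points$se
    t0 <- abs(translation_points$translation) < 1e-9
    t2 <- sum(t^2)
    md$coef_se["translation_slope"] <-
      sqrt(sum(t)^2 * mean(se[t0])^2 + sum((t[!t0])^2 * se[!t0]^2)) / t2
  }
  capture_model(intercept = hm$intercept, height_slope = hm$height_slope,
                translation_slope = s, orientation = orientation,
                metadata = md)
}

#' @export
print.capture_model <- function(x, ...) {
  cat(sprintf(
    "Capture model%s: p(%%) = %.4g - %.4g * height(nm) - %.4g * translation(nm)\n",
    if (is.na(x$orientation)) "" else paste0(" (phosphate ", x$orientation, ")"),
    x$intercept, x$height_slope, x$translation_slope))
  invisible(x)
}
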