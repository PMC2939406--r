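#' Recover the new glycemic curve from an early HbA1c measurement
#'
#' Inverts the two-curve mixture formula: given the steady-state HbA1c
#' \code{hb1} before a change and the measured HbA1c \code{hb_mix} taken
#' \code{m} months after it,
#' \deqn{Hb_x = \frac{16\,Hb_{mix} - Hb_1 (m^2 - 8m + 16)}{8m - m^2}}
#' is the steady-state HbA1c of the new curve — the quantity a naive
#' reading of \code{hb_mix} misses. The inversion is algebraically exact:
#' feeding the result back through \code{\link{hb_mix_value}} reproduces
#' \code{hb_mix}.
#'
#' A non-positive recovered \code{hbx} (or glucose twin) is physiologically
#' impossible; it is flagged, never clamped or raised, because error-grid
#' tabulations legitimately probe such regimes.
#'
#' @param hb_mix measured HbA1c \code{m} months after the change, percent.
#' @param hb1 steady-state HbA1c before the change, percent.
#' @param m months since the change, in (0, 4].
#' @param model a \code{\link{conversion_model}} or model name, used to
#'   attach the MPG twin of the recovered HbA1c.
#' @param intercept_mode see \code{\link{hba1c_from_mpg}}.
#' @return An object of class \code{inversion_result}: list with
#'   \code{hbx}, \code{mpgx}, \code{hb_mix_input}, \code{m} and
#'   \code{flags} (character vector; \code{"non_physiological"} when the
#'   recovered state is not attainable).
#' @examples
#' invert_hbx(hb_mix = 7.6875, hb1 = 9, m = 1)   # recovers hbx = 6
#' @export
invert_hbx <- function(hb_mix, hb1, m, model = "DCCT",
                       intercept_mode = c("paper", "exact")) {
  intercept_mode <- match.arg(intercept_mode)
  model <- resolve_model(model)
  stopifnot(is.numeric(hb_mix), is.numeric(hb1), is.numeric(m),
            length(hb_mix) == 1L, length(hb1) == 1L, length(m) == 1L)
  if (m <= 0 || m > 4) {
    stop("'m' must lie in (0, 4] months (denominator 8m - m^2 must be positive)",
         call. = FALSE)
  }
  hbx <- (16 * hb_mix - hb1 * (m^2 - 8 * m + 16)) / (8 * m - m^2)
  flags <- character()
  mpgx <- NA_real_
  if (hbx <= 0) {
    flags <- "non_physiological"
  } else {
    mpgx <- tryCatch(mpg_from_hba1c(hbx, model), error = function(e) NA_real_)
    if (!is.na(mpgx) && mpgx <= 0) mpgx <- NA_real_
    if (is.na(mpgx)) flags <- "non_physiological"
  }
  new_inversion_result(hbx, mpgx, hb_mix, m, flags)
}

#' Recover the new mean plasma glucose from an early HbA1c measurement
#'
#' MPG-space counterpart of \code{\link{invert_hbx}}:
#' \deqn{MPG_x = \frac{570\,Hb_{mix} - MPG_1 (m^2 - 8m + 16) - 1236}{8m - m^2}.}
#' With \code{constant_mode = "paper"} the conventional rounded constants
#' 570 and 1236 are used verbatim; with \code{"exact"} the inversion is
#' composed from \code{\link{invert_hbx}} and the exact-intercept DCCT
#' conversions, so that MPG and HbA1c space stay mutually consistent.
#'
#' @param hb_mix measured HbA1c, percent.
#' @param mpg1 steady-state MPG before the change, mg/dl.
#' @param m months since the change, in (0, 4].
#' @param constant_mode \code{"paper"} or \code{"exact"}.
#' @param model a \code{\link{conversion_model}} or model name.
#' @return An \code{inversion_result}; see \code{\link{invert_hbx}}.
#' @examples
#' invert_mpgx(hb_mix = 7.6875, mpg1 = 244, m = 1)
#' @export
invert_mpgx <- function(hb_mix, mpg1, m,
                        constant_mode = c("paper", "exact"),
                        model = "DCCT") {
  constant_mode <- match.arg(constant_mode)
  model <- resolve_model(model)
  stopifnot(is.numeric(hb_mix), is.numeric(mpg1), is.numeric(m),
            length(hb_mix) == 1L, length(mpg1) == 1L, length(m) == 1L)
  if (m <= 0 || m > 4) {
    stop("'m' must lie in (0, 4] months (denominator 8m - m^2 must be positive)",
         call. = FALSE)
  }
  if (constant_mode == "exact") {
    hb1 <- hba1c_from_mpg(mpg1, model, "exact")
    res <- invert_hbx(hb_mix, hb1, m, model, "exact")
    return(res)
  }
  k <- mixture_constants("paper")
  mpgx <- (k$scale * hb_mix - mpg1 * (m^2 - 8 * m + 16) - k$shift) /
    (8 * m - m^2)
  flags <- character()
  hbx <- NA_real_
  if (mpgx <= 0) {
    flags <- "non_physiological"
  } else {
    hbx <- hba1c_from_mpg(mpgx, model, "paper")
  }
  new_inversion_result(hbx, mpgx, hb_mix, m, flags)
}

new_inversion_result <- function(hbx, mpgx, hb_mix_input, m, flags) {
  structure(list(hbx = hbx, mpgx = mpgx, hb_mix_input = hb_mix_input,
                 m = m, flags = flags),
            class = "inversion_result")
}

#' @export
print.inversion_result <- function(x, ...) {
  cat(sprintf("Recovered new curve from Hb_mix = %.6g%% at m = %g months:\n",
              x$hb_mix_input, x$m))
  cat(sprintf("  Hbx  = %.6g %%\n", x$hbx))
  cat(sprintf("  MPGx = %.6g mg/dl\n", x$mpgx))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Fraction of the total HbA1c change completed by month m
#'
#' After a step change the measured HbA1c moves from \code{hb1} toward
#' \code{hbx} along the mixture curve; the completed fraction
#' \deqn{100 \cdot \frac{Hb_1 - Hb_{mix}(m)}{Hb_1 - Hb_x} = 100 \cdot \frac{8m - m^2}{16}}
#' is independent of the endpoints (they cancel). It rises steeply at first
#' — 43.75% in the first month — and decelerates, reaching 75% at two
#' months and 100% only at full erythrocyte turnover (4 months).
#'
#' @param m months since the change, in [0, 4]; vectorized.
#' @return Percent of the total change completed.
#' @examples
#' percent_change(1:4)   # 43.75  75.00  93.75 100.00
#' @export
percent_change <- function(m) {
  stopifnot(is.numeric(m))
  if (any(m < 0 | m > 4)) stop("'m' must lie in [0, 4] months", call. = FALSE)
  100 * (8 * m - m^2) / 16
}

#' Time course of measured HbA1c after a step change
#'
#' Evaluates the mixture formula on a grid of elapsed times, attaching the
#' percent-of-total-change at each point.
#'
#' @param hb1,hbx steady-state HbA1c (%) of the old and new curves.
#' @param grid months since the change; strictly within (0, 4].
#' @return An object of class \code{time_course}: a data frame with columns
#'   \code{m}, \code{hb_mix} and \code{percent_complete}.
#' @examples
#' tc <- time_course(hb1 = 12, hbx = 6.93)
#' tc[tc$m == 2, ]   # 8.19375%, 75% of the change done
#' @export
time_course <- function(hb1, hbx, grid = seq(0.1, 4, by = 0.1)) {
  if (length(grid) == 0L) stop("'grid' must be non-empty", call. = FALSE)
  if (any(grid <= 0 | grid > 4)) {
    stop("'grid' values must lie in (0, 4] months", call. = FALSE)
  }
  out <- data.frame(m = grid,
                    hb_mix = hb_mix_value(hb1, hbx, grid),
                    percent_complete = percent_change(grid))
  attr(out, "hb1") <- hb1
  attr(out, "hbx") <- hbx
  class(out) <- c("time_course", "data.frame")
  out
}

#' @export
plot.time_course <- function(x, ...) {
  plot(x$m, x$hb_mix, type = "l", lwd = 2,
       xlab = "months since change", ylab = "measured HbA1c (%)",
       main = "HbA1c time course after a step change", ...)
  graphics::abline(h = c(attr(x, "hb1"), attr(x, "hbx")), lty = 3)
  invisible(x)
}

#' Error of naive HbA1c-to-glucose conversion after a recent change
#'
#' An HbA1c measured within 4 months of a change in glycemic control mixes
#' old- and new-curve glycation; converting it directly with the DCCT
#' regression ("crude" conversion) therefore misestimates the true recent
#' glucose. The relative error is
#' \deqn{100 \cdot \left(1 - \frac{35.6\,Hb_{mix} - 77.3}{MPG_x}\right)}
#' with \eqn{MPG_x} recovered by \code{\link{invert_mpgx}}. Negative errors
#' mean the crude conversion overestimates glucose (control improved;
#' stale high-glycation cells inflate \code{hb_mix}); positive errors mean
#' underestimation.
#'
#' @param hb_mix measured HbA1c, percent.
#' @param mpg1 steady-state MPG before the change, mg/dl.
#' @param m months since the change, in (0, 4].
#' @param constant_mode \code{"paper"} or \code{"exact"}; see
#'   \code{\link{invert_mpgx}}.
#' @param model a \code{\link{conversion_model}} or model name.
#' @return Percent error (a length-1 numeric). When the recovered glucose
#'   is non-positive the value is \code{NA} with attribute
#'   \code{non_physiological = TRUE}.
#' @examples
#' estimation_error(hb_mix = 5, mpg1 = 208, m = 2)   # about -54.5%
#' @export
estimation_error <- function(hb_mix, mpg1, m,
                             constant_mode = c("paper", "exact"),
                             model = "DCCT") {
  constant_mode <- match.arg(constant_mode)
  model <- resolve_model(model)
  inv <- invert_mpgx(hb_mix, mpg1, m, constant_mode, model)
  if (is.na(inv$mpgx) || inv$mpgx <= 0) {
    return(structure(NA_real_, non_physiological = TRUE))
  }
  crude <- model$slope * hb_mix + model$intercept
  100 * (1 - crude / inv$mpgx)
}

#' Grid of naive-conversion errors over baseline glucose and measured HbA1c
#'
#' Tabulates \code{\link{estimation_error}} over a grid of pre-change MPG
#' values (columns) and measured HbA1c values (rows) at a fixed elapsed
#' time. Cells whose implied scenario leaves a plausibility envelope are
#' masked (reported but flagged, and written as blanks by
#' \code{\link{write_error_grid_csv}}): a cell is masked when the implied
#' new-curve HbA1c falls outside \code{hbx_bounds}, when the recovered
#' glucose is non-positive, or when the absolute error exceeds
#' \code{error_cap} percent. The default cap of 55% reproduces the blank
#' corners of the published 2-month error table, where extreme
#' measured-versus-baseline combinations are dropped as out of range.
#'
#' @param m months since the change, in (0, 4].
#' @param mpg1_values baseline MPG anchors, mg/dl (columns).
#' @param hbmix_values measured HbA1c anchors, percent (rows).
#' @param constant_mode \code{"paper"} or \code{"exact"}.
#' @param model a \code{\link{conversion_model}} or model name.
#' @param hbx_bounds plausibility bounds (%) on the implied new-curve HbA1c.
#' @param error_cap cells with |error| above this (percent) are masked;
#'   \code{Inf} disables the cap.
#' @return An object of class \code{error_grid}: list with \code{m},
#'   \code{mpg1_values}, \code{hbmix_values}, \code{cells} (matrix of
#'   percent errors, rows = hbmix), \code{mask} (logical matrix, TRUE =
#'   suppressed) and \code{implied_hbx}.
#' @examples
#' eg <- error_grid(m = 2)
#' eg$cells["9", "244"]   # 0: no change occurred, crude conversion is right
#' @export
error_grid <- function(m,
                       mpg1_values = c(101, 137, 172, 208, 244, 279, 315,
                                       350, 385, 420),
                       hbmix_values = 5:14,
                       constant_mode = c("paper", "exact"),
                       model = "DCCT",
                       hbx_bounds = c(0, 20),
                       error_cap = 55) {
  constant_mode <- match.arg(constant_mode)
  model <- resolve_model(model)
  if (length(mpg1_values) == 0L || length(hbmix_values) == 0L) {
    stop("grid anchors must be non-empty", call. = FALSE)
  }
  if (m <= 0 || m > 4) stop("'m' must lie in (0, 4] months", call. = FALSE)
  nr <- length(hbmix_values); nc <- length(mpg1_values)
  cells <- matrix(NA_real_, nr, nc,
                  dimnames = list(hbmix_values, mpg1_values))
  mask <- matrix(FALSE, nr, nc, dimnames = dimnames(cells))
  implied <- cells
  intercept_mode <- constant_mode   # paper constants pair with paper intercept
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      hb1 <- hba1c_from_mpg(mpg1_values[j], model, intercept_mode)
      hbx <- invert_hbx(hbmix_values[i], hb1, m, model, intercept_mode)$hbx
      err <- estimation_error(hbmix_values[i], mpg1_values[j], m,
                              constant_mode, model)
      implied[i, j] <- hbx
      cells[i, j] <- as.numeric(err)
      mask[i, j] <- isTRUE(attr(err, "non_physiological")) ||
        hbx < hbx_bounds[1] || hbx > hbx_bounds[2] ||
        (is.finite(cells[i, j]) && abs(cells[i, j]) > error_cap) ||
        is.na(cells[i, j])
    }
  }
  structure(list(m = m, mpg1_values = mpg1_values,
                 hbmix_values = hbmix_values, cells = cells, mask = mask,
                 implied_hbx = implied, constant_mode = constant_mode),
            class = "error_grid")
}

#' @export
print.error_grid <- function(x, digits = 2, ...) {
  cat(sprintf(
    "Crude-conversion error grid at m = %g months (%% of true MPG, %s constants)\n",
    x$m, x$constant_mode))
  shown <- round(x$cells, digits)
  disp <- matrix(ifelse(x$mask, "", format(shown)),
                 nrow(x$cells), dimnames = dimnames(x$cells))
  print(as.data.frame(disp), ...)
  cat("rows: measured HbA1c (%); columns: baseline MPG (mg/dl); blank = out of range\n")
  invisible(x)
}

#' @export
as.data.frame.error_grid <- function(x, ...) {
  df <- as.data.frame(ifelse(x$mask, NA_real_, x$cells))
  names(df) <- x$mpg1_values
  cbind(hbmix = x$hbmix_values, df)
}

#' Write an error grid to CSV with masked cells blank
#'
#' @param grid an \code{\link{error_grid}}.
#' @param path output file path.
#' @return The written data frame, invisibly.
#' @export
write_error_grid_csv <- function(grid, path) {
  df <- as.data.frame(grid)
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(df)
}
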