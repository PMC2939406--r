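#' Per-erythrocyte glycation curve at constant glucose
#'
#' Hemoglobin glycation is continuous, nonenzymatic and effectively
#' irreversible, and at constant mean plasma glucose (MPG) an erythrocyte
#' accumulates HbA1c linearly with age: a cell of age \eqn{m} months on the
#' curve with steady-state cohort mean \eqn{H} carries \eqn{H \cdot m / 2}
#' percent HbA1c. At the full 120-day (4-month) lifespan it carries twice
#' the steady-state population mean, so a uniformly age-distributed
#' population averages exactly \eqn{H}.
#'
#' Either \code{mpg} or \code{steady_hba1c} must be given; the missing twin
#' is filled in through the conversion model (forward map for
#' steady-to-MPG, inverse map under \code{intercept_mode} for
#' MPG-to-steady).
#'
#' @param mpg constant plasma glucose of the curve, mg/dl.
#' @param steady_hba1c steady-state cohort-mean HbA1c sustained by the
#'   curve, percent.
#' @param model a \code{\link{conversion_model}} or model name.
#' @param intercept_mode inverse-map intercept convention, see
#'   \code{\link{hba1c_from_mpg}}.
#' @return An object of class \code{glycation_curve} with fields \code{mpg}
#'   and \code{steady_hba1c}.
#' @examples
#' cv <- glycation_curve(mpg = 137)
#' curve_value(cv, m = 4)     # ~12%: a 120-day-old cell on the MPG=137 curve
#' cohort_mean_steady(cv)     # ~6%: the population mean that curve sustains
#' @export
glycation_curve <- function(mpg = NULL, steady_hba1c = NULL, model = "DCCT",
                            intercept_mode = c("paper", "exact")) {
  intercept_mode <- match.arg(intercept_mode)
  model <- resolve_model(model)
  if (is.null(mpg) && is.null(steady_hba1c)) {
    stop("supply 'mpg' or 'steady_hba1c'", call. = FALSE)
  }
  if (is.null(steady_hba1c)) {
    if (mpg <= 0) stop("'mpg' must be strictly positive", call. = FALSE)
    steady_hba1c <- hba1c_from_mpg(mpg, model, intercept_mode)
  } else if (is.null(mpg)) {
    if (steady_hba1c <= 0) {
      stop("'steady_hba1c' must be strictly positive", call. = FALSE)
    }
    mpg <- mpg_from_hba1c(steady_hba1c, model)
  }
  structure(list(mpg = mpg, steady_hba1c = steady_hba1c,
                 model = model$name, intercept_mode = intercept_mode),
            class = "glycation_curve")
}

#' @export
print.glycation_curve <- function(x, ...) {
  cat(sprintf(
    "Glycation curve: MPG = %.6g mg/dl, steady-state HbA1c = %.6g%% (%s, %s intercept)\n",
    x$mpg, x$steady_hba1c, x$model, x$intercept_mode))
  invisible(x)
}

#' Accumulated HbA1c of a single erythrocyte of given age
#'
#' Evaluates the glycation curve at age \code{m} months: a cell that has
#' lived \code{m} months at the curve's glucose level carries
#' \code{steady_hba1c * m / 2} percent HbA1c. Age must lie within the
#' 120-day lifespan, i.e. \code{0 <= m <= 4}.
#'
#' @param curve a \code{\link{glycation_curve}}.
#' @param m age in months (30-day months); vectorized.
#' @return Accumulated HbA1c in percent.
#' @export
curve_value <- function(curve, m) {
  stopifnot(inherits(curve, "glycation_curve"), is.numeric(m))
  if (any(m < 0 | m > 4)) {
    stop("age 'm' must lie in [0, 4] months (erythrocytes do not exceed their 120-day lifespan)",
         call. = FALSE)
  }
  curve$steady_hba1c * m / 2
}

#' Steady-state population mean of a glycation curve
#'
#' With uniform ages (1/120 of cells per day of age) and linear
#' accumulation, the population mean is the arithmetic mean of the youngest
#' (0%) and oldest (4-month) cells, which is the curve's steady-state
#' HbA1c by construction.
#'
#' @param curve a \code{\link{glycation_curve}}.
#' @return Steady-state mean HbA1c in percent.
#' @export
cohort_mean_steady <- function(curve) {
  (curve_value(curve, 0) + curve_value(curve, 4)) / 2
}

#' A step-change scenario: old curve, new curve, elapsed time
#'
#' Describes one episode in which a patient's glycemic control changes
#' abruptly from a steady state sustaining HbA1c \code{hb1} (the old curve)
#' to a new level sustaining \code{hbx}, with an HbA1c measurement taken
#' \code{m} months later (\code{0 < m <= 4}, within one erythrocyte
#' lifespan). Endpoints may be given in MPG space (\code{mpg1},
#' \code{mpgx}, mg/dl) instead; they are converted to HbA1c space once at
#' construction under the given model and intercept mode, and all kinetics
#' then run in HbA1c space.
#'
#' @param hb1,hbx steady-state HbA1c (%) of the old and new curves.
#' @param m months elapsed since the change, in (0, 4].
#' @param mpg1,mpgx MPG-space alternatives to \code{hb1}/\code{hbx}, mg/dl.
#' @param model a \code{\link{conversion_model}} or model name.
#' @param intercept_mode see \code{\link{hba1c_from_mpg}}.
#' @return An object of class \code{mixture_scenario}.
#' @examples
#' sc <- mixture_scenario(hb1 = 9, hbx = 6, m = 1)
#' hb_mix(sc)      # 7.6875
#' phi_upper(sc)   # 13.5
#' @export
mixture_scenario <- function(hb1 = NULL, hbx = NULL, m,
                             mpg1 = NULL, mpgx = NULL, model = "DCCT",
                             intercept_mode = c("paper", "exact")) {
  intercept_mode <- match.arg(intercept_mode)
  model <- resolve_model(model)
  stopifnot(is.numeric(m), length(m) == 1L)
  if (m <= 0 || m > 4) stop("'m' must lie in (0, 4] months", call. = FALSE)
  if ((!is.null(hb1) && hb1 <= 0) || (!is.null(hbx) && hbx <= 0)) {
    stop("'hb1' and 'hbx' must be strictly positive", call. = FALSE)
  }
  if (is.null(hb1)) {
    if (is.null(mpg1)) stop("supply 'hb1' or 'mpg1'", call. = FALSE)
    hb1 <- hba1c_from_mpg(mpg1, model, intercept_mode)
  } else if (is.null(mpg1)) {
    mpg1 <- mpg_from_hba1c(hb1, model)
  }
  if (is.null(hbx)) {
    if (is.null(mpgx)) stop("supply 'hbx' or 'mpgx'", call. = FALSE)
    hbx <- hba1c_from_mpg(mpgx, model, intercept_mode)
  } else if (is.null(mpgx)) {
    mpgx <- mpg_from_hba1c(hbx, model)
  }
  if (hb1 <= 0 || hbx <= 0) {
    stop("'hb1' and 'hbx' must be strictly positive", call. = FALSE)
  }
  structure(list(hb1 = hb1, hbx = hbx, m = m, mpg1 = mpg1, mpgx = mpgx,
                 model = model$name, intercept_mode = intercept_mode),
            class = "mixture_scenario")
}

#' @export
print.mixture_scenario <- function(x, ...) {
  cat(sprintf("Step-change scenario: Hb1 = %.6g%% -> Hbx = %.6g%%, m = %g months\n",
              x$hb1, x$hbx, x$m))
  cat(sprintf("  MPG twins (%s): %.6g -> %.6g mg/dl; predicted Hb_mix = %.6g%%\n",
              x$model, x$mpg1, x$mpgx, hb_mix(x)))
  invisible(x)
}

#' Cohort statistics of the surviving and newborn erythrocyte groups
#'
#' After \code{m} months on the new curve, cells older than \code{4 - m}
#' months at the change have died. These functions give the intermediate
#' cohort statistics of the mixture construction:
#' \describe{
#'   \item{\code{phi_upper}}{\code{hb1 * (4 - m) / 2}, the HbA1c of the
#'     oldest surviving old-curve cell (old-curve glycation only);}
#'   \item{\code{phi_mean}}{\code{hb1 * (4 - m) / 4}, the surviving group's
#'     mean old-curve glycation (half the upper limit, by linearity);}
#'   \item{\code{delta_phi_mean}}{\code{hbx * m / 2}, the glycation those
#'     survivors accrued on the new curve since the change;}
#'   \item{\code{phi1}}{\code{phi_mean + delta_phi_mean}, the survivors'
#'     total mean HbA1c;}
#'   \item{\code{phi2}}{\code{hbx * m / 4}, the mean HbA1c of cells born
#'     after the change.}
#' }
#'
#' @param scenario a \code{\link{mixture_scenario}}.
#' @return HbA1c in percent.
#' @name phi_statistics
NULL

#' @rdname phi_statistics
#' @export
phi_upper <- function(scenario) {
  stopifnot(inherits(scenario, "mixture_scenario"))
  scenario$hb1 * (4 - scenario$m) / 2
}

#' @rdname phi_statistics
#' @export
phi_mean <- function(scenario) phi_upper(scenario) / 2

#' @rdname phi_statistics
#' @export
delta_phi_mean <- function(scenario) {
  stopifnot(inherits(scenario, "mixture_scenario"))
  scenario$hbx * scenario$m / 2
}

#' @rdname phi_statistics
#' @export
phi1 <- function(scenario) phi_mean(scenario) + delta_phi_mean(scenario)

#' @rdname phi_statistics
#' @export
phi2 <- function(scenario) {
  stopifnot(inherits(scenario, "mixture_scenario"))
  scenario$hbx * scenario$m / 4
}

#' Measured HbA1c after a step change: the two-curve mixture
#'
#' The laboratory HbA1c measured \code{m} months after a step change is the
#' mass-weighted average of the surviving old-curve group (weight
#' \code{(4 - m)/4}) and the newborn group (weight \code{m/4}):
#' \deqn{Hb_{mix} = \frac{Hb_x (8m - m^2) + Hb_1 (m^2 - 8m + 16)}{16}.}
#' This HbA1c-space form is canonical: it involves no glucose conversion at
#' all. The MPG-space form
#' \eqn{[MPG_x (8m - m^2) + MPG_1 (m^2 - 8m + 16) + 1236]/570}
#' (\code{space = "mpg"}) derives from it through the DCCT map; with
#' \code{constant_mode = "paper"} the conventional rounded constants 570 and
#' 1236 are used, with \code{"exact"} the unrounded \eqn{16 \times 35.6}
#' and \eqn{16 \times 77.3}.
#'
#' @param scenario a \code{\link{mixture_scenario}}.
#' @param space evaluate in HbA1c space (canonical) or MPG space.
#' @param constant_mode MPG-space constants, \code{"paper"} or \code{"exact"}.
#' @return Predicted measured HbA1c, percent.
#' @examples
#' hb_mix(mixture_scenario(hb1 = 9, hbx = 6, m = 1))   # 7.6875
#' @export
hb_mix <- function(scenario, space = c("hb", "mpg"),
                   constant_mode = c("paper", "exact")) {
  stopifnot(inherits(scenario, "mixture_scenario"))
  space <- match.arg(space)
  constant_mode <- match.arg(constant_mode)
  if (space == "hb") {
    hb_mix_value(scenario$hb1, scenario$hbx, scenario$m)
  } else {
    k <- mixture_constants(constant_mode)
    m <- scenario$m
    (scenario$mpgx * (8 * m - m^2) +
       scenario$mpg1 * (m^2 - 8 * m + 16) + k$shift) / k$scale
  }
}

# MPG-space mixture constants: scale = 16 * slope, shift = scale * inverse
# intercept. The paper-convention values 570/1236 reproduce published
# tables; exact values keep MPG space consistent with HbA1c space.
mixture_constants <- function(constant_mode = c("paper", "exact")) {
  constant_mode <- match.arg(constant_mode)
  if (constant_mode == "paper") list(scale = 570, shift = 1236)
  else list(scale = 16 * 35.6, shift = 16 * 77.3)
}

#' Vectorized two-curve mixture formula
#'
#' Raw HbA1c-space mixture evaluation without a scenario object, vectorized
#' over all three arguments; the workhorse behind \code{\link{hb_mix}},
#' \code{\link{time_course}} and \code{\link{invert_hbx}}.
#'
#' @param hb1,hbx steady-state HbA1c (%) of the old and new curves.
#' @param m months since the change, in (0, 4].
#' @return Mixed HbA1c in percent.
#' @export
hb_mix_value <- function(hb1, hbx, m) {
  if (any(m <= 0 | m > 4)) stop("'m' must lie in (0, 4] months", call. = FALSE)
  (hbx * (8 * m - m^2) + hb1 * (m^2 - 8 * m + 16)) / 16
}
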