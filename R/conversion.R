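#' Conversion models between HbA1c and mean plasma glucose
#'
#' Constructs a conversion model linking glycated hemoglobin (HbA1c, %) to
#' mean plasma glucose (MPG, mg/dl). Two models are built in:
#' \describe{
#'   \item{\code{"DCCT"}}{the linear regression from the Diabetes Control and
#'     Complications Trial seven-point glucose profiles,
#'     \eqn{MPG = 35.6 \times HbA1c - 77.3} (mg/dl), together with its
#'     tabulated reference anchors;}
#'   \item{\code{"ADAG"}}{the A1c-Derived Average Glucose study anchors.
#'     No closed-form regression is carried for ADAG; conversions use the
#'     tabulated anchors with linear interpolation between them.}
#' }
#'
#' The DCCT inverse mapping \eqn{HbA1c = MPG/35.6 + 2.17} is available in two
#' intercept conventions (see \code{\link{hba1c_from_mpg}}): the conventional
#' printed intercept 2.17 (\code{"paper"}), and the algebraically exact
#' \eqn{77.3/35.6 = 2.1713...} (\code{"exact"}) under which forward and
#' inverse maps compose to the identity.
#'
#' @param name model name, \code{"DCCT"} or \code{"ADAG"}.
#' @return An object of class \code{conversion_model}: a list with elements
#'   \code{name}, \code{slope} (mg/dl per \% HbA1c; \code{NA} for tabulated
#'   models), \code{intercept} (mg/dl), \code{inverse_intercept_paper}
#'   (\% HbA1c, the printed inverse intercept), and \code{reference_rows},
#'   a data frame of tabulated anchors with columns \code{hba1c},
#'   \code{mpg_mmol_l} and \code{mpg_mg_dl}.
#' @examples
#' dcct <- conversion_model("DCCT")
#' mpg_from_hba1c(9, dcct)
#' reference_table("ADAG")
#' @export
conversion_model <- function(name = c("DCCT", "ADAG")) {
  name <- match.arg(name)
  if (name == "DCCT") {
    model <- list(
      name = "DCCT",
      slope = 35.6,
      intercept = -77.3,
      inverse_intercept_paper = 2.17,
      reference_rows = data.frame(
        hba1c      = 5:12,
        mpg_mmol_l = c(5.6, 7.6, 9.6, 11.5, 13.5, 15.5, 17.5, 19.5),
        mpg_mg_dl  = c(101, 137, 172, 208, 244, 279, 315, 350)
      )
    )
  } else {
    model <- list(
      name = "ADAG",
      slope = NA_real_,
      intercept = NA_real_,
      inverse_intercept_paper = NA_real_,
      reference_rows = data.frame(
        hba1c      = 5:12,
        mpg_mmol_l = c(5.4, 7.0, 8.6, 10.2, 11.8, 13.4, 14.9, 16.5),
        mpg_mg_dl  = c(97, 126, 154, 183, 212, 240, 269, 298)
      )
    )
  }
  structure(model, class = "conversion_model")
}

#' @export
print.conversion_model <- function(x, ...) {
  cat("Conversion model:", x$name, "\n")
  if (is.finite(x$slope)) {
    cat(sprintf("  MPG (mg/dl) = %.1f x HbA1c %+.1f\n", x$slope, x$intercept))
  } else {
    cat("  tabulated anchors only (linear interpolation between rows)\n")
  }
  cat(sprintf("  %d reference rows, HbA1c %g-%g%%\n",
              nrow(x$reference_rows),
              min(x$reference_rows$hba1c), max(x$reference_rows$hba1c)))
  invisible(x)
}

# Accept either a model object or its name.
resolve_model <- function(model) {
  if (inherits(model, "conversion_model")) return(model)
  if (is.character(model) && length(model) == 1L) return(conversion_model(model))
  stop("'model' must be a conversion_model object or a model name", call. = FALSE)
}

# mmol/l to mg/dl factor for glucose; anchors are stored verbatim, this
# constant is only used when callers ask for unit conversion of new values.
MMOL_TO_MGDL <- 18.016

#' Convert HbA1c to mean plasma glucose
#'
#' For a linear model (DCCT) evaluates \code{slope * hba1c + intercept}
#' without any rounding. For a tabulated model (ADAG) interpolates linearly
#' between the reference anchors.
#'
#' @param hba1c HbA1c in percent; vectorized.
#' @param model a \code{\link{conversion_model}} or model name.
#' @return MPG in mg/dl.
#' @examples
#' mpg_from_hba1c(12)            # 349.9, the value clinically rounded to 350
#' mpg_from_hba1c(9, "ADAG")     # tabulated anchor, 212
#' @export
mpg_from_hba1c <- function(hba1c, model = "DCCT") {
  model <- resolve_model(model)
  stopifnot(is.numeric(hba1c))
  if (is.finite(model$slope)) {
    mpg <- model$slope * hba1c + model$intercept
    if (any(mpg < 0)) {
      stop(sprintf(
        "HbA1c below the minimum representable value for %s (%.4f%%): mapped MPG would be negative",
        model$name, -model$intercept / model$slope), call. = FALSE)
    }
    mpg
  } else {
    interp_anchor(hba1c, model$reference_rows$hba1c,
                  model$reference_rows$mpg_mg_dl, model$name)
  }
}

#' Convert mean plasma glucose to HbA1c
#'
#' Inverse of \code{\link{mpg_from_hba1c}}. For DCCT the mapping is
#' \eqn{HbA1c = MPG/35.6 + c}: with \code{intercept_mode = "paper"} the
#' conventional printed intercept \eqn{c = 2.17} is used (the package
#' default, reproducing published tables); with \code{"exact"},
#' \eqn{c = 77.3/35.6}, making the conversion the exact algebraic inverse
#' of the forward map. For ADAG, inverse linear interpolation between the
#' tabulated anchors.
#'
#' @param mpg MPG in mg/dl, strictly positive; vectorized.
#' @param model a \code{\link{conversion_model}} or model name.
#' @param intercept_mode \code{"paper"} or \code{"exact"} (linear models only).
#' @return HbA1c in percent.
#' @examples
#' hba1c_from_mpg(137)                           # 6.018..., about 6%
#' hba1c_from_mpg(mpg_from_hba1c(9), intercept_mode = "exact")  # exactly 9
#' @export
hba1c_from_mpg <- function(mpg, model = "DCCT",
                           intercept_mode = c("paper", "exact")) {
  model <- resolve_model(model)
  intercept_mode <- match.arg(intercept_mode)
  stopifnot(is.numeric(mpg))
  if (any(mpg <= 0)) stop("'mpg' must be strictly positive", call. = FALSE)
  if (is.finite(model$slope)) {
    cc <- if (intercept_mode == "paper") model$inverse_intercept_paper
          else -model$intercept / model$slope
    mpg / model$slope + cc
  } else {
    interp_anchor(mpg, model$reference_rows$mpg_mg_dl,
                  model$reference_rows$hba1c, model$name)
  }
}

interp_anchor <- function(x, from, to, model_name) {
  if (any(x < min(from)) || any(x > max(from))) {
    stop(sprintf("query outside the tabulated %s range [%g, %g]",
                 model_name, min(from), max(from)), call. = FALSE)
  }
  stats::approx(from, to, xout = x, method = "linear", ties = "ordered")$y
}

#' Tabulated reference anchors for a conversion model
#'
#' Returns the model's reference rows verbatim, or, when \code{hba1c} is
#' supplied, the mg/dl anchor at those HbA1c levels. Queries off the anchor
#' grid are linearly interpolated when \code{interpolate = TRUE}, and must
#' lie within the tabulated HbA1c range.
#'
#' @param model a \code{\link{conversion_model}} or model name.
#' @param hba1c optional HbA1c query values in percent.
#' @param interpolate allow off-anchor queries by linear interpolation.
#' @return A data frame of anchors, or a numeric vector of mg/dl values when
#'   \code{hba1c} is given.
#' @examples
#' reference_table("DCCT")
#' reference_table("DCCT", hba1c = 9)                       # 244
#' reference_table("ADAG", hba1c = 9.5, interpolate = TRUE) # 226
#' @export
reference_table <- function(model = "DCCT", hba1c = NULL, interpolate = FALSE) {
  model <- resolve_model(model)
  rows <- model$reference_rows
  if (is.null(hba1c)) return(rows)
  if (any(hba1c < min(rows$hba1c)) || any(hba1c > max(rows$hba1c))) {
    stop(sprintf("query outside the tabulated range [%g%%, %g%%]",
                 min(rows$hba1c), max(rows$hba1c)), call. = FALSE)
  }
  if (interpolate) {
    interp_anchor(hba1c, rows$hba1c, rows$mpg_mg_dl, model$name)
  } else {
    idx <- match(hba1c, rows$hba1c)
    if (anyNA(idx)) {
      stop("HbA1c value is not a tabulated anchor; use interpolate = TRUE",
           call. = FALSE)
    }
    rows$mpg_mg_dl[idx]
  }
}

#' Write reference tables to CSV
#'
#' Writes the tabulated anchors of one or more conversion models to a single
#' CSV file with columns \code{hba1c_percent}, \code{mpg_mmol_l},
#' \code{mpg_mg_dl} and \code{model}.
#'
#' @param path output file path.
#' @param models character vector of model names, or list of models.
#' @return The written data frame, invisibly.
#' @export
write_reference_csv <- function(path, models = c("DCCT", "ADAG")) {
  out <- do.call(rbind, lapply(models, function(m) {
    m <- resolve_model(m)
    data.frame(hba1c_percent = m$reference_rows$hba1c,
               mpg_mmol_l = m$reference_rows$mpg_mmol_l,
               mpg_mg_dl = m$reference_rows$mpg_mg_dl,
               model = m$name)
  }))
  utils::write.csv(out, path, row.names = FALSE)
  invisible(out)
}

#' Round half away from zero
#'
#' Clinical tables conventionally round .5 away from zero rather than to the
#' nearest even digit (the IEC default of \code{round}). Raw package
#' operations never round; this helper is for table-style display only.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return Rounded numeric vector.
#' @examples
#' round_half_out(43.75)   # 44
#' round_half_out(-0.5)    # -1
#' @export
round_half_out <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
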