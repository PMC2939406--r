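#' Discrete age-structured erythrocyte cohort simulator
#'
#' The simulator tracks 120 daily age cohorts of equal mass (birth rate
#' equals death rate, so 1/120 of the red-cell mass is one day old, 1/120
#' two days old, and so on). Each cohort carries its accumulated HbA1c.
#' Every simulated day all surviving cohorts gain that day's glycation
#' increment, the 120-day-old cohort dies, and a fresh cohort is born.
#' Glycation is irreversible: a cohort's HbA1c never decreases.
#'
#' The daily increment at plasma glucose \code{mpg} is the steady-state
#' HbA1c that glucose sustains divided by 60 (half the lifespan in days),
#' so a cell living its full 120 days at constant glucose ends at twice the
#' steady-state population mean. Cohorts are evaluated at mid-day ages
#' (age + 0.5 days): with this convention the discrete steady-state
#' population mean equals the continuous arithmetic-mean result exactly,
#' rather than with a bias of order 1/120.
#'
#' The model is fully deterministic; there is no randomness to seed.
#'
#' @param mpg constant plasma glucose, mg/dl.
#' @param steady_hba1c alternative to \code{mpg}: the steady-state HbA1c
#'   (%) the glucose sustains, specified directly (bypasses conversion).
#' @param model a \code{\link{conversion_model}} or model name.
#' @param intercept_mode see \code{\link{hba1c_from_mpg}}.
#' @return \code{init_steady_state} returns an object of class
#'   \code{cohort_population}: list with \code{cohort_hba1c} (numeric of
#'   length 120, youngest to oldest) and \code{day} (simulation-day
#'   counter).
#' @examples
#' pop <- init_steady_state(mpg = 137)
#' mean_hba1c(pop)   # equals hba1c_from_mpg(137) exactly
#' @export
init_steady_state <- function(mpg = NULL, steady_hba1c = NULL,
                              model = "DCCT",
                              intercept_mode = c("paper", "exact")) {
  intercept_mode <- match.arg(intercept_mode)
  r <- daily_glycation_rate(mpg, steady_hba1c, model, intercept_mode)
  ages <- seq_len(RBC_LIFESPAN_DAYS) - 0.5   # mid-day ages, youngest first
  structure(list(cohort_hba1c = ages * r, day = 0L),
            class = "cohort_population")
}

RBC_LIFESPAN_DAYS <- 120L
DAYS_PER_MONTH <- 30L

# Daily HbA1c increment (% per day) at a given glucose or steady level.
daily_glycation_rate <- function(mpg = NULL, steady_hba1c = NULL,
                                 model = "DCCT",
                                 intercept_mode = c("paper", "exact")) {
  intercept_mode <- match.arg(intercept_mode)
  if (is.null(steady_hba1c)) {
    if (is.null(mpg)) stop("supply 'mpg' or 'steady_hba1c'", call. = FALSE)
    if (mpg <= 0) stop("'mpg' must be strictly positive", call. = FALSE)
    steady_hba1c <- hba1c_from_mpg(mpg, model, intercept_mode)
  }
  steady_hba1c / (RBC_LIFESPAN_DAYS / 2)
}

#' @export
print.cohort_population <- function(x, ...) {
  cat(sprintf(
    "Erythrocyte cohort population: %d daily cohorts, day %d, mean HbA1c %.4f%%\n",
    length(x$cohort_hba1c), x$day, mean_hba1c(x)))
  invisible(x)
}

#' Advance the cohort population by one day
#'
#' Applies one day of glycation at today's plasma glucose: every surviving
#' cohort gains the daily increment, the oldest cohort is removed, and a
#' newborn cohort enters with half an increment (mid-day convention).
#' The cohort count is conserved at 120.
#'
#' @param pop a \code{cohort_population}.
#' @param mpg today's plasma glucose, mg/dl.
#' @param steady_hba1c alternative forcing: today's glucose given as the
#'   steady-state HbA1c it sustains.
#' @param model,intercept_mode conversion used when forcing is in mg/dl.
#' @return The advanced \code{cohort_population}.
#' @examples
#' pop <- init_steady_state(mpg = 137)
#' pop <- cohort_step(pop, mpg = 137)   # steady state is a fixed point
#' @export
cohort_step <- function(pop, mpg = NULL, steady_hba1c = NULL,
                        model = "DCCT",
                        intercept_mode = c("paper", "exact")) {
  stopifnot(inherits(pop, "cohort_population"))
  r <- daily_glycation_rate(mpg, steady_hba1c, model, intercept_mode)
  n <- length(pop$cohort_hba1c)
  pop$cohort_hba1c <- c(0.5 * r,
                        pop$cohort_hba1c[-n] + r)  # oldest cohort dies
  pop$day <- pop$day + 1L
  pop
}

#' Population-mean HbA1c
#'
#' The measured HbA1c of the whole population: the unweighted mean over the
#' 120 equal-mass cohorts.
#'
#' @param pop a \code{cohort_population}.
#' @return Mean HbA1c in percent.
#' @export
mean_hba1c <- function(pop) {
  stopifnot(inherits(pop, "cohort_population"))
  mean(pop$cohort_hba1c)
}

#' Simulate the population mean under a daily glucose trajectory
#'
#' Runs the cohort simulator day by day under an arbitrary daily plasma
#' glucose trajectory, starting from the steady state of \code{init_mpg}
#' (or \code{init_steady_hba1c}), and records the population-mean HbA1c
#' after each day. This is the brute-force generalization of the two-curve
#' closed forms to any glycemic history, and the numerical oracle against
#' which they are verified.
#'
#' @param trajectory daily plasma glucose, mg/dl: a numeric vector (one
#'   value per day) or a data frame with columns \code{day} and
#'   \code{mpg_mg_dl} (as read by \code{\link{read_mpg_trajectory}}).
#' @param init_mpg glucose (mg/dl) defining the initial steady state.
#' @param init_steady_hba1c alternative initial state in HbA1c space.
#' @param model,intercept_mode conversion used for mg/dl forcing.
#' @return A data frame with columns \code{day} (1-based) and
#'   \code{mean_hba1c} (%).
#' @examples
#' # step change from the 244 mg/dl curve to the 137 mg/dl curve
#' sim <- simulate_cohort(rep(137, 120), init_mpg = 244)
#' sim[sim$day == 30, ]
#' @export
simulate_cohort <- function(trajectory, init_mpg = NULL,
                            init_steady_hba1c = NULL, model = "DCCT",
                            intercept_mode = c("paper", "exact")) {
  intercept_mode <- match.arg(intercept_mode)
  if (is.data.frame(trajectory)) {
    if (!all(c("day", "mpg_mg_dl") %in% names(trajectory))) {
      stop("trajectory data frame needs columns 'day' and 'mpg_mg_dl'",
           call. = FALSE)
    }
    trajectory <- trajectory$mpg_mg_dl[order(trajectory$day)]
  }
  if (length(trajectory) == 0L) {
    stop("'trajectory' must be non-empty", call. = FALSE)
  }
  if (any(trajectory <= 0)) {
    stop("trajectory glucose values must be strictly positive", call. = FALSE)
  }
  pop <- init_steady_state(init_mpg, init_steady_hba1c, model, intercept_mode)
  means <- numeric(length(trajectory))
  for (d in seq_along(trajectory)) {
    pop <- cohort_step(pop, mpg = trajectory[d], model = model,
                       intercept_mode = intercept_mode)
    means[d] <- mean_hba1c(pop)
  }
  data.frame(day = seq_along(trajectory), mean_hba1c = means)
}

#' Read and write daily glucose trajectories as CSV
#'
#' Trajectory files have columns \code{day} and \code{mpg_mg_dl}, one row
#' per simulated day. \code{write_mpg_trajectory} accepts a bare numeric
#' vector (days are numbered from 1) or a data frame in the same layout.
#'
#' @param path CSV file path.
#' @return \code{read_mpg_trajectory}: a data frame with columns
#'   \code{day}, \code{mpg_mg_dl}, ordered by day.
#' @export
read_mpg_trajectory <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("day", "mpg_mg_dl") %in% names(df))) {
    stop("trajectory CSV needs columns 'day' and 'mpg_mg_dl'", call. = FALSE)
  }
  df <- df[order(df$day), c("day", "mpg_mg_dl")]
  if (any(df$mpg_mg_dl <= 0)) {
    stop("trajectory glucose values must be strictly positive", call. = FALSE)
  }
  df
}

#' @rdname read_mpg_trajectory
#' @param trajectory numeric vector of daily mg/dl values, or a data frame
#'   with columns \code{day} and \code{mpg_mg_dl}.
#' @export
write_mpg_trajectory <- function(trajectory, path) {
  if (!is.data.frame(trajectory)) {
    trajectory <- data.frame(day = seq_along(trajectory),
                             mpg_mg_dl = as.numeric(trajectory))
  }
  out <- data.frame(day = trajectory$day,
                    # full precision so a re-read parses bit-identically
                    mpg_mg_dl = sprintf("%.17g", trajectory$mpg_mg_dl))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(trajectory)
}
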