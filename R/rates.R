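# ---- specific-rate estimation from culture time courses --------------------
#
# Under exponential growth, dX/dt = mu X, d[glucose]/dt = -nu X and
# d[acetate]/dt = rho X, so concentrations are linear in the
# time-integrated biomass (g-DCW l^-1 h): the specific rates nu and rho
# are the slopes of the regression of concentration against the
# integrated biomass, and mu is the slope of ln X against time.

#' Build a culture time course
#'
#' @param time_h Strictly increasing sampling times (h).
#' @param biomass Biomass X (g-DCW l^-1), or OD600 together with
#'   `od_to_dcw` (g-DCW l^-1 per OD unit).
#' @param ... One numeric vector per analyte (mmol l^-1), e.g.
#'   `glucose =`, `acetate =`.
#' @param od_to_dcw Optional OD600 to DCW conversion factor; required
#'   when biomass is supplied as OD.
#' @return A `time_course` data.frame.
#' @export
time_course <- function(time_h, biomass, ..., od_to_dcw = NULL) {
  if (any(diff(time_h) <= 0)) stop("time points must be strictly increasing")
  if (any(biomass < 0)) stop("biomass must be >= 0")
  if (!is.null(od_to_dcw)) biomass <- biomass * od_to_dcw
  d <- data.frame(time_h = time_h, biomass = biomass, ...)
  class(d) <- c("time_course", "data.frame")
  d
}

#' Read a time-course CSV (`time_h`, `biomass`, one column per analyte)
#'
#' @inheritParams time_course
#' @param path File path.
#' @return A `time_course`.
#' @export
read_time_course <- function(path, od_to_dcw = NULL) {
  d <- utils::read.csv(path)
  if (!all(c("time_h", "biomass") %in% names(d)))
    stop("time-course file needs columns time_h and biomass")
  do.call(time_course, c(list(time_h = d$time_h, biomass = d$biomass,
                              od_to_dcw = od_to_dcw),
                         d[setdiff(names(d), c("time_h", "biomass"))]))
}

#' Cumulative integrated biomass
#'
#' Trapezoidal integral of X over time; first value 0; units
#' g-DCW l^-1 h.
#'
#' @param tc A `time_course` (or data.frame with `time_h` and `biomass`).
#' @return Numeric vector, same length as the time course.
#' @export
integrated_biomass <- function(tc) {
  if (nrow(tc) < 2L) stop("need at least two time points")
  if (any(diff(tc$time_h) <= 0)) stop("time points must be strictly increasing")
  unname(drop(pracma::cumtrapz(tc$time_h, tc$biomass)))
}

#' Specific consumption or production rate
#'
#' Ordinary least-squares slope of analyte concentration against the
#' integrated biomass. For `sign = "consumption"` the negated slope is
#' returned, so that a falling glucose curve yields a positive uptake
#' rate nu.
#'
#' @param integ Integrated biomass series ([integrated_biomass()]).
#' @param conc Analyte concentrations (mmol l^-1), same length >= 3.
#' @param sign `"consumption"` or `"production"`.
#' @return List: `rate` (mmol g-DCW^-1 h^-1), `se`, `r_squared`, `n`,
#'   `sign`.
#' @export
fit_specific_rate <- function(integ, conc, sign = c("production", "consumption")) {
  sign <- match.arg(sign)
  stopifnot(length(integ) == length(conc), length(integ) >= 3L)
  if (stats::var(integ) == 0) stop("integrated biomass has zero variance")
  fit <- stats::lm(conc ~ integ)
  # noiseless series fit exactly; the perfect-fit warning is expected there
  sm <- suppressWarnings(summary(fit))
  sl <- sm$coefficients["integ", ]
  rate <- unname(if (sign == "consumption") -sl["Estimate"] else sl["Estimate"])
  list(rate = rate, se = unname(sl["Std. Error"]),
       r_squared = sm$r.squared, n = length(conc), sign = sign)
}

#' Specific growth rate from log-linear regression
#'
#' Slope of ln X against time within an explicit exponential-phase
#' window (default: all points). No automatic phase detection is done;
#' the window is the analyst's choice.
#'
#' @param tc A `time_course`.
#' @param window Length-2 numeric: time interval (h) to fit in.
#' @return List: `mu` (h^-1), `se`, `n`, `window`.
#' @export
growth_rate <- function(tc, window = range(tc$time_h)) {
  keep <- tc$time_h >= window[1] & tc$time_h <= window[2]
  t <- tc$time_h[keep]; X <- tc$biomass[keep]
  if (length(t) < 3L) stop("need at least three points in the window")
  if (any(X <= 0)) stop("nonpositive biomass in the fitting window")
  fit <- stats::lm(log(X) ~ t)
  sl <- suppressWarnings(summary(fit))$coefficients["t", ]
  list(mu = unname(sl["Estimate"]), se = unname(sl["Std. Error"]),
       n = length(t), window = window)
}

#' Estimate all specific rates of a culture
#'
#' Convenience wrapper: growth rate plus one regression per analyte
#' column of the time course.
#'
#' @param tc A `time_course`.
#' @param consumed Character vector of analyte columns that are consumed
#'   (reported as positive uptake rates); all other analyte columns are
#'   treated as products.
#' @param window Growth-rate fitting window.
#' @return A `specific_rates` list: `mu`, `mu_se`, and per-analyte
#'   `rate`/`se` entries.
#' @export
specific_rates <- function(tc, consumed = "glucose",
                           window = range(tc$time_h)) {
  integ <- integrated_biomass(tc)
  analytes <- setdiff(names(tc), c("time_h", "biomass"))
  gr <- growth_rate(tc, window)
  rates <- lapply(stats::setNames(analytes, analytes), function(a)
    fit_specific_rate(integ, tc[[a]],
                      if (a %in% consumed) "consumption" else "production"))
  structure(list(mu = gr$mu, mu_se = gr$se, analytes = rates),
            class = "specific_rates")
}

#' @export
print.specific_rates <- function(x, ...) {
  cat(sprintf("mu = %.4f +/- %.4f h^-1\n", x$mu, x$mu_se))
  for (a in names(x$analytes)) {
    r <- x$analytes[[a]]
    cat(sprintf("%-10s %s = %.4f +/- %.4f mmol gDCW^-1 h^-1 (R2 %.4f)\n",
                a, if (r$sign == "consumption") "nu " else "rho",
                r$rate, r$se, r$r_squared))
  }
  invisible(x)
}
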