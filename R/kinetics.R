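#' First-order barrier estimate
#'
#' @param barrier Activation barrier \eqn{\Delta H^\ddagger} in kcal/mol
#'   (>= 0). Enthalpy is the conventional upper estimate of the free-energy
#'   barrier for bond dissociation (see [bond_dissociation()]).
#' @param temperature Temperature in K (> 0).
#' @return Object of class `barrier_estimate`.
#' @export
barrier_estimate <- function(barrier, temperature = 298.15) {
  if (barrier < 0) stop("barrier must be >= 0", call. = FALSE)
  if (temperature <= 0) stop("temperature must be > 0", call. = FALSE)
  structure(list(barrier = barrier, temperature = temperature,
                 order = 1L),
            class = "barrier_estimate")
}

#' Eyring rate constant for a first-order barrier
#'
#' \eqn{k = \kappa (k_B T/h) \exp(-\Delta H^\ddagger / RT)} with transmission
#' coefficient \eqn{\kappa = 1} by default. The computation is carried in
#' log space so that very large barriers (tiny rates) do not underflow; use
#' `log = TRUE` to retrieve ln k directly.
#'
#' @param b A [barrier_estimate()], or a numeric barrier in kcal/mol
#'   combined with `temperature`.
#' @param temperature Temperature in K, used when `b` is numeric.
#' @param kappa Transmission coefficient (advanced; default 1).
#' @param log Return ln k instead of k.
#' @return Rate constant in 1/s (or its natural log).
#' @export
#' @examples
#' eyring_rate(barrier_estimate(50))        # ~1.4e-24 s^-1
#' eyring_rate(50, temperature = 573.15)    # ~1e-6 s^-1
eyring_rate <- function(b, temperature = 298.15, kappa = 1, log = FALSE) {
  if (is.numeric(b)) b <- barrier_estimate(b, temperature)
  stopifnot(inherits(b, "barrier_estimate"))
  cn <- constants_table()
  lnk <- base::log(kappa) +
    base::log(cn$kB_J * b$temperature / cn$h_J) -
    b$barrier / (cn$R_kcal * b$temperature)
  if (log) lnk else exp(lnk)
}

#' First-order half-life from a rate constant
#'
#' \eqn{t_{1/2} = \ln 2 / k}. Accepts ln k through `log_rate` so half-lives
#' of astronomically slow reactions are representable.
#'
#' @param k Rate constant in 1/s (> 0); ignored if `log_rate` given.
#' @param log_rate Optional ln k (overrides `k`).
#' @return Object of class `half_life`: seconds, plus a human-readable
#'   rendering via `format()`/`print()`.
#' @export
#' @examples
#' half_life(log(2))               # 1 s
#' half_life(eyring_rate(50))      # ~1.6e16 years
half_life <- function(k = NULL, log_rate = NULL) {
  if (is.null(log_rate)) {
    if (is.null(k) || k <= 0) stop("rate constant must be > 0", call. = FALSE)
    log_rate <- base::log(k)
  }
  lns <- base::log(base::log(2)) - log_rate
  structure(list(seconds = exp(lns), log_seconds = lns), class = "half_life")
}

#' @export
format.half_life <- function(x, ...) {
  s <- x$seconds
  units <- c(second = 1, minute = 60, hour = 3600, day = 86400,
             year = 86400 * 365.25)
  if (!is.finite(s)) return(sprintf("exp(%.3f) s", x$log_seconds))
  if (s >= units["year"]) {
    sprintf("%.3g years", s / units[["year"]])
  } else if (s >= units["day"]) {
    sprintf("%.3g days", s / units[["day"]])
  } else if (s >= units["hour"]) {
    sprintf("%.3g hours", s / units[["hour"]])
  } else if (s >= 1) {
    sprintf("%.3g s", s)
  } else {
    sprintf("%.3g s", s)
  }
}

#' @export
print.half_life <- function(x, ...) {
  cat("<half_life>", format(x), sprintf("(%.4g s)", x$seconds), "\n")
  invisible(x)
}

#' Convert a half-life to another time unit
#' @param x A [half_life()] or seconds.
#' @param unit One of `"seconds"`, `"days"`, `"years"`.
#' @return Numeric duration in `unit`.
#' @export
as_duration <- function(x, unit = c("seconds", "days", "years")) {
  unit <- match.arg(unit)
  s <- if (inherits(x, "half_life")) x$seconds else x
  switch(unit, seconds = s, days = s / 86400, years = s / (86400 * 365.25))
}

#' Grid of persistence timescales over barriers and temperatures
#'
#' @param barriers Nonempty numeric vector, kcal/mol.
#' @param temperatures Nonempty numeric vector, K.
#' @param kappa Transmission coefficient.
#' @return Data frame with columns `barrier`, `temperature`, `log_rate`
#'   (ln k), `rate` (1/s), `half_life_s`, `half_life_years`; monotone
#'   decreasing in temperature and increasing in barrier.
#' @export
persistence_scan <- function(barriers, temperatures, kappa = 1) {
  if (length(barriers) == 0L || length(temperatures) == 0L) {
    stop("barriers and temperatures must be nonempty", call. = FALSE)
  }
  grid <- expand.grid(barrier = barriers, temperature = temperatures,
                      KEEP.OUT.ATTRS = FALSE)
  lnk <- mapply(function(b, Tk) eyring_rate(b, Tk, kappa = kappa, log = TRUE),
                grid$barrier, grid$temperature)
  hl <- lapply(lnk, function(l) half_life(log_rate = l))
  grid$log_rate <- lnk
  grid$rate <- exp(lnk)
  grid$half_life_s <- vapply(hl, function(h) h$seconds, numeric(1))
  grid$half_life_years <- grid$half_life_s / (86400 * 365.25)
  grid
}
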