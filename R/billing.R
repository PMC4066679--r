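#' Billing policy
#'
#' Bundles the pricing assumptions used to turn VM uptime into dollars.  The
#' base unit is the hourly price of the cheapest (t1.micro) instance,
#' $0.02/h; every other instance is priced as a multiple of it.  Two billing
#' modes are supported: `"linear"` charges exact fractional hours (the mode
#' that reproduces the published cost table), while `"hour_ceiling"` rounds
#' uptime up to whole instance-hours as the real provider does.  A flat
#' per-hour surcharge hook covers premium OS images; it defaults to zero.
#'
#' @param base_unit_usd Base hourly unit in dollars.
#' @param mode `"linear"` or `"hour_ceiling"`.
#' @param surcharge_usd_hr Flat additional dollars per hour per VM.
#' @return A list of class `billing_policy`.
#' @examples
#' billing_policy(mode = "hour_ceiling")
#' @export
billing_policy <- function(base_unit_usd = 0.02,
                           mode = c("linear", "hour_ceiling"),
                           surcharge_usd_hr = 0) {
  mode <- match.arg(mode)
  if (!is.numeric(base_unit_usd) || base_unit_usd <= 0) {
    abort("base_unit_usd must be positive.", class = "ethreadsim_validation")
  }
  if (surcharge_usd_hr < 0) {
    abort("surcharge_usd_hr must be nonnegative.", class = "ethreadsim_validation")
  }
  structure(list(base_unit_usd = base_unit_usd, mode = mode,
                 surcharge_usd_hr = surcharge_usd_hr),
            class = "billing_policy")
}

#' @export
print.billing_policy <- function(x, ...) {
  cat(sprintf("<billing_policy> base $%.3f/h, mode %s, surcharge $%.3f/h\n",
              x$base_unit_usd, x$mode, x$surcharge_usd_hr))
  invisible(x)
}

#' Billed cost of VM uptime
#'
#' Converts uptime minutes into dollars under an hourly rate.  Linear billing
#' charges `uptime / 60 * rate`; ceiling billing charges
#' `ceiling(uptime / 60) * rate` (no partial-hour usage).  No rounding is
#' performed here — round to cents only when reporting.
#'
#' @param uptime_min Nonnegative uptime in minutes (vectorized).
#' @param rate_usd_hr Hourly rate in dollars (vectorized).
#' @param mode `"linear"` or `"hour_ceiling"`.
#' @return Cost in dollars.
#' @examples
#' round(billed_cost(96905.8, 0.02), 2)  # 32.30
#' billed_cost(61, 3.10, mode = "hour_ceiling")  # 6.20
#' @export
billed_cost <- function(uptime_min, rate_usd_hr,
                        mode = c("linear", "hour_ceiling")) {
  mode <- match.arg(mode)
  if (any(uptime_min < 0) || any(rate_usd_hr < 0)) {
    abort("Uptime and rate must be nonnegative.", class = "ethreadsim_validation")
  }
  hours <- uptime_min / 60
  if (mode == "hour_ceiling") hours <- ceiling(hours)
  hours * rate_usd_hr
}

#' Sample VM launch times
#'
#' Draws launch durations from a normal distribution truncated at zero with
#' the instance's measured mean and standard deviation; a zero standard
#' deviation returns the mean exactly.  Draws consume the global RNG stream,
#' so a fixed seed reproduces them.
#'
#' @param instance A single instance-catalog row (tibble or list with
#'   `launch_mean_min`, `launch_sd_min`).
#' @param n Number of draws.
#' @return Numeric vector of launch times in minutes, all `>= 0`.
#' @examples
#' set.seed(1)
#' sample_launch_time(dplyr::filter(load_instance_catalog(), name == "c1.medium"), 3)
#' @export
sample_launch_time <- function(instance, n = 1) {
  mean <- instance$launch_mean_min[[1]]
  sd <- instance$launch_sd_min[[1]]
  if (sd == 0) return(rep(mean, n))
  out <- numeric(0)
  while (length(out) < n) {
    x <- rnorm(n - length(out), mean, sd)
    out <- c(out, x[x >= 0])
  }
  out
}
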