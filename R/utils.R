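`%||%` <- function(x, y) if (is.null(x)) y else x

PROVIDER_TYPES <- c("hospital", "psychiatrist", "gp", "nurse")

AREA_TYPOLOGY_LEVELS <- c(
  "limited_resources",
  "hospital_concentrated",
  "strong_private_urban",
  "strong_resources",
  "rural_health_social"
)

QUALITY_INDICATORS <- c(
  "readmit_15d",
  "referring_contact_2m",
  "prevention_3proc_2y",
  "antipsychotic_9plus_12m"
)

stop_config <- function(field, msg) {
  stop(sprintf("invalid configuration field '%s': %s", field, msg), call. = FALSE)
}

check_prob <- function(x, field) {
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
    stop_config(field, "probabilities must lie in [0, 1]")
  }
  invisible(x)
}

check_count <- function(x, field, allow_zero = FALSE) {
  lo <- if (allow_zero) 0 else 1
  if (any(!is.finite(x)) || any(x < lo) || any(x != round(x))) {
    stop_config(field, sprintf("counts must be integers >= %d", lo))
  }
  invisible(x)
}

#' Third quartile by linear interpolation between order statistics
#'
#' Order-statistic quantile at position 0.75 * (n - 1) (zero-based), i.e. the
#' default linear-interpolation convention of [stats::quantile()] type 7.
#'
#' @param x numeric vector.
#' @return the third quartile as a scalar.
#' @examples
#' third_quartile(c(1, 2, 2, 3, 4, 6, 8, 20)) # 6.5
#' @export
third_quartile <- function(x) {
  unname(stats::quantile(x, probs = 0.75, type = 7, names = FALSE))
}

days_since <- function(date, origin) {
  as.numeric(as.Date(date) - as.Date(origin))
}

## population variance (denominator N), used by the v-test
pop_var <- function(x) {
  mean((x - mean(x))^2)
}
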