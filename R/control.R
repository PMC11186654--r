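#' Binary power-control decision
#'
#' Bang-bang power modulation at a temperature monitoring point: power
#' fully on while the sampled temperature does not exceed the regulation
#' threshold (`T <= Treg`, boundary included), fully off otherwise.  The
#' decision holds until the next update (1 s cadence) and never ends the
#' schedule.
#'
#' @param Ttmp sampled TMP temperature, degC.
#' @param spec a [ControllerSpec-class] of kind `"binary"`.
#' @return power scale, 0 or 1.
#' @examples
#' cs <- controllerSpec("binary", threshold = 45, tmp = c(0, 0, 0))
#' binaryUpdate(45.0, cs)  # 1: boundary included
#' binaryUpdate(45.1, cs)  # 0
#' @export
binaryUpdate <- function(Ttmp, spec) {
  stopifnot(spec@kind == "binary")
  as.numeric(Ttmp <= spec@threshold)
}

#' Pilot-point control decision
#'
#' Treatment-terminating control: power stays on while the monitored
#' temperature is below the threshold; the first sample at or above it
#' switches power off and latches termination permanently (dose accrual
#' during cooldown continues).
#'
#' @param Ttmp sampled TMP temperature, degC.
#' @param spec a [ControllerSpec-class] of kind `"pilot"`.
#' @param terminated current latch state (logical).
#' @return list with `scale` (0/1) and `terminated` (logical).
#' @examples
#' cs <- controllerSpec("pilot", threshold = 52, tmp = c(0, 0, 0))
#' pilotUpdate(51.9, cs, FALSE)  # on, not terminated
#' pilotUpdate(52.0, cs, FALSE)  # off, terminated
#' pilotUpdate(48.0, cs, TRUE)   # still off: latched
#' @export
pilotUpdate <- function(Ttmp, spec, terminated = FALSE) {
  stopifnot(spec@kind == "pilot")
  terminated <- terminated || Ttmp >= spec@threshold
  list(scale = as.numeric(!terminated), terminated = terminated)
}

#' Compose simultaneous controller decisions
#'
#' Multiple controllers bound to the same applicator compose by taking
#' the product of their power scales; any pilot termination wins and
#' zeroes all applicators permanently.
#'
#' @param decisions numeric vector of per-controller scales (0/1).
#' @param terminated logical, any pilot latch set.
#' @return composed power scale.
#' @export
composeDecisions <- function(decisions, terminated = FALSE) {
  if (terminated) 0 else prod(decisions)
}
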