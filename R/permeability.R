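#' Apparent membrane permeability from a donor/receiver assay
#'
#' P = (C_t * V) / (C_0 * A * dt): the receiving-side concentration `C_t`
#' after time `dt`, scaled by the receiver volume `V`, the membrane contact
#' area `A`, and the donor's initial concentration `C_0`. Unbiased only in
#' the sink regime (`C_t << C_0`); outside it the estimate is still computed
#' but flagged.
#'
#' @param C_t Receiver concentration after `dt` (same units as `C_0`).
#' @param C0 Initial donor concentration.
#' @param V Receiver media volume in cm^3.
#' @param A Membrane contact area in cm^2.
#' @param dt Assay duration in s.
#' @param sink_threshold `C_t / C0` above which the sink assumption is
#'   flagged as violated (default 0.1).
#' @return A `permeability_estimate`: one-row tibble with `value_cm_s`, the
#'   echoed inputs and `sink_ok`.
#' @export
#' @examples
#' estimate_permeability(C_t = 1, C0 = 100, V = 0.6, A = 1, dt = 600)
estimate_permeability <- function(C_t, C0, V, A, dt, sink_threshold = 0.1) {
  if (C0 <= 0 || A <= 0 || dt <= 0) {
    abort("C0, A and dt must be strictly positive",
          class = "organflux_precondition_error")
  }
  if (C_t < 0) {
    abort("receiver concentration must be >= 0",
          class = "organflux_precondition_error")
  }
  if (C_t > C0) {
    warn("C_t exceeds C0: sink condition violated, estimate is biased",
         class = "organflux_sink_warning")
  }
  out <- tibble(
    value_cm_s = (C_t * V) / (C0 * A * dt),
    C_t = C_t, C0 = C0, V_cm3 = V, A_cm2 = A, dt_s = dt,
    sink_ok = (C_t / C0) <= sink_threshold
  )
  class(out) <- c("permeability_estimate", class(out))
  out
}
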