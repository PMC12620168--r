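#' Resilient propagation (Rprop) update
#'
#' Sign-based gradient update with per-parameter adaptive step sizes, the
#' optimizer used by both the water fitter and the metabolite fitter. When a
#' gradient keeps its sign the step grows by `eta_plus`; when it flips the
#' step shrinks by `eta_minus` and the gradient is zeroed for that update
#' (the "iRprop-" variant, as implemented in common autodiff frameworks).
#' Steps are clipped to `[step_min, step_max]` and parameters move by
#' `-sign(gradient) * step`.
#'
#' @param par Numeric vector/matrix of parameters.
#' @param step Initial per-parameter step size (scalar or same shape as
#'   `par`); conventionally the "learning rate".
#' @param grad Gradient of the loss at `par` (same shape); must be finite.
#' @param state State list from [rprop_init()] or a previous
#'   [rprop_update()].
#' @param eta_plus,eta_minus Step growth/shrink factors.
#' @param step_min,step_max Step-size clip bounds.
#' @return `rprop_init()`: a state list with elements `step` and
#'   `prev_grad`. `rprop_update()`: list with updated `par` and `state`.
#' @examples
#' # minimize (x - 3)^2
#' par <- 0; st <- rprop_init(par, step = 0.5)
#' for (i in 1:60) {
#'   up <- rprop_update(par, 2 * (par - 3), st)
#'   par <- up$par; st <- up$state
#' }
#' par
#' @export
rprop_init <- function(par, step = 1) {
  s <- par
  s[] <- step
  list(step = s, prev_grad = 0 * par)
}

#' @rdname rprop_init
#' @export
rprop_update <- function(par, grad, state,
                         eta_plus = 1.2, eta_minus = 0.5,
                         step_min = 1e-6, step_max = 50) {
  if (any(!is.finite(grad)))
    stop("non-finite gradient in rprop_update", call. = FALSE)
  sgn <- sign(grad * state$prev_grad)
  step <- state$step
  step[sgn > 0] <- pmin(step[sgn > 0] * eta_plus, step_max)
  step[sgn < 0] <- pmax(step[sgn < 0] * eta_minus, step_min)
  grad[sgn < 0] <- 0
  par <- par - sign(grad) * step
  list(par = par, state = list(step = step, prev_grad = grad))
}
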