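#' Admittance model parameters
#'
#' Virtual mass-spring-damper of the z-axis admittance model
#' \deqn{H(s) = \frac{X(s)}{F(s)} = \frac{1}{M s^2 + B s + K},}
#' mapping applied force to desired probe displacement. Defaults are the
#' z-axis entries used throughout: M = 5.625 kg, K = 50 N/m, and B chosen for
#' a critically damped response (2 sqrt(MK) = 33.54 N s/m to two decimals).
#'
#' @param mass virtual mass M in kg (> 0).
#' @param stiffness virtual stiffness K in N/m (> 0).
#' @param damping virtual damping B in N s/m (>= 0); `NULL` (default) selects
#'   critical damping via [critical_damping()].
#' @return list of class `admittance_params`.
#' @export
admittance_params <- function(mass = 5.625, stiffness = 50, damping = NULL) {
  if (!is.numeric(mass) || mass <= 0 || !is.numeric(stiffness) || stiffness <= 0)
    stop_sonoqc("mass and stiffness must be positive", "sonoqc_domain_error")
  if (is.null(damping)) damping <- critical_damping(mass, stiffness)
  if (!is.numeric(damping) || damping < 0)
    stop_sonoqc("damping must be >= 0", "sonoqc_domain_error")
  structure(list(mass = mass, damping = damping, stiffness = stiffness),
            class = "admittance_params")
}

#' Critically damped damping coefficient
#'
#' Damping ratio 1 (fastest non-oscillatory step response) requires
#' \eqn{B = 2\sqrt{MK}}.
#'
#' @param mass virtual mass in kg (> 0).
#' @param stiffness virtual stiffness in N/m (> 0).
#' @return damping in N s/m.
#' @examples
#' critical_damping(5.625, 50) # 33.54 to two decimals
#' @export
critical_damping <- function(mass, stiffness) {
  if (!is.numeric(mass) || !is.numeric(stiffness) || mass <= 0 || stiffness <= 0)
    stop_sonoqc("mass and stiffness must be positive", "sonoqc_domain_error")
  2 * sqrt(mass * stiffness)
}

#' Force-update policy
#'
#' The scanning force starts at `f_min` and is incremented by `delta_F`
#' whenever the quality verdict is low, capped at `f_max` (the 1-20 N sweep
#' range with 0.25 N increments).
#'
#' @param delta_F force increment in N (> 0). Default 0.25.
#' @param f_min,f_max force range in N. Defaults 1 and 20.
#' @return list of class `force_policy`.
#' @export
force_policy <- function(delta_F = 0.25, f_min = 1, f_max = 20) {
  if (!is.numeric(delta_F) || delta_F <= 0)
    stop_sonoqc("delta_F must be positive", "sonoqc_domain_error")
  if (f_min > f_max)
    stop_sonoqc("f_min must not exceed f_max", "sonoqc_domain_error")
  structure(list(delta_F = delta_F, f_min = f_min, f_max = f_max),
            class = "force_policy")
}

#' Force-update rule
#'
#' \eqn{F_{k+1} = \min(F_k + \delta F\,(1 - V_{svm}),\ F_{max})}: the force is
#' held when the frame is judged high quality and incremented otherwise, never
#' exceeding the policy ceiling.
#'
#' @param f_z current commanded force in N.
#' @param v_svm binary quality verdict (1 = high quality).
#' @param policy a [force_policy()].
#' @return next commanded force in N.
#' @export
update_force <- function(f_z, v_svm, policy = force_policy()) {
  min(f_z + policy$delta_F * (1 - v_svm), policy$f_max)
}

#' Scan state
#'
#' @param t time in s; `force` commanded force in N; `x` probe displacement in
#'   m (z direction of the admittance model); `v` velocity in m/s.
#' @return list of class `scan_state`.
#' @export
scan_state <- function(t = 0, force = 1, x = 0, v = 0) {
  structure(list(t = t, force = force, x = x, v = v), class = "scan_state")
}

# Exact zero-order-hold discretization of M x'' + B x' + K x = F over step dt:
# state (x, v) advances by Ad %*% s + Bd * F with Ad = exp(A dt) and
# Bd = A^{-1} (Ad - I) Bc. Exact at the tick instants for force held constant
# over the tick.
discretize_admittance <- function(params, dt) {
  M <- params$mass; B <- params$damping; K <- params$stiffness
  A <- matrix(c(0, -K / M, 1, -B / M), 2, 2)
  Ad <- as.matrix(Matrix::expm(A * dt))
  Ainv <- matrix(c(-B / K, 1, -M / K, 0), 2, 2)
  Bd <- Ainv %*% (Ad - diag(2)) %*% c(0, 1 / M)
  list(Ad = Ad, Bd = as.vector(Bd), dt = dt)
}

#' Advance the admittance model by one tick
#'
#' Integrates the second-order system with the force held constant over the
#' step, using the exact zero-order-hold discretization (matrix exponential),
#' so the discrete trajectory coincides with the continuous solution at the
#' tick instants to machine precision.
#'
#' @param state a [scan_state()].
#' @param f_applied applied force in N over the step.
#' @param params an [admittance_params()].
#' @param dt step duration in s (> 0).
#' @param disc optional precomputed result of `discretize_admittance(params,
#'   dt)` (used by the scan loop to avoid recomputing the exponential).
#' @return the advanced `scan_state`.
#' @export
admittance_step <- function(state, f_applied, params = admittance_params(),
                            dt = 1 / 30, disc = NULL) {
  if (dt <= 0) stop_sonoqc("dt must be positive", "sonoqc_domain_error")
  if (is.null(disc)) disc <- discretize_admittance(params, dt)
  s <- disc$Ad %*% c(state$x, state$v) + disc$Bd * f_applied
  scan_state(t = state$t + dt, force = state$force, x = s[1], v = s[2])
}

#' Simulate the force-adaptive scan loop
#'
#' Runs the closed loop at `rate` Hz: each tick the phantom renders a frame at
#' the current commanded force, the gated SVM produces the quality verdict,
#' the force-update rule sets the next commanded force, and the admittance
#' model tracks the probe displacement (the inner force-tracking loop is
#' treated as ideal, so applied force equals commanded force within a tick).
#' The loop is declared converged after 10 consecutive high-quality verdicts,
#' after which simulation stops.
#'
#' @param model a trained `quality_model`.
#' @param phantom a [virtual_phantom()] sharing the model's reference frame.
#' @param params an [admittance_params()].
#' @param policy a [force_policy()].
#' @param rate loop rate in Hz (default 30).
#' @param max_ticks maximum number of ticks before giving up (the trace is
#'   then returned with `converged = FALSE`, not an error).
#' @param seed integer seed driving the phantom's per-tick speckle.
#' @param converge_window consecutive high verdicts required (default 10).
#' @return data.frame of class `scan_trace` with columns `tick`, `t_s`,
#'   `force_N`, `depth_m`, `correlation`, `f_c`, `f_n`, `v_svm`, and
#'   attributes `converged` and `rate`.
#' @export
simulate_scan <- function(model, phantom, params = admittance_params(),
                          policy = force_policy(), rate = 30,
                          max_ticks = 600L, seed = 1L,
                          converge_window = 10L) {
  if (!inherits(model, "quality_model"))
    stop_sonoqc("model is not a trained quality_model", "sonoqc_state_error")
  dt <- 1 / rate
  disc <- discretize_admittance(params, dt)
  state <- scan_state(t = 0, force = policy$f_min, x = 0, v = 0)
  reference <- phantom$reference
  n <- as.integer(max_ticks)
  rec <- data.frame(tick = seq_len(n), t_s = NA_real_, force_N = NA_real_,
                    depth_m = NA_real_, correlation = NA_real_,
                    f_c = NA_real_, f_n = NA_real_, v_svm = NA_integer_)
  streak <- 0L; converged <- FALSE; used <- 0L
  for (k in seq_len(n)) {
    frame <- render_contact(phantom, state$force, seed = derive_seed(seed, k))
    cls <- classify(model, frame, reference)
    fv <- cls$features
    rec$t_s[k] <- state$t
    rec$force_N[k] <- state$force
    rec$depth_m[k] <- state$x
    rec$correlation[k] <- fv$correlation_raw
    rec$f_c[k] <- fv$compression
    rec$f_n[k] <- fv$noise
    rec$v_svm[k] <- cls$v_svm
    used <- k
    streak <- if (cls$v_svm == 1L) streak + 1L else 0L
    next_force <- update_force(state$force, cls$v_svm, policy)
    state <- admittance_step(state, state$force, params, dt, disc)
    state$force <- next_force
    if (streak >= converge_window) { converged <- TRUE; break }
  }
  rec <- rec[seq_len(used), , drop = FALSE]
  structure(rec, converged = converged, rate = rate,
            class = c("scan_trace", "data.frame"))
}

#' @exportS3Method
print.scan_trace <- function(x, ...) {
  cat(sprintf("scan trace: %d ticks at %g Hz, %s\n", nrow(x), attr(x, "rate"),
              if (isTRUE(attr(x, "converged"))) "converged" else "not converged"))
  cat(sprintf("  force %.2f -> %.2f N; final depth %.4f m; final f_c %.3f, f_n %.2f\n",
              x$force_N[1], x$force_N[nrow(x)], x$depth_m[nrow(x)],
              x$f_c[nrow(x)], x$f_n[nrow(x)]))
  invisible(x)
}

#' Plot a scan trace
#'
#' Commanded force, probe displacement and quality verdict against time.
#'
#' @param x a `scan_trace`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.scan_trace <- function(x, ...) {
  op <- graphics::par(mfrow = c(3, 1), mar = c(3.5, 4, 1.5, 1))
  on.exit(graphics::par(op))
  graphics::plot(x$t_s, x$force_N, type = "s", xlab = "time (s)",
                 ylab = "force (N)", main = "commanded force", ...)
  graphics::plot(x$t_s, x$depth_m, type = "l", xlab = "time (s)",
                 ylab = "depth (m)", main = "probe displacement")
  graphics::plot(x$t_s, x$v_svm, type = "s", xlab = "time (s)",
                 ylab = "v_svm", main = "quality verdict", ylim = c(0, 1))
  invisible(x)
}

#' Write a scan trace as CSV
#'
#' Columns: tick, t_s, force_N, depth_m, correlation, f_c, f_n, v_svm.
#'
#' @param trace a `scan_trace`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_scan_trace <- function(trace, path) {
  write.csv(as.data.frame(trace), path, row.names = FALSE)
  invisible(path)
}
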