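#' Condition presets and event schedules
#'
#' Builds the event schedule for a simulated cellular state. Induction
#' presets follow the published input table: DDIS has `RAS_input = 0.5`
#' and `kDDRFRAS = 0.5` active from t = 0 with `DDR_input = 5`,
#' `kDDRF = 14` and `kRASF = 0.3` applied at the induction event; OIS has
#' `DDR_input = 0` and `kDDRF = 0.01` from t = 0 with `RAS_input = 5`,
#' `kRASF = 1` and `kDDRFRAS = 5.75` applied at induction. Induction
#' fires at t = 40 AU once the model has equilibrated, the Notch switch
#' (a step reduction of `k_cleave` by `notch_factor`) at t = 65 AU, and
#' the horizon is 100 AU; the day-to-AU mapping is
#' `t = 40 + 5 * days post-induction`.
#'
#' Knockdowns are events at induction time: a p53 knockdown multiplies
#' the p53 level and its synthesis rate `b_p53` by `kd_scale`; a RelA
#' knockdown multiplies the NF-kB level, its synthesis rate `b_NF` and
#' the activation rate `V_NF` by `kd_scale` (knockdown, not knockout;
#' default 0.1). `baseline` schedules no induction and no switch.
#'
#' @param model A `"senescence_model"`.
#' @param condition `"baseline"`, `"DDIS"` or `"OIS"`.
#' @param kd `"none"`, `"p53"` or `"RelA"`.
#' @param kd_scale Knockdown scale factor in (0, 1].
#' @param induction_time,notch_switch_time,horizon Event times (AU).
#' @param notch_factor Multiplier applied to `k_cleave` at the switch.
#' @return A list of class `"event_schedule"`: the parameterised `model`
#'   (t = 0 parameters applied), `events` (list of time-stamped parameter
#'   sets/scalings and state scalings), `condition`, `kd`, and the times.
#' @export
configure_condition <- function(model, condition = c("baseline", "DDIS",
                                                     "OIS"),
                                kd = c("none", "p53", "RelA"),
                                kd_scale = 0.1,
                                induction_time = 40,
                                notch_switch_time = 65,
                                horizon = 100,
                                notch_factor = 0.05) {
  condition <- match.arg(condition)
  kd <- match.arg(kd)
  if (!(induction_time > 0 && induction_time < notch_switch_time &&
        notch_switch_time < horizon))
    stop("event times must satisfy 0 < induction < switch < horizon")
  if (kd_scale <= 0 || kd_scale > 1) stop("kd_scale must be in (0, 1]")
  p <- model$parameters
  events <- list()
  if (condition == "DDIS") {
    p["RAS_input"] <- 0.5
    p["kDDRFRAS"] <- 0.5
    events <- c(events, list(list(
      time = induction_time,
      set = c(DDR_input = 5, kDDRF = 14, kRASF = 0.3))))
  } else if (condition == "OIS") {
    p["DDR_input"] <- 0
    p["kDDRF"] <- 0.01
    events <- c(events, list(list(
      time = induction_time,
      set = c(RAS_input = 5, kRASF = 1, kDDRFRAS = 5.75))))
  }
  if (condition != "baseline") {
    events <- c(events, list(list(
      time = notch_switch_time,
      scale_params = c(k_cleave = notch_factor))))
    if (kd == "p53")
      events <- c(events, list(list(
        time = induction_time,
        scale_params = c(b_p53 = kd_scale),
        scale_states = c(p53 = kd_scale))))
    if (kd == "RelA")
      events <- c(events, list(list(
        time = induction_time,
        scale_params = c(b_NF = kd_scale, V_NF = kd_scale),
        scale_states = c(NFKB = kd_scale))))
  }
  model$parameters <- p
  structure(list(model = model, events = events, condition = condition,
                 kd = kd, induction_time = induction_time,
                 notch_switch_time = notch_switch_time,
                 horizon = horizon),
            class = "event_schedule")
}

apply_event <- function(ev, params, state) {
  if (!is.null(ev$set)) params[names(ev$set)] <- ev$set
  if (!is.null(ev$scale_params))
    params[names(ev$scale_params)] <-
      params[names(ev$scale_params)] * ev$scale_params
  if (!is.null(ev$scale_states))
    state[names(ev$scale_states)] <-
      state[names(ev$scale_states)] * ev$scale_states
  list(params = params, state = state)
}

#' Simulate a scheduled condition
#'
#' Integrates the network with `deSolve::lsoda`, restarting the
#' integration at every event time. The initial state defaults to the
#' fixed point of the t = 0 (pre-induction) parameterisation, so the
#' pre-induction segment is at equilibrium; the maximal derivative just
#' before induction is recorded and a warning is raised if it exceeds
#' `1e-6`. Dense output on `times` (>= 500 points by default). Reported
#' values are clipped to zero from below at `-1e-9`.
#'
#' @param schedule An [configure_condition()] schedule.
#' @param times Output grid; default `seq(t_start, horizon, length.out
#'   = 501)`.
#' @param init Optional initial state (default: pre-induction fixed
#'   point).
#' @param t_start,t_end Integration window (defaults 0 and the schedule
#'   horizon); events outside the window are ignored. Chaining windows
#'   with carried state reproduces a single full-window call.
#' @param rtol,atol Solver tolerances.
#' @param extra_events Additional event list merged into the schedule
#'   (used by the sensitivity machinery); fires after schedule events at
#'   the same time.
#' @return A list of class `"trajectory"`: `times`, `values` (time x
#'   species matrix), `condition`, `kd`, `baseline` (state at induction
#'   time entry), `equilibrated` flag.
#' @export
simulate_condition <- function(schedule, times = NULL, init = NULL,
                               t_start = 0, t_end = schedule$horizon,
                               rtol = 1e-8, atol = 1e-10,
                               extra_events = list()) {
  model <- schedule$model
  params <- model$parameters
  if (is.null(times))
    times <- seq(t_start, t_end, length.out = 501)
  if (is.null(init))
    init <- find_steady_state(model, params)
  evs <- c(schedule$events, extra_events)
  ev_times <- vapply(evs, `[[`, 0, "time")
  ord <- order(ev_times, seq_along(evs))  # schedule before extras at ties
  evs <- evs[ord]; ev_times <- ev_times[ord]
  # events already in the past still shape the parameter set; their state
  # scalings are assumed to be baked into the carried `init`
  for (ev in evs[ev_times <= t_start]) {
    ev$scale_states <- NULL
    params <- apply_event(ev, params, init)$params
  }
  inside <- ev_times > t_start & ev_times <= t_end
  evs <- evs[inside]; ev_times <- ev_times[inside]
  bounds <- unique(c(t_start, ev_times, t_end))
  state <- init
  rows <- list()
  equil_deriv <- NA_real_
  for (i in seq_len(length(bounds) - 1)) {
    seg <- c(bounds[i], bounds[i + 1])
    # events firing at the segment start
    for (ev in evs[ev_times == seg[1]]) {
      if (seg[1] == schedule$induction_time && is.na(equil_deriv))
        equil_deriv <- max(abs(unlist(model$rhs(seg[1], state, params))))
      upd <- apply_event(ev, params, state)
      params <- upd$params; state <- upd$state
    }
    seg_times <- unique(c(seg[1], times[times >= seg[1] &
                                          times <= seg[2]], seg[2]))
    sol <- deSolve::lsoda(state, seg_times, model$rhs, params,
                          rtol = rtol, atol = atol)
    if (attr(sol, "istate")[1] < 0)
      stop(sprintf("integration failure at t = %.3f", sol[nrow(sol), 1]))
    state <- sol[nrow(sol), model$species]
    rows[[i]] <- sol[sol[, 1] %in% times, , drop = FALSE]
  }
  out <- do.call(rbind, rows)
  out <- out[!duplicated(out[, 1]), , drop = FALSE]
  vals <- out[, model$species, drop = FALSE]
  if (any(vals < -1e-9))
    warning("negative species value below tolerance floor")
  vals[vals < 0] <- 0
  if (is.na(equil_deriv)) {
    equil_deriv <- 0
  } else if (equil_deriv >= 1e-6) {
    warning(sprintf("pre-induction equilibrium not reached (max |dX/dt| = %.2e)",
                    equil_deriv))
  }
  base_idx <- which(out[, 1] <= schedule$induction_time)
  baseline <- if (length(base_idx))
    stats::setNames(as.numeric(vals[max(base_idx), ]), model$species)
  else stats::setNames(as.numeric(init), model$species)
  structure(list(times = out[, 1], values = vals,
                 condition = schedule$condition, kd = schedule$kd,
                 baseline = baseline,
                 equilibrated = equil_deriv < 1e-6,
                 final_state = state),
            class = "trajectory")
}

#' Interpolate a species from a trajectory
#' @param traj A `"trajectory"`.
#' @param species Species name.
#' @param t Time(s) to evaluate at.
#' @return Numeric vector.
#' @export
traj_at <- function(traj, species, t) {
  stats::approx(traj$times, traj$values[, species], xout = t,
                rule = 2)$y
}

#' Time-mean of a species over a window
#' @param traj A `"trajectory"`.
#' @param species Species name (or vector summed together).
#' @param window `c(from, to)` in AU.
#' @return Scalar trapezoidal mean.
#' @export
traj_mean <- function(traj, species, window) {
  tt <- seq(max(window[1], min(traj$times)),
            min(window[2], max(traj$times)), length.out = 201)
  y <- rowSums(cbind(sapply(species, function(s) traj_at(traj, s, tt))))
  pracma::trapz(tt, y) / (tt[length(tt)] - tt[1])
}

#' Write a trajectory as CSV (time plus one column per species)
#' @param traj A `"trajectory"`.
#' @param path Output file.
#' @export
write_trajectory <- function(traj, path) {
  utils::write.csv(data.frame(time = traj$times, traj$values,
                              check.names = FALSE),
                   path, row.names = FALSE)
  invisible(path)
}
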