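# Deterministic integration of the mass-action ODE system with
# time-triggered activation events.

# Flatten the declarative network into index vectors for a fast RHS.
# All shipped reactions are at most second order in reactants with one
# optional enzyme, so the flux vector is k * yy[i1] * yy[i2] * yy[i3]
# against the state augmented with a constant 1 slot.
compile_network <- function(model, rate_values = NULL) {
  sp <- model$species$name
  n <- length(sp)
  rxns <- model$reactions
  nr <- length(rxns)
  one <- n + 1L
  i1 <- i2 <- i3 <- rep(one, nr)
  S <- matrix(0, n, nr, dimnames = list(sp, vapply(rxns, `[[`, "", "id")))
  for (j in seq_len(nr)) {
    r <- rxns[[j]]
    idx <- rep(match(names(r$reactants), sp), times = r$reactants)
    if (length(idx) > 2L)
      stop("reaction ", r$id, " has molecularity > 2 in reactants")
    if (length(idx) >= 1L) i1[j] <- idx[1L]
    if (length(idx) == 2L) i2[j] <- idx[2L]
    if (!is.na(r$enzyme)) i3[j] <- match(r$enzyme, sp)
    S[names(r$reactants), j] <- S[names(r$reactants), j] - r$reactants
    S[names(r$products), j] <- S[names(r$products), j] + r$products
  }
  if (is.null(rate_values))
    rate_values <- stats::setNames(model$rates$basal, model$rates$id)
  k <- unname(rate_values[vapply(rxns, `[[`, "", "rate")])
  list(species = sp, S = S, i1 = i1, i2 = i2, i3 = i3, k = k,
       rate_of = vapply(rxns, `[[`, "", "rate"))
}

make_rhs <- function(net) {
  S <- net$S; i1 <- net$i1; i2 <- net$i2; i3 <- net$i3
  function(t, y, k) {
    yy <- c(pmax(y, 0), 1)
    flux <- k * yy[i1] * yy[i2] * yy[i3]
    list(as.vector(S %*% flux))
  }
}

current_rates <- function(model, activated_phase = FALSE, switches = NULL) {
  k <- stats::setNames(model$rates$basal, model$rates$id)
  if (activated_phase && length(switches)) {
    act <- stats::setNames(model$rates$activated, model$rates$id)
    k[switches] <- act[switches]
  }
  k
}

#' Simulate a model
#'
#' Integrates the mass-action ODE system with the stiff/non-stiff switching
#' LSODA solver. Time-triggered activation events are handled by stopping the
#' integration at the event time, applying the discrete changes (receptor
#' conversion, rate-constant switches, later reset) and restarting, so the
#' state of untouched species is continuous across events. Values reported at
#' an event time are the pre-event (left-limit) state.
#'
#' Solver noise producing small negative amounts (within `1e-9` of the
#' largest amount of the run) is clipped to zero; larger negatives raise an
#' error.
#'
#' @param model a `pi_model`, with or without an activation scheme attached.
#' @param t_end end of the integration horizon, seconds.
#' @param times output grid (seconds) within `[0, t_end]`; defaults to 201
#'   evenly spaced points.
#' @param atol,rtol solver tolerances (molecules; relative).
#' @return a `pi_timecourse`: list with `times`, `amounts` (time x species
#'   matrix, molecules/cell), and `observables` (time x the seven monitored
#'   outputs, lipid totals including bound complexes).
#' @export
simulate_model <- function(model, t_end, times = NULL,
                           atol = 1e-6, rtol = 1e-8) {
  if (t_end <= 0) stop("t_end must be > 0")
  if (is.null(times)) times <- seq(0, t_end, length.out = 201L)
  if (any(times < 0 | times > t_end)) stop("output grid outside [0, t_end]")
  times <- sort(unique(times))
  net <- compile_network(model)
  rhs <- make_rhs(net)
  y0 <- stats::setNames(model$species$initial, net$species)

  a <- model$activation
  breaks <- numeric(0)
  if (!is.null(a) && a$t_activation < t_end)
    breaks <- c(a$t_activation,
                min(a$t_activation + a$termination_timescale, t_end))
  breaks <- unique(c(0, breaks[breaks < t_end], t_end))

  out <- matrix(NA_real_, length(times), length(y0),
                dimnames = list(NULL, net$species))
  y <- y0
  if (times[1] == 0) out[1, ] <- y0
  for (seg in seq_len(length(breaks) - 1L)) {
    t0 <- breaks[seg]; t1 <- breaks[seg + 1L]
    phase <- if (!is.null(a) && t0 >= a$t_activation &&
                 t0 < a$t_activation + a$termination_timescale) "active"
             else if (!is.null(a) && t0 >= a$t_activation +
                      a$termination_timescale) "post" else "basal"
    k <- current_rates(model, activated_phase = (phase == "active"),
                       switches = if (!is.null(a)) a$rate_switches)
    kk <- unname(k[net$rate_of])
    if (!is.null(a)) {
      if (t0 == a$t_activation) {            # activation event
        y["GPCR_a"] <- y["GPCR_a"] + min(y["GPCR"], a$receptor_count)
        y["GPCR"] <- max(y["GPCR"] - a$receptor_count, 0)
      }
      if (t0 == a$t_activation + a$termination_timescale &&
          a$termination == "reset") {        # return to basal state
        y["GPCR"] <- y["GPCR"] + y["GPCR_a"]
        y["GPCR_a"] <- 0
      }
      if (phase == "active" && a$termination != "inactivation")
        kk[net$rate_of == "k_r_inact"] <- 0
      if (phase == "active" && a$termination == "inactivation")
        kk[net$rate_of == "k_r_inact"] <- 1 / a$termination_timescale
    }
    grid <- sort(unique(c(t0, times[times > t0 & times <= t1], t1)))
    sol <- try(deSolve::ode(y = y, times = grid, func = rhs, parms = kk,
                            method = "lsoda", atol = atol, rtol = rtol),
               silent = TRUE)
    if (inherits(sol, "try-error") ||
        attr(sol, "istate")[1L] < 0 || nrow(sol) < length(grid)) {
      last_t <- if (inherits(sol, "try-error")) t0 else sol[nrow(sol), 1L]
      stop("solver failed to converge; last good time ", signif(last_t, 6),
           call. = FALSE)
    }
    m <- sol[, -1L, drop = FALSE]
    keep <- grid %in% times & grid > t0
    if (any(keep)) out[match(grid[keep], times), ] <- m[keep, , drop = FALSE]
    if (times[1] == t0 && seg == 1L) out[1L, ] <- y
    y <- m[nrow(m), ]
  }
  big <- max(abs(out), na.rm = TRUE)
  neg <- out < 0
  if (any(neg, na.rm = TRUE)) {
    if (min(out, na.rm = TRUE) < -1e-9 * big)
      stop("integration produced substantially negative amounts")
    out[neg] <- 0
  }
  tc <- structure(list(times = times, amounts = out,
                       binding_pairs = model$binding_pairs),
                  class = "pi_timecourse")
  tc$observables <- observable_matrix(tc)
  tc
}

# Lipid observables are free + bound totals; soluble observables direct.
observable_matrix <- function(tc) {
  am <- tc$amounts
  bp <- tc$binding_pairs
  obs <- matrix(NA_real_, nrow(am), length(pi_observables),
                dimnames = list(NULL, pi_observables))
  for (o in pi_observables) {
    if (!o %in% colnames(am)) next
    v <- am[, o]
    if (!is.null(bp) && nrow(bp)) {
      cx <- bp$complex[bp$lipid == o]
      for (cc in cx) if (cc %in% colnames(am)) v <- v + am[, cc]
    }
    obs[, o] <- v
  }
  obs
}

#' @export
print.pi_timecourse <- function(x, ...) {
  cat("<pi_timecourse> ", nrow(x$amounts), " time points x ",
      ncol(x$amounts), " species, t in [", min(x$times), ", ",
      max(x$times), "] s\n", sep = "")
  invisible(x)
}

#' @export
as.data.frame.pi_timecourse <- function(x, ...) {
  data.frame(time = rep(x$times, ncol(x$amounts)),
             species = rep(colnames(x$amounts), each = length(x$times)),
             amount = as.vector(x$amounts), stringsAsFactors = FALSE)
}

#' Find the pre-activation steady state
#'
#' Relaxes the unactivated system by long-time integration (in doubling
#' rounds) until the residual `max |dX/dt|` falls below tolerance or the
#' iteration budget is exhausted, in which case the best state found is
#' returned with a warning flag. Any pending activation event is ignored:
#' steady-state analysis concerns the reactions occurring before activation.
#'
#' @param model a `pi_model`.
#' @param tol absolute residual tolerance, molecules/second.
#' @param t_relax initial relaxation horizon, seconds.
#' @param max_rounds relaxation rounds (horizon doubles each round).
#' @return list with `amounts` (named vector), `residual`, `converged`.
#' @export
find_steady_state <- function(model, tol = 10, t_relax = 2e5, max_rounds = 4) {
  model$activation <- NULL
  net <- compile_network(model)
  rhs <- make_rhs(net)
  kk <- unname(current_rates(model)[net$rate_of])
  y <- stats::setNames(model$species$initial, net$species)
  resid <- function(y) max(abs(rhs(0, y, kk)[[1]]))
  r <- resid(y)
  horizon <- t_relax
  rounds <- 0
  while (r > tol && rounds < max_rounds) {
    sol <- deSolve::ode(y = y, times = c(0, horizon / 2, horizon), func = rhs,
                        parms = kk, method = "lsoda",
                        atol = 1e-6, rtol = 1e-10)
    y <- pmax(sol[nrow(sol), -1L], 0)
    r <- resid(y)
    horizon <- horizon * 2
    rounds <- rounds + 1
  }
  converged <- r <= tol
  if (!converged)
    warning("steady state not reached within iteration budget; residual ",
            signif(r, 3))
  list(amounts = y, residual = r, converged = converged)
}

#' Replace a model's initial amounts
#' @keywords internal
set_initial_state <- function(model, amounts) {
  i <- match(model$species$name, names(amounts))
  model$species$initial[!is.na(i)] <- unname(amounts[i[!is.na(i)]])
  model
}

#' Summarise a trajectory over a window
#'
#' Reports the peak (maximum), its time, the level at the window end, and the
#' ratio of the peak to the initial (t = 0) level for one species or
#' observable.
#'
#' @param tc a `pi_timecourse`.
#' @param species a species name or one of [pi_observables] (observable
#'   totals take precedence).
#' @param window `c(t0, t1)` within the trajectory range.
#' @return list with `peak`, `time_of_peak`, `level_at_end`,
#'   `ratio_to_initial`.
#' @export
summarize_timecourse <- function(tc, species, window = range(tc$times)) {
  v <- if (species %in% colnames(tc$observables) &&
           !all(is.na(tc$observables[, species]))) tc$observables[, species]
       else if (species %in% colnames(tc$amounts)) tc$amounts[, species]
       else stop("unknown species or observable: ", species)
  if (window[1] < min(tc$times) || window[2] > max(tc$times))
    stop("window outside trajectory range")
  sel <- tc$times >= window[1] & tc$times <= window[2]
  vw <- v[sel]; tw <- tc$times[sel]
  i <- which.max(vw)
  init <- v[which.min(tc$times)]
  list(peak = vw[i], time_of_peak = tw[i], level_at_end = vw[length(vw)],
       ratio_to_initial = if (init > 0) vw[i] / init else NA_real_)
}

#' Interpolate a trajectory column at arbitrary times
#' @keywords internal
timecourse_at <- function(tc, species, at, observable = TRUE) {
  v <- if (observable && species %in% colnames(tc$observables))
    tc$observables[, species] else tc$amounts[, species]
  stats::approx(tc$times, v, xout = at, rule = 1)$y
}
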