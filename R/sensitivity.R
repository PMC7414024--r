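# Scaled time-series sensitivity of IP3 to initial protein copy numbers,
# by central finite differences on the log scale.

#' IP3 sensitivity to initial protein concentrations
#'
#' Scaled sensitivity `(dIP3/IP3) / (dp/p)` of the IP3 time course with
#' respect to each protein's initial copy number, by a central finite
#' difference at `p (1 +/- delta)` with the delta factor defaulting to 0.2.
#' Entries where baseline IP3 is at or below the floor are reported as
#' undefined (`NA`) rather than propagating division noise.
#'
#' @param model a `pi_model` (activation scheme attached if post-activation
#'   sensitivities are wanted).
#' @param proteins character vector of protein species to perturb.
#' @param delta relative perturbation, in (0, 1).
#' @param times output times, seconds.
#' @param t_end horizon; defaults to `max(times)`.
#' @param floor molecules below which IP3 is treated as undefined.
#' @return a `pi_sensitivity`: matrix proteins x times of scaled
#'   sensitivities, with attributes `times`, `undefined` (logical matrix)
#'   and `peak` (per-protein sensitivity at the unperturbed IP3 peak time).
#' @export
ip3_sensitivity <- function(model, proteins = pi_key_proteins, delta = 0.2,
                            times = NULL, t_end = NULL, floor = 1) {
  if (delta <= 0 || delta >= 1) stop("delta must be in (0, 1)")
  missing_p <- setdiff(proteins, model$species$name)
  if (length(missing_p))
    stop("proteins absent from model: ", paste(missing_p, collapse = ", "))
  if (is.null(t_end))
    t_end <- if (!is.null(times)) max(times) else
      if (!is.null(model$activation)) model$activation$t_activation * 20 else
        2000
  if (is.null(times)) times <- seq(0, t_end, length.out = 101L)
  base <- simulate_model(model, t_end, times = times)
  ip3_0 <- base$observables[, "IP3"]
  S <- matrix(NA_real_, length(proteins), length(times),
              dimnames = list(proteins, signif(times, 6)))
  for (p in proteins) {
    p0 <- get_parameter(model, paste0("init:", p))
    up <- simulate_model(set_parameter(model, paste0("init:", p),
                                       p0 * (1 + delta)), t_end, times = times)
    dn <- simulate_model(set_parameter(model, paste0("init:", p),
                                       p0 * (1 - delta)), t_end, times = times)
    S[p, ] <- (up$observables[, "IP3"] - dn$observables[, "IP3"]) /
      (2 * delta * ip3_0)
  }
  undef <- matrix(rep(ip3_0 <= floor, each = length(proteins)),
                  nrow = length(proteins))
  S[undef] <- NA_real_
  ipk <- which.max(ip3_0)
  structure(S, class = c("pi_sensitivity", class(S)), times = times,
            undefined = undef, peak_time = times[ipk], peak = S[, ipk])
}

#' @export
print.pi_sensitivity <- function(x, ...) {
  cat("<pi_sensitivity> ", nrow(x), " proteins x ", ncol(x),
      " times; IP3 peak at t = ", attr(x, "peak_time"), " s\n", sep = "")
  print(round(attr(x, "peak"), 3))
  invisible(x)
}
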