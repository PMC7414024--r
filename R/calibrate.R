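# Scan-based calibration: log-grid parameter scans with a quantitative
# <= 20% acceptance rule against experimental time courses, staged model
# building, and the binding-protein-number prediction.

#' Specify a logarithmic parameter scan
#'
#' @param parameter a parameter id. Rate constants are addressed by id
#'   (`"k16"`, basal value) or with an explicit field (`"k14:activated"`);
#'   species initial amounts as `"init:PLCb"`; binding-protein totals as
#'   `"bp_total:PI45P2"` (the pair's lipid).
#' @param center central value of the scan.
#' @param span orders of magnitude each side of the center (default 4, the
#'   widest scan used in staged calibration).
#' @param points_per_decade grid density (log-spaced; >= 3).
#' @return a `pi_scan_spec`.
#' @export
scan_spec <- function(parameter, center, span = 4, points_per_decade = 5) {
  if (span <= 0) stop("span must be > 0")
  if (points_per_decade < 3) stop("points_per_decade must be >= 3")
  if (center <= 0) stop("center must be > 0 for a log-scale scan")
  structure(list(parameter = parameter, center = center, span = span,
                 points_per_decade = points_per_decade),
            class = "pi_scan_spec")
}

scan_grid <- function(spec) {
  # symmetric log offsets so the center value is always a grid point
  off <- seq(0, spec$span, by = 1 / spec$points_per_decade)
  spec$center * 10 ^ sort(unique(c(-off, off)))
}

#' Get or set a scannable parameter on a model
#'
#' @rdname set_parameter
#' @export
get_parameter <- function(model, parameter) {
  p <- parse_parameter(parameter)
  switch(p$kind,
    rate = {
      i <- match(p$id, model$rates$id)
      if (is.na(i)) stop("unknown rate constant: ", p$id)
      model$rates[[p$field]][i]
    },
    init = {
      i <- match(p$id, model$species$name)
      if (is.na(i)) stop("unknown species: ", p$id)
      model$species$initial[i]
    },
    bp_total = {
      i <- match(p$id, model$binding_pairs$lipid)
      if (is.na(i)) stop("no binding pair for lipid: ", p$id)
      model$binding_pairs$bp_total[i]
    })
}

#' @param model a `pi_model`.
#' @param parameter parameter id (see [scan_spec()]).
#' @param value new value. Setting a `bp_total` repartitions the pair's
#'   current total lipid pool between free and bound at binding equilibrium.
#' @rdname set_parameter
#' @export
set_parameter <- function(model, parameter, value) {
  p <- parse_parameter(parameter)
  switch(p$kind,
    rate = {
      i <- match(p$id, model$rates$id)
      if (is.na(i)) stop("unknown rate constant: ", p$id)
      model$rates[[p$field]][i] <- value
    },
    init = {
      i <- match(p$id, model$species$name)
      if (is.na(i)) stop("unknown species: ", p$id)
      model$species$initial[i] <- value
    },
    bp_total = {
      i <- match(p$id, model$binding_pairs$lipid)
      if (is.na(i)) stop("no binding pair for lipid: ", p$id)
      bp <- model$binding_pairs[i, ]
      sp <- match(c(bp$lipid, bp$bp, bp$complex), model$species$name)
      l_total <- sum(model$species$initial[sp[c(1, 3)]])
      kv <- stats::setNames(model$rates$basal, model$rates$id)
      cplx <- binding_equilibrium(l_total, value, kv[[bp$kon]], kv[[bp$koff]])
      model$species$initial[sp[1]] <- l_total - cplx
      model$species$initial[sp[2]] <- value - cplx
      model$species$initial[sp[3]] <- cplx
      model$binding_pairs$bp_total[i] <- value
    })
  model
}

parse_parameter <- function(parameter) {
  if (grepl("^init:", parameter))
    list(kind = "init", id = sub("^init:", "", parameter))
  else if (grepl("^bp_total:", parameter))
    list(kind = "bp_total", id = sub("^bp_total:", "", parameter))
  else if (grepl(":activated$", parameter))
    list(kind = "rate", id = sub(":activated$", "", parameter),
         field = "activated")
  else list(kind = "rate", id = sub(":basal$", "", parameter),
            field = "basal")
}

#' Maximum relative deviation of a simulation from a dataset
#'
#' For each observable in the dataset, the maximum over its time points of
#' `|sim - mean| / max(|mean|, floor)`, where the floor is
#' `floor_frac * max(|mean|)` for that observable, guarding near-zero
#' baselines such as pre-activation IP3. A parameter set whose worst
#' observable deviation exceeds 0.20 is rejected during calibration.
#'
#' @param tc a `pi_timecourse` (observable totals are compared).
#' @param data an experimental dataset: data.frame with columns
#'   `observable`, `time`, `mean` (and optionally `sem`, `n`).
#' @param floor_frac relative floor (default 0.01).
#' @return named numeric vector, one maximum relative deviation per
#'   observable.
#' @export
deviation <- function(tc, data, floor_frac = 0.01) {
  if (!nrow(data)) stop("empty dataset")
  if (max(data$time) > max(tc$times) || min(data$time) < min(tc$times))
    stop("dataset time points outside the simulated range")
  obs <- unique(data$observable)
  out <- stats::setNames(numeric(length(obs)), obs)
  for (o in obs) {
    d <- data[data$observable == o, ]
    sim <- timecourse_at(tc, o, d$time)
    fl <- floor_frac * max(abs(d$mean))
    out[o] <- max(abs(sim - d$mean) / pmax(abs(d$mean), fl))
  }
  out
}

#' Scan one parameter against a dataset
#'
#' Simulates the model at every point of the log grid, scores each point by
#' [deviation()] and returns results sorted by worst-observable deviation
#' (ties broken toward the smaller parameter value). A point is `accepted`
#' iff every observable deviates at most `threshold` (default 20%).
#'
#' @param model a `pi_model` (with its activation scheme attached if the
#'   dataset spans post-activation times).
#' @param spec a [scan_spec()].
#' @param data experimental dataset (see [deviation()]).
#' @param threshold acceptance threshold on the max relative deviation.
#' @param t_end simulation horizon; defaults to just past the last data time.
#' @param ... passed to [simulate_model()].
#' @return data.frame with `parameter`, `value`, one `dev_*` column per
#'   observable, `worst`, `accepted`; attribute `n_failed` counts grid points
#'   whose integration failed.
#' @export
scan_parameter <- function(model, spec, data, threshold = 0.20,
                           t_end = NULL, ...) {
  grid <- scan_grid(spec)
  get_parameter(model, spec$parameter)  # existence check
  if (is.null(t_end)) t_end <- max(data$time) * 1.0001
  obs <- unique(data$observable)
  rows <- vector("list", length(grid))
  n_failed <- 0L
  for (i in seq_along(grid)) {
    mi <- set_parameter(model, spec$parameter, grid[i])
    tc <- try(simulate_model(mi, t_end,
                             times = sort(unique(c(0, data$time, t_end))),
                             ...), silent = TRUE)
    if (inherits(tc, "try-error")) { n_failed <- n_failed + 1L; next }
    dv <- deviation(tc, data)
    rows[[i]] <- c(value = grid[i], dv, worst = max(dv))
  }
  if (all(vapply(rows, is.null, TRUE)))
    stop("all grid points failed to integrate")
  res <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  res <- data.frame(parameter = spec$parameter, res, check.names = FALSE)
  names(res)[match(obs, names(res))] <- paste0("dev_", obs)
  res$accepted <- res$worst <= threshold
  res <- res[order(res$worst, res$value), ]
  rownames(res) <- NULL
  attr(res, "n_failed") <- n_failed
  res
}

#' Predict a binding-protein copy number by scanning
#'
#' Scans a pair's `bp_total` on a log grid (and its on-rate on a coarse
#' secondary grid) against the lipid's experimental time course and returns
#' the `bp_total` of the best accepted fit; if no point is accepted the best
#' effort is returned with `accepted = FALSE`.
#'
#' @param model a `pi_model` with activation scheme.
#' @param lipid lipid of the pair (e.g. `"PI45P2"`).
#' @param data experimental dataset containing the lipid's time course.
#' @param span,points_per_decade grid for `bp_total` (default one decade each
#'   way at 5 points/decade).
#' @param kon_factors coarse multipliers for the pair's on-rate.
#' @param center scan center; defaults to the model's current `bp_total`.
#' @param threshold acceptance threshold.
#' @return list with `bp_total`, `kon_factor`, `worst`, `accepted`, and the
#'   full scan table `results`.
#' @export
scan_binding_protein_number <- function(model, lipid, data, span = 1,
                                        points_per_decade = 5,
                                        kon_factors = c(0.1, 1, 10),
                                        center = NULL, threshold = 0.20) {
  i <- match(lipid, model$binding_pairs$lipid)
  if (is.na(i)) stop("no binding pair for lipid: ", lipid)
  if (!lipid %in% data$observable)
    stop("dataset lacks the lipid's time course: ", lipid)
  if (is.null(center)) center <- model$binding_pairs$bp_total[i]
  kon_id <- model$binding_pairs$kon[i]
  kon0 <- get_parameter(model, kon_id)
  all_res <- list()
  for (f in kon_factors) {
    mf <- set_parameter(model, kon_id, kon0 * f)
    res <- scan_parameter(mf, scan_spec(paste0("bp_total:", lipid), center,
                                        span, points_per_decade),
                          data, threshold = threshold)
    res$kon_factor <- f
    all_res[[as.character(f)]] <- res
  }
  res <- do.call(rbind, all_res)
  res <- res[order(res$worst, res$value, abs(log(res$kon_factor))), ]
  rownames(res) <- NULL
  list(bp_total = res$value[1], kon_factor = res$kon_factor[1],
       worst = res$worst[1], accepted = res$accepted[1], results = res)
}

# Parameters fitted at each staged-calibration iteration. Stages 1-2 work on
# the reduced lipid network (binding pairs and PLC-product reactions
# disabled), stage 3 adds the binding pairs, stage 4 the IP3 -> IPx -> Ins
# and DAG/PA branches.
stage_params <- list(
  `1` = c("k16", "k14", "k15", "k17"),
  `2` = c("k16:activated", "k14:activated", "k15:activated"),
  `3` = c("bp_total:PI45P2", "bp_total:PI4P"),
  `4` = c("k_plcb_act", "k_ip3_rm", "k_ipx_ins", "k_dgk")
)

stage_observables <- list(
  `1` = c("PI", "PI4P", "PI45P2"),
  `2` = c("PI", "PI4P", "PI45P2"),
  `3` = c("PI4P", "PI45P2"),
  `4` = c("IP3", "Ins", "DAG", "PA")
)

#' One iteration of staged calibration
#'
#' Reproduces the staged, scan-based model-building workflow as a staged
#' partition of the parameter space and data: stage 1 fits the basal lipid
#' synthesis/recycling constants against the lipid observables; stage 2 the
#' activated (primed) constants; stage 3 the binding-protein copy numbers;
#' stage 4 the PLC-product branch (IP3 removal, the slow IPx -> Ins step,
#' DAG/PA rates) against the second-messenger observables. Parameters fixed
#' by earlier stages are frozen; each stage scans its parameters
#' coordinate-wise with one refinement pass.
#'
#' @param stage integer 1..4.
#' @param data experimental dataset covering the stage's observables.
#' @param model the model carrying all values fixed so far. For stages > 1
#'   this must be the result of the previous stage (enforced).
#' @param span,points_per_decade scan grid (default span 1 decade for
#'   refinement efficiency; pass 4 for the full initial search).
#' @param threshold acceptance threshold.
#' @param force_direct_ins if TRUE at stage 4, IP3 is converted to Ins by a
#'   single direct reaction (the IPx intermediate is bypassed), for testing
#'   the necessity of the two-step removal.
#' @return the model with the stage's parameters set to their best grid
#'   values; attributes `stage`, `fit` (per-parameter best rows) and
#'   `accepted`.
#' @export
fit_iteration <- function(stage, data, model, span = 1,
                          points_per_decade = 5, threshold = 0.20,
                          force_direct_ins = FALSE) {
  stage <- as.integer(stage)
  if (!stage %in% 1:4) stop("stage must be 1..4")
  prev <- attr(model, "stage")
  if (stage > 1 && (is.null(prev) || prev != stage - 1L))
    stop("stage ", stage, " requires the result of stage ", stage - 1L,
         " (stages must run in order)")
  work <- model
  if (force_direct_ins && stage == 4) {
    ids <- vapply(work$reactions, `[[`, "", "id")
    work$reactions[[which(ids == "ip3_removal")]]$products <- c(Ins = 1)
    work$rates$basal[work$rates$id == "k_ipx_ins"] <- 1e-30
  }
  obs <- intersect(stage_observables[[as.character(stage)]],
                   unique(data$observable))
  if (!length(obs)) stop("dataset lacks the stage's observables")
  d <- data[data$observable %in% obs, ]
  params <- stage_params[[as.character(stage)]]
  if (force_direct_ins && stage == 4) params <- setdiff(params, "k_ipx_ins")
  fits <- list()
  for (pass in 1:2) {                    # coordinate scans + one refinement
    for (p in params) {
      center <- get_parameter(work, p)
      if (center <= 0) center <- 1e-9
      sp <- scan_spec(p, center, span = if (pass == 1) span else 0.5,
                      points_per_decade = points_per_decade)
      res <- scan_parameter(work, sp, d, threshold = threshold)
      work <- set_parameter(work, p, res$value[1])
      fits[[p]] <- res[1, ]
    }
  }
  # write fitted values back onto the full (unreduced) model
  for (p in params) model <- set_parameter(model, p, get_parameter(work, p))
  fit <- do.call(rbind, fits)
  structure(model, stage = stage, fit = fit,
            accepted = all(fit$accepted))
}

#' Full staged calibration with a final restart pass
#'
#' Runs stages 1-4 in order, then — mirroring the workflow in which a
#' rejected parameter set restarts the full analysis — polishes every staged
#' parameter with narrow, dense coordinate scans over the complete dataset
#' until the acceptance rule is met or the pass budget is exhausted.
#'
#' @param data experimental dataset covering all observables.
#' @param model starting `pi_model` (activation scheme attached).
#' @param threshold acceptance threshold.
#' @param polish_passes maximum number of restart passes.
#' @param span,points_per_decade stage-scan grid (see [fit_iteration()]).
#' @return the calibrated model; attributes `accepted` and `worst`.
#' @export
run_staged_calibration <- function(data, model, threshold = 0.20,
                                   polish_passes = 2, span = 1,
                                   points_per_decade = 5) {
  m <- model
  for (s in 1:4)
    m <- fit_iteration(s, data, m, span = span,
                       points_per_decade = points_per_decade,
                       threshold = threshold)
  params <- unlist(stage_params)
  final_worst <- function(m) {
    tc <- simulate_model(m, max(data$time) * 1.0001,
                         times = sort(unique(c(0, data$time,
                                               max(data$time) * 1.0001))))
    max(deviation(tc, data))
  }
  worst <- final_worst(m)
  for (pass in seq_len(polish_passes)) {
    if (worst <= threshold) break
    for (p in params) {
      res <- scan_parameter(m, scan_spec(p, get_parameter(m, p), span = 0.4,
                                         points_per_decade = 10),
                            data, threshold = threshold)
      m <- set_parameter(m, p, res$value[1])
    }
    worst <- final_worst(m)
  }
  structure(m, stage = 4L, accepted = worst <= threshold, worst = worst)
}
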