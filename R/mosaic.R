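# Exhaustive mix-and-match of protein copy numbers between two source
# proteomes across the 12 key proteins, with rule-based classification of
# the resulting dynamics against a reference simulation.

#' Behaviour classifier configuration
#'
#' An observable's behaviour is "correct" iff (i) its pre-activation drift is
#' below `pre_drift_tol` (relative to its initial level, with a floor of
#' `floor_frac` of the reference's maximum for near-zero baselines), (ii) the
#' direction of its post-activation response (rise, fall, or flat within
#' `direction_tol`) matches the reference, and (iii) the magnitude of its
#' peak (or trough) change from the pre-activation baseline is within
#' `fold_band`-fold of the reference's. The headline summary is reported
#' across 3-, 5- and 10-fold bands; 5-fold is the default.
#'
#' @param pre_drift_tol relative pre-activation drift tolerated (default 0.10).
#' @param fold_band symmetric fold band on the response magnitude (default 5).
#' @param direction_tol relative change below which a response counts as flat.
#' @param floor_frac floor for relative comparisons on near-zero baselines,
#'   as a fraction of the reference observable's maximum.
#' @return a list of class `pi_classifier_config`.
#' @export
classifier_config <- function(pre_drift_tol = 0.10, fold_band = 5,
                              direction_tol = 0.10, floor_frac = 0.01) {
  if (fold_band <= 1) stop("fold_band must exceed 1")
  structure(list(pre_drift_tol = pre_drift_tol, fold_band = fold_band,
                 direction_tol = direction_tol, floor_frac = floor_frac),
            class = "pi_classifier_config")
}

# Per-observable response features on a common grid: pre-activation drift,
# and the signed up/down excursions from the pre-activation baseline.
behaviour_features <- function(tc, t_activation,
                               observables = pi_observables) {
  pre <- tc$times <= t_activation
  post <- tc$times >= t_activation
  feats <- lapply(observables, function(o) {
    if (!o %in% colnames(tc$observables)) stop("missing observable: ", o)
    v <- tc$observables[, o]
    if (all(is.na(v))) stop("missing observable: ", o)
    base <- v[max(which(pre))]
    list(initial = v[1], baseline = base,
         drift = max(abs(v[pre] - v[1])),
         up = max(v[post] - base), down = max(base - v[post]))
  })
  names(feats) <- observables
  feats
}

classify_features <- function(f, fr, config) {
  floor <- config$floor_frac * max(fr$baseline + fr$up, fr$baseline, 1)
  drift_ok <- f$drift <= config$pre_drift_tol * max(f$initial, floor)
  dir_of <- function(x) {
    amp <- max(x$up, x$down)
    if (amp <= config$direction_tol * max(x$baseline, floor)) "flat"
    else if (x$up >= x$down) "rise" else "fall"
  }
  d <- dir_of(f); dr <- dir_of(fr)
  dir_ok <- identical(d, dr)
  mag_ok <- TRUE
  if (dir_ok && dr != "flat") {
    amp <- if (dr == "rise") f$up else f$down
    ampr <- if (dr == "rise") fr$up else fr$down
    mag_ok <- amp >= ampr / config$fold_band && amp <= ampr * config$fold_band
  }
  drift_ok && dir_ok && mag_ok
}

#' Classify a trajectory's behaviour against a reference
#'
#' Applies the three-rule classifier (pre-activation stability, response
#' direction, response-magnitude fold band) per monitored observable. The
#' overall verdict is incorrect if any observable is incorrect.
#'
#' @param tc candidate `pi_timecourse`.
#' @param reference reference `pi_timecourse` on a grid spanning the same
#'   pre- and post-activation phases.
#' @param t_activation activation time shared by both trajectories.
#' @param config a [classifier_config()].
#' @param observables observables to judge.
#' @return list with `per_observable` (named logical, TRUE = correct) and
#'   `overall`.
#' @export
classify_behaviour <- function(tc, reference, t_activation,
                               config = classifier_config(),
                               observables = pi_observables) {
  f <- behaviour_features(tc, t_activation, observables)
  fr <- behaviour_features(reference, t_activation, observables)
  per <- vapply(observables, function(o)
    classify_features(f[[o]], fr[[o]], config), TRUE)
  list(per_observable = per, overall = all(per))
}

#' Enumerate all mix-and-match combinations of two proteomes
#'
#' Exhaustively enumerates the 2^12 = 4096 assignments of the 12 key
#' proteins to source A or source B (lexicographic over the fixed protein
#' order of [pi_key_proteins]; bit i set means protein i is taken from B),
#' simulates each combination at the given geometry and activation design,
#' and classifies every monitored observable against the reference
#' behaviour. Failed integrations are counted incorrect and flagged.
#'
#' @param core calibrated reference `pi_model`.
#' @param source_a,source_b complete proteomes ([proteome_table()] or named
#'   vectors) for the 12 key proteins.
#' @param reference reference `pi_timecourse` (e.g. the source-A cell
#'   simulated on the same design).
#' @param geometry cell geometry (default nucleated).
#' @param receptor_count receptors (default 85,000).
#' @param scheme activation scheme (default activation at 1000 s into a
#'   5000 s horizon).
#' @param t_end simulation horizon.
#' @param config primary [classifier_config()].
#' @param bands fold bands at which the summary fraction is also reported.
#' @param proteins the proteins mixed between the sources (default: the 12
#'   key proteins, giving the canonical 4096 enumeration).
#' @param sample_n if non-NULL and smaller than `2^length(proteins)`, a
#'   seeded random subset of assignments of this size is used instead of the
#'   exhaustive enumeration (for larger protein sets).
#' @param seed seed for the sampling mode.
#' @param progress print a progress line every 512 combinations.
#' @param atol,rtol solver tolerances for the scan's integrations; the
#'   defaults are looser than single-run defaults (amounts at nucleated
#'   scale are of order 1e6-1e8 molecules, so 0.01 molecule absolute
#'   tolerance is far below resolution).
#' @return list with `n_total`, `n_incorrect`, `fraction_incorrect`,
#'   `per_observable` incorrect fractions, `band_fractions` (named by fold
#'   band), `verdicts` (data.frame with bitmask and per-observable verdicts)
#'   and `n_failed`.
#' @export
mix_and_match <- function(core, source_a, source_b, reference,
                          geometry = nucleated_cell_geometry(),
                          receptor_count = 85000,
                          scheme = activation_scheme(t_activation = 1000,
                                                     receptor_count = 85000),
                          t_end = 5000, config = classifier_config(),
                          bands = c(3, 5, 10), progress = FALSE,
                          atol = 1e-2, rtol = 1e-6,
                          proteins = pi_key_proteins, sample_n = NULL,
                          seed = 1L) {
  pa <- if (is.data.frame(source_a)) proteome_vector(source_a) else source_a
  pb <- if (is.data.frame(source_b)) proteome_vector(source_b) else source_b
  for (nm in c("A", "B")) {
    pv <- if (nm == "A") pa else pb
    gaps <- setdiff(pi_key_proteins, names(pv)[!is.na(pv)])
    if (length(gaps)) stop("source ", nm, " missing: ",
                           paste(gaps, collapse = ", "))
  }
  base <- rescale_model(core, geometry, pa, receptor_count)
  # every combination starts from the reference cell's homeostatic pools;
  # only the 12 protein copy numbers vary with the assignment
  base <- set_initial_state(base, nonprotein_state(reference))
  base <- apply_activation(base, scheme)
  times <- reference$times
  fr <- behaviour_features(reference, scheme$t_activation)
  nprot <- length(proteins)
  masks <- 0:(2L ^ nprot - 1L)
  if (!is.null(sample_n) && sample_n < length(masks))
    masks <- with_seed(seed, sort(sample(masks, sample_n)))
  n_total <- length(masks)
  sp_idx <- match(proteins, base$species$name)
  bits <- t(vapply(masks, function(m)
    as.integer(intToBits(m))[seq_len(nprot)], integer(nprot)))
  feats_list <- vector("list", n_total)
  failed <- logical(n_total)
  for (i in seq_len(n_total)) {
    take_b <- bits[i, ] == 1L
    m <- base
    m$species$initial[sp_idx] <- ifelse(take_b, pb[proteins], pa[proteins])
    tc <- try(simulate_model(m, t_end, times = times, atol = atol,
                             rtol = rtol), silent = TRUE)
    if (inherits(tc, "try-error")) failed[i] <- TRUE
    else feats_list[[i]] <- behaviour_features(tc, scheme$t_activation)
    if (progress && i %% 512L == 0L)
      message("mix_and_match: ", i, "/", n_total)
  }
  judge <- function(cfg) {
    t(vapply(seq_len(n_total), function(i) {
      if (failed[i]) return(stats::setNames(rep(FALSE, length(pi_observables)),
                                            pi_observables))
      vapply(pi_observables, function(o)
        classify_features(feats_list[[i]][[o]], fr[[o]], cfg), TRUE)
    }, stats::setNames(logical(length(pi_observables)), pi_observables)))
  }
  per <- judge(config)
  overall <- apply(per, 1L, all)
  band_fractions <- vapply(bands, function(b) {
    cfg <- config; cfg$fold_band <- b
    mean(!apply(judge(cfg), 1L, all))
  }, 0)
  names(band_fractions) <- paste0("fold_", bands)
  verdicts <- data.frame(mask = masks, per, overall = overall,
                         failed = failed, check.names = FALSE)
  if (any(failed)) message(sum(failed), " combinations failed to integrate")
  list(n_total = n_total, n_incorrect = sum(!overall),
       fraction_incorrect = mean(!overall),
       per_observable = 1 - colMeans(per),
       band_fractions = band_fractions,
       verdicts = verdicts, n_failed = sum(failed))
}
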