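# Seeded synthetic-data generation: pseudo experimental time courses
# emulating collated thrombin-stimulation datasets (n replicates with SEM)
# and pseudo proteome tables with controlled between-cell-type variation.

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else on.exit(rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(code)
}

#' Define a synthetic ground truth
#'
#' Couples a generating model with a multiplicative log-normal noise level
#' and a seed; regeneration with the same seed is bit-identical.
#'
#' @param model the generating `pi_model`.
#' @param noise_sd standard deviation of the log-normal replicate noise on
#'   the natural-log scale (>= 0). The noise factor is mean-corrected
#'   (`exp(sd * z - sd^2 / 2)`) so replicate means are unbiased.
#' @param seed integer seed.
#' @return a list of class `pi_truth`.
#' @export
synthetic_truth <- function(model, noise_sd = 0.15, seed = 1L) {
  if (noise_sd < 0) stop("noise sd must be >= 0")
  structure(list(model = model, noise_sd = noise_sd, seed = as.integer(seed)),
            class = "pi_truth")
}

#' Generate pseudo experimental time courses
#'
#' Simulates the truth model, then draws `n` multiplicative log-normal
#' replicates per observable and time point and reports their mean and SEM,
#' emulating collated stimulated-platelet datasets (default n = 10).
#'
#' @param truth a [synthetic_truth()].
#' @param observables observables to report.
#' @param times sampling times, seconds, within the simulation horizon.
#' @param n replicates per point (>= 1).
#' @param t_end simulation horizon; defaults to just past `max(times)`.
#' @return data.frame with columns `observable`, `time`, `mean`, `sem`, `n`.
#' @export
generate_timecourses <- function(truth, observables = pi_observables,
                                 times, n = 10, t_end = NULL) {
  stopifnot(inherits(truth, "pi_truth"))
  if (n < 1) stop("n must be >= 1")
  if (is.null(t_end)) t_end <- max(times) * 1.0001
  if (max(times) > t_end || min(times) < 0)
    stop("sampling times outside the simulation horizon")
  tc <- simulate_model(truth$model, t_end,
                       times = sort(unique(c(0, times, t_end))))
  sd <- truth$noise_sd
  with_seed(truth$seed, {
    out <- lapply(observables, function(o) {
      v <- timecourse_at(tc, o, times)
      reps <- matrix(v, n, length(times), byrow = TRUE) *
        exp(sd * matrix(stats::rnorm(n * length(times)), n) - sd^2 / 2)
      data.frame(observable = o, time = times, mean = colMeans(reps),
                 sem = apply(reps, 2, stats::sd) / sqrt(n), n = n,
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, out)
  })
}

#' Generate a pseudo proteome table
#'
#' Multiplies each copy number of a template proteome by an independent
#' log-normal factor (`meanlog = 0`, median-preserving), emulating
#' between-cell-type variation in protein abundance; `fold_sd` is the
#' standard deviation of the natural-log fold change.
#'
#' @param template named copies vector or [proteome_table()].
#' @param fold_sd log-scale fold standard deviation (>= 0).
#' @param seed integer seed (deterministic).
#' @param cell_type label for the generated table.
#' @return a [proteome_table()] with provenance `native`.
#' @export
generate_proteome <- function(template, fold_sd, seed = 1L,
                              cell_type = "synthetic") {
  if (fold_sd < 0) stop("fold_sd must be >= 0")
  pv <- if (is.data.frame(template)) proteome_vector(template) else template
  with_seed(seed, {
    f <- exp(fold_sd * stats::rnorm(length(pv)))
    proteome_table(cell_type, stats::setNames(unname(pv) * f, names(pv)))
  })
}
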