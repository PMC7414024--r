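# Receptor-number titration: IP3 output as a function of the number of
# Gq-coupled receptors activated, modelling thrombin (+ secreted TxA2/ADP),
# TxA2 + secreted ADP, and ADP-only stimulation.

#' Receptor-number titration of IP3 output
#'
#' Simulates the model under the standard activation design for each
#' receptor count and reports the IP3 peak, its time, and the peak ratio to
#' the largest-receptor-number condition. The defaults are the platelet
#' ligand panel: RGq = 5000 (thrombin with secondary TxA2/ADP signalling),
#' 1650 (TxA2 with secreted ADP) and 150 (ADP alone).
#'
#' @param model unactivated `pi_model` (the calibrated platelet model).
#' @param receptor_counts RGq values to titrate.
#' @param t_activation activation time, seconds.
#' @param t_end horizon.
#' @param ... passed to [activation_scheme()] (termination options).
#' @return data.frame with `rgq`, `ip3_peak`, `t_peak`, `peak_ratio`
#'   (relative to the largest count).
#' @export
run_receptor_titration <- function(model, receptor_counts = c(150, 1650, 5000),
                                   t_activation = 100, t_end = 2000, ...) {
  rows <- lapply(receptor_counts, function(rgq) {
    m <- apply_activation(model, activation_scheme(
      t_activation = t_activation, receptor_count = rgq, ...))
    tc <- simulate_model(m, t_end,
                         times = sort(unique(c(
                           seq(0, t_end, length.out = 201L),
                           seq(t_activation, min(t_activation + 300, t_end),
                               length.out = 301L)))))
    s <- summarize_timecourse(tc, "IP3", c(t_activation, t_end))
    data.frame(rgq = rgq, ip3_peak = s$peak, t_peak = s$time_of_peak)
  })
  out <- do.call(rbind, rows)
  out$peak_ratio <- out$ip3_peak / out$ip3_peak[which.max(out$rgq)]
  out
}
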