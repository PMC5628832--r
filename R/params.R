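#' Inference parameters for the two likelihood-ratio tests
#'
#' @param p1 significance threshold of the pairwise link test (Test 1).
#' @param p2 significance threshold of the directness test (Test 2).
#' @param epsilon pseudo-weight replacing 0/1 in truth-table constraints so
#'   that a single violated definite output does not send the log-likelihood
#'   to minus infinity. Decreasing it sharpens perfectly satisfied functions
#'   and can slightly increase the number of reported links.
#' @param tau_min,tau_max delay search range, in sampling intervals. Use
#'   `tau_min = 0` to allow co-regulation (zero-lag) links.
#' @param chisq_df degrees of freedom of the chi-square approximation to the
#'   2 log R statistic. The default of 1 (one constrained transition pattern
#'   added by the linked model) is anti-conservative because the statistic is
#'   maximized over functions and delays; raise it or lower `p1`/`p2` for
#'   stricter screening.
#' @param adjust p-value adjustment method passed to [stats::p.adjust()]
#'   applied to the Test-1 scan; `"none"` (default) thresholds raw p-values.
#' @return List of validated parameters, class `bfn_params`.
#' @export
bfn_params <- function(p1 = 0.05, p2 = 0.05, epsilon = 0.005,
                       tau_min = 0L, tau_max = 5L, chisq_df = 1L,
                       adjust = "none") {
  stopifnot(p1 > 0, p1 <= 1, p2 > 0, p2 <= 1,
            epsilon > 0, epsilon < 0.5,
            tau_min >= 0, tau_max >= tau_min,
            chisq_df >= 1)
  structure(list(p1 = p1, p2 = p2, epsilon = epsilon,
                 tau_min = as.integer(tau_min), tau_max = as.integer(tau_max),
                 chisq_df = as.integer(chisq_df), adjust = adjust),
            class = "bfn_params")
}
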