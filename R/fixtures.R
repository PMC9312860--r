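#' Hand-checkable fixture datasets with embedded oracle values
#'
#' Tiny datasets used across the test-suite, each carrying independently
#' computed oracle values: `aj6`, a 6-record competing-risk example with
#' hand-computed Aalen-Johansen cumulative incidences and censoring-KM
#' weights; `lik12`, a 12-record single-covariate example whose Fine-Gray
#' coefficient was found by brute-force grid search of the IPCW-weighted
#' partial likelihood; and `dca10`, a 10-record uncensored decision-curve
#' example with hand-computed net benefit at three thresholds.
#'
#' @return named list of fixtures; each has `data` and `oracle`.
#' @export
fixture_suite <- function() {
  aj6 <- list(
    data = data.frame(
      time = c(1, 2, 3, 4, 5, 6),
      cause = c(1, 2, 0, 1, 2, 0)
    ),
    oracle = list(
      # cause-1 CIF: 1/6 on [1,4), 7/18 from t = 4
      cif_at = c(`1` = 1 / 6, `3.5` = 1 / 6, `4` = 7 / 18, `6` = 7 / 18),
      # censoring KM: G = 1 before 3, 3/4 on [3,6), 0 from 6
      G_at = c(`2.9` = 1, `3` = 0.75, `5.9` = 0.75),
      # IPCW weight of the t=2 competing death at the t=4 event time
      w_comp2_at4 = 0.75,
      # weight of the t=5 competing death just after 5: G(t-)/G(5-) = 1
      w_comp5_at5.5 = 1
    )
  )

  lik12 <- list(
    data = data.frame(
      x = c(0, 0, 0, 0, 0, 0, 1, 1, 1, 1, 1, 1),
      time = c(1.1, 2.3, 3.0, 4.5, 5.2, 6.1, 0.8, 1.7, 2.9, 3.6, 4.8, 5.9),
      cause = c(1, 0, 2, 1, 0, 2, 1, 1, 0, 2, 1, 0)
    ),
    oracle = list(
      # brute-force maximizer of the weighted partial likelihood (grid
      # search refined by golden-section to 1e-10; frozen)
      coefficient = 0.5008216624
    )
  )

  dca10 <- list(
    data = data.frame(
      risk = c(0.05, 0.10, 0.15, 0.20, 0.30, 0.35, 0.40, 0.50, 0.60, 0.70),
      time = c(12, 12, 12, 12, 2, 12, 3, 12, 4, 5),
      cause = c(0, 0, 0, 0, 1, 0, 1, 0, 1, 1)
    ),
    oracle = list(
      # hand computation: TP/n - FP/n * t/(1-t) at horizon 10
      nb = c(`0.1` = 0.4 - 0.5 * (0.1 / 0.9),
             `0.25` = 0.4 - 0.2 * (0.25 / 0.75),
             `0.4` = 0.3 - 0.1 * (0.4 / 0.6))
    )
  )

  list(aj6 = aj6, lik12 = lik12, dca10 = dca10)
}
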