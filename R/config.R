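#' Analysis run configuration
#'
#' Bundles the thresholds used across the pipeline.  Defaults follow the
#' settings of the study design this package operationalises: STRING-style
#' confidence cutoff 0.9, permutation tests of 1,000 repetitions, proximity
#' significance at Z < -1.5 and FDR < 0.05, differential-entropy calls at
#' FDR < 0.05 with an absolute median shift above 0.03 nats, and MCODE
#' cluster scores of at least 5.
#'
#' @param confidence_cutoff minimum edge confidence retained when reading a
#'   scored scaffold, in \[0, 1\].
#' @param n_permutations number of degree-matched permutations for the
#'   proximity null.
#' @param z_threshold proximity Z-score below which a pair is called proximal.
#' @param fdr_threshold Benjamini-Hochberg FDR threshold shared by the
#'   differential-entropy and proximity tests.
#' @param median_shift_threshold minimum absolute difference in median local
#'   entropy (nats) for a differential-entropy call.
#' @param location_stat statistic used for the entropy shift filter,
#'   \code{"median"} (default) or \code{"mean"}.
#' @param mcode_score_min minimum MCODE cluster score reported.
#' @param rng_seed integer seed used by stochastic stages.
#'
#' @return A list of class \code{"agenet_config"}.
#' @export
run_config <- function(confidence_cutoff = 0.9,
                       n_permutations = 1000L,
                       z_threshold = -1.5,
                       fdr_threshold = 0.05,
                       median_shift_threshold = 0.03,
                       location_stat = c("median", "mean"),
                       mcode_score_min = 5,
                       rng_seed = 1L) {
  stopifnot(confidence_cutoff >= 0, confidence_cutoff <= 1,
            n_permutations >= 1,
            fdr_threshold > 0, fdr_threshold <= 1,
            median_shift_threshold >= 0,
            mcode_score_min >= 0)
  location_stat <- match.arg(location_stat)
  structure(list(confidence_cutoff = confidence_cutoff,
                 n_permutations = as.integer(n_permutations),
                 z_threshold = z_threshold,
                 fdr_threshold = fdr_threshold,
                 median_shift_threshold = median_shift_threshold,
                 location_stat = location_stat,
                 mcode_score_min = mcode_score_min,
                 rng_seed = as.integer(rng_seed)),
            class = "agenet_config")
}
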