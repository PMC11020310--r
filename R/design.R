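#' Full factorial chemostat sample design
#'
#' Builds the 2 nutrient-regime x 3 temperature x 5 replicate design used
#' throughout the package: continuous cultures grown under N-stress
#' (molar N:P input ratio 1.7) or P-stress (N:P input ratio 80) at 20, 24,
#' or 28 degrees C, with five replicate samplings per treatment.
#'
#' @param n_replicates Number of replicate samples per treatment cell
#'   (default 5).
#' @return A `data.frame` with one row per sample and columns `sample_id`,
#'   `nutrient_regime` (factor, `N_stress`/`P_stress`), `np_input` (molar
#'   N:P supply ratio), `temperature` (factor with levels 20, 24, 28) and
#'   `replicate`.
#' @examples
#' d <- make_design()
#' table(d$nutrient_regime, d$temperature)
#' @export
make_design <- function(n_replicates = 5) {
  stopifnot(n_replicates >= 1)
  d <- expand.grid(
    replicate       = seq_len(n_replicates),
    temperature     = c(20, 24, 28),
    nutrient_regime = c("N_stress", "P_stress"),
    KEEP.OUT.ATTRS  = FALSE,
    stringsAsFactors = FALSE
  )
  d$nutrient_regime <- factor(d$nutrient_regime,
                              levels = c("N_stress", "P_stress"))
  d$np_input <- ifelse(d$nutrient_regime == "N_stress", 1.7, 80)
  d$temperature <- factor(d$temperature, levels = c(20, 24, 28))
  d$sample_id <- sprintf("%s%s_%d",
                         substr(as.character(d$nutrient_regime), 1, 1),
                         as.character(d$temperature), d$replicate)
  stopifnot(!anyDuplicated(d$sample_id))
  d[, c("sample_id", "nutrient_regime", "np_input", "temperature",
        "replicate")]
}
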