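# Published constants of the index: feature order, normalization bounds,
# importance weights, mixing ratio, classification threshold, staging bins.

#' Canonical feature order
#'
#' All matrices, vectors and CSV columns handled by the package use this fixed
#' feature ordering: PSD, MD, RNFL_S, RNFL_I, RNFL_T, IOP.
#'
#' @return Character vector of the six feature names.
#' @export
igri_features <- function() {
  c("PSD", "MD", "RNFL_S", "RNFL_I", "RNFL_T", "IOP")
}

# Published min-max normalization bounds per feature (dB, dB, um, um, um, mmHg).
.DEFAULT_BOUNDS <- list(
  PSD    = c(0.95, 16.9),
  MD     = c(-24.1, 6.39),
  RNFL_S = c(6, 172),
  RNFL_I = c(0, 195),
  RNFL_T = c(20, 110),
  IOP    = c(5, 29)
)

# Features whose normalized value is reversed (1 - x) so that every coordinate
# is severity-aligned: lower MD and thinner RNFL mean more severe disease.
# Higher IOP is itself the risk direction, so IOP is not reversed.
.DEFAULT_REVERSED <- c("MD", "RNFL_S", "RNFL_I", "RNFL_T")

# Published gradient-boosting importance weights (sum exactly 1).
.DEFAULT_WEIGHTS <- c(
  PSD = 0.27, MD = 0.14, RNFL_S = 0.11, RNFL_I = 0.31, RNFL_T = 0.10,
  IOP = 0.07
)

.DEFAULT_BASE_RATIO <- 0.8
.DEFAULT_NNI_RATIO  <- 0.2
.DEFAULT_THRESHOLD  <- 0.36
.DEFAULT_K          <- 5L

# MD staging bins (dB): advanced strictly below `advanced`, intermediate on the
# closed interval [advanced, intermediate], early above `intermediate`.
.DEFAULT_STAGING_BINS <- c(intermediate = -5, advanced = -12)

# Loose physiological plausibility bounds used only by validation (never for
# scaling): values outside these are errors, values outside the normalization
# bounds merely warn and will clip.
.PLAUSIBLE_RANGE <- list(
  PSD    = c(0, 30),
  MD     = c(-40, 10),
  RNFL_S = c(0, 300),
  RNFL_I = c(0, 300),
  RNFL_T = c(0, 300),
  IOP    = c(1, 80)
)

.STAGE_LEVELS <- c("normal", "early", "intermediate", "advanced")

#' Round half away from zero
#'
#' Presentation rounding matching how the published tables print values
#' (base R `round()` is round-half-even).
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded vector.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
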