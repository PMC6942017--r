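#' Molecular-weight and assay constants
#'
#' Unit bridges used throughout the package. The antibody molecular weight
#' defaults to the IgG1 convention of 150 kDa. The soluble-receptor
#' molecular weight is back-derived from the population baseline pair
#' (0.45 nM, ~14 ng/mL), giving 14 / 0.45 = 31.1 kDa; it is a configuration
#' constant, not a measured quantity.
#'
#' @format Named numeric scalars.
#' @name unit_constants
NULL

#' @rdname unit_constants
#' @export
MW_MAB_KDA <- 150

#' @rdname unit_constants
#' @export
MW_SR_KDA <- 14 / 0.45 # ~31.1 kDa

#' @rdname unit_constants
#' @export
LLOQ_PK_NGML <- 75

#' Convert a weight-based dose to molar amount
#'
#' @param dose_mgkg dose in mg per kg body weight.
#' @param weight_kg body weight in kg.
#' @param mw_kda molecular weight in kDa.
#' @return Amount in nmol.
#' @examples
#' mgkg_to_nmol(1, 70, 150) # 466.67 nmol
#' @export
mgkg_to_nmol <- function(dose_mgkg, weight_kg, mw_kda) {
  stopifnot(all(dose_mgkg >= 0), all(weight_kg > 0))
  if (any(mw_kda <= 0)) stop("molecular weight must be positive")
  # mg -> nmol: mg / (kDa * 1000 g/mol) * 1e6 nmol/mmol = mg * 1000 / kDa
  dose_mgkg * weight_kg * 1000 / mw_kda
}

#' Convert between molar and mass concentration
#'
#' `nM_to_ngml()` and `ngml_to_nM()` are exact inverses:
#' ng/mL = nM x MW(kDa).
#'
#' @param conc_nM concentration in nmol/L.
#' @param conc_ngml concentration in ng/mL.
#' @param mw_kda molecular weight in kDa.
#' @export
nM_to_ngml <- function(conc_nM, mw_kda) {
  if (any(mw_kda <= 0)) stop("molecular weight must be positive")
  conc_nM * mw_kda
}

#' @rdname nM_to_ngml
#' @export
ngml_to_nM <- function(conc_ngml, mw_kda) {
  if (any(mw_kda <= 0)) stop("molecular weight must be positive")
  conc_ngml / mw_kda
}
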