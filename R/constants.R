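# Physical constants (CODATA / AME monoisotopic values, Da).

#' Mass of the proton in Da
#' @export
PROTON_MASS <- 1.00727646688

#' Mass difference between 13C and 12C in Da
#'
#' The dominant isotopologue spacing in organic small molecules; the m/z
#' spacing of the M+k peak is `k * ISOTOPE_SPACING / |charge|`.
#' @export
ISOTOPE_SPACING <- 1.0033548
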