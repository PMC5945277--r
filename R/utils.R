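#' Thermal energy at a given temperature
#'
#' Returns kT in kJ/mol at temperature `temperature` (Kelvin), using the
#' molar gas constant R = 0.0083144621 kJ/(mol K). At the default 300 K this
#' is 2.494 kJ/mol, the conversion factor used throughout for spring
#' constants given in kJ/(mol nm^2).
#'
#' @param temperature temperature in Kelvin.
#' @return kT in kJ/mol.
#' @export
kT_kJmol <- function(temperature = 300) 0.0083144621 * temperature

# Derive a stage sub-seed from a master seed; kept below 2^31.
derive_seed <- function(master_seed, offset) {
  (as.integer(master_seed) + 104729L * as.integer(offset)) %% 2147483647L
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_input <- function(...) stop(..., call. = FALSE)
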