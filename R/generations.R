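#' Generations elapsed under serial dilution
#'
#' In a serial-transfer batch culture, each cycle the population regrows by
#' the dilution factor, i.e. \eqn{\log_2(\mathrm{dilution})} doublings per
#' cycle. Nine daily 1:100 cycles are thus ~60 generations
#' (9 x 6.6439 = 59.79), five cycles ~30.
#'
#' @param n_cycles Number of transfer cycles (>= 0).
#' @param dilution Fold-dilution per cycle, >= 2 (less than one doubling per
#'   cycle is out of scope).
#' @return Real number of generations.
#' @examples
#' generations_elapsed(9, 100) # 59.79
#' @export
generations_elapsed <- function(n_cycles, dilution = 100) {
  if (any(n_cycles < 0)) abort("`n_cycles` must be >= 0.")
  if (any(dilution < 2)) abort("`dilution` must be >= 2 (at least one doubling per cycle).")
  n_cycles * log2(dilution)
}
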