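# Unit conversions. All mechanics work in SI (Pa, m, N); clinical units
# (mmHg, mm, um, kPa) appear only at I/O boundaries.

#' Convert pressures between mmHg and Pa
#'
#' The package uses SI units internally; clinical pressures are entered and
#' reported in mmHg. The conversion factor is 1 mmHg = 133.322 Pa.
#'
#' @param x numeric vector of pressures.
#' @return numeric vector in the target unit.
#' @examples
#' mmHg_to_Pa(120)
#' Pa_to_mmHg(mmHg_to_Pa(120))
#' @export
mmHg_to_Pa <- function(x) x * 133.322

#' @rdname mmHg_to_Pa
#' @export
Pa_to_mmHg <- function(x) x / 133.322
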