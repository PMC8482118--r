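#' SART protocol constants
#'
#' The Sustained Attention to Response Task presents the digits 1 to 9 in a
#' fixed repeating order; the participant presses a key for every digit (GO)
#' except the digit 3 (NO-GO), for which the response must be withheld. One
#' run of the nine digits is a *cycle*; the full administration repeats the
#' cycle 23 times, for 207 single-digit *presentations*. Each digit is shown
#' for 300 ms with an 800 ms inter-stimulus interval, so the task lasts about
#' four minutes. A perfect administration therefore contains
#' 8 x 23 = 184 recorded reaction times (correct GO presses) and 23
#' correctly withheld NO-GO presentations.
#'
#' @return A list of protocol constants: `n_cycles` (23), `n_digits` (9),
#'   `nogo_digit` (3), `n_presentations` (207), `n_go` (184),
#'   `n_go_per_cycle` (8), `stimulus_ms` (300), `isi_ms` (800).
#' @export
#' @examples
#' sart_protocol()$n_presentations # 207
sart_protocol <- function() {
  list(
    n_cycles = 23L,
    n_digits = 9L,
    nogo_digit = 3L,
    n_presentations = 207L,
    n_go = 184L,
    n_go_per_cycle = 8L,
    stimulus_ms = 300,
    isi_ms = 800
  )
}

# digit shown at each presentation (1..207), in protocol order
protocol_digits <- function() rep.int(1:9, 23)

# cycle index of each presentation
protocol_cycles <- function() rep(1:23, each = 9L)

# presentation columns that are GO / NO-GO
protocol_go_idx <- function() which(protocol_digits() != 3L)
protocol_nogo_idx <- function() which(protocol_digits() == 3L)

# within-cycle offsets (1..9) of the 8 GO digits
protocol_go_in_cycle <- function() c(1L, 2L, 4L, 5L, 6L, 7L, 8L, 9L)
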