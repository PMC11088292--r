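# Health-state space of the six-state CRC disease model.
#
# Progression is strictly to the next higher stage (stage jumps and stage
# regression carry no usable published probabilities and are excluded);
# stage IV is persistent. The two death states are absorbing.

#' Health states of the CRC surveillance model
#'
#' The model distinguishes the four CRC stages plus two absorbing death
#' states: death from general (all-cause, non-CRC) mortality and death from
#' CRC. Living patients can stay in their stage, progress to the immediately
#' next stage (stage IV excepted: it is persistent), or die of either cause.
#'
#' @return Character vector of the six state names, in model order.
#' @export
#' @examples
#' health_states()
health_states <- function() {
  c("stage_I", "stage_II", "stage_III", "stage_IV",
    "death_general", "death_crc")
}

# index helpers used throughout the engines
.STATES <- c("stage_I", "stage_II", "stage_III", "stage_IV",
             "death_general", "death_crc")
.LIVING <- 1:4
.STAGES <- c("I", "II", "III", "IV")
.GEN <- 5L
.CRC <- 6L

#' @rdname health_states
#' @return `living_states()` returns the four non-absorbing stage names.
#' @export
living_states <- function() .STATES[.LIVING]

.stage_index <- function(stage) {
  i <- match(stage, c(.STAGES, .STATES[.LIVING]))
  if (is.na(i)) stop("unknown stage: ", stage, call. = FALSE)
  ((i - 1L) %% 4L) + 1L
}
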