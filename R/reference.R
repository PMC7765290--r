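#' Per-joint overall-score SRMs from the sPsAMRIS development cohort
#'
#' The published per-joint standardized response means of the overall PsAMRIS
#' in the hand-MRI cohort from which the simplified instrument was originally
#' derived. Ranking these values by magnitude and keeping the top three joints
#' reproduces the published sPsAMRIS joint set \{MCP3, MCP4, PIP4\}
#' (|SRM| = 0.07 each).
#'
#' @return Named numeric vector of length 12, names in anatomical order.
#' @examples
#' sel <- select_joints(rank_joints(spsamris_reference_srms()), k = 3)
#' sel$selected # "MCP3" "MCP4" "PIP4"
#' @export
spsamris_reference_srms <- function() {
  c(MCP2 = -0.01, MCP3 = 0.07, MCP4 = -0.07, MCP5 = -0.03,
    PIP2 = -0.01, PIP3 = 0.00, PIP4 = -0.07, PIP5 = 0.00,
    DIP2 = 0.00, DIP3 = -0.01, DIP4 = 0.00, DIP5 = -0.03)
}
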