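# State space of the Markov model: 12 living diabetes states plus Death.

.STATE_NAMES <- c(
  "no_complications", "retinopathy", "nephropathy", "neuropathy", "chd",
  "blindness", "esrd", "lea",
  "nephropathy_chd", "neuropathy_chd", "retinopathy_chd",
  "neuropathy_nephropathy", "death"
)

.STATE_LABELS <- c(
  no_complications       = "Diabetes with no complications",
  retinopathy            = "Retinopathy",
  nephropathy            = "Nephropathy",
  neuropathy             = "Neuropathy",
  chd                    = "CHD",
  blindness              = "Blindness",
  esrd                   = "ESRD",
  lea                    = "LEA",
  nephropathy_chd        = "Nephropathy and CHD",
  neuropathy_chd         = "Neuropathy and CHD",
  retinopathy_chd        = "Retinopathy and CHD",
  neuropathy_nephropathy = "Neuropathy and nephropathy",
  death                  = "Death"
)

.LIVING_STATES <- .STATE_NAMES[.STATE_NAMES != "death"]
.DEATH <- "death"

# Complication composition of each living state.
.STATE_COMPLICATIONS <- list(
  no_complications       = character(0),
  retinopathy            = "retinopathy",
  nephropathy            = "nephropathy",
  neuropathy             = "neuropathy",
  chd                    = "CHD",
  blindness              = "blindness",
  esrd                   = "ESRD",
  lea                    = "LEA",
  nephropathy_chd        = c("nephropathy", "CHD"),
  neuropathy_chd         = c("neuropathy", "CHD"),
  retinopathy_chd        = c("retinopathy", "CHD"),
  neuropathy_nephropathy = c("neuropathy", "nephropathy")
)

# Directed complication transitions. `param` names the row of the parameter
# table supplying the annual probability; `adds` is the complication gained by
# the move, which is what the CGM relative risk reductions act on (NA where no
# risk reduction applies). The three CHD -> composite rows reuse the
# microvascular -> CHD probabilities, so a single drawn value drives both
# directions in the PSA.
.TRANSITIONS <- data.frame(
  from = c(
    "no_complications", "no_complications", "no_complications", "no_complications",
    "retinopathy", "retinopathy",
    "nephropathy", "nephropathy",
    "neuropathy", "neuropathy", "neuropathy",
    "chd", "chd", "chd"
  ),
  to = c(
    "retinopathy", "nephropathy", "neuropathy", "chd",
    "blindness", "retinopathy_chd",
    "esrd", "nephropathy_chd",
    "lea", "neuropathy_nephropathy", "neuropathy_chd",
    "retinopathy_chd", "nephropathy_chd", "neuropathy_chd"
  ),
  param = c(
    "p_nc_retinopathy", "p_nc_nephropathy", "p_nc_neuropathy", "p_nc_chd",
    "p_retinopathy_blindness", "p_retinopathy_chd",
    "p_nephropathy_esrd", "p_nephropathy_chd",
    "p_neuropathy_lea", "p_neuropathy_nephropathy", "p_neuropathy_chd",
    "p_retinopathy_chd", "p_nephropathy_chd", "p_neuropathy_chd"
  ),
  adds = c(
    "retinopathy", "nephropathy", "neuropathy", "chd",
    NA, "chd",
    NA, "chd",
    NA, "nephropathy", "chd",
    "retinopathy", "nephropathy", "neuropathy"
  ),
  stringsAsFactors = FALSE
)

#' Health states of the diabetes progression model
#'
#' The model tracks a type 1 diabetes cohort through 13 mutually exclusive
#' states: diabetes with no complications; four first complications
#' (retinopathy, nephropathy, neuropathy, coronary heart disease); four
#' terminal-complication states (blindness, end-stage renal disease,
#' lower-extremity amputation) and four two-complication composites; and
#' death. Composite states, blindness, ESRD and LEA permit no exit other than
#' death or remaining in place.
#'
#' @return A data frame with one row per state and columns `name` (identifier
#'   used throughout the package), `label` (display name), `complications`
#'   (comma-separated complication composition) and `is_death`.
#' @examples
#' health_states()
#' @export
health_states <- function() {
  data.frame(
    name = .STATE_NAMES,
    label = unname(.STATE_LABELS[.STATE_NAMES]),
    complications = vapply(
      .STATE_NAMES,
      function(s) {
        if (s == .DEATH) "" else paste(.STATE_COMPLICATIONS[[s]], collapse = ",")
      },
      character(1)
    ),
    is_death = .STATE_NAMES == .DEATH,
    row.names = NULL,
    stringsAsFactors = FALSE
  )
}

#' Complication transition structure
#'
#' The directed moves between living states that the model allows, with the
#' parameter supplying each annual probability and the complication the move
#' adds (the hook for the CGM relative risk reductions). From the CHD state
#' the moves into the three CHD composites reuse the corresponding
#' microvascular-to-CHD probabilities.
#'
#' @return A data frame with columns `from`, `to`, `param`, `adds`.
#' @export
state_transitions <- function() .TRANSITIONS
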