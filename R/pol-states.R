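#' Polarization states of the generator and analyzer
#'
#' The widefield P-SHG instrument prepares four incident polarization states
#' with a liquid-crystal variable retarder and probes the emitted SHG with
#' the same four states on the analyzer side: left circular (LCP,
#' quarter-wave), horizontal linear (HLP, half-wave), right circular (RCP,
#' three-quarter-wave) and vertical linear (VLP, full-wave).
#'
#' @return A data frame with columns `label` and `retardance` (in waves),
#'   one row per state, in the canonical order LCP, HLP, RCP, VLP.
#' @export
#' @examples
#' pol_states()
pol_states <- function() {
  data.frame(
    label = c("lcp", "hlp", "rcp", "vlp"),
    retardance = c(1 / 4, 1 / 2, 3 / 4, 1),
    stringsAsFactors = FALSE
  )
}

#' Enumerate the 16-state measurement scheme
#'
#' All combinations of polarization-state-generator (PSG) and
#' polarization-state-analyzer (PSA) states, PSG-major, each side in the
#' canonical order LCP, HLP, RCP, VLP. This fixed order defines the page
#' order of multi-page TIFF stacks and the layout of simulated datasets.
#'
#' @return A 16-row data frame with columns `psg` and `psa`.
#' @export
#' @examples
#' head(measurement_scheme())
measurement_scheme <- function() {
  st <- pol_states()$label
  data.frame(
    psg = rep(st, each = 4L),
    psa = rep(st, times = 4L),
    stringsAsFactors = FALSE
  )
}

# Jones vector of an incident state in the lab frame (x horizontal, y
# vertical, propagation along +z). Handedness convention: RCP = (1, i)/sqrt2,
# which carries Stokes s3 = +1 under s3 = -2 Im(Ex Ey*). The convention is
# arbitrary but used consistently by the simulator and the analyzer model.
jones_vector <- function(state) {
  switch(state,
    hlp = c(1 + 0i, 0 + 0i),
    vlp = c(0 + 0i, 1 + 0i),
    rcp = c(1 + 0i, 0 + 1i) / sqrt(2),
    lcp = c(1 + 0i, 0 - 1i) / sqrt(2),
    stop("unknown polarization state: ", state)
  )
}

# Unit Stokes direction (s1, s2, s3) of an analyzer state; a perfect
# analyzer transmits I = (s0 + shat . (s1,s2,s3)) / 2.
analyzer_stokes <- function(state) {
  switch(state,
    hlp = c(1, 0, 0),
    vlp = c(-1, 0, 0),
    rcp = c(0, 0, 1),
    lcp = c(0, 0, -1),
    stop("unknown polarization state: ", state)
  )
}

state_key <- function(psg, psa) paste(psg, psa, sep = "_")
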