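# Map functions relating recombination fraction r to map distance d (cM).

#' Convert recombination fraction to map distance
#'
#' Haldane (default): d = -50 ln(1 - 2r); assumes no crossover interference.
#' Kosambi: d = 25 ln((1 + 2r) / (1 - 2r)).
#'
#' @param r recombination fraction(s) in [0, 0.5); values at or above 0.4999
#'   are capped there for numerical stability.
#' @param map_function "haldane" or "kosambi".
#' @return distance(s) in centiMorgans.
#' @export
rf_to_distance <- function(r, map_function = c("haldane", "kosambi")) {
  map_function <- match.arg(map_function)
  r <- pmin(pmax(r, 0), 0.4999)
  switch(map_function,
    haldane = -50 * log(1 - 2 * r),
    kosambi = 25 * log((1 + 2 * r) / (1 - 2 * r)))
}

#' Convert map distance to recombination fraction
#'
#' Inverse of [rf_to_distance()]: Haldane r = (1 - exp(-2d/100)) / 2,
#' Kosambi r = tanh(2d/100) / 2.
#'
#' @param d distance(s) in cM, non-negative.
#' @inheritParams rf_to_distance
#' @return recombination fraction(s) in [0, 0.5).
#' @export
distance_to_rf <- function(d, map_function = c("haldane", "kosambi")) {
  map_function <- match.arg(map_function)
  switch(map_function,
    haldane = (1 - exp(-2 * d / 100)) / 2,
    kosambi = tanh(2 * d / 100) / 2)
}
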