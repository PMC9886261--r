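#' MET lookup table
#'
#' Default MET (metabolic equivalent of task) values per activity class and
#' intensity band of the magnitude SD `sigma`:
#' inactive 1; light (active, non-periodic) 1.5 when `sigma < 0.025` else
#' 1.8; periodic low 2 (`sigma <= 0.09`), moderate 3.3
#' (`0.09 < sigma <= 0.2`), brisk 5 (`sigma > 0.2`); weightlessness
#' segments (airborne activity, MET "> 6") default to 7. Boundary values
#' fall in the lower band.
#'
#' @param weightless_met MET assigned to weightlessness segments (default 7).
#' @return A list of class `met_table` with the band edges and values.
#' @export
met_table <- function(weightless_met = 7) {
  structure(list(inactive = 1,
                 light_low = 1.5, light_high = 1.8, light_edge = 0.025,
                 periodic_low = 2, periodic_moderate = 3.3, periodic_brisk = 5,
                 periodic_edges = c(0.09, 0.2),
                 weightless = weightless_met),
            class = "met_table")
}

met_of <- function(segments, met) {
  m <- numeric(nrow(segments))
  m[segments$state == "inactive"] <- met$inactive
  li <- segments$state == "active" & segments$type == "light"
  m[li] <- ifelse(segments$sigma[li] < met$light_edge,
                  met$light_low, met$light_high)
  pe <- segments$state == "active" & segments$type == "periodic"
  m[pe] <- ifelse(segments$sigma[pe] <= met$periodic_edges[1], met$periodic_low,
                  ifelse(segments$sigma[pe] <= met$periodic_edges[2],
                         met$periodic_moderate, met$periodic_brisk))
  m[segments$type == "weightless"] <- met$weightless
  m
}

#' Energy expenditure (G9)
#'
#' Burned calories per labeled segment are `MET * duration(h) * weight(kg)`;
#' G9 sums them over the day. With `normalize = TRUE` the weight is taken as
#' 1 and the result is in kcal/kg (the unit used for cohort comparisons).
#'
#' @param segments Data frame of non-overlapping labeled segments with
#'   columns `state` (`"active"`/`"inactive"`), `type` (`"light"`,
#'   `"periodic"`, `"weightless"` or `NA` for inactive), `sigma` (magnitude
#'   SD in g) and `duration_h`.
#' @param met A [met_table()].
#' @param weight_kg Body weight; required when `normalize = FALSE`.
#' @param normalize When TRUE (default) report kcal/kg.
#' @return A list with `G9` and the per-segment calories `C_i`.
#' @export
energy_expenditure <- function(segments, met = met_table(), weight_kg = NA,
                               normalize = TRUE) {
  if (!normalize && (is.na(weight_kg) || weight_kg <= 0))
    stop("parameter error: weight_kg required when normalize = FALSE")
  w <- if (normalize) 1 else weight_kg
  ci <- met_of(segments, met) * segments$duration_h * w
  list(G9 = sum(ci), C_i = ci)
}
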