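#' Instantaneous pesticide-induced mortality acting on the community
#'
#' Bundles the mortality rates that a pesticide currently imposes: `p_now`
#' on the pest, `p_now * q` on the natural enemy and `p_now * s` on the
#' alternative prey. Keeping these separate from the biological parameter
#' sets lets application regimes switch `p_now` on and off in time without
#' touching the biology.
#'
#' @param p_now Pest mortality currently acting (1/day); 0 when no
#'   pesticide is active.
#' @param q Enemy mortality relative to that of the pest (ratio, >= 0).
#' @param s Alternative-prey mortality relative to that of the pest
#'   (ratio, >= 0; food web model only).
#' @return An object of class `"mortality_input"`.
#' @export
mortality_input <- function(p_now = 0, q = 0, s = 0) {
  if (p_now < 0 || q < 0 || s < 0)
    stop("mortality rates and ratios must be >= 0")
  structure(list(p_now = p_now, q = q, s = s), class = "mortality_input")
}

check_state <- function(state, vars) {
  if (!all(vars %in% names(state)))
    stop("state must have components named ", paste(vars, collapse = ", "))
  if (any(state[vars] < 0))
    stop("state components must be >= 0")
}

#' Right-hand side of the basic predator-prey model
#'
#' Evaluates the derivatives of pest (`N`) and natural enemy (`P`)
#' densities: logistic pest growth minus Type II predation minus pesticide
#' mortality, and predation-fuelled predator growth minus natural and
#' pesticide mortality:
#' \deqn{dN/dt = rN(1 - N/K) - aNP/(N + D) - pN}
#' \deqn{dP/dt = acNP/(N + D) - mP - pqP}
#'
#' @param state Named numeric vector with components `N` and `P` (>= 0).
#' @param params An [rm_params()] object.
#' @param mort A [mortality_input()] object; `p = mort$p_now`.
#' @return Named numeric vector `(dN, dP)` of time derivatives.
#' @export
rm_rhs <- function(state, params, mort = mortality_input()) {
  check_state(state, c("N", "P"))
  N <- state[["N"]]; P <- state[["P"]]
  p <- mort$p_now
  dN <- params$r * N * (1 - N / params$K) -
    params$a * N * P / (N + params$D) - p * N
  dP <- params$a * params$c * N * P / (N + params$D) -
    params$m * P - p * mort$q * P
  c(N = dN, P = dP)
}

#' Right-hand side of the tritrophic/food web model
#'
#' Evaluates derivatives of resource (`R`), pest (`N1`), alternative prey
#' (`N2`) and predator (`P`) densities in the bioenergetic food web:
#' logistic resource growth grazed by both herbivores, herbivore dynamics
#' `-x_i N_i (1 - y_i R/(R + R0i))` minus preference-weighted saturating
#' predation, and predator dynamics gaining from both prey. Pesticide
#' losses are `-p N1`, `-p s N2` and `-p q P`. With `N2 = 0` the system
#' reduces to a tritrophic chain.
#'
#' @param state Named numeric vector with components `R`, `N1`, `N2`, `P`
#'   (>= 0).
#' @param params A [foodweb_params()] object.
#' @param mort A [mortality_input()] object.
#' @return Named numeric vector `(dR, dN1, dN2, dP)`.
#' @export
foodweb_rhs <- function(state, params, mort = mortality_input()) {
  check_state(state, c("R", "N1", "N2", "P"))
  R <- state[["R"]]; N1 <- state[["N1"]]; N2 <- state[["N2"]]; P <- state[["P"]]
  p <- mort$p_now; w <- params$omega
  den <- w * N1 + (1 - w) * N2 + params$N0
  fR1 <- R / (R + params$R01)
  fR2 <- R / (R + params$R02)
  dR <- R * (1 - R / params$K) -
    params$xN1 * params$yN1 * fR1 * N1 -
    params$xN2 * params$yN2 * fR2 * N2
  dN1 <- -params$xN1 * N1 * (1 - params$yN1 * fR1) -
    w * params$xP * params$yP * N1 * P / den - p * N1
  dN2 <- -params$xN2 * N2 * (1 - params$yN2 * fR2) -
    (1 - w) * params$xP * params$yP * N2 * P / den - p * mort$s * N2
  dP <- -params$xP * P *
    (1 - (w * params$yP * N1 + (1 - w) * params$yP * N2) / den) -
    p * mort$q * P
  c(R = dR, N1 = dN1, N2 = dN2, P = dP)
}

#' Positive pest equilibrium under continuous pesticide mortality
#'
#' From the natural-enemy isocline of the basic model the pest equilibrium
#' in the presence of predators is
#' \deqn{N^* = (m + pq) D / (ac - m - pq).}
#' It depends only on predator traits and enemy-directed mortality: for a
#' perfectly selective pesticide (`q = 0`) the no-pesticide equilibrium is
#' recovered whatever `p`, and it increases with `p` for `q > 0`.
#'
#' @param params An [rm_params()] object.
#' @param p Continuous pesticide-induced pest mortality (1/day).
#' @param q Enemy mortality relative to the pest (ratio).
#' @return Equilibrium pest density (individuals/m2).
#' @export
rm_pest_equilibrium <- function(params, p = 0, q = 0) {
  denom <- params$a * params$c - params$m - p * q
  if (denom <= 0)
    stop("predator cannot persist: a*c - m - p*q must be > 0")
  (params$m + p * q) * params$D / denom
}

#' Predator equilibrium companion of the pest equilibrium
#'
#' Evaluates the prey nullcline at the pest equilibrium to obtain
#' \deqn{P^* = (r (1 - N^*/K) - p) (N^* + D) / a}
#' under the continuous-mortality interpretation of `p`. Continuous
#' pest-directed mortality lowers the predator equilibrium while leaving
#' the pest equilibrium unchanged when `q = 0`.
#'
#' @inheritParams rm_pest_equilibrium
#' @return Equilibrium predator density, or `0` with attribute
#'   `no_predator = TRUE` when the surplus production cannot sustain
#'   predators (`P* <= 0`).
#' @export
rm_predator_equilibrium <- function(params, p = 0, q = 0) {
  Nstar <- rm_pest_equilibrium(params, p, q)
  Pstar <- (params$r * (1 - Nstar / params$K) - p) * (Nstar + params$D) /
    params$a
  if (Pstar <= 0) return(structure(0, no_predator = TRUE))
  Pstar
}
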