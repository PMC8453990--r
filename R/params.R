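#' Parameters of the basic predator-prey (Rosenzweig-MacArthur) model
#'
#' Constructs the biological parameter set for the pest-natural enemy model
#' with logistic pest growth and a Type II predator functional response.
#' Defaults describe a thrips-predatory mite system at 22 C.
#'
#' @param r Pest intrinsic growth rate (1/day).
#' @param K Pest carrying capacity (individuals/m2).
#' @param a Maximum predation rate (prey/predator/day).
#' @param D Half-saturation pest density of the Type II functional response
#'   (prey/m2).
#' @param c Conversion efficiency of consumed pests into predator
#'   reproduction (predators/prey).
#' @param m Natural predator mortality (1/day).
#' @param generation_time Days per pest generation, used to express season
#'   summaries in pest generations.
#'
#' @return An object of class `c("rm_params", "model_params")`.
#' @examples
#' p <- rm_params()
#' rm_pest_equilibrium(p)  # approx 107.14 pests/m2
#' @export
rm_params <- function(r = 0.166, K = 1000, a = 4, D = 1500, c = 0.375,
                      m = 0.1, generation_time = 20) {
  p <- list(r = r, K = K, a = a, D = D, c = c, m = m,
            generation_time = generation_time)
  vals <- unlist(p)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all rm_params fields must be finite and > 0")
  if (a * c <= m)
    stop("predator cannot persist on abundant prey: need a*c > m")
  structure(p, class = c("rm_params", "model_params"))
}

#' Parameters of the bioenergetic tritrophic/food web model
#'
#' Constructs the parameter set of the consumer-resource food web with a
#' basal resource (plant), one or two herbivores (the pest `N1` and an
#' optional alternative prey `N2`) and one shared predator. The form follows
#' the Yodzis-Innes bioenergetic scaling with a preference-weighted
#' multi-prey functional response.
#'
#' @param K Resource carrying capacity (model units).
#' @param xN1,xN2,xP Mass-specific metabolic rates of pest, alternative prey
#'   and predator.
#' @param yN1,yN2,yP Maximum ingestion rates (scaled to metabolism).
#' @param R01,R02 Resource half-saturation densities for the two herbivores.
#' @param N0 Herbivore half-saturation density of the predator.
#' @param omega Predator preference for the pest `N1` relative to the
#'   alternative prey `N2`, in `[0, 1]`.
#' @param generation_time Time units per pest generation.
#'
#' @return An object of class `c("foodweb_params", "model_params")`.
#' @export
foodweb_params <- function(K = 1, xN1 = 0.201, xN2 = 0.2, xP = 0.08,
                           yN1 = 2.009, yN2 = 2.01, yP = 5,
                           R01 = 0.1625, R02 = 0.16129, N0 = 0.5,
                           omega = 0.5, generation_time = 20) {
  p <- list(K = K, xN1 = xN1, xN2 = xN2, xP = xP, yN1 = yN1, yN2 = yN2,
            yP = yP, R01 = R01, R02 = R02, N0 = N0, omega = omega,
            generation_time = generation_time)
  vals <- unlist(p[setdiff(names(p), "omega")])
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all foodweb_params rates must be finite and > 0")
  if (!is.finite(omega) || omega < 0 || omega > 1)
    stop("omega must lie in [0, 1]")
  structure(p, class = c("foodweb_params", "model_params"))
}

#' @export
print.rm_params <- function(x, ...) {
  cat("Basic predator-prey model parameters:\n")
  print(unlist(unclass(x)))
  invisible(x)
}

#' @export
print.foodweb_params <- function(x, ...) {
  cat("Tritrophic/food web model parameters:\n")
  print(unlist(unclass(x)))
  invisible(x)
}

#' Default initial densities for a model
#'
#' Standard starting densities: 50 pests and 10 natural enemies per m2 for
#' the basic model; `R = 0.1`, `N1 = 0.2`, `N2 = 0` (tritrophic chain) or
#' `0.2` (with alternative prey) and `P = 0.1` for the food web model.
#'
#' @param params A `model_params` object.
#' @param alt_prey For food-web parameters, start with the alternative prey
#'   present (`N2 = 0.2`) instead of absent.
#' @return Named numeric state vector.
#' @export
default_initial_state <- function(params, alt_prey = FALSE) {
  if (inherits(params, "rm_params")) {
    c(N = 50, P = 10)
  } else {
    c(R = 0.1, N1 = 0.2, N2 = if (alt_prey) 0.2 else 0, P = 0.1)
  }
}

#' Name of the pest state variable for a model
#' @param params A `model_params` object.
#' @return `"N"` for the basic model, `"N1"` for the food web model.
#' @export
pest_variable <- function(params) {
  if (inherits(params, "rm_params")) "N" else "N1"
}

#' Name of the predator state variable for a model
#' @param params A `model_params` object.
#' @return `"P"` for both models.
#' @export
predator_variable <- function(params) "P"

#' Write model parameters and a regime to a structured config file
#'
#' Serializes one or both parameter sets and an optional pesticide regime to
#' a flat YAML file with one section per component, readable by
#' [read_model_config()].
#'
#' @param path Output file path.
#' @param rm An `rm_params` object or `NULL`.
#' @param foodweb A `foodweb_params` object or `NULL`.
#' @param regime A `pesticide_regime` object or `NULL`.
#' @return `path`, invisibly.
#' @export
write_model_config <- function(path, rm = NULL, foodweb = NULL, regime = NULL) {
  cfg <- list()
  if (!is.null(rm)) cfg$rm <- lapply(unclass(rm), identity)
  if (!is.null(foodweb)) cfg$foodweb <- lapply(unclass(foodweb), identity)
  if (!is.null(regime)) cfg$regime <- lapply(unclass(regime), identity)
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' Read model parameters and a regime from a config file
#'
#' @param path Path to a YAML file written by [write_model_config()] (or
#'   hand-edited with the same sections: `rm`, `foodweb`, `regime`).
#' @return A list with elements `rm`, `foodweb` and `regime`, each `NULL`
#'   when the section is absent; parameter sections are validated through
#'   their constructors.
#' @export
read_model_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  out <- list(rm = NULL, foodweb = NULL, regime = NULL)
  if (!is.null(cfg$rm)) out$rm <- do.call(rm_params, cfg$rm)
  if (!is.null(cfg$foodweb)) out$foodweb <- do.call(foodweb_params, cfg$foodweb)
  if (!is.null(cfg$regime)) out$regime <- do.call(pesticide_regime, cfg$regime)
  out
}
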