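#' @include AllClasses.R
NULL

.paramCache <- new.env(parent = emptyenv())

#' Reference parameterization of the HVC_X model
#'
#' Loads the versioned reference-parameter file shipped with the package
#' (see \code{system.file("extdata", "reference_parameters.yaml",
#' package = "hvcx")}).  All gating kinetics, reversal potentials, fixed
#' conductances and the calcium pool are defined there; the five varied
#' conductances default to a mid-range reference set.  Capacitance is 50 pF
#' for adults and 75 pF (50\% larger cells) for juveniles.
#'
#' @param age "adult" or "juvenile" (selects the capacitance).
#' @param file optional path to an alternative parameter YAML.
#' @return An \linkS4class{HHParameters} object.
#' @examples
#' p <- referenceParameters()
#' conductances(p)
#' @export
referenceParameters <- function(age = c("adult", "juvenile"), file = NULL) {
  age <- match.arg(age)
  if (is.null(file))
    file <- system.file("extdata", "reference_parameters.yaml",
                        package = "hvcx", mustWork = TRUE)
  key <- paste0(normalizePath(file), "::", age)
  if (!is.null(.paramCache[[key]])) return(.paramCache[[key]])
  y <- yaml::read_yaml(file)
  kin <- c(
    m_half = y$sodium$m_half, m_slope = y$sodium$m_slope,
    h_half = y$sodium$h_half, h_slope = y$sodium$h_slope,
    tauh_base = y$sodium$tauh_base_ms, tauh_amp = y$sodium$tauh_amp_ms,
    tauh_half = y$sodium$tauh_half, tauh_slope = y$sodium$tauh_slope,
    n_half = y$potassium$n_half, n_slope = y$potassium$n_slope,
    taun_base = y$potassium$taun_base_ms, taun_amp = y$potassium$taun_amp_ms,
    taun_half = y$potassium$taun_half, taun_slope = y$potassium$taun_slope,
    a_half = y$calcium_T$a_half, a_slope = y$calcium_T$a_slope,
    b_half = y$calcium_T$b_half, b_slope = y$calcium_T$b_slope,
    taub_base = y$calcium_T$taub_base_ms, taub_amp = y$calcium_T$taub_amp_ms,
    taub_half = y$calcium_T$taub_half, taub_slope = y$calcium_T$taub_slope,
    s_half = y$calcium_L$s_half, s_slope = y$calcium_L$s_slope,
    e_half = y$a_type$e_half, e_slope = y$a_type$e_slope,
    r_half = y$h_current$r_half, r_slope = y$h_current$r_slope,
    taur_base = y$h_current$taur_base_ms, taur_amp = y$h_current$taur_amp_ms,
    taur_half = y$h_current$taur_half, taur_slope = y$h_current$taur_slope
  )
  obj <- new("HHParameters",
    capacitance = as.numeric(y$capacitance_pF[[age]]),
    conductances = unlist(y$conductances_nS),
    reversals = unlist(y$reversal_mV),
    kinetics = kin,
    calcium = c(ks = y$calcium_pool$ks_uM,
                kca = y$calcium_pool$kca_uM_per_pA_ms,
                tauCa = y$calcium_pool$tau_ms,
                ca0 = y$calcium_pool$ca0_uM)
  )
  .paramCache[[key]] <- obj
  obj
}

# Pack an HHParameters object into the flat vector consumed by the C++
# integrator.  The order must match the ParIndex enum in src/hh.cpp.
.hhParVector <- function(params) {
  g <- params@conductances
  E <- params@reversals
  k <- params@kinetics
  ca <- params@calcium
  c(params@capacitance,
    g[["gNa"]], g[["gK"]], g[["gSK"]], g[["gh"]], g[["gCaT"]],
    g[["gCaL"]], g[["gA"]], g[["gL"]],
    E[["ENa"]], E[["EK"]], E[["Eh"]], E[["ECa"]], E[["EL"]],
    k[["m_half"]], k[["m_slope"]],
    k[["h_half"]], k[["h_slope"]],
    k[["tauh_base"]], k[["tauh_amp"]], k[["tauh_half"]], k[["tauh_slope"]],
    k[["n_half"]], k[["n_slope"]],
    k[["taun_base"]], k[["taun_amp"]], k[["taun_half"]], k[["taun_slope"]],
    k[["a_half"]], k[["a_slope"]],
    k[["b_half"]], k[["b_slope"]],
    k[["taub_base"]], k[["taub_amp"]], k[["taub_half"]], k[["taub_slope"]],
    k[["s_half"]], k[["s_slope"]],
    k[["e_half"]], k[["e_slope"]],
    k[["r_half"]], k[["r_slope"]],
    k[["taur_base"]], k[["taur_amp"]], k[["taur_half"]], k[["taur_slope"]],
    ca[["ks"]], ca[["kca"]], ca[["tauCa"]], ca[["ca0"]])
}

#' Set the five fitted conductances of a parameter set
#'
#' Convenience wrapper around \code{conductances<-} taking a named vector
#' over any subset of the five varied axes (and optionally the fixed ones).
#'
#' @param params an HHParameters object.
#' @param g named numeric vector of conductances to set, nS.
#' @return The modified HHParameters.
#' @export
withConductances <- function(params, g) {
  conductances(params) <- g
  params
}
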