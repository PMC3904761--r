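# Dependency kinds: role signatures, causal orientation, and the residual
# equations of each physical-law class.
#
# Sign convention (used everywhere, enforced by tests): positive flow runs
# from the high-force player to the low-force player.

.role <- function(categories, min = 1L, max = min) {
  list(categories = categories, min = as.integer(min), max = if (is.finite(max)) as.integer(max) else Inf)
}

.DYN <- c("amount", "momentum", "force", "flow")

# Each kind: id, label, roles (role name -> {categories, min, max}),
# domainRule ("single": all dynamical players in one domain; "two": transducer
# sides in two distinct domains; "any": unconstrained, mismatch is a warning),
# outputs (causally computed roles), boundary flag, params (allowed prefixes).
.kindList <- list(
  list(id = "boundary_flow", label = "Boundary flow dependency",
       roles = list(source_player = .role("amount", 0, 1),
                    target_player = .role("amount", 0, 1),
                    flow_player = .role("flow", 1, Inf)),
       domainRule = "single", outputs = character(0), boundary = TRUE),
  list(id = "boundary_force", label = "Boundary force dependency",
       roles = list(momentum_player = .role("momentum", 1, 1),
                    force_player_high = .role("force", 1, Inf),
                    force_player_low = .role("force", 0, Inf)),
       domainRule = "single", outputs = character(0), boundary = TRUE),
  list(id = "summation", label = "Summation dependency",
       roles = list(whole_player = .role("amount", 1, 1),
                    part_player = .role("amount", 1, Inf)),
       domainRule = "single", outputs = "whole_player", boundary = FALSE),
  list(id = "spatial", label = "Spatial dependency",
       roles = list(source_player = .role(c("amount", "momentum"), 1, 1),
                    target_player = .role(c("amount", "momentum"), 1, 1)),
       domainRule = "any", outputs = "target_player", boundary = FALSE,
       params = c("a", "b")),
  list(id = "resistive", label = "Resistive flow dependency",
       roles = list(flow_player = .role("flow", 1, 1),
                    force_player_high = .role("force", 1, 1),
                    force_player_low = .role("force", 1, 1),
                    constitutive = .role(c("constitutive.resistance", "constitutive.conductance"), 1, 1)),
       domainRule = "single", outputs = "flow_player", boundary = FALSE),
  list(id = "mass_action", label = "Chemical mass-action rate dependency",
       roles = list(flow_player = .role("flow", 1, 1),
                    source_player = .role("amount", 1, Inf),
                    target_player = .role("amount", 0, Inf),
                    constitutive = .role("constitutive.rate_constant", 1, 2)),
       domainRule = "single", outputs = "flow_player", boundary = FALSE,
       params = "stoich_"),
  list(id = "diffusion", label = "Diffusion gradient rate dependency",
       roles = list(flow_player = .role("flow", 1, 1),
                    source_player = .role("amount", 1, 1),
                    target_player = .role("amount", 1, 1),
                    constitutive = .role("constitutive.rate_constant", 1, 1)),
       domainRule = "single", outputs = "flow_player", boundary = FALSE),
  list(id = "michaelis_menten", label = "Michaelis-Menten rate dependency",
       roles = list(flow_player = .role("flow", 1, 1),
                    amount_player = .role("amount", 1, 1)),
       domainRule = "single", outputs = "flow_player", boundary = FALSE,
       params = c("Vmax", "Km")),
  list(id = "transformer", label = "Transformer (coupled flow) dependency",
       roles = list(force_player_1 = .role("force", 1, 1),
                    flow_player_1 = .role("flow", 1, 1),
                    force_player_2 = .role("force", 1, 1),
                    flow_player_2 = .role("flow", 1, 1),
                    constitutive = .role("constitutive.modulus", 1, 1)),
       domainRule = "single", outputs = c("force_player_2", "flow_player_1"), boundary = FALSE),
  list(id = "transducer", label = "Transducer (cross-domain coupled flow) dependency",
       roles = list(force_player_1 = .role("force", 1, 1),
                    flow_player_1 = .role("flow", 1, 1),
                    force_player_2 = .role("force", 1, 1),
                    flow_player_2 = .role("flow", 1, 1),
                    constitutive = .role("constitutive.modulus", 1, 1)),
       domainRule = "two", outputs = c("force_player_2", "flow_player_1"), boundary = FALSE),
  list(id = "capacitive", label = "Capacitive storage dependency",
       roles = list(force_player_high = .role("force", 1, 1),
                    force_player_low = .role("force", 0, 1),
                    amount_player = .role("amount", 1, 1),
                    constitutive = .role("constitutive.capacitance", 1, 1)),
       domainRule = "single", outputs = "force_player_high", boundary = FALSE),
  list(id = "inductive", label = "Inductive storage dependency",
       roles = list(flow_player = .role("flow", 1, 1),
                    momentum_player = .role("momentum", 1, 1),
                    constitutive = .role("constitutive.inductance", 1, 1)),
       domainRule = "single", outputs = "flow_player", boundary = FALSE),
  list(id = "transactor", label = "Transactor dependency",
       roles = list(source_player = .role(.DYN, 1, 1),
                    target_player = .role(.DYN, 1, 1),
                    constitutive = .role("constitutive.coefficient", 1, 1)),
       domainRule = "any", outputs = "target_player", boundary = FALSE)
)
names(.kindList) <- vapply(.kindList, `[[`, "", "id")

#' Catalogue of dependency kinds
#'
#' Every registered physical-law class with its role signature (role name,
#' admissible categories, multiplicity), domain rule, and causal outputs, in a
#' stable documented order: boundary kinds first, then state dependencies,
#' then rate dependencies, then the transactor wild card.
#'
#' @return Named list of kind descriptors.
#' @examples
#' names(dependencyCatalog())
#' dependencyCatalog()$resistive$roles
#' @export
dependencyCatalog <- function() .kindList

#' Look up a single dependency kind
#' @param id Kind id, e.g. `"resistive"`.
#' @return The kind descriptor.
#' @export
dependencyKind <- function(id) {
  k <- .kindList[[id]]
  if (is.null(k)) physdepStop("E_SCHEMA", sprintf("unknown dependency kind '%s'", id))
  k
}

# ---- law functions -----------------------------------------------------

#' Resistive (Ohm-analogue) flow
#'
#' `flow = (forceHigh - forceLow) / R`: the generalized Ohm's law relating a
#' flow rate to a force differential through a resistance. Positive flow runs
#' high to low.
#'
#' @param forceHigh,forceLow Force values (canonical units).
#' @param R Resistance, strictly positive.
#' @return Flow value.
#' @examples
#' resistiveFlow(6, 0, 2)   # 3
#' @export
resistiveFlow <- function(forceHigh, forceLow, R) {
  if (!is.numeric(R) || R <= 0) physdepStop("E_BAD_CONSTITUTIVE", "resistance must be > 0")
  (forceHigh - forceLow) / R
}

#' Capacitive (Hooke-analogue) force
#'
#' `force = amount / C (+ reference force)`: more stored amount, more
#' potential-energy force.
#'
#' @param amount Stored amount.
#' @param C Capacitance, strictly positive.
#' @param forceLow Optional reference force (default 0).
#' @return Force value.
#' @export
capacitiveForce <- function(amount, C, forceLow = 0) {
  if (!is.numeric(C) || C <= 0) physdepStop("E_BAD_CONSTITUTIVE", "capacitance must be > 0")
  amount / C + forceLow
}

#' Inductive flow
#'
#' `flow = momentum / L`: kinetic-energy storage; for a mechanical mass,
#' velocity = momentum / m.
#'
#' @param momentum Stored momentum.
#' @param L Inductance, strictly positive.
#' @return Flow value.
#' @export
inductiveFlow <- function(momentum, L) {
  if (!is.numeric(L) || L <= 0) physdepStop("E_BAD_CONSTITUTIVE", "inductance must be > 0")
  momentum / L
}

#' Mass-action reaction flux
#'
#' `flow = kf * prod(fwd^s) - kr * prod(rev^s)`; vanishes exactly at detailed
#' balance.
#'
#' @param fwdAmounts Amounts of forward-side (substrate) pools.
#' @param revAmounts Amounts of reverse-side (product) pools.
#' @param kf,kr Forward and reverse rate constants, non-negative.
#' @param fwdStoich,revStoich Positive integer stoichiometries (default 1).
#' @return Net flux.
#' @examples
#' massActionFlow(c(1), c(2), kf = 2, kr = 1)  # 0, detailed balance
#' @export
massActionFlow <- function(fwdAmounts, revAmounts = numeric(0), kf, kr = 0,
                           fwdStoich = rep(1, length(fwdAmounts)),
                           revStoich = rep(1, length(revAmounts))) {
  if (kf < 0 || kr < 0) physdepStop("E_BAD_CONSTITUTIVE", "rate constants must be >= 0")
  if (any(fwdAmounts < 0) || any(revAmounts < 0))
    physdepStop("E_NEGATIVE_STATE", "negative amount in mass-action law")
  kf * prod(fwdAmounts ^ fwdStoich) - kr * prod(revAmounts ^ revStoich)
}

#' Diffusion (Fick-analogue) flux
#'
#' `flow = kd * (amountHigh - amountLow)`: amount-difference-driven transport.
#'
#' @param amountHigh,amountLow Amounts on the two sides.
#' @param kd Diffusion rate constant, strictly positive.
#' @return Flux from high to low.
#' @export
diffusionFlow <- function(amountHigh, amountLow, kd) {
  if (!is.numeric(kd) || kd <= 0) physdepStop("E_BAD_CONSTITUTIVE", "diffusion rate constant must be > 0")
  kd * (amountHigh - amountLow)
}

#' Michaelis-Menten saturable flux
#'
#' `flow = Vmax * amount / (Km + amount)`: the one sanctioned non-proportional
#' rate form, parameterized by a maximum flow rate and a half-maximal amount.
#'
#' @param amount Substrate amount, non-negative.
#' @param Vmax Maximum flux, > 0.
#' @param Km Half-maximal amount, > 0.
#' @return Flux.
#' @export
michaelisMentenFlow <- function(amount, Vmax, Km) {
  if (Vmax <= 0 || Km <= 0) physdepStop("E_BAD_CONSTITUTIVE", "Vmax and Km must be > 0")
  if (amount < 0) physdepStop("E_NEGATIVE_STATE", "negative amount in Michaelis-Menten law")
  Vmax * amount / (Km + amount)
}

#' Transformer / transducer coupling
#'
#' Given side-1 force and side-2 flow, returns `force2 = m * force1` and
#' `flow1 = m * flow2`, so `force1 * flow1 == force2 * flow2` exactly (ideal
#' power conservation).
#'
#' @param force1 Side-1 force (input).
#' @param flow2 Side-2 flow (input).
#' @param m Modulus, non-zero.
#' @return Named numeric vector `c(force2, flow1)`.
#' @examples
#' transformerPair(10, 2, 0.5)  # force2 = 5, flow1 = 1; power 10*1 == 5*2
#' @export
transformerPair <- function(force1, flow2, m) {
  if (!is.numeric(m) || m == 0) physdepStop("E_BAD_CONSTITUTIVE", "modulus must be non-zero")
  c(force2 = m * force1, flow1 = m * flow2)
}

#' Transactor (proportional wild-card) value
#'
#' `target = c * source`; stands in for mechanistically unknown or
#' thermodynamically negligible couplings such as the baroreflex.
#'
#' @param source Source property value.
#' @param coefficient Proportionality, any sign.
#' @return Target value.
#' @export
transactorValue <- function(source, coefficient) coefficient * source

#' Summation over proper parts
#'
#' The whole's amount is the sum of the amounts of its parts.
#'
#' @param parts Non-empty numeric vector of part amounts.
#' @return The sum.
#' @export
summationValue <- function(parts) {
  if (length(parts) == 0L) physdepStop("E_MISSING_ROLE", "summation requires at least one part")
  sum(parts)
}

#' Spatial (instantaneous state-state) relation
#'
#' `derived = a * primary^b`, e.g. sphere volume from radius with
#' `a = 4*pi/3, b = 3`.
#'
#' @param primary Primary state value; must be non-negative when `b` is
#'   non-integer.
#' @param a,b Coefficient and exponent.
#' @return Derived state value.
#' @export
spatialValue <- function(primary, a, b) {
  if (primary < 0 && b != round(b))
    physdepStop("E_BAD_STATE", "negative primary state with non-integer exponent")
  a * primary ^ b
}
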