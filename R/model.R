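## Instantaneous model: Liebig growth, realized uptake, excretion, gas fluxes,
## and the chemostat ODE right-hand side.

#' Supply specification
#'
#' Inflow concentrations of the five resources (uM N). In the standard
#' configuration only organic matter and nitrate are supplied externally; all
#' other pools are fed by microbial excretion.
#'
#' @param OM,NO3,NO2,N2O,NH4 inflow concentrations (uM N), all `>= 0`
#' @return named numeric vector of length 5
#' @export
supply_spec <- function(OM = 0, NO3 = 0, NO2 = 0, N2O = 0, NH4 = 0) {
  s <- c(OM = OM, NO3 = NO3, NO2 = NO2, N2O = N2O, NH4 = NH4)
  if (any(!is.finite(s) | s < 0)) stop("supply concentrations must be finite and >= 0")
  s
}

as_supply <- function(s) {
  if (length(s) == 2) s <- c(s, 0, 0, 0)
  if (length(s) != 5 || any(!is.finite(s) | s < 0)) {
    stop("supply must be a non-negative vector of length 5 (or 2: OM, NO3)")
  }
  stats::setNames(as.numeric(s), omz_resources)
}

#' Community state
#'
#' Bundles the seven biomasses and five resource concentrations (all uM N).
#'
#' @param B biomass 7-vector (uM N)
#' @param R resource 5-vector (uM N)
#' @return object of class `community_state`
#' @export
community_state <- function(B, R) {
  B <- stats::setNames(as.numeric(B), omz_types)
  R <- stats::setNames(as.numeric(R), omz_resources)
  if (length(B) != 7 || length(R) != 5) stop("need 7 biomasses and 5 resources")
  if (any(B < 0) || any(R < 0)) stop("state entries must be non-negative")
  structure(list(B = B, R = R), class = "community_state")
}

#' @export
print.community_state <- function(x, ...) {
  cat("Community state (uM N)\n")
  print(signif(x$B, 4)); print(signif(x$R, 4))
  invisible(x)
}

## 7x5 matrix of potential growth rates; NA on unused pairs
growth_matrix <- function(traits, R) {
  Rm <- matrix(R, 7, 5, byrow = TRUE)
  traits$YVm * Rm / (Rm + traits$K)
}

## row-wise Liebig minimum of the potential-growth matrix
liebig_min <- function(P) {
  P[is.na(P)] <- Inf
  pmin(P[, 1], P[, 2], P[, 3], P[, 4], P[, 5])
}

#' Potential growth rate on one essential resource
#'
#' Monod-saturating growth the given resource alone could support:
#' `y * Vm * R / (R + K)`. Defined only where the type uses the resource.
#'
#' @param traits a `trait_set`
#' @param R resource concentration 5-vector (uM N), or a `community_state`
#' @param i functional type (index or label)
#' @param j resource (index or name)
#' @return growth rate (per day)
#' @export
potential_growth <- function(traits, R, i, j) {
  if (inherits(R, "community_state")) R <- R$R
  i <- type_index(i); j <- resource_index(j)
  if (traits$A[i, j] != 1L) {
    stop(omz_types[i], " does not use ", omz_resources[j])
  }
  traits$YVm[i, j] * R[j] / (R[j] + traits$K[i, j])
}

#' Realized growth rate under Liebig's law of the minimum
#'
#' The realized growth rate is the minimum of the potential growth rates over
#' the type's essential resources; the minimizing resource is reported as
#' limiting. Ties (within relative tolerance 1e-9) are flagged as
#' colimitation and the lowest resource index is reported.
#'
#' @inheritParams potential_growth
#' @return list with `rate` (per day), `limiting` (resource index) and
#'   `colimited` (logical)
#' @export
realized_growth <- function(traits, R, i) {
  if (inherits(R, "community_state")) R <- R$R
  i <- type_index(i)
  used <- which(traits$A[i, ] == 1L)
  pot <- vapply(used, function(j) traits$YVm[i, j] * R[j] / (R[j] + traits$K[i, j]),
                numeric(1))
  rate <- min(pot)
  near <- pot <= rate * (1 + 1e-9) + 1e-15
  list(rate = rate, limiting = unname(used[which(near)[1]]),
       colimited = sum(near) > 1L)
}

## excretion-rate matrix (per-biomass rates, uM N per uM biomass N per day)
## given realized growth rates mu. Rows follow the reduction stoichiometry:
##  - B1 routes all reduced NO3-N to NO2 (mu1/y_{1,NO3})
##  - B2 and B6 route all acceptor-N to N2O
##  - every heterotroph regenerates NH4 at e_i5 = mu_i (1/y_iOM - 1), the
##    nitrogen-balance closure of OM remineralization
##  - anammox (B5) excretes nothing tracked
excretion_matrix <- function(traits, mu) {
  E <- matrix(0, 7, 5, dimnames = list(omz_types, omz_resources))
  E[1, 3] <- mu[1] * traits$invY[1, 2]
  E[2, 4] <- mu[2] * traits$invY[2, 2]
  E[6, 4] <- mu[6] * traits$invY[6, 3]
  E[, 5] <- mu * traits$e5_coef
  E
}

#' Per-biomass excretion rates of one functional type
#'
#' @inheritParams potential_growth
#' @param mu realized growth rate of the type (per day)
#' @return named 5-vector of per-biomass excretion rates (per day)
#' @export
excretion_rates <- function(traits, mu, i) {
  i <- type_index(i)
  mu_all <- numeric(7); mu_all[i] <- mu
  excretion_matrix(traits, mu_all)[i, ]
}

#' Instantaneous fluxes of a community state
#'
#' Evaluates potential and realized growth, limiting resources, realized
#' uptake (`Vr = mu / y` on used resources), excretion, and the gaseous
#' nitrogen fluxes at a given state.
#'
#' @inheritParams potential_growth
#' @param B biomass 7-vector (uM N)
#' @return object of class `flux_record`: list with `mu` (7), `mu_pot` (7x5,
#'   NA on unused pairs), `limiting` (7, resource index), `colimited` (7),
#'   `Vr` (7x5), `E` (7x5), and `gas` with elements `N2` (production),
#'   `N2O_prod`, `N2O_cons` (all uM N per day).
#' @export
flux_record <- function(traits, B, R) {
  P <- growth_matrix(traits, R)
  Pm <- P; Pm[is.na(Pm)] <- Inf
  mu <- pmin(Pm[, 1], Pm[, 2], Pm[, 3], Pm[, 4], Pm[, 5])
  near <- Pm <= mu * (1 + 1e-9) + 1e-15
  limiting <- max.col(-Pm, ties.method = "first")
  colimited <- rowSums(near) > 1L
  Vr <- mu * traits$invY       # zero on unused pairs by construction of invY
  E <- excretion_matrix(traits, mu)
  gas <- gas_fluxes_internal(B, mu, Vr, E)
  structure(list(mu = stats::setNames(mu, omz_types), mu_pot = P,
                 limiting = limiting, colimited = colimited,
                 Vr = Vr, E = E, gas = gas),
            class = "flux_record")
}

gas_fluxes_internal <- function(B, mu, Vr, E) {
  ## N2: terminal reducers route acceptor-N to N2; anammox converts both
  ## substrates minus biomass synthesis
  N2 <- Vr[3, 3] * B[3] + Vr[4, 4] * B[4] + Vr[7, 2] * B[7] +
    (Vr[5, 3] + Vr[5, 5] - mu[5]) * B[5]
  N2O_prod <- E[2, 4] * B[2] + E[6, 4] * B[6]
  N2O_cons <- Vr[4, 4] * B[4]
  c(N2 = unname(N2), N2O_prod = unname(N2O_prod), N2O_cons = unname(N2O_cons))
}

#' Gaseous nitrogen fluxes at a state
#'
#' Total N2 production, N2O production and N2O consumption (uM N per day).
#' N2 leaves the modeled pools (nitrogen loss); N2O is a tracked pool, so its
#' production/consumption are internal transfers reported for pathway
#' classification.
#'
#' @inheritParams flux_record
#' @param fluxes optionally, a precomputed `flux_record`
#' @return named numeric vector `c(N2, N2O_prod, N2O_cons)`
#' @export
gas_fluxes <- function(traits, B, R, fluxes = NULL) {
  if (is.null(fluxes)) fluxes <- flux_record(traits, B, R)
  fluxes$gas
}

#' Chemostat right-hand side
#'
#' Time derivatives of the full model:
#' `dB_i/dt = (mu_i - a) B_i` and
#' `dR_j/dt = a (s_j - R_j) + sum_i E_ij B_i - sum_i Vr_ij B_i`.
#'
#' The total-nitrogen budget closes exactly by construction:
#' `d/dt (sum R + sum B) = a (sum s - sum R - sum B) - N2 flux`.
#'
#' @inheritParams flux_record
#' @param supply inflow concentration 5-vector (see [supply_spec()])
#' @return list with `dB` (7), `dR` (5) and `fluxes` (a `flux_record`)
#' @export
community_rhs <- function(traits, B, R, supply) {
  s <- as_supply(supply)
  if (any(B < -1e-12) || any(R < -1e-12)) {
    stop("state integrity error: negative biomass or resource concentration")
  }
  B <- pmax(B, 0); R <- pmax(R, 0)
  fl <- flux_record(traits, B, R)
  dB <- (fl$mu - traits$a) * B
  dR <- traits$a * (s - R) + as.numeric(crossprod(fl$E - fl$Vr, B))
  list(dB = stats::setNames(dB, omz_types),
       dR = stats::setNames(dR, omz_resources), fluxes = fl)
}

## lean rhs for the integrator (no flux bookkeeping, minimal allocation)
rhs_ode <- function(t, x, p) {
  B <- pmax(x[1:7], 0)
  B[!p$active] <- 0   # absent types cannot appear without inoculation;
                      # keeps solver roundoff from seeding exponential growth
  R <- pmax(x[8:12], 0)
  Rm <- matrix(R, 7, 5, byrow = TRUE)
  P <- p$YVm * Rm / (Rm + p$K)
  P[p$unused] <- Inf
  mu <- pmin(P[, 1], P[, 2], P[, 3], P[, 4], P[, 5])
  Vr <- mu * p$invY
  net <- -Vr                               # E - Vr
  net[1, 3] <- net[1, 3] + mu[1] * p$invY[1, 2]
  net[2, 4] <- net[2, 4] + mu[2] * p$invY[2, 2]
  net[6, 4] <- net[6, 4] + mu[6] * p$invY[6, 3]
  net[, 5] <- net[, 5] + mu * p$e5_coef
  dB <- (mu - p$a) * B
  dB[!p$active] <- 0
  list(c(dB, p$a * (p$s - R) + as.numeric(crossprod(net, B))))
}

rhs_parms <- function(traits, supply, active = rep(TRUE, 7)) {
  list(YVm = traits$YVm, K = traits$K, invY = traits$invY,
       e5_coef = traits$e5_coef, unused = is.na(traits$YVm),
       a = traits$a, s = as_supply(supply), active = active)
}

#' Global nitrogen budget residual
#'
#' Evaluates the conservation identity at a state: the rate of change of total
#' tracked nitrogen must equal the net chemostat exchange minus N2 loss
#' (N2O is a tracked pool and is not counted as loss). Returns the residual
#' relative to `max(1, a * sum(s))`.
#'
#' @inheritParams community_rhs
#' @return scalar relative residual (dimensionless)
#' @export
nitrogen_budget_residual <- function(traits, B, R, supply) {
  s <- as_supply(supply)
  d <- community_rhs(traits, B, R, supply)
  lhs <- sum(d$dB) + sum(d$dR)
  rhs <- traits$a * (sum(s) - sum(pmax(R, 0)) - sum(pmax(B, 0))) - d$fluxes$gas[["N2"]]
  abs(lhs - rhs) / max(1, traits$a * sum(s))
}
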