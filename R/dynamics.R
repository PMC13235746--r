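## Time integration to ecological equilibrium.

#' Integrate the chemostat dynamics
#'
#' Integrates the community ODEs with a stiff-capable solver (deSolve's
#' `lsoda`). The Liebig minimum makes the right-hand side continuous but not
#' smooth, so tight tolerances are used rather than any smoothing of the
#' minimum. Negative excursions below 1e-14 (solver noise) are clipped to
#' zero in the returned trajectory.
#'
#' @param traits a `trait_set`
#' @param init a `community_state`, or a list with elements `B` (7) and `R`
#'   (5)
#' @param supply inflow 5-vector (see [supply_spec()]); a length-2 vector is
#'   taken as (OM, NO3)
#' @param times output time points (days); a scalar is expanded to
#'   `seq(0, times, length.out = 101)`
#' @param rtol,atol solver tolerances
#' @param method deSolve method name
#' @param active logical 7-vector of types allowed to be present. Types with
#'   zero biomass cannot appear without inoculation, so by default only types
#'   starting above zero take part in the dynamics (this also prevents solver
#'   roundoff from seeding spurious exponential growth of absent types).
#' @return data.frame with column `time`, seven biomass columns `B1..B7` and
#'   five resource columns `OM..NH4`
#' @export
simulate_chemostat <- function(traits, init, supply, times,
                               rtol = 1e-10, atol = 1e-12, method = "lsoda",
                               active = init$B > 0) {
  s <- as_supply(supply)
  if (length(times) == 1) times <- seq(0, times, length.out = 101)
  x0 <- c(pmax(init$B, 0), pmax(init$R, 0))
  out <- deSolve::ode(y = x0, times = times, func = rhs_ode,
                      parms = rhs_parms(traits, s, active),
                      method = method, rtol = rtol, atol = atol,
                      maxsteps = 100000)
  if (attr(out, "istate")[1] < 0) {
    stop("integrator failure at t = ", max(out[, 1]),
         "; state = ", paste(signif(out[nrow(out), -1], 4), collapse = ", "))
  }
  df <- as.data.frame(out)
  names(df) <- c("time", omz_types, omz_resources)
  num <- df[, -1]
  num[num < 0 & num > -1e-14] <- 0
  df[, -1] <- num
  df
}

## scaled residual: max_k |dX_k/dt| / (|X_k| + 1e-6)
scaled_residual <- function(traits, B, R, supply) {
  d <- community_rhs(traits, pmax(B, 0), pmax(R, 0), supply)
  x <- c(B, R); dx <- c(d$dB, d$dR)
  max(abs(dx) / (abs(x) + 1e-6))
}

#' Find the ecological equilibrium of a community
#'
#' Integrates from the initial state over doubling checkpoints (1e3, 2e3,
#' 4e3, ... days, capped at `horizon`) until the scaled derivative residual
#' `max |dX/dt| / (|X| + 1e-6)` falls below `residual_tol`. Types falling
#' below the extinction threshold are pruned to zero between checkpoints.
#' If the horizon is exhausted the result is flagged not converged
#' ("nonstationary"): possible non-equilibrium attractors are reported as
#' such, never averaged.
#'
#' @inheritParams simulate_chemostat
#' @param init optional initial `community_state`; by default every type in
#'   `subsystem` starts at `inoculum` and resources start at the inflow
#'   values (the "all present" assembly)
#' @param subsystem types present initially (indices or labels); default all
#'   seven
#' @param inoculum default initial biomass (uM N)
#' @param horizon maximum integration time (days)
#' @param residual_tol convergence tolerance on the scaled residual
#' @param extinct_tol biomasses below this (uM N) are pruned to zero
#' @return object of class `equilibrium_result`: list with `state`
#'   (`community_state`), `persistent` (logical 7), `limiting` (resource
#'   index per persistent type, NA otherwise), `fluxes` (`flux_record`),
#'   `converged`, `t_final`, `residual`, `supply`
#' @export
find_equilibrium <- function(traits, supply, init = NULL, subsystem = 1:7,
                             inoculum = 1e-3, horizon = 1e6,
                             residual_tol = 1e-8, extinct_tol = 1e-9,
                             rtol = 1e-10, atol = 1e-12) {
  s <- as_supply(supply)
  if (is.null(init)) {
    B <- numeric(7)
    B[type_index(subsystem)] <- inoculum
    R <- s
  } else {
    B <- pmax(init$B, 0); R <- pmax(init$R, 0)
  }
  t_now <- 0
  seg <- 1e3
  converged <- FALSE
  repeat {
    t_next <- min(t_now + seg, horizon)
    traj <- simulate_chemostat(traits, list(B = B, R = R), s,
                               times = c(t_now, t_next),
                               rtol = rtol, atol = atol)
    B <- pmax(as.numeric(traj[nrow(traj), 2:8]), 0)
    R <- pmax(as.numeric(traj[nrow(traj), 9:13]), 0)
    B[B < extinct_tol] <- 0
    t_now <- t_next
    res <- scaled_residual(traits, B, R, s)
    if (res < residual_tol) { converged <- TRUE; break }
    if (t_now >= horizon) break
    seg <- seg * 2
  }
  fl <- flux_record(traits, B, R)
  persistent <- B > extinct_tol
  limiting <- ifelse(persistent, fl$limiting, NA_integer_)
  structure(
    list(state = community_state(B, R), persistent = persistent,
         limiting = limiting, fluxes = fl, converged = converged,
         t_final = t_now, residual = res, supply = s),
    class = "equilibrium_result"
  )
}

#' @export
print.equilibrium_result <- function(x, ...) {
  lab <- if (any(x$persistent)) {
    paste(omz_types[x$persistent], collapse = "+")
  } else "none"
  cat("Equilibrium:", if (x$converged) "converged" else "NONSTATIONARY",
      "at t =", x$t_final, "d (residual", signif(x$residual, 3), ")\n")
  cat("Persistent:", lab, "\n")
  if (any(x$persistent)) {
    cat("Limiting resources:",
        paste0(omz_types[x$persistent], ":",
               omz_resources[x$limiting[x$persistent]], collapse = " "), "\n")
  }
  print(x$state)
  cat("Gas fluxes (uM N/d):", paste(names(x$fluxes$gas),
                                    signif(x$fluxes$gas, 4), sep = "=",
                                    collapse = " "), "\n")
  invisible(x)
}

#' Closed-form single-species chemostat equilibrium
#'
#' Analytic equilibrium for one functional type alone, used as an independent
#' oracle for the numerical solver. The type persists if the inflow of each
#' of its essential resources exceeds the subsistence concentration; the
#' limiting resource (the one permitting the smallest biomass) settles at its
#' R*, biomass equals `y_lim (s_lim - R*_lim)`, non-limiting used resources
#' at `s - B/y`, and excreted pools accumulate to `s + flux/a`. Infeasible
#' supply returns the washout state (`B = 0`, `R = s`).
#'
#' @inheritParams find_equilibrium
#' @param i functional type (index or label)
#' @return list with `B` (7-vector), `R` (5-vector), `persistent` (logical),
#'   `limiting` (resource index or NA), `colimited` (logical)
#' @export
closed_form_equilibrium <- function(traits, i, supply) {
  i <- type_index(i)
  s <- as_supply(supply)
  used <- which(traits$A[i, ] == 1L)
  rs <- vapply(used, function(j) rstar(traits, i, j), numeric(1))
  B <- numeric(7); R <- s
  if (any(s[used] <= rs)) {
    return(list(B = stats::setNames(B, omz_types), R = R, persistent = FALSE,
                limiting = NA_integer_, colimited = FALSE))
  }
  cand <- traits$Y[i, used] * (s[used] - rs)
  Bi <- min(cand)
  near <- cand <= Bi * (1 + 1e-9)
  lim <- unname(used[which(near)[1]])
  B[i] <- Bi
  for (j in used) R[j] <- if (j == lim) rs[used == j] else s[j] - Bi / traits$Y[i, j]
  a <- traits$a
  mu <- a
  ## excreted pools: inflow plus excretion flux / dilution
  if (i == 1) R[3] <- R[3] + (mu / traits$Y[1, 2]) * Bi / a
  if (i == 2) R[4] <- R[4] + (mu / traits$Y[2, 2]) * Bi / a
  if (i == 6) R[4] <- R[4] + (mu / traits$Y[6, 3]) * Bi / a
  if (i != 5) R[5] <- R[5] + mu * traits$e5_coef[i] * Bi / a
  list(B = stats::setNames(B, omz_types), R = R, persistent = TRUE,
       limiting = lim, colimited = sum(near) > 1L)
}

#' Export a trajectory in long format
#'
#' Writes `(time, variable, value)` rows as comma-separated text.
#'
#' @param traj data.frame from [simulate_chemostat()]
#' @param path output file
#' @return `path`, invisibly
#' @export
write_trajectory <- function(traj, path) {
  long <- do.call(rbind, lapply(names(traj)[-1], function(v) {
    data.frame(time = traj$time, variable = v, value = traj[[v]])
  }))
  utils::write.csv(long, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
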