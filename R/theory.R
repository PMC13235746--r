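## Closed-form resource-ratio theory: subsistence concentrations, consumption
## vectors, feeder-threshold criterion, and ZNGIs.

#' Subsistence concentration R*
#'
#' The resource concentration at which growth exactly balances dilution:
#' `R* = K a / (y Vm - a)`. Lower R* means stronger competitive ability under
#' limitation by that resource; under single-resource limitation the lowest-R*
#' competitor excludes the others.
#'
#' @param traits a `trait_set`
#' @param i functional type (index or label)
#' @param j resource (index or name)
#' @return concentration (uM N)
#' @export
rstar <- function(traits, i, j) {
  i <- type_index(i); j <- resource_index(j)
  if (traits$A[i, j] != 1L) stop(omz_types[i], " does not use ", omz_resources[j])
  denom <- traits$Y[i, j] * traits$Vm[i, j] - traits$a
  if (denom <= 0) {
    stop("R* undefined for (", omz_types[i], ", ", omz_resources[j],
         "): a >= y*Vm, the population cannot persist")
  }
  traits$K[i, j] * traits$a / denom
}

#' Table of subsistence concentrations
#'
#' @inheritParams rstar
#' @return data.frame with one row per used (type, resource) pair and column
#'   `rstar` (uM N)
#' @export
rstar_table <- function(traits) {
  df <- as.data.frame(traits)
  df[, c("type", "resource", "rstar")]
}

## the single N acceptor of a heterotrophic type
acceptor_of <- function(traits, i) {
  i <- type_index(i)
  if (i == 5) stop("B5 (anammox) has no OM/acceptor consumption vector")
  acc <- which(traits$A[i, 2:4] == 1L) + 1L
  if (length(acc) != 1L || traits$A[i, 1] != 1L) {
    stop(omz_types[i], " does not use OM plus a single N acceptor")
  }
  acc
}

#' Consumption vector of a heterotrophic denitrifier
#'
#' Direction of joint resource depletion per unit growth in (OM, acceptor)
#' supply space, reported as the yield ratio `c_i = y_iOM / y_i,acceptor`.
#' Because realized uptake is `mu/y`, this equals the acceptor-N consumed per
#' OM-N consumed, i.e. the slope `d(acceptor)/d(OM)` of the depletion
#' direction (not its reciprocal).
#'
#' @inheritParams rstar
#' @return object of class `consumption_vector`: list with `value`,
#'   `members`, `acceptor`
#' @export
consumption_vector <- function(traits, i) {
  i <- type_index(i)
  acc <- acceptor_of(traits, i)
  structure(list(value = traits$Y[i, 1] / traits$Y[i, acc],
                 members = omz_types[i], acceptor = omz_resources[acc]),
            class = "consumption_vector")
}

#' @export
print.consumption_vector <- function(x, ...) {
  cat("Consumption vector", paste(x$members, collapse = "+"), "(",
      x$acceptor, "-N per OM-N ):", signif(x$value, 5), "\n")
  invisible(x)
}

#' Consortium consumption vector of a feeder-recipient pair
#'
#' When a recipient consumes its feeder's excreted acceptor plus OM, the pair
#' depletes resources as a unit with combined vector
#' `c_fr = c_f / (1 + c_f / c_r)`, which is strictly smaller than the
#' feeder's own `c_f`: the consortium consumes relatively more OM per unit of
#' the feeder's acceptor, intensifying OM competition against third parties.
#'
#' @inheritParams rstar
#' @param feeder,recipient functional types forming a dependent pair
#'   (recipient's acceptor must be the feeder's excreted product, e.g.
#'   (B1, B3) via NO2 or (B2, B4) via N2O)
#' @return a `consumption_vector`
#' @export
consortium_vector <- function(traits, feeder, recipient) {
  f <- type_index(feeder); r <- type_index(recipient)
  prod_of <- c(3L, 4L, NA, NA, NA, 4L, NA)  # excreted acceptor by type
  if (is.na(prod_of[f]) || acceptor_of(traits, r) != prod_of[f]) {
    stop(omz_types[r], " does not consume the acceptor excreted by ", omz_types[f])
  }
  cf <- consumption_vector(traits, f)$value
  cr <- consumption_vector(traits, r)$value
  structure(list(value = cf / (1 + cf / cr),
                 members = omz_types[c(f, r)],
                 acceptor = omz_resources[acceptor_of(traits, f)]),
            class = "consumption_vector")
}

#' Minimum feeder biomass sustaining a recipient
#'
#' The feeder's equilibrium biomass must exceed
#' `a * y_feeder,converted / mu_recipient` for its excreted resource flux to
#' sustain the recipient, where `y_feeder,converted` is the feeder's yield on
#' the resource it converts into the recipient's substrate and
#' `mu_recipient` the recipient's realized growth rate (at recipient
#' equilibrium, `mu = a`). The threshold is inversely proportional to the
#' recipient's growth rate.
#'
#' @inheritParams consortium_vector
#' @param mu_recipient recipient growth rate (per day), `> 0`
#' @return biomass threshold (uM N)
#' @export
feeder_threshold <- function(traits, feeder, recipient, mu_recipient = traits$a) {
  f <- type_index(feeder); r <- type_index(recipient)
  if (!is.finite(mu_recipient) || mu_recipient <= 0) {
    stop("mu_recipient must be positive")
  }
  prod_of <- c(3L, 4L, NA, NA, NA, 4L, NA)
  conv <- c(2L, 2L, NA, NA, NA, 3L, NA)    # resource the feeder converts
  racc <- if (r == 5L) 3L else acceptor_of(traits, r)
  if (is.na(prod_of[f]) || racc != prod_of[f]) {
    stop(omz_types[r], " does not consume the acceptor excreted by ", omz_types[f])
  }
  traits$a * traits$Y[f, conv[f]] / mu_recipient
}

#' Zero net growth isoclines
#'
#' For a type using both axis resources the ZNGI is the L-shaped corner at
#' its two subsistence concentrations. For anammox (B5) on the (OM, NO3)
#' supply axes, which it does not itself consume, a derived boundary is
#' computed numerically: for each NO3 inflow, bisection on the OM inflow
#' locates the smallest supply at which the single-B1 subsystem equilibrium
#' biomass first meets the feeder-threshold criterion (see
#' [feeder_threshold()]). This derived curve lies strictly above B1's own
#' persistence boundary: anammox persists only once its feeder establishes
#' sufficient biomass.
#'
#' @inheritParams rstar
#' @param axes pair of resource names (direct case) or supply axes
#'   `c("OM", "NO3")` (derived anammox case)
#' @param ranges axis upper limits used to trace the polyline arms
#' @param s2 NO3 inflow values at which to evaluate the derived anammox
#'   boundary
#' @param mu_recipient recipient growth rate used in the threshold criterion
#' @return object of class `zngi`: list with `type`, `axes`, `corner` (direct
#'   case) and `vertices` (data.frame tracing the polyline)
#' @export
zngi <- function(traits, i, axes = c("OM", "NO3"), ranges = c(30, 30),
                 s2 = NULL, mu_recipient = traits$a) {
  i <- type_index(i)
  ax <- resource_index(axes)
  if (i == 5L && !all(traits$A[5L, ax] == 1L)) {
    return(zngi_anammox(traits, ax, ranges, s2, mu_recipient))
  }
  if (!all(traits$A[i, ax] == 1L)) {
    stop(omz_types[i], " does not use both of ",
         paste(omz_resources[ax], collapse = ", "))
  }
  r1 <- rstar(traits, i, ax[1]); r2 <- rstar(traits, i, ax[2])
  vertices <- data.frame(x = c(r1, r1, ranges[1]), y = c(ranges[2], r2, r2))
  names(vertices) <- omz_resources[ax]
  structure(list(type = omz_types[i], axes = omz_resources[ax],
                 corner = stats::setNames(c(r1, r2), omz_resources[ax]),
                 vertices = vertices),
            class = "zngi")
}

zngi_anammox <- function(traits, ax, ranges, s2, mu_recipient) {
  if (!identical(ax, c(1L, 2L))) {
    stop("the derived anammox boundary is defined on the (OM, NO3) supply axes")
  }
  if (is.null(s2)) s2 <- seq(1, ranges[2], length.out = 30)
  thr <- feeder_threshold(traits, 1, 5, mu_recipient)
  b1_at <- function(s1, s2v) {
    eq <- closed_form_equilibrium(traits, 1, c(s1, s2v, 0, 0, 0))
    eq$B[1]
  }
  lo0 <- rstar(traits, 1, "OM")
  s1_min <- vapply(s2, function(s2v) {
    hi <- max(ranges[1], 10 * (lo0 + thr / traits$Y[1, 1]))
    if (b1_at(hi, s2v) < thr) return(NA_real_)
    lo <- lo0
    for (it in 1:60) {
      mid <- (lo + hi) / 2
      if (b1_at(mid, s2v) >= thr) hi <- mid else lo <- mid
    }
    hi
  }, numeric(1))
  vertices <- data.frame(OM = s1_min, NO3 = s2)
  structure(list(type = "B5", axes = c("OM", "NO3"), corner = NULL,
                 threshold = thr, vertices = vertices),
            class = "zngi")
}

#' @export
print.zngi <- function(x, ...) {
  cat("ZNGI of", x$type, "on (", paste(x$axes, collapse = ", "), ")\n")
  if (!is.null(x$corner)) {
    cat("Corner (R*):", paste(signif(x$corner, 4), collapse = ", "), "\n")
  } else {
    cat("Derived feeder-threshold boundary,", nrow(x$vertices), "points\n")
  }
  invisible(x)
}

#' Export a ZNGI polyline as delimited text
#'
#' @param z a `zngi`
#' @param path output file
#' @return `path`, invisibly
#' @export
write_zngi <- function(z, path) {
  utils::write.csv(z$vertices, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
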