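## Invasion analysis, assembly-order experiments, priority-effect detection.

#' Invasion rate of a type into a resident equilibrium
#'
#' Evaluates the invader's realized growth rate at the resident equilibrium's
#' (frozen) resource concentrations, the standard adaptive-dynamics
#' criterion. Invasion succeeds when the per-capita growth rate exceeds the
#' dilution rate.
#'
#' @param traits a `trait_set`
#' @param resident_eq a converged `equilibrium_result`
#' @param invader functional type (index or label)
#' @return object of class `invasion_outcome`: list with `residents`,
#'   `invader`, `invasion_rate` (per day), `limiting`, `success`
#' @export
invasion_rate <- function(traits, resident_eq, invader) {
  if (!inherits(resident_eq, "equilibrium_result") || !resident_eq$converged) {
    stop("resident equilibrium must be a converged equilibrium_result")
  }
  inv <- type_index(invader)
  g <- realized_growth(traits, resident_eq$state$R, inv)
  structure(
    list(residents = omz_types[resident_eq$persistent],
         invader = omz_types[inv],
         invasion_rate = g$rate, limiting = g$limiting,
         success = g$rate > traits$a),
    class = "invasion_outcome"
  )
}

#' @export
print.invasion_outcome <- function(x, ...) {
  cat("Invasion of", x$invader, "into {",
      paste(x$residents, collapse = ","), "}: mu =",
      signif(x$invasion_rate, 5), "/d ->",
      if (x$success) "SUCCESS" else "failure", "\n")
  invisible(x)
}

#' Sequential community assembly
#'
#' Introduces types one at a time in the given order, inoculating each at a
#' small density into the current state and re-equilibrating before the next
#' introduction. Records every intermediate equilibrium.
#'
#' @inheritParams invasion_rate
#' @param order sequence of types (indices or labels) to introduce
#' @param supply inflow 5-vector (see [supply_spec()])
#' @param inoculum introduction density (uM N); small enough not to perturb
#'   residents, large enough to avoid underflow against the extinction
#'   threshold
#' @param ... passed to [find_equilibrium()]
#' @return object of class `assembly_record`: list with `order`, `final`
#'   (`equilibrium_result`) and `history` (list of intermediate equilibria)
#' @export
assemble_community <- function(traits, order, supply, inoculum = 1e-6, ...) {
  if (!length(order)) stop("assembly order must contain at least one type")
  ord <- type_index(order)
  s <- as_supply(supply)
  B <- numeric(7); R <- s
  history <- vector("list", length(ord))
  eq <- NULL
  for (k in seq_along(ord)) {
    B[ord[k]] <- B[ord[k]] + inoculum
    eq <- find_equilibrium(traits, s, init = list(B = B, R = R), ...)
    history[[k]] <- eq
    B <- eq$state$B; R <- eq$state$R
  }
  structure(list(order = omz_types[ord], final = eq, history = history),
            class = "assembly_record")
}

#' @export
print.assembly_record <- function(x, ...) {
  cat("Assembly order:", paste(x$order, collapse = " -> "), "\n")
  cat("Final ")
  print(x$final)
  invisible(x)
}

#' Detect multistability (priority effects) of a subsystem
#'
#' Runs a canonical battery of assembly orders — each subsystem type
#' introduced first followed by the rest in index order, plus the
#' all-at-once start — and clusters the final states, first by the identity
#' of the persistent set and then by relative state distance. Because a type
#' introduced before its substrate exists washes out and is never
#' reintroduced, some orders end in assembly dead-ends that an excluded type
#' could still invade; those are reported but are not alternative stable
#' states. The subsystem is bistable when at least two distinct clusters are
#' converged and mutually non-invasible (every excluded subsystem type has
#' invasion rate at most `a + 1e-6`), verified via [invasion_rate()].
#'
#' @inheritParams assemble_community
#' @param subsystem set of types (indices or labels)
#' @param cluster_tol relative state-distance tolerance for clustering
#' @param ... passed to [find_equilibrium()] via [assemble_community()]
#' @return list with `states` (one representative `equilibrium_result` per
#'   cluster), `labels` (community label per cluster), `non_invasible`
#'   (logical per cluster), `stable` (indices of converged non-invasible
#'   clusters), `bistable` (`length(stable) >= 2`), `orders` (the battery)
#'   and `outcome` (cluster index per order)
#' @export
detect_multistability <- function(traits, supply, subsystem, inoculum = 1e-6,
                                  cluster_tol = 1e-4, ...) {
  sub <- sort(type_index(subsystem))
  s <- as_supply(supply)
  orders <- lapply(sub, function(t1) c(t1, setdiff(sub, t1)))
  finals <- lapply(orders, function(o) {
    assemble_community(traits, o, s, inoculum = inoculum, ...)$final
  })
  ## all-at-once start at the standard sweep inoculation density
  finals <- c(finals, list(find_equilibrium(traits, s, subsystem = sub, ...)))
  orders <- c(orders, list(sub))

  key <- vapply(finals, classify_community, character(1))
  dist_rel <- function(e1, e2) {
    x1 <- c(e1$state$B, e1$state$R); x2 <- c(e2$state$B, e2$state$R)
    max(abs(x1 - x2) / pmax(abs(x1), abs(x2), 1e-6))
  }
  cluster <- integer(length(finals))
  reps <- list()
  for (k in seq_along(finals)) {
    hit <- 0L
    for (ci in seq_along(reps)) {
      if (key[k] == key[reps[[ci]]] &&
          dist_rel(finals[[k]], finals[[reps[[ci]]]]) < cluster_tol) {
        hit <- ci; break
      }
    }
    if (hit == 0L) { reps[[length(reps) + 1L]] <- k; hit <- length(reps) }
    cluster[k] <- hit
  }
  states <- finals[unlist(reps)]
  non_inv <- vapply(states, function(eq) {
    if (!eq$converged) return(NA)
    absent <- sub[!eq$persistent[sub]]
    all(vapply(absent, function(t) {
      invasion_rate(traits, eq, t)$invasion_rate <= traits$a + 1e-6
    }, logical(1)))
  }, logical(1))
  stable <- which(!is.na(non_inv) & non_inv)
  list(states = states, labels = key[unlist(reps)],
       non_invasible = non_inv, stable = stable,
       bistable = length(stable) >= 2L,
       orders = lapply(orders, function(o) omz_types[o]),
       outcome = cluster)
}

#' Export assembly results as a long table
#'
#' One row per (order id, stage, type) with the equilibrium biomass.
#'
#' @param records list of `assembly_record`s
#' @param path output file
#' @return `path`, invisibly
#' @export
write_assembly <- function(records, path) {
  rows <- list()
  for (oi in seq_along(records)) {
    rec <- records[[oi]]
    for (st in seq_along(rec$history)) {
      eq <- rec$history[[st]]
      rows[[length(rows) + 1L]] <- data.frame(
        order_id = oi, order = paste(rec$order, collapse = ">"),
        stage = st, type = omz_types, biomass = unname(eq$state$B)
      )
    }
  }
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
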