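## 2D OM x NO3 supply-space sweeps: community-composition and nitrogen-loss
## regime maps.

#' Logarithmic supply axis
#'
#' The default grid axis for supply sweeps: `n` log-spaced inflow
#' concentrations between `from` and `to` (uM N). The range straddles every
#' subsistence concentration of the builtin trait set (0.011--0.31 uM N) as
#' well as the stoichiometric NO3:OM demand ratio (13.6) of the nitrate
#' reducer, so both the low-supply persistence boundaries and the
#' ratio-controlled coexistence wedges fall inside the grid.
#'
#' @param from,to axis range (uM N), both positive
#' @param n number of grid points
#' @return numeric vector of length `n`
#' @export
supply_axis <- function(from = 0.01, to = 30, n = 61) {
  if (from <= 0 || to <= from) stop("need 0 < from < to")
  exp(seq(log(from), log(to), length.out = n))
}

#' Canonical community label
#'
#' Sorted "+"-joined label of the persistent set ("B1+B3"), "none" for an
#' empty set, "nonstationary" for a non-converged run, and
#' `"bistable:{A|B}"` when a list of distinct equilibria is supplied.
#'
#' @param eq an `equilibrium_result`, or a list of them (bistable set)
#' @return character label
#' @export
classify_community <- function(eq) {
  if (inherits(eq, "equilibrium_result")) {
    if (!eq$converged) return("nonstationary")
    if (!any(eq$persistent)) return("none")
    return(paste(omz_types[eq$persistent], collapse = "+"))
  }
  if (is.list(eq)) {
    labs <- vapply(eq, classify_community, character(1))
    labs <- unique(labs)
    if (length(labs) == 1L) return(labs)
    return(paste0("bistable:{", paste(sort(labs), collapse = "|"), "}"))
  }
  stop("expected an equilibrium_result or a list of them")
}

#' Classify the nitrogen-loss pathway of an equilibrium
#'
#' A pure function of the gaseous fluxes (threshold `tol`, in uM N per day):
#' \describe{
#'   \item{conserved}{no N2 production and no N2O production -- all nitrogen
#'     is retained in tracked pools}
#'   \item{N2_only}{N2 produced, no N2O production}
#'   \item{N2O_no_consumption}{N2O produced but not consumed -- the
#'     accumulation-potential regime: steady-state N2O is set by supply and
#'     dilution, not by a consumer's R*}
#'   \item{N2O_cycled_with_N2}{N2O both produced and consumed (cycled as an
#'     intermediate), with N2 as the terminal product}
#' }
#'
#' @param fluxes a `flux_record` (or an `equilibrium_result`)
#' @param tol flux zero-threshold (uM N per day)
#' @return character label
#' @export
classify_nloss <- function(fluxes, tol = 1e-10) {
  if (inherits(fluxes, "equilibrium_result")) fluxes <- fluxes$fluxes
  g <- fluxes$gas
  n2 <- g[["N2"]] > tol
  prod <- g[["N2O_prod"]] > tol
  cons <- g[["N2O_cons"]] > tol
  if (!n2 && !prod) return("conserved")
  if (n2 && !prod) return("N2_only")
  if (prod && !cons) return("N2O_no_consumption")
  "N2O_cycled_with_N2"
}

#' Sweep the 2D OM x NO3 supply space
#'
#' Runs [find_equilibrium()] from the all-present start for every (s1, s2)
#' grid cell and records the community composition, nitrogen-loss pathway
#' and gas fluxes. Deterministic given its settings; solver failures are
#' recorded per cell (label "error"), not fatal. With `bistable = TRUE`
#' every cell additionally runs [detect_multistability()] (battery of
#' assembly orders; roughly 8x the cost), and bistable cells are labelled
#' `"bistable:{...}"`.
#'
#' The axes are the inflow concentrations `s_j` (uM N) of the chemostat
#' exchange term `a (s_j - R_j)`; multiply by `a` for supply in uM N per day.
#' The default axes are logarithmically spaced over 0.01--30 uM N
#' (see [supply_axis()]): every subsistence concentration of the builtin
#' trait set lies between 0.011 and 0.31 uM N, so the persistence and
#' feeder-threshold boundaries that organize the map sit below 1 uM N and
#' are only resolved by log spacing.
#'
#' @inheritParams find_equilibrium
#' @param subsystem types present (indices or labels); default all seven
#' @param s1,s2 grid axis values for OM and NO3 inflow (uM N)
#' @param bistable run the assembly-order battery per cell (default off)
#' @param ... passed to [find_equilibrium()]
#' @return object of class `regime_map`: list with `s1`, `s2`, `cells` (long
#'   data.frame with columns s1, s2, community, nloss, N2, N2O_prod,
#'   N2O_cons, netN2O, converged, persistent columns B1..B7) and `meta`
#' @export
supply_sweep <- function(traits, subsystem = 1:7,
                         s1 = supply_axis(),
                         s2 = supply_axis(),
                         bistable = FALSE, inoculum = 1e-3, ...) {
  sub <- sort(type_index(subsystem))
  grid <- expand.grid(s1 = s1, s2 = s2, KEEP.OUT.ATTRS = FALSE)
  n <- nrow(grid)
  community <- character(n); nloss <- character(n)
  N2 <- numeric(n); prod <- numeric(n); cons <- numeric(n)
  conv <- logical(n)
  pers <- matrix(FALSE, n, 7, dimnames = list(NULL, omz_types))
  for (k in seq_len(n)) {
    s <- c(grid$s1[k], grid$s2[k], 0, 0, 0)
    eq <- tryCatch(
      find_equilibrium(traits, s, subsystem = sub, inoculum = inoculum, ...),
      error = function(e) e
    )
    if (inherits(eq, "error")) {
      community[k] <- "error"; nloss[k] <- NA_character_
      N2[k] <- prod[k] <- cons[k] <- NA_real_
      next
    }
    if (bistable) {
      ms <- detect_multistability(traits, s, sub, ...)
      keep <- if (length(ms$stable)) ms$stable else seq_along(ms$states)
      community[k] <- classify_community(ms$states[keep])
      eq <- ms$states[[keep[1]]]
    } else {
      community[k] <- classify_community(eq)
    }
    g <- eq$fluxes$gas
    N2[k] <- g[["N2"]]; prod[k] <- g[["N2O_prod"]]; cons[k] <- g[["N2O_cons"]]
    nloss[k] <- classify_nloss(eq)
    conv[k] <- eq$converged
    pers[k, ] <- eq$persistent
  }
  cells <- data.frame(grid, community = community, nloss = nloss,
                      N2 = N2, N2O_prod = prod, N2O_cons = cons,
                      netN2O = prod - cons, converged = conv)
  cells <- cbind(cells, as.data.frame(pers))
  structure(list(s1 = s1, s2 = s2, cells = cells,
                 meta = list(subsystem = omz_types[sub],
                             dilution = traits$a,
                             bistable_aware = bistable,
                             inoculum = inoculum)),
            class = "regime_map")
}

#' @export
print.regime_map <- function(x, ...) {
  cat("Regime map:", length(x$s1), "x", length(x$s2), "supply grid, subsystem {",
      paste(x$meta$subsystem, collapse = ","), "}\n")
  print(table(x$cells$community))
  cat("Nitrogen-loss pathways:\n")
  print(table(x$cells$nloss))
  invisible(x)
}

#' Niche breadth of a functional type across a regime map
#'
#' Fraction of converged grid cells in which the type persists. In
#' bistable-aware maps a cell counts if the type appears in any branch of
#' the bistable label.
#'
#' @param map a `regime_map`
#' @param i functional type (index or label)
#' @return fraction in `[0, 1]` (0 for an empty map)
#' @export
niche_breadth <- function(map, i) {
  i <- type_index(i)
  cells <- map$cells
  ok <- cells$converged | startsWith(cells$community, "bistable")
  if (!any(ok)) return(0)
  hit <- cells[[omz_types[i]]] |
    grepl(paste0("\\b", omz_types[i], "\\b"), cells$community)
  sum(hit & ok) / sum(ok)
}

#' Write / read a regime map
#'
#' The long cell table is written as comma-separated text and the metadata
#' as a JSON sidecar (`<path>.meta.json`) when the jsonlite package is
#' available.
#'
#' @param map a `regime_map`
#' @param path output file for the cell table
#' @return `write_regime_map()` returns `path` invisibly;
#'   `read_regime_map()` returns a `regime_map`.
#' @export
write_regime_map <- function(map, path) {
  utils::write.csv(map$cells, path, row.names = FALSE, quote = FALSE)
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    jsonlite::write_json(map$meta, paste0(path, ".meta.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(path)
}

#' @rdname write_regime_map
#' @export
read_regime_map <- function(path) {
  cells <- utils::read.csv(path, stringsAsFactors = FALSE)
  meta_path <- paste0(path, ".meta.json")
  meta <- if (file.exists(meta_path) &&
              requireNamespace("jsonlite", quietly = TRUE)) {
    jsonlite::read_json(meta_path, simplifyVector = TRUE)
  } else list()
  structure(list(s1 = sort(unique(cells$s1)), s2 = sort(unique(cells$s2)),
                 cells = cells, meta = meta),
            class = "regime_map")
}
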