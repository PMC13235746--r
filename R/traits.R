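#' @keywords internal
"_PACKAGE"

## Registries -----------------------------------------------------------------

#' Resource and functional-type registries
#'
#' The model tracks five dissolved pools, indexed 1--5, all expressed in
#' micromolar nitrogen atoms (N2O included, so its half-saturation constant in
#' N units applies directly):
#' OM (organic matter N), NO3 (nitrate), NO2 (nitrite), N2O (nitrous oxide),
#' NH4 (ammonium).
#'
#' Seven microbial functional types, indexed 1--7:
#' \describe{
#'   \item{B1}{NO3 -> NO2 denitrifier (heterotroph; OM + NO3)}
#'   \item{B2}{NO3 -> N2O denitrifier (heterotroph; OM + NO3)}
#'   \item{B3}{NO2 -> N2 denitrifier (heterotroph; OM + NO2)}
#'   \item{B4}{N2O -> N2 denitrifier (heterotroph; OM + N2O)}
#'   \item{B5}{anammox bacteria (autotroph; NO2 + NH4)}
#'   \item{B6}{NO2 -> N2O denitrifier (heterotroph; OM + NO2)}
#'   \item{B7}{complete denitrifier NO3 -> N2 (heterotroph; OM + NO3)}
#' }
#'
#' @format `omz_resources` is a character vector of length 5; `omz_types` a
#'   character vector of length 7; `omz_pathways` the reduction pathway
#'   carried out by each type.
#' @export
omz_resources <- c("OM", "NO3", "NO2", "N2O", "NH4")

#' @rdname omz_resources
#' @export
omz_types <- paste0("B", 1:7)

#' @rdname omz_resources
#' @export
omz_pathways <- c(
  B1 = "NO3->NO2", B2 = "NO3->N2O", B3 = "NO2->N2", B4 = "N2O->N2",
  B5 = "anammox", B6 = "NO2->N2O", B7 = "NO3->N2"
)

## index helpers: accept 1-based integers or registry names
type_index <- function(i) {
  if (is.character(i)) {
    idx <- match(i, omz_types)
    if (anyNA(idx)) stop("unknown functional type: ", paste(i[is.na(idx)], collapse = ", "))
    return(idx)
  }
  i <- as.integer(i)
  if (any(i < 1L | i > 7L)) stop("type index must be in 1..7")
  i
}

resource_index <- function(j) {
  if (is.character(j)) {
    idx <- match(j, omz_resources)
    if (anyNA(idx)) stop("unknown resource: ", paste(j[is.na(idx)], collapse = ", "))
    return(idx)
  }
  j <- as.integer(j)
  if (any(j < 1L | j > 5L)) stop("resource index must be in 1..5")
  j
}

## resource-usage indicator matrix (rows = types, cols = resources)
usage_matrix <- function() {
  A <- matrix(0L, 7, 5, dimnames = list(omz_types, omz_resources))
  A[1, c(1, 2)] <- 1L  # B1: OM + NO3
  A[2, c(1, 2)] <- 1L  # B2: OM + NO3
  A[3, c(1, 3)] <- 1L  # B3: OM + NO2
  A[4, c(1, 4)] <- 1L  # B4: OM + N2O
  A[5, c(3, 5)] <- 1L  # B5: NO2 + NH4 (no OM: chemoautotroph)
  A[6, c(1, 3)] <- 1L  # B6: OM + NO2
  A[7, c(1, 2)] <- 1L  # B7: OM + NO3
  A
}

## builtin physiological trait rows (Vm: mol resource-N / mol biomass-N / d;
## K: uM N; y: mol biomass-N / mol resource-N)
builtin_trait_rows <- function() {
  data.frame(
    type = c("B1", "B1", "B2", "B2", "B3", "B3", "B4", "B4",
             "B5", "B5", "B6", "B6", "B7", "B7"),
    resource = c("OM", "NO3", "OM", "NO3", "OM", "NO2", "OM", "N2O",
                 "NH4", "NO2", "OM", "NO2", "OM", "NO3"),
    vmax = c(1.377, 50.8, 1.377, 50.8, 1.377, 50.8, 1.377, 50.8,
             50.8, 50.8, 1.377, 50.8, 1.377, 50.8),
    K = c(0.1, 4, 0.1, 4, 0.1, 4, 0.1, 0.6, 0.45, 0.45, 0.1, 4, 0.1, 4),
    yield = c(0.15, 0.011, 0.148, 0.023, 0.197, 0.024, 0.298, 0.013,
              0.013, 0.011, 0.201, 0.016, 0.138, 0.026),
    stringsAsFactors = FALSE
  )
}

## Construction ---------------------------------------------------------------

new_trait_set <- function(Vm, K, Y, A, dilution, nh4_factor = 1) {
  used <- A == 1L
  YVm <- Y * Vm
  YVm[!used] <- NA_real_
  invY <- 1 / Y
  invY[!used] <- 0
  # per-biomass NH4 regeneration coefficient per unit growth rate:
  # e_i5 / mu_i = (1/y_iOM - 1) for heterotrophs, 0 for anammox
  e5_coef <- ifelse(used[, 1], (1 / Y[, 1] - 1) * nh4_factor, 0)
  e5_coef[is.na(e5_coef)] <- 0
  structure(
    list(Vm = Vm, K = K, Y = Y, A = A, a = dilution,
         nh4_factor = nh4_factor,
         YVm = YVm, invY = invY, e5_coef = e5_coef,
         types = omz_types, resources = omz_resources),
    class = "trait_set"
  )
}

#' Builtin trait parameterization of the seven anaerobic nitrogen cyclers
#'
#' Returns the physiological trait set used throughout: maximum specific
#' uptake rates, half-saturation constants and biomass yields for each of the
#' 14 used (type, resource) pairs, together with the binary resource-usage
#' matrix and the chemostat dilution rate.
#'
#' The default dilution rate of 0.04 per day is the value recovered by
#' inverting the subsistence-concentration relation `R* = K a / (y Vm - a)`
#' against the tabulated `R*` values of the source trait compilation; because
#' tabulated yields are rounded, back-computed `R*` match the tabulated column
#' to about 1% on well-conditioned rows and to within 5% everywhere (see
#' [validate_traits()] and [rstar()]).
#'
#' @param dilution chemostat dilution rate `a` (per day). Must be positive and
#'   smaller than `y * Vm` for every used pair, otherwise no population can
#'   persist.
#' @param nh4_factor optional scalar multiplier on the ammonium regeneration
#'   coefficient `e_i5 = mu_i (1/y_iOM - 1)` for sensitivity runs (default 1,
#'   the nitrogen-balance closure).
#' @return An object of class `trait_set`: a list with 7x5 matrices `Vm`, `K`,
#'   `Y` (NA where a resource is unused), integer usage matrix `A`, dilution
#'   rate `a`, and registries.
#' @seealso [read_traits()], [validate_traits()], [rstar()]
#' @examples
#' tr <- omz_traits()
#' rstar(tr, "B1", "OM")  # ~0.024 uM N
#' @export
omz_traits <- function(dilution = 0.04, nh4_factor = 1) {
  rows <- builtin_trait_rows()
  traits_from_frame(rows, dilution = dilution, nh4_factor = nh4_factor)
}

## assemble a trait_set from a (type, resource, vmax, K, yield) data.frame
traits_from_frame <- function(rows, dilution, nh4_factor = 1) {
  req <- c("type", "resource", "vmax", "K", "yield")
  miss <- setdiff(req, names(rows))
  if (length(miss)) stop("trait table is missing column(s): ", paste(miss, collapse = ", "))
  ti <- type_index(rows$type)
  rj <- resource_index(rows$resource)
  key <- paste(rows$type, rows$resource)
  if (anyDuplicated(key)) {
    stop("duplicate (type, resource) trait row(s): ",
         paste(unique(key[duplicated(key)]), collapse = ", "))
  }
  for (col in c("vmax", "K", "yield")) {
    bad <- !is.finite(rows[[col]]) | rows[[col]] <= 0
    if (any(bad)) {
      stop("non-positive ", col, " in trait row(s): ",
           paste(key[bad], collapse = ", "))
    }
  }
  dm <- list(omz_types, omz_resources)
  Vm <- matrix(NA_real_, 7, 5, dimnames = dm)
  K <- matrix(NA_real_, 7, 5, dimnames = dm)
  Y <- matrix(NA_real_, 7, 5, dimnames = dm)
  A <- matrix(0L, 7, 5, dimnames = dm)
  idx <- cbind(ti, rj)
  Vm[idx] <- rows$vmax
  K[idx] <- rows$K
  Y[idx] <- rows$yield
  A[idx] <- 1L
  tr <- new_trait_set(Vm, K, Y, A, dilution, nh4_factor)
  bad <- which(A == 1L & !(dilution < Y * Vm), arr.ind = TRUE)
  if (nrow(bad)) {
    lab <- paste0("(", omz_types[bad[, 1]], ", ", omz_resources[bad[, 2]], ")")
    stop("dilution rate a = ", dilution, " is not below y*Vm for ",
         paste(lab, collapse = ", "),
         ": the subsistence concentration R* = K a/(y Vm - a) is undefined ",
         "and the population cannot persist at any concentration")
  }
  tr
}

#' Tabular view of a trait set
#'
#' One row per used (type, resource) pair with columns
#' `type, resource, vmax, K, yield` plus the implied subsistence
#' concentration `rstar` at the set's dilution rate.
#'
#' @param x a `trait_set`
#' @param ... unused
#' @return a `data.frame` with 14 rows for the builtin fixture
#' @export
as.data.frame.trait_set <- function(x, ...) {
  used <- which(x$A == 1L, arr.ind = TRUE)
  used <- used[order(used[, 1], used[, 2]), , drop = FALSE]
  data.frame(
    type = omz_types[used[, 1]],
    resource = omz_resources[used[, 2]],
    vmax = x$Vm[used],
    K = x$K[used],
    yield = x$Y[used],
    rstar = x$K[used] * x$a / (x$Y[used] * x$Vm[used] - x$a),
    stringsAsFactors = FALSE
  )
}

#' @export
print.trait_set <- function(x, ...) {
  cat("Trait set: 7 functional types x 5 resources,",
      sum(x$A), "used pairs, dilution a =", x$a, "/d\n")
  print(as.data.frame(x), digits = 4)
  invisible(x)
}

## IO -------------------------------------------------------------------------

#' Read and write trait tables
#'
#' Trait tables are plain comma-separated text with header columns
#' `type,resource,vmax,K,yield`, one row per used (type, resource) pair; types
#' and resources are referenced by registry labels ("B1".."B7",
#' "OM","NO3","NO2","N2O","NH4"). Numeric values round-trip exactly for
#' decimal inputs of up to six significant digits.
#'
#' @param path file path
#' @param dilution dilution rate to attach to the loaded set (per day)
#' @param nh4_factor see [omz_traits()]
#' @param traits a `trait_set` to write
#' @return `read_traits()` returns a validated `trait_set`; `write_traits()`
#'   returns `path` invisibly.
#' @export
read_traits <- function(path, dilution = 0.04, nh4_factor = 1) {
  rows <- utils::read.csv(path, stringsAsFactors = FALSE)
  tr <- traits_from_frame(rows, dilution = dilution, nh4_factor = nh4_factor)
  viol <- validate_traits(tr)
  if (length(viol)) stop("invalid trait table: ", paste(viol, collapse = "; "))
  tr
}

#' @rdname read_traits
#' @export
write_traits <- function(traits, path) {
  df <- as.data.frame(traits)
  utils::write.csv(df[, c("type", "resource", "vmax", "K", "yield")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

## Validation -----------------------------------------------------------------

#' Validate a trait set
#'
#' Checks the structural invariants of the parameterization and returns a
#' character vector of violations (empty when the set is valid):
#' dimensions and binary usage matrix; anammox (B5) must use NO2 and NH4 only
#' (in particular it must not consume OM); every heterotroph must use OM plus
#' exactly one nitrogen acceptor; all parameters strictly positive on used
#' pairs and absent elsewhere; the persistence condition `a < y Vm` on every
#' used pair; and the donor/acceptor competitive trade-off between the two
#' nitrate reducers (`R*` of B1 lower on OM, higher on NO3, than B2) when both
#' are parameterized.
#'
#' @param traits a `trait_set`
#' @return character vector of human-readable violations; `character(0)` if
#'   none.
#' @export
validate_traits <- function(traits) {
  v <- character(0)
  A <- traits$A
  if (!all(dim(A) == c(7, 5))) {
    return("usage matrix must be 7 types x 5 resources")
  }
  if (!all(A %in% c(0L, 1L))) v <- c(v, "usage matrix entries must be 0/1")
  if (A[5, 1] == 1L) v <- c(v, "B5 must not use OM (anammox is autotrophic)")
  if (!identical(as.integer(A[5, ]), c(0L, 0L, 1L, 0L, 1L))) {
    v <- c(v, "B5 must use exactly NO2 and NH4")
  }
  for (i in setdiff(1:7, 5)) {
    if (A[i, 1] != 1L || sum(A[i, 2:4]) != 1L || A[i, 5] != 0L) {
      v <- c(v, paste0(omz_types[i], " must use OM plus exactly one N acceptor"))
    }
  }
  used <- A == 1L
  for (p in c("Vm", "K", "Y")) {
    M <- traits[[p]]
    bad <- used & (!is.finite(M) | M <= 0)
    if (any(bad)) {
      w <- which(bad, arr.ind = TRUE)
      v <- c(v, paste0(p, " must be positive for (", omz_types[w[, 1]], ", ",
                       omz_resources[w[, 2]], ")"))
    }
    stray <- !used & is.finite(M)
    if (any(stray)) {
      w <- which(stray, arr.ind = TRUE)
      v <- c(v, paste0(p, " defined for unused pair (", omz_types[w[, 1]],
                       ", ", omz_resources[w[, 2]], ")"))
    }
  }
  if (!is.finite(traits$a) || traits$a < 0) {
    v <- c(v, "dilution rate must be a non-negative number")
  } else if (traits$a > 0) {
    nper <- used & is.finite(traits$Y) & is.finite(traits$Vm) &
      !(traits$a < traits$Y * traits$Vm)
    if (any(nper)) {
      w <- which(nper, arr.ind = TRUE)
      v <- c(v, paste0("persistence condition a < y*Vm violated for (",
                       omz_types[w[, 1]], ", ", omz_resources[w[, 2]],
                       "): y*Vm = ",
                       signif(traits$Y[nper] * traits$Vm[nper], 4),
                       " <= a = ", traits$a))
    }
  }
  # donor/acceptor trade-off between the two primary NO3 reducers
  if (!length(v) && all(used[1:2, 1]) && all(used[1:2, 2]) && traits$a > 0) {
    rs <- function(i, j) traits$K[i, j] * traits$a / (traits$Y[i, j] * traits$Vm[i, j] - traits$a)
    if (!(rs(1, 1) < rs(2, 1))) {
      v <- c(v, "trade-off violated: B1 should have the lower R* for OM")
    }
    if (!(rs(1, 2) > rs(2, 2))) {
      v <- c(v, "trade-off violated: B2 should have the lower R* for NO3")
    }
  }
  v
}
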