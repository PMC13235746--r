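# shared fixtures and utilities for the suite

fixture_traits <- omz_traits()

rel_err <- function(x, ref) abs(x - ref) / abs(ref)

# draw a feasible random supply for a single type: every used resource is
# supplied above its subsistence concentration
random_feasible_supply <- function(traits, i, scale = 20) {
  used <- which(traits$A[type_index(i), ] == 1L)
  s <- numeric(5)
  for (j in used) {
    rs <- rstar(traits, i, j)
    s[j] <- 2 * rs + stats::runif(1, 0, scale)
  }
  s
}

# printed R* column of the builtin trait compilation, keyed type.resource
printed_rstar <- c(
  B1.OM = 0.024, B1.NO3 = 0.295, B2.OM = 0.0245, B2.NO3 = 0.144,
  B3.OM = 0.0172, B3.NO2 = 0.138, B4.OM = 0.0108, B4.N2O = 0.039,
  B5.NH4 = 0.028, B5.NO2 = 0.034, B6.OM = 0.0169, B6.NO2 = 0.2066,
  B7.OM = 0.0268, B7.NO3 = 0.124
)
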