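# Shared fixtures: small configs and brute-force oracles used across tests.

fast_config <- function(seed = 11L, ...) {
  args <- list(...)
  defaults <- list(seed = seed, n_animals_per_target = 1L,
                   n_L6_cells = 300L, n_L5_cells = 40L, n_brainwide = 1000L,
                   n_sc_cells = 150L, border_jitter_um = 0)
  do.call(synth_config, utils::modifyList(defaults, args))
}

# trapezoid integral of a density data frame
grid_integral <- function(d) {
  sum(diff(d$grid) * (head(d$density, -1) + tail(d$density, -1)) / 2)
}

# Enumerate all tables with the margins of a 2 x c table and return the
# exact Fisher p (probability-mass extremeness definition).
fisher_exact_enum <- function(tab) {
  rs <- rowSums(tab); cs <- colSums(tab)
  stopifnot(nrow(tab) == 2)
  ranges <- lapply(seq_along(cs), function(j) 0:min(cs[j], rs[1]))
  grid <- expand.grid(ranges)
  keep <- rowSums(grid) == rs[1]
  grid <- grid[keep, , drop = FALSE]
  logp <- apply(grid, 1, function(a) {
    t2 <- rbind(as.numeric(a), cs - as.numeric(a))
    if (any(t2 < 0)) return(NA_real_)
    sum(lgamma(rs + 1)) + sum(lgamma(cs + 1)) -
      lgamma(sum(cs) + 1) - sum(lgamma(t2 + 1))
  })
  logp <- logp[!is.na(logp)]
  p_obs <- sum(lgamma(rs + 1)) + sum(lgamma(cs + 1)) -
    lgamma(sum(tab) + 1) - sum(lgamma(tab + 1))
  sum(exp(logp)[logp <= p_obs + 1e-7])
}

# A two-rectangle map with known areas for assignment tests.
two_area_map <- function() {
  flatmap_parcellation("toy", list(
    A = cbind(x = c(0, 1000, 1000, 0), y = c(0, 0, 1000, 1000)),
    B = cbind(x = c(1000, 4000, 4000, 1000), y = c(0, 0, 1000, 1000))
  ))
}
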