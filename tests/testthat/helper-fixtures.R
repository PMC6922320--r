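# Shared fixtures, all built in code.

# two-species chain: A eats m0 -> secretes m1; B eats m1 -> secretes m2,
# which nothing consumes
chain_net <- function() {
  cross_feeding_network(data.frame(
    species    = c("A", "A", "B", "B"),
    metabolite = c("m0", "m1", "m1", "m2"),
    direction  = c("consumption", "production",
                   "consumption", "production")
  ))
}

# every species consumes and produces every metabolite: nothing is ever
# unconsumable and no species lacks byproducts, so biomass has the
# geometric closed form 1 - f^N
complete_net <- function(n_species = 3L, n_metabolites = 2L) {
  sp <- paste0("S", seq_len(n_species))
  met <- paste0("m", seq_len(n_metabolites))
  grid <- expand.grid(species = sp, metabolite = met,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  cross_feeding_network(rbind(
    cbind(grid, direction = "consumption"),
    cbind(grid, direction = "production")
  ))
}

# random network + sample + intake for property tests; may contain
# unconsumable metabolites and byproduct-free species
random_instance <- function(seed, n_species = NULL, n_metabolites = NULL,
                            no_sink = FALSE) {
  set.seed(seed)
  S <- if (is.null(n_species)) sample(3:60, 1) else n_species
  M <- if (is.null(n_metabolites)) sample(4:80, 1) else n_metabolites
  sp <- paste0("sp", seq_len(S))
  met <- paste0("met", seq_len(M))
  rows <- list()
  for (s in sp) {
    cm <- sample(met, sample(1:min(4, M), 1))
    rows[[length(rows) + 1L]] <- data.frame(species = s, metabolite = cm,
                                            direction = "consumption")
    n_pm <- if (no_sink) sample(1:min(3, M), 1) else sample(0:min(3, M), 1)
    if (n_pm > 0) {
      pm <- sample(met, n_pm)
      rows[[length(rows) + 1L]] <- data.frame(species = s, metabolite = pm,
                                              direction = "production")
    }
  }
  net <- cross_feeding_network(unique(do.call(rbind, rows)),
                               species = sp, metabolites = met)
  ab <- stats::runif(S)
  sample <- community_sample("rnd", stats::setNames(ab / sum(ab), sp))
  n_int <- sample(1:min(5, M), 1)
  intake <- stats::setNames(stats::runif(n_int, 0.1, 1), sample(met, n_int))
  f <- stats::runif(1, 0.11, 0.98)
  N <- sample(1:10, 1)
  list(net = net, sample = sample, intake = intake,
       params = flow_parameters(f = f, n_levels = N))
}

mass_balance_residual <- function(fl) {
  tot <- sum(fl$intake)
  abs(sum(fl$biomass) + sum(fl$metabolome) + sum(fl$sink_by_level) - tot) / tot
}

# independent matrix-power oracle for the closed-form biomass expression
# (1-f) f^(l-1) A_in (A_out A_in)^(l-1) c, implemented with plain loops,
# no reuse of cascade_core
oracle_biomass <- function(net, sample, intake, params) {
  mets <- union(net$metabolites, names(intake))
  sp <- names(sample$abundances)
  Ain <- matrix(0, length(sp), length(mets), dimnames = list(sp, mets))
  for (r in seq_len(nrow(net$consumption))) {
    a <- net$consumption$species[r]; i <- net$consumption$metabolite[r]
    if (a %in% sp) Ain[a, i] <- sample$abundances[[a]]
  }
  for (i in seq_along(mets)) {
    cs <- sum(Ain[, i])
    if (cs > 0) Ain[, i] <- Ain[, i] / cs
  }
  Aout <- matrix(0, length(mets), length(sp), dimnames = list(mets, sp))
  for (r in seq_len(nrow(net$production))) {
    a <- net$production$species[r]; i <- net$production$metabolite[r]
    if (a %in% sp) Aout[i, a] <- 1
  }
  for (a in seq_along(sp)) {
    cs <- sum(Aout[, a])
    if (cs > 0) Aout[, a] <- Aout[, a] / cs
  }
  iv <- stats::setNames(numeric(length(mets)), mets)
  iv[names(intake)] <- intake
  f <- params$f
  total <- numeric(length(sp))
  v <- iv
  for (l in seq_len(params$n_levels)) {
    total <- total + (1 - f) * f^(l - 1) * drop(Ain %*% v)
    v <- drop((Aout %*% Ain) %*% v)
  }
  stats::setNames(total, sp)
}
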