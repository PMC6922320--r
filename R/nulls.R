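#' Degree-preserving shuffle of metabolic capabilities
#'
#' Randomizes who-eats-what while preserving how much everyone eats: applies
#' double-edge swaps independently to the consumption and the production
#' edge sets (a swap picks two edges `(s1, m1)`, `(s2, m2)` and rewires them
#' to `(s1, m2)`, `(s2, m1)`). Each species keeps its exact number of
#' consumed and secreted metabolites and each metabolite keeps its exact
#' number of consumers and producers. `3 x |edges|` swaps are attempted per
#' edge set; attempts that would create a duplicate edge are skipped. The
#' two edge sets use independent RNG streams derived from `seed`.
#'
#' @param net a `cross_feeding_network`.
#' @param seed integer seed; shuffles are seed-deterministic.
#' @return a shuffled `cross_feeding_network` (same node lists and genus
#'   map).
#' @export
shuffle_capabilities <- function(net, seed = 1L) {
  validate_network(net)
  set.seed(seed)
  sub_seeds <- sample.int(.Machine$integer.max - 1L, 2L)
  out <- net
  out$consumption <- swap_edges(net$consumption, sub_seeds[1L])
  out$production <- swap_edges(net$production, sub_seeds[2L])
  validate_network(out)
  out
}

swap_edges <- function(e, seed) {
  n <- nrow(e)
  if (n < 2L) {
    if (n) warning("edge set too small to swap; returned unchanged")
    return(e)
  }
  if (length(unique(e$species)) < 2L) {
    warning("all edges share one species; no legal swap, returned unchanged")
    return(e)
  }
  set.seed(seed)
  sp <- e$species; met <- e$metabolite
  key <- new.env(hash = TRUE, size = 2L * n)
  for (i in seq_len(n)) assign(paste0(sp[i], "\r", met[i]), TRUE, envir = key)
  attempts <- 3L * n
  pairs <- matrix(sample.int(n, 2L * attempts, replace = TRUE), ncol = 2L)
  for (a in seq_len(attempts)) {
    i <- pairs[a, 1L]; j <- pairs[a, 2L]
    if (i == j) next
    if (sp[i] == sp[j] || met[i] == met[j]) next
    k1 <- paste0(sp[i], "\r", met[j])
    k2 <- paste0(sp[j], "\r", met[i])
    if (exists(k1, envir = key, inherits = FALSE) ||
        exists(k2, envir = key, inherits = FALSE)) next
    rm(list = c(paste0(sp[i], "\r", met[i]), paste0(sp[j], "\r", met[j])),
       envir = key)
    assign(k1, TRUE, envir = key)
    assign(k2, TRUE, envir = key)
    tmp <- met[i]; met[i] <- met[j]; met[j] <- tmp
  }
  data.frame(species = sp, metabolite = met, stringsAsFactors = FALSE)
}

#' Shuffle species labels across capability sets
#'
#' Permutes species ids jointly across both edge sets, so each capability
#' set (consumables plus byproducts) travels intact to a new name. The
#' multiset of capability sets is invariant; which species owns which set is
#' randomized.
#'
#' @inheritParams shuffle_capabilities
#' @return a `cross_feeding_network` with permuted species labels.
#' @export
shuffle_species_labels <- function(net, seed = 1L) {
  validate_network(net)
  if (length(net$species) < 2L) return(net)
  set.seed(seed)
  perm <- sample(net$species)
  relab <- stats::setNames(perm, net$species)
  out <- net
  out$consumption$species <- unname(relab[net$consumption$species])
  out$production$species <- unname(relab[net$production$species])
  validate_network(out)
  out
}

#' Random uptake rates
#'
#' Draws every lambda on a consumption edge i.i.d. from Uniform(0, 1) —
#' the robustness control for the default assumption lambda = 1. Rates off
#' consumption edges stay zero (no new capabilities appear).
#'
#' @param params a `flow_parameters` whose f, level count and secretion
#'   settings are kept.
#' @param net a `cross_feeding_network`.
#' @param seed integer seed.
#' @return a new `flow_parameters` with randomized `uptake_rates`.
#' @export
randomize_uptake_rates <- function(params, net, seed = 1L) {
  validate_network(net)
  set.seed(seed)
  e <- net$consumption
  rates <- data.frame(species = e$species, metabolite = e$metabolite,
                      rate = stats::runif(nrow(e)), stringsAsFactors = FALSE)
  flow_parameters(f = params$f, n_levels = params$n_levels,
                  uptake_rates = rates,
                  secretion_mode = params$secretion_mode,
                  secretion_weights = params$secretion_weights)
}

#' Dirichlet-distributed secretion weights
#'
#' Replaces equal byproduct splitting with per-species weights drawn from a
#' symmetric Dirichlet over each species' byproduct set (each column of the
#' secretion matrix still sums to 1). Large concentrations approach equal
#' splitting.
#'
#' @param net a `cross_feeding_network`.
#' @param seed integer seed.
#' @param concentration symmetric Dirichlet concentration (> 0); default 1
#'   (flat over the simplex).
#' @param params a `flow_parameters` whose f and level count are kept.
#' @return a `flow_parameters` in explicit secretion mode.
#' @export
dirichlet_secretion <- function(net, seed = 1L, concentration = 1,
                                params = flow_parameters()) {
  validate_network(net)
  stopifnot(concentration > 0)
  set.seed(seed)
  e <- net$production
  w <- numeric(nrow(e))
  for (sp in unique(e$species)) {
    idx <- which(e$species == sp)
    g <- stats::rgamma(length(idx), shape = concentration, rate = 1)
    # guard against all-zero gamma draws at tiny concentration
    if (sum(g) == 0) g <- rep(1, length(idx))
    w[idx] <- g / sum(g)
  }
  flow_parameters(f = params$f, n_levels = params$n_levels,
                  uptake_rates = params$uptake_rates,
                  secretion_mode = "explicit",
                  secretion_weights = data.frame(
                    species = e$species, metabolite = e$metabolite,
                    weight = w, stringsAsFactors = FALSE))
}

#' Constant enzyme-budget uptake rates
#'
#' Gives each species a fixed total uptake budget spread evenly over its
#' consumable metabolites: `lambda[a, i] = 1 / |consumables(a)|` on
#' consumption edges, so each species' rates sum to 1.
#'
#' @param net a `cross_feeding_network`.
#' @param params a `flow_parameters` whose other settings are kept.
#' @return a `flow_parameters` with budgeted `uptake_rates`.
#' @export
enzyme_budget_rates <- function(net, params = flow_parameters()) {
  validate_network(net)
  e <- net$consumption
  deg <- table(e$species)
  rates <- data.frame(species = e$species, metabolite = e$metabolite,
                      rate = 1 / as.numeric(deg[e$species]),
                      stringsAsFactors = FALSE)
  flow_parameters(f = params$f, n_levels = params$n_levels,
                  uptake_rates = rates,
                  secretion_mode = params$secretion_mode,
                  secretion_weights = params$secretion_weights)
}

#' Bootstrap resamples of a cohort
#'
#' Draws `n_datasets` cohorts, each the size of the original, by sampling
#' samples with replacement — used to measure the statistical uncertainty of
#' calibrated `(f, n_levels)` by re-running [calibrate_grid()] on each
#' resample.
#'
#' @param cht a [cohort()].
#' @param n_datasets number of resampled cohorts.
#' @param seed integer seed.
#' @return list of `cohort` objects; resampled copies of a sample get a
#'   replicate-suffixed sample id to keep ids unique.
#' @export
bootstrap_cohort <- function(cht, n_datasets = 100L, seed = 1L) {
  stopifnot(inherits(cht, "cohort"), length(cht$samples) >= 1L)
  set.seed(seed)
  n <- length(cht$samples)
  lapply(seq_len(n_datasets), function(d) {
    idx <- sample.int(n, n, replace = TRUE)
    samples <- lapply(seq_along(idx), function(k) {
      s <- cht$samples[[idx[k]]]
      dup <- sum(idx[seq_len(k)] == idx[k])
      if (dup > 1L) s$sample_id <- paste0(s$sample_id, ".rep", dup)
      s
    })
    ch <- cohort(samples, cht$network)
    attr(ch, "member_indices") <- idx
    ch
  })
}
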