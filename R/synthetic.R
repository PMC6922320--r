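#' Generate a random cross-feeding network with known structure
#'
#' Builds a random bipartite capability network for testing and simulation:
#' every species gets at least one consumable and at least one byproduct
#' (so no mass is lost to the sink by default), designated intake
#' metabolites are guaranteed at least one consumer, and species are
#' partitioned into genera. Degrees are Poisson-distributed around the
#' requested means (floored at 1).
#'
#' @param n_species,n_metabolites network size.
#' @param mean_in_degree,mean_out_degree mean consumption / production
#'   degree per species (>= 1).
#' @param n_intake number of designated intake metabolites.
#' @param intake_min_consumers minimum number of distinct consumer species
#'   per designated intake metabolite (extra consumption edges are added as
#'   needed). Intake nutrients are polysaccharide breakdown products that
#'   many gut species can use, and a generous consumer base also keeps the
#'   intake identifiable from abundances.
#' @param seed integer seed; generation is fully deterministic.
#' @param genus_size species per genus (labels `G001 sp001`, ... so the
#'   first name token is the genus).
#' @param chain if `TRUE`, ignore degrees and wire a linear food chain:
#'   species k consumes metabolite k and produces metabolite k + 1.
#' @return list with `network` (a `cross_feeding_network`) and
#'   `intake_metabolites` (character vector of length `n_intake`).
#' @export
generate_network <- function(n_species = 80L, n_metabolites = 150L,
                             mean_in_degree = 4, mean_out_degree = 3,
                             n_intake = 19L, intake_min_consumers = 10L,
                             seed = 1L, genus_size = 3L, chain = FALSE) {
  stopifnot(n_species >= 1L, n_metabolites >= 2L,
            mean_in_degree >= 1, mean_out_degree >= 1)
  if (!chain) stopifnot(n_intake >= 1L, n_intake <= n_metabolites)
  set.seed(seed)
  genus_ids <- sprintf("G%03d", seq_len(ceiling(n_species / genus_size)))
  species <- sprintf("%s sp%03d",
                     rep(genus_ids, each = genus_size)[seq_len(n_species)],
                     seq_len(n_species))
  mets <- sprintf("C%05d", seq_len(n_metabolites))
  if (chain) {
    if (n_metabolites < n_species + 1L) {
      stop("chain wiring needs n_metabolites >= n_species + 1")
    }
    cons <- data.frame(species = species, metabolite = mets[seq_len(n_species)],
                       stringsAsFactors = FALSE)
    prod <- data.frame(species = species,
                       metabolite = mets[seq_len(n_species) + 1L],
                       stringsAsFactors = FALSE)
    intake <- mets[1L]
  } else {
    if (mean_in_degree > n_metabolites || mean_out_degree > n_metabolites - 1L) {
      stop("infeasible degree constraints for the metabolite count")
    }
    draw_deg <- function(mu, mx) pmin(1L + stats::rpois(n_species, mu - 1), mx)
    din <- draw_deg(mean_in_degree, n_metabolites)
    dout <- draw_deg(mean_out_degree, n_metabolites - 1L)
    cons_l <- vector("list", n_species)
    prod_l <- vector("list", n_species)
    for (s in seq_len(n_species)) {
      cm <- sample(mets, din[s])
      pm <- sample(setdiff(mets, cm), min(dout[s], n_metabolites - din[s]))
      if (!length(pm)) pm <- sample(setdiff(mets, cm[1L]), 1L)
      cons_l[[s]] <- data.frame(species = species[s], metabolite = cm,
                                stringsAsFactors = FALSE)
      prod_l[[s]] <- data.frame(species = species[s], metabolite = pm,
                                stringsAsFactors = FALSE)
    }
    cons <- do.call(rbind, cons_l)
    prod <- do.call(rbind, prod_l)
    consumed <- unique(cons$metabolite)
    intake <- sample(consumed, min(n_intake, length(consumed)))
    if (length(intake) < n_intake) {
      # give the remaining designated intakes a consumer each
      extra <- sample(setdiff(mets, consumed), n_intake - length(intake))
      add <- data.frame(species = sample(species, length(extra), replace = TRUE),
                        metabolite = extra, stringsAsFactors = FALSE)
      cons <- unique(rbind(cons, add))
      intake <- c(intake, extra)
    }
    want <- min(intake_min_consumers, n_species)
    for (m in intake) {
      have <- unique(cons$species[cons$metabolite == m])
      if (length(have) < want) {
        new_sp <- sample(setdiff(species, have), want - length(have))
        cons <- rbind(cons, data.frame(species = new_sp, metabolite = m,
                                       stringsAsFactors = FALSE))
      }
    }
  }
  ia <- rbind(cbind(cons, direction = "consumption"),
              cbind(prod, direction = "production"))
  net <- cross_feeding_network(ia, species = species, metabolites = mets)
  list(network = net, intake_metabolites = sort(intake))
}

# Iterate the measured-abundance bootstrap to a fixed point: starting from
# uniform abundances over present species, repeatedly run the cascade and
# feed the resulting relative biomass back in as the measured abundances.
# Species falling below the detection limit are dropped, as they would be in
# a real sequencing survey; without the cutoff, species decaying
# geometrically toward zero keep the iteration from ever settling. At the
# fixed point the observed profile is exactly reproducible by the cascade
# that uses it, which is what noiseless intake inversion requires.
fixed_point_abundances <- function(net, present, intake, params,
                                   detection_limit = 1e-5,
                                   tol = 1e-13, max_iter = 2000L) {
  ab <- stats::setNames(rep(1 / length(present), length(present)), present)
  for (it in seq_len(max_iter)) {
    fl <- run_cascade(net, community_sample("fp", ab), intake, params)
    B <- fl$biomass
    if (sum(B) <= 0) return(NULL)
    rel <- B / sum(B)
    keep <- rel >= detection_limit
    if (!any(keep)) return(NULL)
    new_ab <- rel[keep] / sum(rel[keep])
    ok <- length(new_ab) == length(ab) &&
      setequal(names(new_ab), names(ab)) &&
      max(abs(new_ab[names(ab)] - ab)) < tol
    ab <- new_ab
    if (ok) return(ab)
  }
  NULL
}

#' Generate a synthetic cohort with known ground truth
#'
#' Emulates a calibration dataset: for each sample a true intake vector is
#' drawn from a symmetric Dirichlet over the intake metabolites, a random
#' subset of species is present, measured abundances are obtained as the
#' fixed point of the forward cascade (so the noiseless data are exactly
#' self-consistent with the model), and multiplicative log-normal
#' observation noise (in dex) is applied to abundances and metabolome
#' separately.
#'
#' @param net a `cross_feeding_network` (e.g. from [generate_network()]).
#' @param intake_metabolites candidate intake metabolites.
#' @param f,n_levels true model parameters used to generate the data.
#' @param n_samples number of individuals (default 41, a typical
#'   calibration-cohort size).
#' @param presence probability a species is present in a sample.
#' @param intake_concentration symmetric Dirichlet concentration for true
#'   intakes.
#' @param sigma_abund,sigma_metab log10 (dex) standard deviations of the
#'   multiplicative observation noise.
#' @param detection_limit relative-abundance detection threshold below which
#'   a species drops out of the sample, emulating the sensitivity of
#'   sequencing surveys.
#' @param min_species optional minimum species richness per sample after
#'   competitive exclusion and the detection limit; presence masks whose
#'   fixed point is poorer are redrawn (within `max_retries`). Use it to
#'   emulate study designs that target a given per-sample richness.
#' @param seed integer seed.
#' @param max_retries per-sample retries when a presence mask leaves some
#'   intake metabolite without a consumer.
#' @return list with `cohort` (a [cohort()] whose samples carry noisy
#'   abundances and metabolomes) and `truth` (class `synthetic_truth`:
#'   true f, n_levels, per-sample true intake, noiseless abundances and
#'   metabolomes, noise levels, seed).
#' @export
generate_cohort <- function(net, intake_metabolites, f = 0.9, n_levels = 4L,
                            n_samples = 41L, presence = 0.8,
                            intake_concentration = 1,
                            sigma_abund = 0, sigma_metab = 0,
                            detection_limit = 1e-5, min_species = NULL,
                            seed = 1L, max_retries = 25L) {
  validate_network(net)
  stopifnot(length(intake_metabolites) >= 1L, n_samples >= 0L,
            presence > 0, presence <= 1)
  params <- flow_parameters(f = f, n_levels = n_levels)
  set.seed(seed)
  samples <- vector("list", n_samples)
  truth_intake <- vector("list", n_samples)
  clean_ab <- vector("list", n_samples)
  clean_met <- vector("list", n_samples)
  K <- length(intake_metabolites)
  consumers_of <- split(net$consumption$species, net$consumption$metabolite)
  for (j in seq_len(n_samples)) {
    g <- stats::rgamma(K, shape = intake_concentration, rate = 1)
    if (sum(g) == 0) g <- rep(1, K)
    true_intake <- stats::setNames(g / sum(g), intake_metabolites)
    ab <- NULL
    for (try in seq_len(max_retries)) {
      mask <- stats::runif(length(net$species)) < presence
      present <- net$species[mask]
      if (!length(present)) next
      covered <- vapply(intake_metabolites, function(m) {
        any(consumers_of[[m]] %in% present)
      }, TRUE)
      if (!all(covered)) next
      ab <- fixed_point_abundances(net, present, true_intake, params,
                                   detection_limit = detection_limit)
      if (!is.null(ab) && !is.null(min_species) && length(ab) < min_species) {
        ab <- NULL
      }
      if (!is.null(ab)) break
    }
    if (is.null(ab)) {
      stop("could not draw a feasible presence mask for sample ", j,
           " after ", max_retries, " retries")
    }
    fl <- run_cascade(net, community_sample("truth", ab), true_intake, params)
    prof <- predict_profiles(fl)
    noiseless_ab <- prof$abundance[prof$abundance > 0]
    noiseless_met <- prof$metabolome[prof$metabolome > 0]
    obs_ab <- noiseless_ab *
      10^stats::rnorm(length(noiseless_ab), 0, sigma_abund)
    obs_ab <- obs_ab / sum(obs_ab)
    obs_met <- noiseless_met *
      10^stats::rnorm(length(noiseless_met), 0, sigma_metab)
    obs_met <- obs_met / sum(obs_met)
    sid <- sprintf("synth%03d", j)
    samples[[j]] <- community_sample(sid, obs_ab, metabolome = obs_met)
    truth_intake[[j]] <- true_intake
    clean_ab[[j]] <- noiseless_ab
    clean_met[[j]] <- noiseless_met
  }
  truth <- structure(
    list(f = f, n_levels = n_levels,
         intake = truth_intake, abundances = clean_ab,
         metabolomes = clean_met,
         sigma_abund = sigma_abund, sigma_metab = sigma_metab,
         intake_metabolites = intake_metabolites, seed = seed),
    class = "synthetic_truth"
  )
  list(cohort = cohort(samples, net), truth = truth)
}

#' Synthetic capability table at curated-database scale
#'
#' A synthetic stand-in emulating the size and structure of a curated
#' gut capability database before filtering: 570 "species" (567 microbes
#' plus 3 host cell types), 244 metabolites (235 nutrients plus 9 inorganic
#' ions), and exactly 4,248 microbe-metabolite interactions among the
#' retained entities, plus extra ion/host edges that the documented
#' filtering removes. Entirely generated; shares no content with any real
#' database beyond these published counts.
#'
#' @param seed integer seed.
#' @return list with `interactions` (data.frame: species, metabolite,
#'   direction), `ion_metabolites` (9 ids), `host_species` (3 ids).
#' @export
synthetic_capability_table <- function(seed = 1L) {
  set.seed(seed)
  n_sp <- 567L; n_met <- 235L; n_edges <- 4248L
  species <- sprintf("Genus%03d species%03d",
                     rep(seq_len(190L), each = 3L)[seq_len(n_sp)],
                     seq_len(n_sp))
  mets <- sprintf("C%05d", seq_len(n_met))
  ions <- c("Na+", "Ca+", "K+", "Mg2+", "Cl-", "Fe2+", "Zn2+", "Mn2+", "PO4-")
  hosts <- c("host cell type 1", "host cell type 2", "host cell type 3")
  # guarantee every species and metabolite at least one edge, then fill
  base_sp <- data.frame(
    species = species,
    metabolite = sample(mets, n_sp, replace = TRUE),
    stringsAsFactors = FALSE)
  base_met <- data.frame(
    species = sample(species, n_met, replace = TRUE),
    metabolite = mets,
    stringsAsFactors = FALSE)
  edges <- unique(rbind(base_sp, base_met))
  while (nrow(edges) < n_edges) {
    need <- n_edges - nrow(edges)
    more <- data.frame(
      species = sample(species, 2L * need, replace = TRUE),
      metabolite = sample(mets, 2L * need, replace = TRUE),
      stringsAsFactors = FALSE)
    edges <- utils::head(unique(rbind(edges, more)), n_edges)
  }
  direction <- ifelse(stats::runif(n_edges) < 0.55, "consumption", "production")
  core <- cbind(edges, direction = direction)
  ion_edges <- data.frame(
    species = c(sample(species, 9L), sample(species, 31L, replace = TRUE)),
    metabolite = c(ions, sample(ions, 31L, replace = TRUE)),
    direction = sample(c("consumption", "production"), 40L, replace = TRUE),
    stringsAsFactors = FALSE)
  host_edges <- data.frame(
    species = c(hosts, sample(hosts, 22L, replace = TRUE)),
    metabolite = c(sample(mets, 3L), sample(mets, 22L, replace = TRUE)),
    direction = sample(c("consumption", "production"), 25L, replace = TRUE),
    stringsAsFactors = FALSE)
  ia <- unique(rbind(core, ion_edges, host_edges))
  list(interactions = ia, ion_metabolites = ions, host_species = hosts)
}

#' Synthetic intake-metabolite list
#'
#' A 19-entry stand-in for a curated list of nutrient-intake metabolites
#' (polysaccharide breakdown products such as arabinose, raffinose and
#' xylose); ids here are synthetic placeholders drawn from the given
#' metabolite universe.
#'
#' @param metabolites metabolite id universe to draw from.
#' @param n list length (default 19).
#' @param seed integer seed.
#' @return character vector of metabolite ids.
#' @export
synthetic_intake_list <- function(metabolites, n = 19L, seed = 1L) {
  stopifnot(length(metabolites) >= n)
  set.seed(seed)
  sort(sample(metabolites, n))
}
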