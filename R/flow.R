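#' Flow parameters for the trophic cascade
#'
#' Bundles the two global model knobs — the byproduct fraction `f` (fraction
#' of consumed metabolite mass a species re-secretes as byproducts; `1 - f`
#' becomes biomass) and the number of trophic levels `n_levels` (counted as
#' consumption steps) — together with the microscopic rate assumptions: the
#' per-(species, metabolite) uptake rates lambda and the secretion-splitting
#' rule.
#'
#' @param f byproduct fraction, in (0, 1). Default 0.9, the value at which
#'   the model best matches measured fecal metabolomes.
#' @param n_levels integer number of consumption steps, >= 1. Default 4.
#' @param uptake_rates `NULL` (all lambda = 1, the default assumption) or a
#'   data.frame with columns `species`, `metabolite`, `rate` (>= 0) giving
#'   lambda on consumption edges; absent edges keep rate 1.
#' @param secretion_mode `"equal_split"` (each species splits its byproduct
#'   mass equally over its producible metabolites), `"explicit"` (use
#'   `secretion_weights`), or `"dirichlet"` (weights are expected to have
#'   been drawn by [dirichlet_secretion()], which returns an explicit-mode
#'   object).
#' @param secretion_weights for `"explicit"` mode: data.frame with columns
#'   `species`, `metabolite`, `weight` (>= 0) on production edges; weights
#'   are renormalized per species.
#' @return an object of class `flow_parameters`.
#' @export
flow_parameters <- function(f = 0.9, n_levels = 4L, uptake_rates = NULL,
                            secretion_mode = c("equal_split", "explicit",
                                               "dirichlet"),
                            secretion_weights = NULL) {
  secretion_mode <- match.arg(secretion_mode)
  stopifnot(is.numeric(f), length(f) == 1L, f > 0, f < 1)
  n_levels <- as.integer(n_levels)
  stopifnot(length(n_levels) == 1L, n_levels >= 1L)
  if (!is.null(uptake_rates)) {
    stopifnot(is.data.frame(uptake_rates),
              all(c("species", "metabolite", "rate") %in% names(uptake_rates)),
              all(uptake_rates$rate >= 0))
  }
  if (secretion_mode == "explicit") {
    if (is.null(secretion_weights)) stop("explicit mode requires secretion_weights")
    stopifnot(is.data.frame(secretion_weights),
              all(c("species", "metabolite", "weight") %in% names(secretion_weights)))
    if (any(secretion_weights$weight < 0)) {
      stop("secretion weights must be non-negative")
    }
  }
  structure(
    list(f = f, n_levels = n_levels, uptake_rates = uptake_rates,
         secretion_mode = secretion_mode, secretion_weights = secretion_weights),
    class = "flow_parameters"
  )
}

#' @export
print.flow_parameters <- function(x, ...) {
  cat("Flow parameters: f =", x$f, ", n_levels =", x$n_levels,
      ", secretion =", x$secretion_mode,
      if (is.null(x$uptake_rates)) ", lambda = 1 everywhere" else
        ", custom uptake rates", "\n")
  invisible(x)
}

#' A single community sample
#'
#' Holds one individual's species relative abundances (renormalized to sum
#' to 1) and, optionally, a measured metabolome keyed by metabolite id.
#'
#' @param sample_id sample identifier string.
#' @param abundances named non-negative numeric vector of species relative
#'   abundances; renormalized to sum to 1.
#' @param metabolome optional named non-negative numeric vector of measured
#'   metabolite levels.
#' @return an object of class `community_sample`.
#' @export
community_sample <- function(sample_id, abundances, metabolome = NULL) {
  stopifnot(is.numeric(abundances), !is.null(names(abundances)),
            all(nzchar(names(abundances))), all(abundances >= 0))
  tot <- sum(abundances)
  if (tot <= 0) stop("abundances must contain a positive entry")
  if (!is.null(metabolome)) {
    stopifnot(is.numeric(metabolome), !is.null(names(metabolome)),
              all(metabolome >= 0))
  }
  structure(
    list(sample_id = as.character(sample_id),
         abundances = abundances / tot,
         metabolome = metabolome),
    class = "community_sample"
  )
}

#' A cohort of samples sharing one network
#'
#' @param samples list of [community_sample()] objects.
#' @param network the shared `cross_feeding_network`.
#' @return an object of class `cohort`.
#' @export
cohort <- function(samples, network) {
  stopifnot(is.list(samples),
            all(vapply(samples, inherits, TRUE, "community_sample")),
            inherits(network, "cross_feeding_network"))
  ids <- vapply(samples, `[[`, "", "sample_id")
  if (anyDuplicated(ids)) stop("duplicate sample ids in cohort")
  structure(list(samples = samples, network = network), class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  n_met <- sum(vapply(x$samples, function(s) !is.null(s$metabolome), TRUE))
  cat("Cohort:", length(x$samples), "samples (", n_met,
      "with measured metabolomes ) on", length(x$network$species),
      "network species\n")
  invisible(x)
}

rates_lookup <- function(uptake_rates) {
  if (is.null(uptake_rates)) return(NULL)
  stats::setNames(uptake_rates$rate,
                  paste(uptake_rates$species, uptake_rates$metabolite, sep = "\r"))
}

#' Build the uptake matrix A_in for one sample
#'
#' The uptake matrix splits each metabolite across its consumers in
#' proportion to abundance times uptake rate: on consumption edges,
#' `A_in[a, i] = kappa_i * lambda[a, i] * B_exp[a]`, with
#' `kappa_i = 1 / sum_a lambda[a, i] * B_exp[a]`, so every column with at
#' least one positive-weight consumer sums to exactly 1. Metabolites
#' consumed only by zero-abundance (or zero-rate) species get an all-zero
#' column and are flagged effectively unconsumable for this sample.
#'
#' @param net a `cross_feeding_network`.
#' @param sample a `community_sample` whose species all resolve in `net`.
#' @param params a `flow_parameters` object (supplies `uptake_rates`).
#' @param metabolites optional metabolite universe for the columns; defaults
#'   to `net$metabolites`.
#' @return species-by-metabolite numeric matrix with a logical
#'   `"consumable"` attribute marking columns that sum to 1.
#' @export
build_uptake_matrix <- function(net, sample, params = flow_parameters(),
                                metabolites = NULL) {
  validate_network(net)
  sp <- names(sample$abundances)
  unknown <- setdiff(sp, net$species)
  if (length(unknown)) {
    stop("sample species not in network: ",
         paste(utils::head(unknown, 5L), collapse = ", "))
  }
  if (is.null(metabolites)) metabolites <- net$metabolites
  A <- matrix(0, length(sp), length(metabolites),
              dimnames = list(sp, metabolites))
  e <- net$consumption[net$consumption$species %in% sp &
                         net$consumption$metabolite %in% metabolites, ,
                       drop = FALSE]
  if (nrow(e)) {
    lam <- rep(1, nrow(e))
    lk <- rates_lookup(params$uptake_rates)
    if (!is.null(lk)) {
      hit <- lk[paste(e$species, e$metabolite, sep = "\r")]
      lam[!is.na(hit)] <- hit[!is.na(hit)]
    }
    w <- lam * sample$abundances[e$species]
    A[cbind(e$species, e$metabolite)] <- w
    cs <- colSums(A)
    pos <- cs > 0
    A[, pos] <- sweep(A[, pos, drop = FALSE], 2L, cs[pos], "/")
  }
  attr(A, "consumable") <- colSums(A) > 0
  A
}

#' Build the secretion matrix A_out
#'
#' Splits each species' byproduct mass across its producible metabolites.
#' Under equal splitting every nonzero entry of a species' column equals
#' `1 / N_out(species)`, the reciprocal of its byproduct count; explicit
#' weights are renormalized per species. Species with no production edges
#' get an all-zero column (their f-fraction is routed to the sink by
#' [run_cascade()]).
#'
#' @inheritParams build_uptake_matrix
#' @param species optional species universe for the columns.
#' @return metabolite-by-species numeric matrix with a logical `"has_sink"`
#'   attribute marking all-zero (byproduct-free) species columns.
#' @export
build_secretion_matrix <- function(net, params = flow_parameters(),
                                   species = NULL, metabolites = NULL) {
  validate_network(net)
  if (is.null(species)) species <- net$species
  if (is.null(metabolites)) metabolites <- net$metabolites
  A <- matrix(0, length(metabolites), length(species),
              dimnames = list(metabolites, species))
  e <- net$production[net$production$species %in% species &
                        net$production$metabolite %in% metabolites, ,
                      drop = FALSE]
  if (nrow(e)) {
    if (params$secretion_mode == "equal_split") {
      w <- rep(1, nrow(e))
    } else {
      sw <- params$secretion_weights
      key <- stats::setNames(sw$weight,
                             paste(sw$species, sw$metabolite, sep = "\r"))
      w <- key[paste(e$species, e$metabolite, sep = "\r")]
      if (anyNA(w)) stop("secretion_weights missing for some production edges")
      w <- unname(w)
    }
    A[cbind(e$metabolite, e$species)] <- w
    cs <- colSums(A)
    pos <- cs > 0
    A[, pos] <- sweep(A[, pos, drop = FALSE], 2L, cs[pos], "/")
  }
  attr(A, "has_sink") <- colSums(A) == 0
  A
}

# Core level-by-level recursion, shared by run_cascade() and
# intake_response(). d_0 = intake; at step l the entering vector splits into
# a consumable part (columns of A_in that sum to 1) and an unconsumable part
# u_l that is banked into the metabolome; b_l = (1-f) A_in d_{l-1};
# d_l = f A_out A_in d_{l-1}; mass consumed by byproduct-free species times f
# goes to the sink. M = d_N + sum_l u_l.
cascade_core <- function(Ain, Aout, f, n_levels, intake_vec) {
  consumable <- attr(Ain, "consumable")
  sinky <- attr(Aout, "has_sink")
  S <- nrow(Ain); M <- ncol(Ain); N <- n_levels
  b_lv <- matrix(0, S, N, dimnames = list(rownames(Ain), NULL))
  d_lv <- matrix(0, M, N, dimnames = list(colnames(Ain), NULL))
  u_lv <- matrix(0, M, N, dimnames = list(colnames(Ain), NULL))
  enter <- matrix(0, M, N, dimnames = list(colnames(Ain), NULL))
  sink <- numeric(N)
  d <- intake_vec
  for (l in seq_len(N)) {
    enter[, l] <- d
    u <- d; u[consumable] <- 0
    dcon <- d - u
    consumed <- drop(Ain %*% dcon)
    b_lv[, l] <- (1 - f) * consumed
    sink[l] <- f * sum(consumed[sinky])
    d <- f * drop(Aout %*% consumed)
    u_lv[, l] <- u
    d_lv[, l] <- d
  }
  list(biomass_by_level = b_lv, byproducts = d_lv, unconsumable = u_lv,
       entering = enter, sink_by_level = sink,
       biomass = rowSums(b_lv),
       metabolome = d + rowSums(u_lv))
}

#' Run the multi-level trophic cascade
#'
#' Propagates an intake vector through `n_levels` consumption steps. At each
#' step the entering metabolite pool is split into a consumable part
#' (metabolites with at least one present consumer) and an unconsumable part
#' that is banked into the predicted fecal metabolome; the consumable part
#' is distributed to species by the uptake matrix, a fraction `1 - f`
#' becomes biomass and `f` is re-secreted via the secretion matrix as the
#' next level's pool. Byproducts of the final level join the metabolome.
#' Mass consumed by species with no recorded byproducts is tracked in an
#' explicit sink so that biomass + metabolome + sink = intake exactly.
#'
#' Intake metabolites absent from the network pass straight into the
#' metabolome as level-1 unconsumables. Measured abundances are used inside
#' the uptake matrix at every level (no abundance updating between levels).
#'
#' @param net a `cross_feeding_network`.
#' @param sample a `community_sample`; its species must resolve in `net`.
#' @param intake named non-negative numeric vector of nutrient amounts
#'   entering the gut; at least one entry must be positive.
#' @param params a `flow_parameters` object.
#' @return an object of class `trophic_flow`: per-level biomass increments,
#'   entering/byproduct/unconsumable vectors, sink masses, total per-species
#'   biomass `biomass`, raw predicted metabolome `metabolome`, and echoes of
#'   the intake and parameters.
#' @export
run_cascade <- function(net, sample, intake, params = flow_parameters()) {
  stopifnot(is.numeric(intake), !is.null(names(intake)), all(intake >= 0))
  if (sum(intake) <= 0) stop("intake is all zero: nothing to propagate")
  mets <- union(net$metabolites, names(intake))
  sp <- names(sample$abundances)
  Ain <- build_uptake_matrix(net, sample, params, metabolites = mets)
  Aout <- build_secretion_matrix(net, params, species = sp, metabolites = mets)
  iv <- stats::setNames(numeric(length(mets)), mets)
  iv[names(intake)] <- iv[names(intake)] + intake
  res <- cascade_core(Ain, Aout, params$f, params$n_levels, iv)
  structure(
    c(res,
      list(intake = iv, f = params$f, n_levels = params$n_levels,
           sample_id = sample$sample_id, species = sp, metabolites = mets)),
    class = "trophic_flow"
  )
}

#' @export
print.trophic_flow <- function(x, ...) {
  tot <- sum(x$intake)
  cat("Trophic flow for sample", x$sample_id, ": f =", x$f,
      ", levels =", x$n_levels, "\n")
  cat(sprintf("  biomass %.4g (%.1f%%), metabolome %.4g (%.1f%%), sink %.4g\n",
              sum(x$biomass), 100 * sum(x$biomass) / tot,
              sum(x$metabolome), 100 * sum(x$metabolome) / tot,
              sum(x$sink_by_level)))
  invisible(x)
}

#' Normalize a flow into relative abundance and metabolome profiles
#'
#' Biomass and metabolome are normalized separately to sum to 1, mirroring
#' how measured metagenomes and metabolomes are reported as relative
#' profiles. Both are invariant under rescaling of the intake vector.
#'
#' @param flow a `trophic_flow`.
#' @return list with `abundance` (named, sums to 1) and `metabolome`
#'   (named, sums to 1); an all-zero total yields an empty vector with a
#'   warning.
#' @export
predict_profiles <- function(flow) {
  stopifnot(inherits(flow, "trophic_flow"))
  norm1 <- function(v, what) {
    s <- sum(v)
    if (s <= 0) {
      warning("total ", what, " is zero; returning empty profile")
      return(v[0])
    }
    v / s
  }
  list(abundance = norm1(flow$biomass, "biomass"),
       metabolome = norm1(flow$metabolome, "metabolome"))
}

#' Per-level summary of a trophic flow
#'
#' Expresses the cascade as fractions of total intake: what entered each
#' level, how much was consumed, fixed as biomass, lost unconsumable to the
#' metabolome, routed to the sink, and passed on as byproducts. The
#' `figure_level` column shifts microbe steps by one (intake occupies level
#' 1, so microbes first appear in level 2), the labeling used in level-wise
#' plots.
#'
#' @param flow a `trophic_flow`.
#' @return data.frame, one row per consumption step.
#' @export
flow_summary <- function(flow) {
  stopifnot(inherits(flow, "trophic_flow"))
  tot <- sum(flow$intake)
  N <- flow$n_levels
  consumed <- colSums(flow$biomass_by_level) / (1 - flow$f)
  data.frame(
    level = seq_len(N),
    figure_level = seq_len(N) + 1L,
    entering_fraction = colSums(flow$entering) / tot,
    consumed_fraction = consumed / tot,
    biomass_fraction = colSums(flow$biomass_by_level) / tot,
    unconsumable_fraction = colSums(flow$unconsumable) / tot,
    sink_fraction = flow$sink_by_level / tot,
    passed_on_fraction = colSums(flow$byproducts) / tot
  )
}

#' Export a flow as long-format tables
#'
#' `flow_long()` returns per-level amounts for every entity (for TSV
#' export); `flow_layer_edges()` returns the level-resolved bipartite edge
#' list (metabolite -> species consumption flows, species -> metabolite
#' production flows) used for layer-wise network plots.
#'
#' @param flow a `trophic_flow`.
#' @param net the network the flow was computed on (edge structure).
#' @param params the `flow_parameters` used.
#' @param min_flow drop edges carrying less than this absolute flow.
#' @return data.frame.
#' @export
flow_long <- function(flow) {
  stopifnot(inherits(flow, "trophic_flow"))
  N <- flow$n_levels
  per_level <- function(mat, class, what) {
    data.frame(
      level = rep(seq_len(N), each = nrow(mat)),
      entity_id = rep(rownames(mat), N),
      entity_class = class,
      quantity = what,
      amount = as.vector(mat),
      stringsAsFactors = FALSE
    )
  }
  out <- rbind(
    per_level(flow$biomass_by_level, "species", "biomass"),
    per_level(flow$entering, "metabolite", "entering"),
    per_level(flow$byproducts, "metabolite", "byproduct"),
    per_level(flow$unconsumable, "metabolite", "unconsumable")
  )
  out[out$amount > 0, , drop = FALSE]
}

#' @rdname flow_long
#' @param sample the `community_sample` the flow was computed on.
#' @export
flow_layer_edges <- function(flow, net, sample, params = flow_parameters(),
                             min_flow = 0) {
  stopifnot(inherits(flow, "trophic_flow"))
  mets <- flow$metabolites
  Ain <- build_uptake_matrix(net, sample, params, metabolites = mets)
  Aout <- build_secretion_matrix(net, params, species = flow$species,
                                 metabolites = mets)
  rows <- list()
  for (l in seq_len(flow$n_levels)) {
    d <- flow$entering[, l]
    cons_flow <- Ain * rep(d, each = nrow(Ain))          # metabolite -> species
    consumed <- drop(Ain %*% ifelse(attr(Ain, "consumable"), d, 0))
    prod_flow <- flow$f * Aout * rep(consumed, each = nrow(Aout))
    ic <- which(cons_flow > min_flow, arr.ind = TRUE)
    if (nrow(ic)) {
      rows[[length(rows) + 1L]] <- data.frame(
        level = l, source = mets[ic[, 2L]], target = flow$species[ic[, 1L]],
        kind = "consumption", flow = cons_flow[ic], stringsAsFactors = FALSE)
    }
    ip <- which(prod_flow > min_flow, arr.ind = TRUE)
    if (nrow(ip)) {
      rows[[length(rows) + 1L]] <- data.frame(
        level = l, source = flow$species[ip[, 2L]], target = mets[ip[, 1L]],
        kind = "production", flow = prod_flow[ip], stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(data.frame(level = integer(), source = character(),
                      target = character(), kind = character(),
                      flow = numeric(), stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

#' Collapse the cascade into a linear intake-response operator
#'
#' For a fixed sample and fixed parameters the cascade is linear in the
#' intake vector, so total biomass, predicted metabolome and sink mass can
#' be written as matrices acting on the intake. This function runs
#' [run_cascade()] once per intake metabolite (unit amount) and assembles
#' those matrices. Used by the fitting and calibration routines, where the
#' cascade is evaluated thousands of times for the same sample.
#'
#' @param net a `cross_feeding_network`.
#' @param sample a `community_sample`.
#' @param params a `flow_parameters` object.
#' @param intake_metabolites character vector of candidate intake
#'   metabolite ids (the columns of the response).
#' @return list with `biomass` (species x intake matrix), `metabolome`
#'   (metabolite x intake matrix) and `sink` (per-intake sink mass), such
#'   that for any intake vector `c`, `biomass %*% c` equals
#'   `run_cascade(...)$biomass` exactly.
#' @export
intake_response <- function(net, sample, params, intake_metabolites) {
  stopifnot(length(intake_metabolites) >= 1L,
            !anyDuplicated(intake_metabolites))
  mets <- union(net$metabolites, intake_metabolites)
  sp <- names(sample$abundances)
  Ain <- build_uptake_matrix(net, sample, params, metabolites = mets)
  Aout <- build_secretion_matrix(net, params, species = sp, metabolites = mets)
  K <- length(intake_metabolites)
  Rb <- matrix(0, length(sp), K, dimnames = list(sp, intake_metabolites))
  Rm <- matrix(0, length(mets), K, dimnames = list(mets, intake_metabolites))
  sink <- stats::setNames(numeric(K), intake_metabolites)
  for (k in seq_len(K)) {
    iv <- stats::setNames(numeric(length(mets)), mets)
    iv[intake_metabolites[k]] <- 1
    res <- cascade_core(Ain, Aout, params$f, params$n_levels, iv)
    Rb[, k] <- res$biomass
    Rm[, k] <- res$metabolome
    sink[k] <- sum(res$sink_by_level)
  }
  list(biomass = Rb, metabolome = Rm, sink = sink,
       f = params$f, n_levels = params$n_levels)
}
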