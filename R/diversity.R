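#' Per-level relative contributions of species, genera or metabolites
#'
#' For a set of flows (one per individual, all computed on the same network
#' and parameters), quantifies how much each entity contributes to each
#' trophic level: species use the per-level biomass increments, genera sum
#' congeners' contributions, and metabolites use one of three per-level
#' profiles — `"entering"` (the pool entering the level, level 1 = intake;
#' the default, so level-1 metabolite diversity is intake diversity),
#' `"produced"` (the byproducts generated at the level) or `"unconsumed"`
#' (the unconsumable part banked at the level). Each (level, sample) slice
#' is normalized to sum to 1 where any contribution exists.
#'
#' @param flows list of `trophic_flow` objects sharing parameters.
#' @param entity_class `"species"`, `"genus"` or `"metabolite"`.
#' @param level_profile_mode metabolite profile definition (see above).
#' @param genus named character vector mapping species to genus (e.g.
#'   `net$genus`); required for `entity_class = "genus"`. Species missing
#'   from the map are grouped under their own name with a warning.
#' @return object of class `level_contribution`: array `p` of dimension
#'   (entity, level, sample), plus `entity_class` and `mode`.
#' @export
level_contributions <- function(flows,
                                entity_class = c("species", "genus",
                                                 "metabolite"),
                                level_profile_mode = c("entering", "produced",
                                                       "unconsumed"),
                                genus = NULL) {
  entity_class <- match.arg(entity_class)
  level_profile_mode <- match.arg(level_profile_mode)
  stopifnot(length(flows) >= 1L,
            all(vapply(flows, inherits, TRUE, "trophic_flow")))
  n_levels <- unique(vapply(flows, `[[`, 0L, "n_levels"))
  if (length(n_levels) != 1L) stop("flows differ in n_levels")
  pick <- function(fl) {
    if (entity_class %in% c("species", "genus")) {
      m <- fl$biomass_by_level
      if (entity_class == "genus") {
        if (is.null(genus)) stop("genus map required for entity_class = 'genus'")
        g <- genus[rownames(m)]
        miss <- is.na(g)
        if (any(miss)) {
          warning(sum(miss), " species missing from genus map; ",
                  "grouped under their own names")
          g[miss] <- rownames(m)[miss]
        }
        m <- rowsum(m, group = unname(g))
      }
      m
    } else {
      switch(level_profile_mode,
             entering = fl$entering,
             produced = fl$byproducts,
             unconsumed = fl$unconsumable)
    }
  }
  mats <- lapply(flows, pick)
  entities <- sort(unique(unlist(lapply(mats, rownames))))
  J <- length(flows)
  p <- array(0, dim = c(length(entities), n_levels, J),
             dimnames = list(entities, NULL,
                             vapply(flows, `[[`, "", "sample_id")))
  for (j in seq_len(J)) {
    m <- mats[[j]]
    cs <- colSums(m)
    pos <- cs > 0
    m[, pos] <- sweep(m[, pos, drop = FALSE], 2L, cs[pos], "/")
    m[, !pos] <- 0
    p[rownames(m), , j] <- m
  }
  structure(list(p = p, entity_class = entity_class,
                 mode = level_profile_mode),
            class = "level_contribution")
}

#' Level-resolved inverse-Simpson alpha, gamma and beta diversity
#'
#' At each level, alpha diversity is the reciprocal of the mean (over
#' samples) Simpson concentration, `D_alpha = 1 / <sum_i p_i(l, j)^2>_j`;
#' gamma diversity is the inverse Simpson concentration of the cohort-mean
#' profile, `D_gamma = 1 / sum_i mean_j(p_i(l, j))^2`; and beta diversity is
#' their ratio `D_beta = D_gamma / D_alpha`, which is always >= 1 and
#' measures between-individual turnover. Samples with no contribution at a
#' level are excluded from that level's averages; levels with no
#' contributing sample are reported `NA`.
#'
#' @param contrib a [level_contributions()] result.
#' @return data.frame of class `diversity_summary`: level, D_alpha, D_gamma,
#'   D_beta, n_samples.
#' @export
diversity_summary <- function(contrib) {
  stopifnot(inherits(contrib, "level_contribution"))
  p <- contrib$p
  n_levels <- dim(p)[2L]
  out <- data.frame(level = seq_len(n_levels), D_alpha = NA_real_,
                    D_gamma = NA_real_, D_beta = NA_real_, n_samples = 0L)
  for (l in seq_len(n_levels)) {
    slab <- matrix(p[, l, ], nrow = dim(p)[1L])   # entity x sample
    used <- colSums(slab) > 0
    if (!any(used)) next
    slab <- slab[, used, drop = FALSE]
    simpson <- colSums(slab^2)
    pbar <- rowMeans(slab)
    out$D_alpha[l] <- 1 / mean(simpson)
    out$D_gamma[l] <- 1 / sum(pbar^2)
    out$D_beta[l] <- out$D_gamma[l] / out$D_alpha[l]
    out$n_samples[l] <- sum(used)
  }
  class(out) <- c("diversity_summary", "data.frame")
  out
}

#' Assign each entity to its dominant trophic level
#'
#' Averages each entity's within-level relative contribution across samples
#' and assigns the entity to the level where that mean is largest. Exact
#' ties break toward the earlier level and are flagged.
#'
#' @param contrib a [level_contributions()] result.
#' @param figure_levels report microbe levels shifted by one (intake = level
#'   1, microbes first appear at level 2); applies to species/genus classes.
#' @return data.frame: entity, entity_class, level, mean_contribution, tie.
#' @export
assign_dominant_level <- function(contrib, figure_levels = FALSE) {
  stopifnot(inherits(contrib, "level_contribution"))
  mean_p <- apply(contrib$p, c(1L, 2L), mean)   # entity x level
  lev <- apply(mean_p, 1L, which.max)           # ties -> earliest
  tie <- vapply(seq_len(nrow(mean_p)), function(i) {
    mx <- max(mean_p[i, ])
    mx > 0 && sum(mean_p[i, ] == mx) > 1L
  }, TRUE)
  offset <- if (figure_levels && contrib$entity_class != "metabolite") 1L else 0L
  data.frame(
    entity = rownames(mean_p),
    entity_class = contrib$entity_class,
    level = as.integer(lev) + offset,
    mean_contribution = mean_p[cbind(seq_len(nrow(mean_p)), lev)],
    tie = tie,
    stringsAsFactors = FALSE
  )
}
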