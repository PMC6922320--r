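#' Normalize a taxon or metabolite name
#'
#' Case-folds, trims, collapses internal whitespace and converts underscores
#' to single spaces, so that MetaPhlAn-style labels
#' (`"Bacteroides_fragilis"`) and curated labels (`"Bacteroides fragilis"`)
#' compare equal.
#'
#' @param x character vector of names.
#' @return character vector of normalized names.
#' @export
normalize_name <- function(x) {
  x <- gsub("_", " ", as.character(x), fixed = TRUE)
  x <- gsub("[[:space:]]+", " ", x)
  tolower(trimws(x))
}

#' Construct a cross-feeding network
#'
#' A cross-feeding network is a bipartite graph between microbial species and
#' metabolites with two edge sets: consumption edges (species eats metabolite)
#' and production edges (species secretes metabolite as a byproduct).
#'
#' @param interactions data.frame with columns `species`, `metabolite`,
#'   `direction` (`"consumption"` or `"production"`). Duplicate rows are
#'   dropped with a warning.
#' @param genus optional named character vector mapping species id to genus.
#'   When `NULL`, the genus is taken to be the first whitespace-delimited
#'   token of the species name.
#' @param species,metabolites optional character vectors fixing the node
#'   lists (used to retain explicitly listed zero-degree nodes). Defaults to
#'   first-appearance order in `interactions`.
#' @return an object of class `cross_feeding_network`: a list with elements
#'   `species`, `metabolites`, `consumption`, `production` (two-column
#'   data.frames of edges) and `genus`.
#' @export
cross_feeding_network <- function(interactions, genus = NULL,
                                  species = NULL, metabolites = NULL) {
  stopifnot(is.data.frame(interactions))
  need <- c("species", "metabolite", "direction")
  if (!all(need %in% names(interactions))) {
    stop("interactions must have columns: ", paste(need, collapse = ", "))
  }
  ia <- data.frame(
    species    = trimws(as.character(interactions$species)),
    metabolite = trimws(as.character(interactions$metabolite)),
    direction  = trimws(as.character(interactions$direction)),
    stringsAsFactors = FALSE
  )
  if (any(ia$species == "") || any(ia$metabolite == "")) {
    stop("empty species or metabolite id after whitespace normalization")
  }
  bad <- !(ia$direction %in% c("consumption", "production"))
  if (any(bad)) {
    stop("unknown direction token(s) in rows: ",
         paste(utils::head(which(bad), 10L), collapse = ", "),
         " (", paste(unique(ia$direction[bad]), collapse = ", "), ")")
  }
  dup <- duplicated(ia)
  if (any(dup)) {
    warning(sum(dup), " duplicate interaction row(s) dropped")
    ia <- ia[!dup, , drop = FALSE]
  }
  if (is.null(species)) species <- unique(ia$species)
  if (is.null(metabolites)) metabolites <- unique(ia$metabolite)
  stopifnot(!anyDuplicated(species), !anyDuplicated(metabolites))
  edges <- function(dir) {
    e <- ia[ia$direction == dir, c("species", "metabolite"), drop = FALSE]
    rownames(e) <- NULL
    e
  }
  net <- structure(
    list(
      species = species,
      metabolites = metabolites,
      consumption = edges("consumption"),
      production = edges("production"),
      genus = resolve_genus(species, genus)
    ),
    class = "cross_feeding_network"
  )
  validate_network(net)
  net
}

resolve_genus <- function(species, genus) {
  g <- vapply(strsplit(species, "[[:space:]_]+"), `[`, "", 1L)
  names(g) <- species
  if (!is.null(genus)) {
    genus <- genus[names(genus) %in% species]
    g[names(genus)] <- unname(genus)
  }
  g
}

#' Validate the internal consistency of a cross-feeding network
#'
#' Checks that edge endpoints appear in the node lists and that neither edge
#' set contains duplicates. Called by all constructors; exported because the
#' synthetic generator's outputs are tested against it.
#'
#' @param net a `cross_feeding_network`.
#' @return `net`, invisibly; stops on violation.
#' @export
validate_network <- function(net) {
  stopifnot(inherits(net, "cross_feeding_network"))
  for (nm in c("consumption", "production")) {
    e <- net[[nm]]
    if (nrow(e)) {
      if (!all(e$species %in% net$species)) {
        stop(nm, " edge references species absent from the species list")
      }
      if (!all(e$metabolite %in% net$metabolites)) {
        stop(nm, " edge references metabolite absent from the metabolite list")
      }
      if (anyDuplicated(paste(e$species, e$metabolite, sep = "\r"))) {
        stop("duplicate edges in ", nm, " set")
      }
    }
  }
  invisible(net)
}

#' @export
print.cross_feeding_network <- function(x, ...) {
  cat("Cross-feeding network:",
      length(x$species), "species,",
      length(x$metabolites), "metabolites,",
      nrow(x$consumption), "consumption +",
      nrow(x$production), "production edges\n")
  invisible(x)
}

#' Metabolites a species can consume / secrete
#'
#' @param net a `cross_feeding_network`.
#' @param species a species id.
#' @return character vector of metabolite ids.
#' @export
consumables <- function(net, species) {
  net$consumption$metabolite[net$consumption$species == species]
}

#' @rdname consumables
#' @export
byproducts <- function(net, species) {
  net$production$metabolite[net$production$species == species]
}

#' Read a microbe-metabolite capability table
#'
#' Reads a delimited (TSV/CSV, delimiter sniffed from the extension or
#' header) or XLSX capability table into a [cross_feeding_network()]. Node
#' order is first appearance; duplicate rows are dropped with a warning.
#'
#' @param path file path.
#' @param dialect `"auto"` (default, by extension), `"delimited"` or
#'   `"xlsx"` (requires the readxl package).
#' @param col_map named character vector mapping the canonical column names
#'   `species`, `metabolite`, `direction` to the column names used in the
#'   file.
#' @param direction_tokens length-2 named character vector giving the file's
#'   tokens for consumption and production.
#' @return a `cross_feeding_network`.
#' @export
load_interactions <- function(path, dialect = c("auto", "delimited", "xlsx"),
                              col_map = c(species = "species",
                                          metabolite = "metabolite",
                                          direction = "direction"),
                              direction_tokens = c(consumption = "consumption",
                                                   production = "production")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  if (dialect == "auto") {
    dialect <- if (grepl("\\.xlsx?$", path, ignore.case = TRUE)) "xlsx" else "delimited"
  }
  if (dialect == "xlsx") {
    if (!requireNamespace("readxl", quietly = TRUE)) {
      stop("reading xlsx requires the readxl package")
    }
    tab <- as.data.frame(readxl::read_excel(path), stringsAsFactors = FALSE)
  } else {
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
    tab <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                             comment.char = "", check.names = FALSE,
                             colClasses = "character")
  }
  missing_cols <- setdiff(unname(col_map), names(tab))
  if (length(missing_cols)) {
    stop("capability table lacks required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  ia <- data.frame(
    species    = tab[[col_map[["species"]]]],
    metabolite = tab[[col_map[["metabolite"]]]],
    direction  = tab[[col_map[["direction"]]]],
    stringsAsFactors = FALSE
  )
  ia$direction <- trimws(tolower(ia$direction))
  tok <- stats::setNames(names(direction_tokens), tolower(direction_tokens))
  known <- ia$direction %in% names(tok)
  if (!all(known)) {
    stop("unknown direction token(s) in rows: ",
         paste(utils::head(which(!known), 10L), collapse = ", "),
         " (tokens: ", paste(unique(ia$direction[!known]), collapse = ", "), ")")
  }
  ia$direction <- unname(tok[ia$direction])
  cross_feeding_network(ia)
}

#' Write a capability table to TSV
#'
#' Inverse of [load_interactions()] for the delimited dialect: a
#' load-write-load round trip reproduces the edge sets exactly.
#'
#' @param net a `cross_feeding_network`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_interactions <- function(net, path) {
  validate_network(net)
  tab <- rbind(
    cbind(net$consumption, direction = rep("consumption", nrow(net$consumption))),
    cbind(net$production, direction = rep("production", nrow(net$production)))
  )
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Filter a cross-feeding network
#'
#' Removes excluded metabolites (e.g. inorganic ions) and excluded species
#' (e.g. host cell types) together with their incident edges, mirroring the
#' curation step that strips ions and human cell types from capability
#' databases before modeling.
#'
#' @param net a `cross_feeding_network`.
#' @param exclude_metabolites,exclude_species character vectors of ids to
#'   drop; excluding an absent id is a no-op.
#' @param drop_isolated if `TRUE`, species and metabolites left with zero
#'   edges after the exclusion are also removed.
#' @return the filtered `cross_feeding_network`, with a `"filter_report"`
#'   attribute (list of removed counts).
#' @export
filter_network <- function(net, exclude_metabolites = character(),
                           exclude_species = character(),
                           drop_isolated = TRUE) {
  validate_network(net)
  exclude_metabolites <- as.character(exclude_metabolites)
  exclude_species <- as.character(exclude_species)
  keep_edges <- function(e) {
    e[!(e$species %in% exclude_species) &
        !(e$metabolite %in% exclude_metabolites), , drop = FALSE]
  }
  cons <- keep_edges(net$consumption)
  prod <- keep_edges(net$production)
  species <- setdiff(net$species, exclude_species)
  metabolites <- setdiff(net$metabolites, exclude_metabolites)
  n_iso_sp <- 0L; n_iso_met <- 0L
  if (drop_isolated) {
    used_sp <- unique(c(cons$species, prod$species))
    used_met <- unique(c(cons$metabolite, prod$metabolite))
    n_iso_sp <- sum(!(species %in% used_sp))
    n_iso_met <- sum(!(metabolites %in% used_met))
    species <- species[species %in% used_sp]
    metabolites <- metabolites[metabolites %in% used_met]
  }
  out <- structure(
    list(species = species, metabolites = metabolites,
         consumption = cons, production = prod,
         genus = net$genus[species]),
    class = "cross_feeding_network"
  )
  validate_network(out)
  attr(out, "filter_report") <- list(
    species_excluded = sum(net$species %in% exclude_species),
    metabolites_excluded = sum(net$metabolites %in% exclude_metabolites),
    edges_removed = (nrow(net$consumption) - nrow(cons)) +
      (nrow(net$production) - nrow(prod)),
    isolated_species_dropped = n_iso_sp,
    isolated_metabolites_dropped = n_iso_met,
    absent_ids_ignored = sum(!(exclude_species %in% net$species)) +
      sum(!(exclude_metabolites %in% net$metabolites))
  )
  out
}

#' Read an exclusion list (one id per line)
#'
#' @param path plain-text file, one id per line; blank lines and lines
#'   starting with `#` are skipped.
#' @return character vector of ids.
#' @export
read_exclusion_list <- function(path) {
  x <- trimws(readLines(path, warn = FALSE))
  x[nzchar(x) & !startsWith(x, "#")]
}

#' Map observed taxa onto a capability network
#'
#' Stage 1 matches observed names to network species ids after
#' [normalize_name()] normalization. Stage 2 (optional genus fallback)
#' handles an unmapped species whose genus is present in the network: if all
#' in-network congeners share an identical capability set, the new species
#' is added to the network with that shared set; for genera listed in
#' `core_genera`, the intersection ("core") of the congeners' capabilities
#' is used instead even when they differ.
#'
#' @param observed_names character vector of observed taxon names.
#' @param net a `cross_feeding_network`.
#' @param genus_fallback enable stage 2.
#' @param core_genera genera given the core-capability (intersection)
#'   treatment; default none.
#' @param abundances optional numeric vector (same length/order as
#'   `observed_names`, or named by them) used to compute the coverage
#'   fraction of mapped abundance.
#' @return list with `report` (data.frame: observed_name, mapped_id, stage,
#'   n_capabilities), `network` (possibly augmented with stage-2 species)
#'   and `coverage` (mapped abundance fraction, `NA` without abundances).
#' @export
map_taxa <- function(observed_names, net, genus_fallback = TRUE,
                     core_genera = character(), abundances = NULL) {
  validate_network(net)
  observed_names <- as.character(observed_names)
  norm_obs <- normalize_name(observed_names)
  norm_net <- normalize_name(net$species)
  if (anyDuplicated(norm_net)) {
    warning("distinct network species collide after name normalization; ",
            "first occurrence wins")
  }
  idx <- match(norm_obs, norm_net)
  mapped_id <- ifelse(is.na(idx), NA_character_, net$species[idx])
  stage <- ifelse(is.na(idx), "unmapped", "exact")

  cap_key <- function(n, sp) {
    paste(
      paste(sort(consumables(n, sp)), collapse = "|"),
      paste(sort(byproducts(n, sp)), collapse = "|"),
      sep = "||"
    )
  }
  aug <- net
  if (genus_fallback) {
    norm_core <- normalize_name(core_genera)
    for (k in which(is.na(idx))) {
      genus_obs <- strsplit(norm_obs[k], " ", fixed = TRUE)[[1]][1]
      congeners <- net$species[normalize_name(net$genus[net$species]) == genus_obs]
      if (!length(congeners)) next
      keys <- vapply(congeners, function(sp) cap_key(net, sp), "")
      use_core <- genus_obs %in% norm_core
      if (length(unique(keys)) == 1L || use_core) {
        if (length(unique(keys)) == 1L && !use_core) {
          con <- sort(consumables(net, congeners[1L]))
          pro <- sort(byproducts(net, congeners[1L]))
          this_stage <- "genus_identical"
        } else {
          con <- sort(Reduce(intersect, lapply(congeners, consumables, net = net)))
          pro <- sort(Reduce(intersect, lapply(congeners, byproducts, net = net)))
          this_stage <- "genus_core"
        }
        if (!length(con) && !length(pro)) next
        new_id <- observed_names[k]
        if (new_id %in% aug$species) next
        aug$species <- c(aug$species, new_id)
        aug$genus <- c(aug$genus, stats::setNames(net$genus[congeners[1L]], new_id))
        if (length(con)) {
          aug$consumption <- rbind(aug$consumption,
                                   data.frame(species = new_id, metabolite = con,
                                              stringsAsFactors = FALSE))
        }
        if (length(pro)) {
          aug$production <- rbind(aug$production,
                                  data.frame(species = new_id, metabolite = pro,
                                             stringsAsFactors = FALSE))
        }
        mapped_id[k] <- new_id
        stage[k] <- this_stage
      }
    }
    validate_network(aug)
  }

  n_caps <- ifelse(
    is.na(mapped_id), 0L,
    vapply(mapped_id, function(sp) {
      if (is.na(sp)) 0L else
        length(consumables(aug, sp)) + length(byproducts(aug, sp))
    }, 0L)
  )
  report <- data.frame(
    observed_name = observed_names,
    mapped_id = mapped_id,
    stage = stage,
    n_capabilities = as.integer(n_caps),
    stringsAsFactors = FALSE
  )
  coverage <- NA_real_
  if (!is.null(abundances)) {
    ab <- if (!is.null(names(abundances))) {
      unname(abundances[observed_names])
    } else {
      stopifnot(length(abundances) == length(observed_names))
      abundances
    }
    tot <- sum(ab)
    coverage <- if (tot > 0) sum(ab[!is.na(mapped_id)]) / tot else NA_real_
  }
  list(report = report, network = aug, coverage = coverage)
}

#' Write a taxon-mapping report to TSV
#'
#' @param mapping result of [map_taxa()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_mapping_report <- function(mapping, path) {
  utils::write.table(mapping$report, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' Summarize a cross-feeding network
#'
#' @param net a `cross_feeding_network`.
#' @return list with node and edge counts plus per-species and
#'   per-metabolite degree tables for both edge sets.
#' @export
network_summary <- function(net) {
  validate_network(net)
  deg <- function(e, by, ids) {
    d <- table(factor(e[[by]], levels = ids))
    stats::setNames(as.integer(d), ids)
  }
  list(
    n_species = length(net$species),
    n_metabolites = length(net$metabolites),
    n_consumption_edges = nrow(net$consumption),
    n_production_edges = nrow(net$production),
    n_interactions = nrow(net$consumption) + nrow(net$production),
    species_in_degree = deg(net$consumption, "species", net$species),
    species_out_degree = deg(net$production, "species", net$species),
    metabolite_consumer_degree = deg(net$consumption, "metabolite", net$metabolites),
    metabolite_producer_degree = deg(net$production, "metabolite", net$metabolites)
  )
}
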