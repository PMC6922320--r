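# Readers and writers for the package's delimited interchange formats.
# All tables are long-format TSV so that cohorts of any size stay diffable.

#' Read and write per-sample abundance tables
#'
#' Long-format TSV with columns `sample_id`, `species`, `abundance`.
#' Abundances are renormalized per sample by [community_sample()].
#'
#' @param path file path.
#' @return `read_abundance_table()`: named list of named numeric vectors,
#'   one per sample.
#' @export
read_abundance_table <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t", quote = "\"",
                           comment.char = "", check.names = FALSE,
                           stringsAsFactors = FALSE)
  need <- c("sample_id", "species", "abundance")
  if (!all(need %in% names(tab))) {
    stop("abundance table needs columns: ", paste(need, collapse = ", "))
  }
  lapply(split(tab, tab$sample_id), function(d) {
    stats::setNames(as.numeric(d$abundance), d$species)
  })
}

#' @rdname read_abundance_table
#' @param samples named list of named numeric vectors.
#' @export
write_abundance_table <- function(samples, path) {
  rows <- do.call(rbind, lapply(names(samples), function(sid) {
    data.frame(sample_id = sid, species = names(samples[[sid]]),
               abundance = unname(samples[[sid]]), stringsAsFactors = FALSE)
  }))
  utils::write.table(format_num_df(rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read and write per-sample metabolome tables
#'
#' Long-format TSV with columns `sample_id`, `metabolite`, `level`.
#'
#' @param path file path.
#' @return `read_metabolome_table()`: named list of named numeric vectors.
#' @export
read_metabolome_table <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t", quote = "\"",
                           comment.char = "", check.names = FALSE,
                           stringsAsFactors = FALSE)
  need <- c("sample_id", "metabolite", "level")
  if (!all(need %in% names(tab))) {
    stop("metabolome table needs columns: ", paste(need, collapse = ", "))
  }
  lapply(split(tab, tab$sample_id), function(d) {
    stats::setNames(as.numeric(d$level), d$metabolite)
  })
}

#' @rdname read_metabolome_table
#' @param metabolomes named list of named numeric vectors.
#' @export
write_metabolome_table <- function(metabolomes, path) {
  rows <- do.call(rbind, lapply(names(metabolomes), function(sid) {
    data.frame(sample_id = sid, metabolite = names(metabolomes[[sid]]),
               level = unname(metabolomes[[sid]]), stringsAsFactors = FALSE)
  }))
  utils::write.table(format_num_df(rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read an intake-amount table
#'
#' TSV with columns `metabolite`, `amount` and optionally `sample_id`;
#' without `sample_id`, the same intake applies to every sample.
#'
#' @param path file path.
#' @return named numeric vector, or a named list of them when the table has
#'   a `sample_id` column.
#' @export
read_intake_table <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t", quote = "\"",
                           comment.char = "", check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (!all(c("metabolite", "amount") %in% names(tab))) {
    stop("intake table needs columns: metabolite, amount")
  }
  if ("sample_id" %in% names(tab)) {
    lapply(split(tab, tab$sample_id), function(d) {
      stats::setNames(as.numeric(d$amount), d$metabolite)
    })
  } else {
    stats::setNames(as.numeric(tab$amount), tab$metabolite)
  }
}

# fixed 15-significant-digit formatting keeps reruns byte-identical across
# platforms while staying lossless for comparison purposes
format_num_df <- function(d) {
  for (j in seq_along(d)) {
    if (is.numeric(d[[j]]) && !is.integer(d[[j]])) {
      d[[j]] <- formatC(d[[j]], digits = 15, format = "g")
    }
  }
  d
}

write_tsv <- function(d, path) {
  utils::write.table(format_num_df(d), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}
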