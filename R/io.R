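#' Read and write observation tables as tidy CSV
#'
#' Columns: `age_days`, `genotype`, `quantity`, `value` and optional `sd`.
#'
#' @param path File path.
#' @return [read_observations()] returns a validated observation table.
#' @export
read_observations <- function(path) {
  validate_observations(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname read_observations
#' @param table An observation table.
#' @export
write_observations <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}

#' Serialize a parameter set and variant to JSON or YAML
#'
#' @param params A [model_params()].
#' @param variant A [model_variant()].
#' @param path Output path; format chosen by extension (`.json`, `.yaml` /
#'   `.yml`).
#' @export
write_params <- function(params, variant, path) {
  obj <- list(params = unclass(params), variant = unclass(variant))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                         null = "null", na = "null")
  } else if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::write_yaml(obj, path, precision = 15)
  } else {
    stop("unsupported extension (use .json, .yaml or .yml): ", path)
  }
  invisible(path)
}

#' @rdname write_params
#' @return [read_params()] returns `list(params = , variant = )`.
#' @export
read_params <- function(path) {
  obj <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    stop("unsupported extension (use .json, .yaml or .yml): ", path)
  }
  p <- lapply(obj$params, function(x) if (is.null(x)) NA_real_ else x)
  list(params = do.call(model_params, p),
       variant = model_variant(obj$variant$activation,
                               obj$variant$selfrenewal))
}

#' Write a trajectory with derived series as tidy CSV
#'
#' Columns: `time_days`, `qNSC`, `aNSC`, `total`, `fraction_active`,
#' `progenitor_flux`.
#'
#' @param traj An `nsc_trajectory`.
#' @param path Output path.
#' @inheritParams as_trajectory_table
#' @export
write_trajectory <- function(traj, path, params = attr(traj, "params"),
                             variant = attr(traj, "variant")) {
  utils::write.csv(as_trajectory_table(traj, params, variant), path,
                   row.names = FALSE)
  invisible(path)
}

#' Read and write 5'UTR sets as FASTA
#'
#' Uses Biostrings when available.
#'
#' @param path File path.
#' @return [read_utr_fasta()] returns a data frame with columns `id` and
#'   `sequence`.
#' @export
read_utr_fasta <- function(path) {
  if (requireNamespace("Biostrings", quietly = TRUE)) {
    set <- Biostrings::readBStringSet(path)
    data.frame(id = names(set), sequence = as.character(set))
  } else {
    lines <- readLines(path)
    hdr <- grepl("^>", lines)
    id <- sub("^>", "", lines[hdr])
    seqs <- tapply(lines[!hdr], cumsum(hdr)[!hdr], paste, collapse = "")
    data.frame(id = sub("\\s.*$", "", id), sequence = as.character(seqs))
  }
}

#' @rdname read_utr_fasta
#' @param utrs Data frame with columns `id` and `sequence` (as produced by
#'   [generate_utr_set()]).
#' @export
write_utr_fasta <- function(utrs, path) {
  if (requireNamespace("Biostrings", quietly = TRUE)) {
    set <- Biostrings::BStringSet(stats::setNames(utrs$sequence, utrs$id))
    Biostrings::writeXStringSet(set, path)
  } else {
    writeLines(paste0(">", utrs$id, "\n", utrs$sequence), path)
  }
  invisible(path)
}

#' Read and write gene sets as one-id-per-line text
#'
#' @param path File path.
#' @export
read_gene_set <- function(path) {
  ids <- trimws(readLines(path))
  ids[nzchar(ids)]
}

#' @rdname read_gene_set
#' @param gene_set Character vector of gene ids.
#' @export
write_gene_set <- function(gene_set, path) {
  writeLines(as.character(gene_set), path)
  invisible(path)
}

#' Read a time course CSV (`time_hours`, `value`, optional `replicate`)
#'
#' @param path File path.
#' @export
read_timecourse <- function(path) {
  tc <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("time_hours", "value") %in% names(tc))) {
    stop("time course CSV needs columns 'time_hours' and 'value'")
  }
  tc
}
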