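#' @importFrom Biostrings readAAStringSet writeXStringSet AAStringSet
NULL

#' Read drugs from a .smi or .csv file
#'
#' `.smi`: one SMILES per line, optionally followed by whitespace and an
#' id (ids are generated when absent). `.csv`: columns `id` and `smiles`.
#'
#' @param path File path.
#' @return Data frame with columns `id`, `smiles`.
#' @export
read_drugs <- function(path) {
  if (!file.exists(path)) stop("drug file not found: ", path)
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    if (!all(c("id", "smiles") %in% names(df))) {
      stop("drug CSV must have columns 'id' and 'smiles': ", path)
    }
    return(df[, c("id", "smiles")])
  }
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(trimws(lines), "[ \t]+")
  smiles <- vapply(parts, `[[`, character(1), 1L)
  id <- vapply(seq_along(parts), function(i) {
    if (length(parts[[i]]) >= 2L) parts[[i]][[2L]] else sprintf("D%03d", i)
  }, character(1))
  data.frame(id = id, smiles = smiles, stringsAsFactors = FALSE)
}

#' Read target sequences from a FASTA file
#'
#' Record ids are the FASTA headers up to the first whitespace.
#'
#' @param path File path.
#' @return Data frame with columns `id`, `sequence`.
#' @export
read_targets <- function(path) {
  if (!file.exists(path)) stop("target FASTA not found: ", path)
  ss <- Biostrings::readAAStringSet(path)
  data.frame(id = sub("\\s.*$", "", names(ss)),
             sequence = as.character(ss), stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Write target sequences to a FASTA file
#'
#' @param targets Data frame with columns `id`, `sequence`.
#' @param path Output path.
#' @export
write_fasta <- function(targets, path) {
  ss <- Biostrings::AAStringSet(targets$sequence)
  names(ss) <- targets$id
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Read labeled affinity records from CSV
#'
#' Expected header: `drug_id,target_id,affinity`.
#'
#' @param path File path.
#' @return An `affinity_records` data frame.
#' @export
read_affinities <- function(path) {
  if (!file.exists(path)) stop("affinity CSV not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("drug_id", "target_id", "affinity")
  if (!all(need %in% names(df))) {
    stop("affinity CSV must have columns drug_id, target_id, affinity: ",
         path)
  }
  if (!all(is.finite(df$affinity))) stop("non-finite affinity values in ", path)
  df <- df[, need]
  class(df) <- c("affinity_records", class(df))
  df
}

# Check that every id in records resolves; error listing offending rows.
check_ids <- function(records, drugs, targets) {
  bad_d <- !(records$drug_id %in% drugs$id)
  bad_t <- !(records$target_id %in% targets$id)
  if (any(bad_d) || any(bad_t)) {
    rows <- sort(unique(c(which(bad_d), which(bad_t))))
    stop("unresolvable ids in affinity rows: ",
         paste(utils::head(rows, 20L), collapse = ", "),
         if (length(rows) > 20L) " ..." else "")
  }
  invisible(TRUE)
}

#' Save a pretrained encoder or model checkpoint
#'
#' A versioned container (RDS) holding the object and its configuration
#' snapshot.
#'
#' @param object A `pretrain_state` or `gindta` model.
#' @param path Output path.
#' @export
write_checkpoint <- function(object, path) {
  saveRDS(list(format = "gindta-checkpoint", version = 1L,
               class = class(object)[1L], object = object), path)
  invisible(path)
}

#' Load a checkpoint written by [write_checkpoint()]
#'
#' @param path Checkpoint path.
#' @return The stored object.
#' @export
read_checkpoint <- function(path) {
  if (!file.exists(path)) stop("checkpoint not found: ", path)
  x <- readRDS(path)
  if (!identical(x$format, "gindta-checkpoint")) {
    stop("not a gindta checkpoint: ", path)
  }
  x$object
}
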