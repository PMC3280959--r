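#' Read sequencing reads from FASTA/FASTQ
#'
#' Gzip-transparent; format is inferred from the file name (`.fq`/`.fastq`
#' means FASTQ, anything else FASTA). Sequences are upper-cased; qualities
#' are ignored. The sample id defaults to the file stem.
#'
#' @param path path to a FASTA or FASTQ file (optionally .gz).
#' @param sample sample id; default is the file name without extensions.
#' @return list with `reads` (named character vector, names = record ids) and
#'   `sample`.
#' @export
read_reads <- function(path, sample = NULL) {
  if (!file.exists(path)) stop("input file not found: ", path)
  fq <- grepl("\\.(fq|fastq)(\\.gz)?$", path, ignore.case = TRUE)
  if (fq) {
    nl <- length(readLines(path, warn = FALSE))
    if (nl %% 4 != 0)
      stop("malformed FASTQ (truncated record ", nl %/% 4 + 1, ") in ", path)
  }
  x <- Biostrings::readDNAStringSet(path, format = if (fq) "fastq" else "fasta")
  reads <- toupper(as.character(x))
  names(reads) <- sub("\\s.*$", "", names(x))
  if (anyDuplicated(names(reads)))
    stop("duplicate read ids in ", path)
  sample <- sample %||%
    sub("\\.(fa|fasta|fq|fastq)(\\.gz)?$", "", basename(path),
        ignore.case = TRUE)
  list(reads = reads, sample = sample)
}

#' Write reads to FASTA
#'
#' @param reads named character vector of sequences.
#' @param path output path.
#' @export
write_fasta <- function(reads, path) {
  ids <- names(reads) %||% paste0("read", seq_along(reads))
  writeLines(paste0(">", ids, "\n", reads), path)
  invisible(path)
}

#' @rdname counts_io
#' @title Counts matrix TSV round-trip
#' @description Tab-separated, UTF-8, '#'-comment lines allowed; header row of
#'   canonical class strings, one row per sample, first column `sample`.
#' @param counts `mj_counts` or samples x classes matrix.
#' @param path file path.
#' @export
write_counts <- function(counts, path) {
  R <- as_counts_matrix(counts)
  df <- data.frame(sample = rownames(R) %||% paste0("sample", seq_len(nrow(R))),
                   R, check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname counts_io
#' @export
read_counts <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (names(df)[1] != "sample") stop("counts TSV must start with a 'sample' column")
  R <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(R) <- "integer"
  rownames(R) <- df$sample
  k <- nchar(colnames(R)[1])
  structure(list(R = R, samples = df$sample, totals = rowSums(R), k = k,
                 strategy = NA_character_),
            class = "mj_counts")
}

#' @rdname model_io
#' @title Mixture model JSON round-trip
#' @description The fitted model (P, F, K, log-likelihood, options and seed)
#'   serialized as JSON.
#' @param model `mj_plsa`.
#' @param path file path.
#' @param opts optional [fit_options()] stored alongside.
#' @export
write_model <- function(model, path, opts = NULL) {
  obj <- list(P = unname(model$P), F = unname(model$F), K = model$K,
              loglik = model$loglik,
              samples = rownames(model$P), classes = colnames(model$F),
              options = if (!is.null(opts)) unclass(opts))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname model_io
#' @export
read_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  P <- as.matrix(obj$P)
  F <- as.matrix(obj$F)
  rownames(P) <- obj$samples
  colnames(F) <- obj$classes
  new_plsa(P, F, loglik = obj$loglik %||% NA_real_)
}

#' @rdname bins_io
#' @title Bin assignment and truth-label TSV round-trips
#' @description Bins: columns `read_id`, `sample`, `bin`. Truth layouts:
#'   columns `read_id`, `sample`, `species`, `genome`, `start`, `strand`
#'   (0-based, half-open coordinates).
#' @param df data.frame in the respective schema.
#' @param path file path.
#' @export
write_bins <- function(df, path) {
  need <- c("read_id", "sample", "bin")
  if (!all(need %in% names(df)))
    stop("bins table needs columns: ", paste(need, collapse = ", "))
  utils::write.table(df[need], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname bins_io
#' @export
read_bins <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                          stringsAsFactors = FALSE)
  need <- c("read_id", "sample", "bin")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("bins TSV missing column(s): ", paste(missing, collapse = ", "))
  df[need]
}

#' @rdname bins_io
#' @export
write_truth <- function(df, path) {
  need <- c("read_id", "sample", "species", "start")
  if (!all(need %in% names(df)))
    stop("truth table needs columns: ", paste(need, collapse = ", "))
  keep <- intersect(c("read_id", "sample", "species", "genome", "start",
                      "strand", "length"), names(df))
  utils::write.table(df[keep], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname bins_io
#' @export
read_truth <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                          stringsAsFactors = FALSE)
  need <- c("read_id", "sample", "species", "start")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("truth TSV missing column(s): ", paste(missing, collapse = ", "))
  df
}

#' Read a phenotype table
#'
#' TSV with a `sample_id` column followed by one column per phenotype;
#' dichotomous phenotypes coded 0/1.
#'
#' @param path file path.
#' @return data.frame.
#' @export
read_phenotypes <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                          stringsAsFactors = FALSE)
  if (!"sample_id" %in% names(df)) stop("phenotype TSV needs a 'sample_id' column")
  df
}
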