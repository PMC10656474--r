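#' Read a paired FASTQ sample
#'
#' Standard 4-line FASTQ, optionally gzip-compressed. Structural problems
#' (record count not a multiple of four, missing `@`/`+` markers,
#' sequence/quality length mismatch) raise an error naming the offending
#' file and line.
#'
#' @param r1_path,r2_path Paths to the `_R1`/`_R2` files.
#' @return List `id`, `r1`, `q1`, `r2`, `q2` (identifiers from R1, without
#'   the leading `@`).
#' @export
read_fastq_pair <- function(r1_path, r2_path) {
  a <- read_fastq_one(r1_path)
  b <- read_fastq_one(r2_path)
  assert_that(length(a$seq) == length(b$seq),
              "R1 and R2 contain different numbers of records")
  list(id = a$id, r1 = a$seq, q1 = a$qual, r2 = b$seq, q2 = b$qual)
}

read_fastq_one <- function(path) {
  lines <- readLines(path)
  n <- length(lines)
  if (n %% 4 != 0) {
    stop("malformed FASTQ ", path, ": truncated record at line ",
         4 * (n %/% 4) + 1, call. = FALSE)
  }
  if (n == 0) {
    return(list(id = character(0), seq = character(0), qual = character(0)))
  }
  idx <- seq(1, n, by = 4)
  bad_at <- !startsWith(lines[idx], "@")
  if (any(bad_at)) {
    stop("malformed FASTQ ", path, ": expected '@' at line ",
         idx[which(bad_at)[1]], call. = FALSE)
  }
  bad_plus <- !startsWith(lines[idx + 2], "+")
  if (any(bad_plus)) {
    stop("malformed FASTQ ", path, ": expected '+' at line ",
         idx[which(bad_plus)[1]] + 2, call. = FALSE)
  }
  seqs <- lines[idx + 1]
  quals <- lines[idx + 3]
  bad_len <- nchar(seqs) != nchar(quals)
  if (any(bad_len)) {
    stop("malformed FASTQ ", path,
         ": sequence/quality length mismatch at line ",
         idx[which(bad_len)[1]] + 1, call. = FALSE)
  }
  list(id = sub("^@", "", lines[idx]), seq = seqs, qual = quals)
}

#' Write a paired FASTQ sample
#'
#' @param reads List with `id`, `r1`, `q1`, `r2`, `q2` (as produced by
#'   [emit_reads()] or [read_fastq_pair()]).
#' @param r1_path,r2_path Output paths; a `.gz` suffix triggers gzip.
#' @return The two paths, invisibly.
#' @export
write_fastq_pair <- function(reads, r1_path, r2_path) {
  write_fastq_one(reads$id, reads$r1, reads$q1, r1_path)
  write_fastq_one(reads$id, reads$r2, reads$q2, r2_path)
  invisible(c(r1_path, r2_path))
}

write_fastq_one <- function(id, seq, qual, path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  if (length(id)) {
    writeLines(paste0("@", id, "\n", seq, "\n+\n", qual), con)
  }
  invisible(path)
}

#' Read a FASTA file as a named character vector
#'
#' Wrapped or unwrapped lines are accepted; duplicate identifiers are an
#' error.
#'
#' @param path FASTA file.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(x))
  if (anyDuplicated(ids)) {
    stop("duplicate FASTA ids in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "),
         call. = FALSE)
  }
  setNames(as.character(x), ids)
}

#' Write a named character vector as FASTA
#'
#' @param seqs Named character vector.
#' @param path Output file.
#' @param width Line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70) {
  assert_that(!is.null(names(seqs)) || length(seqs) == 0,
              "sequences must be named")
  x <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(x, path, width = width)
  invisible(path)
}

#' Write a clonotype table as TSV
#'
#' One row per clonotype (`key`, `key_level`, `count`, `proportion`) with
#' the table's metadata repeated as extra columns.
#'
#' @param table A `clonotype_table`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_clonotype_tsv <- function(table, path) {
  d <- table$data
  d$key_level <- table$key_level
  for (nm in names(table$metadata)) d[[nm]] <- table$metadata[[nm]]
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a diversity report as JSON
#'
#' @param report Output of [diversity_report()] (or a named list of them).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_diversity_json <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Write enrichment or selectivity results as TSV
#'
#' @param x Data frame ([enrichment_filter()] / [selectivity_matrix()]
#'   output).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_result_tsv <- function(x, path) {
  write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Export annotated records as an AIRR-style rearrangement TSV
#'
#' Minimal AIRR-flavored columns: `sequence`, `sequence_aa`, `cdr1_aa`,
#' `cdr2_aa`, `cdr3_aa`, `complete_vdj`. Coordinates elsewhere in the
#' package are 0-based half-open on the amino-acid sequence.
#'
#' @param records Data frame from [annotate_vhh()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
export_airr <- function(records, path) {
  d <- data.frame(sequence = records$nt_cds, sequence_aa = records$aa,
                  cdr1_aa = records$cdr1_aa, cdr2_aa = records$cdr2_aa,
                  cdr3_aa = records$cdr3_aa,
                  complete_vdj = records$complete,
                  stringsAsFactors = FALSE)
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
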