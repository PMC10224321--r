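# Plain-text artifact I/O: FASTA, count/label CSVs, JSON reports.

#' Read / write FASTA sequence files
#'
#' Reading is delegated to Biostrings (install suggested); writing emits
#' plain 60-column wrapped FASTA.
#'
#' @param path file path.
#' @param sequences named character vector (names become headers).
#' @return `read_fasta()` returns a named character vector.
#' @export
read_fasta <- function(path) {
  if (!requireNamespace("Biostrings", quietly = TRUE))
    stop("reading FASTA requires the Biostrings package")
  set <- Biostrings::readAAStringSet(path)
  setNames(as.character(set), names(set))
}

#' @rdname read_fasta
#' @export
write_fasta <- function(sequences, path) {
  if (is.null(names(sequences)))
    names(sequences) <- sprintf("seq_%05d", seq_along(sequences))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(sequences)) {
    writeLines(paste0(">", names(sequences)[i]), con)
    s <- sequences[[i]]
    starts <- seq(1L, nchar(s), by = 60L)
    writeLines(substring(s, starts, pmin(starts + 59L, nchar(s))), con)
  }
  invisible(path)
}

#' Write a read-count table as CSV (columns pool, sequence, count)
#'
#' @param table a [read_count_table()].
#' @param path file path.
#' @export
write_count_csv <- function(table, path) {
  stopifnot(inherits(table, "read_count_table"))
  write.csv(data.frame(pool = table$pool,
                       sequence = names(table$counts),
                       count = unname(table$counts)),
            path, row.names = FALSE)
  invisible(path)
}

#' Read a count CSV back into a read-count table
#'
#' @param path CSV with columns pool, sequence, count (single pool).
#' @return a [read_count_table()].
#' @export
read_count_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("pool", "sequence", "count") %in% names(df)))
  pool <- unique(df$pool)
  if (length(pool) != 1L) stop("count CSV must describe a single pool")
  read_count_table(pool, setNames(as.integer(df$count), df$sequence))
}

#' Write a labelled dataset as CSV (columns id, sequence, label)
#'
#' @param dataset a [labeled_dataset()].
#' @param path file path.
#' @export
write_labeled_csv <- function(dataset, path) {
  stopifnot(inherits(dataset, "labeled_dataset"))
  write.csv(data.frame(id = dataset$ids, sequence = dataset$sequences,
                       label = dataset$labels),
            path, row.names = FALSE)
  invisible(path)
}
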