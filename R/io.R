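## Readers/writers for on-disk artifacts and the packaged phenotype table.
##
## Conventions: coordinates 0-based, windows half-open, all signals stored
## in log2 space, tab-delimited text with explicit headers. Writers are
## deterministic (same object, byte-identical file); readers reject with a
## line-numbered message anything their writer could not have produced.

FEATURE_FLAGS <- c("ok", "suppressed")

#' Read a FASTA file
#'
#' Minimal strict FASTA reader: ids are the first whitespace-delimited
#' token of each header, sequences are uppercased on ingest. Duplicate ids,
#' empty records, and sequence lines before the first header are rejected
#' with the offending line number.
#'
#' @param path File path.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  lines <- readLines(path)
  ids <- character(); seqs <- list(); cur <- NULL
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (ln == "") next
    if (startsWith(ln, ">")) {
      id <- strsplit(sub("^>", "", ln), "\\s+")[[1]][1]
      if (is.na(id) || id == "")
        stop2("%s:%d: empty FASTA header", path, i)
      if (id %in% ids)
        stop2("%s:%d: duplicate FASTA id '%s'", path, i, id)
      if (!is.null(cur) && !nzchar(seqs[[cur]]))
        stop2("%s:%d: record '%s' has no sequence", path, i, ids[cur])
      ids <- c(ids, id); seqs[[length(ids)]] <- ""
      cur <- length(ids)
    } else {
      if (is.null(cur))
        stop2("%s:%d: sequence line before any header", path, i)
      seqs[[cur]] <- paste0(seqs[[cur]], toupper(ln))
    }
  }
  if (is.null(cur)) stop2("%s: no FASTA records found", path)
  if (!nzchar(seqs[[cur]]))
    stop2("%s: last record '%s' has no sequence", path, ids[cur])
  out <- unlist(seqs)
  names(out) <- ids
  out
}

#' Write a FASTA file
#'
#' @param records Named character vector of sequences.
#' @param path Output path.
#' @param width Line wrap width (default 70).
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(records, path, width = 70L) {
  if (is.null(names(records)) || any(!nzchar(names(records))))
    stop2("write_fasta: records must be named")
  con <- file(path, "wb")
  on.exit(close(con))
  for (i in seq_along(records)) {
    s <- toupper(records[[i]])
    chunks <- substring(s, seq(1, nchar(s), width),
                        pmin(seq(1, nchar(s), width) + width - 1, nchar(s)))
    writeLines(c(paste0(">", names(records)[i]), chunks), con, sep = "\n")
  }
  invisible(path)
}

#' Write a spot-level feature table
#'
#' Tab-delimited, full numeric precision (values survive a write/read
#' round-trip exactly). Required columns: `row`, `col`, `probe_id`,
#' `log2_signal`, `flag`; any additional columns are preserved.
#'
#' @param table Feature table data.frame.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_feature_table <- function(table, path) {
  req <- c("row", "col", "probe_id", "log2_signal", "flag")
  miss <- setdiff(req, names(table))
  if (length(miss)) stop2("feature table lacks column(s): %s",
                          paste(miss, collapse = ", "))
  if (anyDuplicated(table[, c("row", "col")]))
    stop2("duplicate (row, col) coordinates in feature table")
  if (!all(table$flag %in% FEATURE_FLAGS))
    stop2("flag values must be one of: %s",
          paste(FEATURE_FLAGS, collapse = ", "))
  out <- table[, c(req, setdiff(names(table), req)), drop = FALSE]
  out$log2_signal <- format_num(out$log2_signal)
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(paste(names(out), collapse = "\t"), con, sep = "\n")
  writeLines(do.call(paste, c(lapply(out, as.character), sep = "\t")),
             con, sep = "\n")
  invisible(path)
}

#' Read a spot-level feature table
#'
#' @param path File written by [write_feature_table()].
#' @return Feature table data.frame.
#' @export
read_feature_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  req <- c("row", "col", "probe_id", "log2_signal", "flag")
  miss <- setdiff(req, names(tab))
  if (length(miss))
    stop2("%s:1: header lacks column(s): %s", path,
          paste(miss, collapse = ", "))
  num <- suppressWarnings(as.numeric(tab$log2_signal))
  bad <- which(is.na(num) & tab$log2_signal != "NA")
  if (length(bad))
    stop2("%s:%d: non-numeric log2_signal '%s'", path, bad[1] + 1L,
          tab$log2_signal[bad[1]])
  tab$log2_signal <- num
  tab$row <- as.integer(tab$row)
  tab$col <- as.integer(tab$col)
  if (anyDuplicated(tab[, c("row", "col")])) {
    d <- which(duplicated(tab[, c("row", "col")]))[1]
    stop2("%s:%d: duplicate coordinates (%d, %d)", path, d + 1L,
          tab$row[d], tab$col[d])
  }
  badflag <- which(!tab$flag %in% FEATURE_FLAGS)
  if (length(badflag))
    stop2("%s:%d: unknown flag '%s'", path, badflag[1] + 1L,
          tab$flag[badflag[1]])
  tab
}

#' Write an array design table
#'
#' @param design Output of [generate_design()] or compatible.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_design <- function(design, path) {
  req <- c("probe_id", "gene_id", "species", "row", "col")
  miss <- setdiff(req, names(design))
  if (length(miss)) stop2("design lacks column(s): %s",
                          paste(miss, collapse = ", "))
  con <- file(path, "wb")
  on.exit(close(con))
  out <- design[, req]
  writeLines(paste(names(out), collapse = "\t"), con, sep = "\n")
  writeLines(do.call(paste, c(lapply(out, as.character), sep = "\t")),
             con, sep = "\n")
  invisible(path)
}

#' Read an array design table
#'
#' @param path File written by [write_design()].
#' @return Design data.frame.
#' @export
read_design <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  req <- c("probe_id", "gene_id", "species", "row", "col")
  miss <- setdiff(req, names(tab))
  if (length(miss))
    stop2("%s:1: header lacks column(s): %s", path,
          paste(miss, collapse = ", "))
  if (anyDuplicated(tab[, c("row", "col")]))
    stop2("%s: duplicate spot coordinates", path)
  tab
}

#' Load the packaged wild-fish phenotype table
#'
#' The 22 male hornyhead turbot sampled at the five southern-California
#' stations, with plasma vitellogenin (VTG, ng/ug protein), estradiol (E2,
#' pg/ml), cortisol (Cort, ng/ml), thyroxine (T4, ng/ml), testosterone (T,
#' ng/ml), IGF-I (ng/ml), calculated age (y), and standard length (SL, cm).
#'
#' @return data.frame of 22 fish records.
#' @export
load_packaged_phenotypes <- function() {
  path <- system.file("extdata", "table1_phenotypes.csv",
                      package = "msarray", mustWork = TRUE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  tab$fish_id <- sprintf("%s_%d", tab$station, tab$sample)
  tab
}
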