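# Dataset and manifest I/O.
#
# Two on-disk representations of a paired dataset:
#  * one TSV with header id, enhancer, promoter, label, cell_line;
#  * a FASTA pair (<prefix>_enhancer.fa / <prefix>_promoter.fa) whose records
#    are matched by id, with label and cell line carried in the description.
# Sequences stay raw strings on disk (~1 byte per base); numeric encodings
# are only materialised transiently inside the model.

#' Write pair records to disk
#'
#' @param records an [epi_pairs()] data.frame.
#' @param path for `format = "tsv"` the output file; for `format = "fasta"` a
#'   path prefix, producing `<path>_enhancer.fa` and `<path>_promoter.fa`.
#' @param format `"tsv"` or `"fasta"` (FASTA wrapped at 80 columns).
#' @return the written path(s), invisibly.
#' @export
write_dataset <- function(records, path, format = c("tsv", "fasta")) {
  format <- match.arg(format)
  records <- validate_pairs(records)
  if (format == "tsv") {
    write.table(as.data.frame(records)[, PAIR_COLUMNS], path,
                sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(path))
  }
  paths <- paste0(path, c("_enhancer.fa", "_promoter.fa"))
  desc <- sprintf("%s label=%d cell_line=%s", records$id, records$label, records$cell_line)
  for (k in 1:2) {
    seqs <- Biostrings::DNAStringSet(records[[c("enhancer", "promoter")[k]]])
    names(seqs) <- desc
    Biostrings::writeXStringSet(seqs, paths[k], width = 80L)
  }
  invisible(paths)
}

#' Read pair records from disk
#'
#' Inverse of [write_dataset()]: `read_dataset(write_dataset(x))` is a
#' field-for-field identity. FASTA pairs are matched by id; an id present in
#' one file but not the other is an error naming the orphan. Empty files
#' yield an empty record set.
#'
#' @param path TSV file, or the FASTA path prefix used when writing.
#' @param format `"tsv"` or `"fasta"`.
#' @return an [epi_pairs()] data.frame.
#' @export
read_dataset <- function(path, format = c("tsv", "fasta")) {
  format <- match.arg(format)
  if (format == "tsv") {
    if (!file.exists(path)) stop("no such file: ", path)
    if (file.size(path) == 0L)
      return(epi_pairs(character(), character(), character(), integer(), character()))
    df <- read.delim(path, colClasses = "character", check.names = FALSE)
    miss <- setdiff(PAIR_COLUMNS, names(df))
    if (length(miss)) stop("TSV missing column(s): ", paste(miss, collapse = ", "))
    if (nrow(df) == 0L)
      return(epi_pairs(character(), character(), character(), integer(), character()))
    return(epi_pairs(df$id, df$enhancer, df$promoter, as.integer(df$label), df$cell_line))
  }
  paths <- paste0(path, c("_enhancer.fa", "_promoter.fa"))
  for (p in paths) if (!file.exists(p)) stop("no such file: ", p)
  parse_fa <- function(p) {
    if (file.size(p) == 0L)
      return(data.frame(id = character(), seq = character(), label = integer(),
                        cell_line = character(), stringsAsFactors = FALSE))
    ss <- Biostrings::readDNAStringSet(p)
    hdr <- names(ss)
    id <- sub("\\s.*$", "", hdr)
    lab <- suppressWarnings(as.integer(sub(".*label=(\\d+).*", "\\1", hdr)))
    cl <- sub(".*cell_line=(\\S+).*", "\\1", hdr)
    data.frame(id = id, seq = as.character(ss), label = lab, cell_line = cl,
               stringsAsFactors = FALSE)
  }
  e <- parse_fa(paths[1L]); p <- parse_fa(paths[2L])
  orphans <- c(setdiff(e$id, p$id), setdiff(p$id, e$id))
  if (length(orphans))
    stop("FASTA pair ids do not match; orphan id(s): ", paste(orphans, collapse = ", "))
  if (nrow(e) == 0L)
    return(epi_pairs(character(), character(), character(), integer(), character()))
  p <- p[match(e$id, p$id), , drop = FALSE]
  epi_pairs(e$id, e$seq, p$seq, e$label, e$cell_line)
}

#' Write / read a ground-truth manifest
#'
#' Manifests (see [generate_dataset()]) are stored as a single JSON document:
#' generator settings, motif definitions and the per-record plant table.
#'
#' @param manifest manifest list from [generate_dataset()].
#' @param path JSON file path.
#' @return `write_manifest` returns the path invisibly; `read_manifest`
#'   returns the manifest list with the record table as a data.frame.
#' @export
write_manifest <- function(manifest, path) {
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", pretty = TRUE, na = "null")
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  m$records <- as.data.frame(m$records, stringsAsFactors = FALSE)
  m
}
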