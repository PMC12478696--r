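# Container for labeled enhancer/promoter sequence pairs. A plain data.frame
# with a class tag so validation happens once at the boundaries.

PAIR_COLUMNS <- c("id", "enhancer", "promoter", "label", "cell_line")

#' Construct a set of enhancer-promoter sequence pair records
#'
#' The unit of all I/O in the package: one record pairs an enhancer sequence
#' with a promoter sequence, a binary interaction label and a cell-line tag.
#' Sequences are stored as raw strings over `{A,C,G,T,N}` (about one byte per
#' base); they are only expanded to numeric encodings inside the model.
#'
#' @param id character vector of unique record ids.
#' @param enhancer,promoter character vectors of DNA sequences (upper or lower
#'   case; lower case is folded to upper).
#' @param label integer vector of 0/1 interaction labels.
#' @param cell_line character vector (or scalar) of cell-line tags.
#' @return a `data.frame` of class `epi_pairs` with columns
#'   `id, enhancer, promoter, label, cell_line`.
#' @export
epi_pairs <- function(id, enhancer, promoter, label, cell_line = "synthetic") {
  df <- data.frame(id = as.character(id),
                   enhancer = toupper(as.character(enhancer)),
                   promoter = toupper(as.character(promoter)),
                   label = as.integer(label),
                   cell_line = as.character(cell_line),
                   stringsAsFactors = FALSE)
  class(df) <- c("epi_pairs", "data.frame")
  validate_pairs(df)
}

#' Validate pair records
#'
#' Checks column presence, id uniqueness, label domain, sequence alphabet and
#' (by default) that all records share the same enhancer and promoter lengths.
#' Errors name the offending record id.
#'
#' @param records an `epi_pairs` data.frame (or coercible data.frame).
#' @param require_uniform_length if `TRUE`, all enhancers must share one length
#'   and all promoters another.
#' @return the validated records, invisibly classed as `epi_pairs`.
#' @export
validate_pairs <- function(records, require_uniform_length = TRUE) {
  if (!is.data.frame(records)) stop("records must be a data.frame")
  miss <- setdiff(PAIR_COLUMNS, names(records))
  if (length(miss)) stop("records missing column(s): ", paste(miss, collapse = ", "))
  if (!inherits(records, "epi_pairs")) class(records) <- c("epi_pairs", "data.frame")
  if (nrow(records) == 0L) return(records)
  if (anyDuplicated(records$id))
    stop("duplicate record id(s): ",
         paste(unique(records$id[duplicated(records$id)]), collapse = ", "))
  if (!all(records$label %in% c(0L, 1L)))
    stop("labels must be 0 or 1; offending row id: ",
         records$id[which(!records$label %in% c(0L, 1L))[1L]])
  for (col in c("enhancer", "promoter")) {
    bad <- grepl("[^ACGTN]", records[[col]])
    if (any(bad))
      stop("record '", records$id[which(bad)[1L]], "' has non-ACGTN characters in ", col)
    if (require_uniform_length) {
      lens <- nchar(records[[col]])
      if (length(unique(lens)) > 1L) {
        off <- which(lens != lens[1L])[1L]
        stop("record '", records$id[off], "' has ", col, " length ", lens[off],
             " but the dataset uses length ", lens[1L])
      }
    }
  }
  records
}

#' @export
print.epi_pairs <- function(x, ...) {
  cat(sprintf("epi_pairs: %d records (%d positive, %d negative)\n",
              nrow(x), sum(x$label == 1L), sum(x$label == 0L)))
  if (nrow(x)) {
    cat(sprintf("  enhancer %d bp, promoter %d bp; cell lines: %s\n",
                nchar(x$enhancer[1L]), nchar(x$promoter[1L]),
                paste(unique(x$cell_line), collapse = ", ")))
  }
  invisible(x)
}

# rbind that preserves the class tag
bind_pairs <- function(...) {
  out <- do.call(rbind, lapply(list(...), as.data.frame))
  class(out) <- c("epi_pairs", "data.frame")
  rownames(out) <- NULL
  out
}
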