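# Motif and interaction interchange formats: MEME motif files (consumed by
# TOMTOM), TOMTOM result TSVs, and BioGRID TAB exports. The external tools
# themselves are never invoked; only their formats are written and read.

#' Write region PWMs as a MEME motif file
#'
#' Minimal MEME motif format: version header, `ALPHABET= ACGT`, `strands: +`,
#' uniform background, then one MOTIF block per PWM with a
#' letter-probability matrix (`w` columns = PWM width, `nsites` = number of
#' contributing sequences). The motif names are the region names
#' (`enh_r<i>` / `prom_r<j>`), which become the `Query_ID`s in TOMTOM
#' output.
#'
#' @param pwms a list of [extract_region_pwm()] objects (at least one).
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_meme <- function(pwms, path) {
  if (inherits(pwms, "epi_region_pwm")) pwms <- list(pwms)
  if (!length(pwms)) stop("empty PWM list")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("MEME version 4", "",
               "ALPHABET= ACGT", "",
               "strands: +", "",
               "Background letter frequencies",
               "A 0.25 C 0.25 G 0.25 T 0.25", ""), con)
  for (p in pwms) {
    stopifnot(inherits(p, "epi_region_pwm"))
    writeLines(sprintf("MOTIF %s", p$name), con)
    writeLines(sprintf("letter-probability matrix: alength= 4 w= %d nsites= %d E= 0",
                       p$width, p$n_sequences), con)
    writeLines(apply(p$freq, 2L, function(col)
      paste(sprintf("%.6f", col), collapse = " ")), con)
    writeLines("", con)
  }
  invisible(path)
}

#' Read a MEME motif file (the dialect written by [write_meme()])
#'
#' @param path MEME motif file.
#' @return a named list of motifs, each a list with `name`, `freq`
#'   (4 x w matrix, rows A,C,G,T), `width` and `nsites`.
#' @export
read_meme <- function(path) {
  lines <- readLines(path)
  starts <- grep("^MOTIF\\s", lines)
  out <- list()
  for (s in starts) {
    name <- sub("^MOTIF\\s+(\\S+).*", "\\1", lines[s])
    hdr <- lines[s + 1L]
    if (!grepl("^letter-probability matrix", hdr))
      stop("MOTIF ", name, ": missing letter-probability matrix header")
    w <- as.integer(sub(".*\\bw=\\s*(\\d+).*", "\\1", hdr))
    nsites <- as.integer(sub(".*\\bnsites=\\s*(\\d+).*", "\\1", hdr))
    rows <- lines[s + 1L + seq_len(w)]
    freq <- t(vapply(rows, function(l) scan(text = l, quiet = TRUE),
                     numeric(4L), USE.NAMES = FALSE))
    freq <- t(freq)  # 4 x w
    rownames(freq) <- c("A", "C", "G", "T")
    out[[name]] <- list(name = name, freq = freq, width = w, nsites = nsites)
  }
  out
}

#' Read and threshold a TOMTOM result table
#'
#' Parses the TOMTOM TSV dialect (tab-separated, header line with columns
#' including `Query_ID`, `Target_ID`, `p-value`, `E-value`; trailing `#`
#' comment lines) and keeps only hits passing the published thresholds
#' `E-value < e_max` and `p-value < p_max`.
#'
#' @param path TOMTOM TSV file.
#' @param e_max,p_max retention thresholds (defaults 0.07 and 1e-4).
#' @return a data.frame of retained hits with columns `query`, `target`,
#'   `pvalue`, `evalue`, `source`; attributes `n_kept` and `n_dropped`
#'   record the filter outcome. A file with no data rows yields an empty
#'   data.frame.
#' @export
read_tomtom <- function(path, e_max = 0.07, p_max = 1e-4) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  empty <- data.frame(query = character(), target = character(),
                      pvalue = numeric(), evalue = numeric(),
                      source = character(), stringsAsFactors = FALSE)
  if (!length(lines)) {
    attr(empty, "n_kept") <- 0L; attr(empty, "n_dropped") <- 0L
    return(empty)
  }
  df <- read.delim(text = paste(lines, collapse = "\n"), check.names = FALSE,
                   stringsAsFactors = FALSE)
  need <- c("Query_ID", "Target_ID", "p-value", "E-value")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("TOMTOM file missing required column(s): ", paste(miss, collapse = ", "))
  if (nrow(df) == 0L) {
    attr(empty, "n_kept") <- 0L; attr(empty, "n_dropped") <- 0L
    return(empty)
  }
  keep <- df[["E-value"]] < e_max & df[["p-value"]] < p_max
  out <- data.frame(query = df$Query_ID[keep], target = df$Target_ID[keep],
                    pvalue = df[["p-value"]][keep], evalue = df[["E-value"]][keep],
                    source = "tomtom", stringsAsFactors = FALSE)
  attr(out, "n_kept") <- sum(keep)
  attr(out, "n_dropped") <- sum(!keep)
  message(sum(keep), " TOMTOM hit(s) kept, ", sum(!keep),
          " dropped at E<", e_max, ", p<", p_max)
  out
}

#' Read a BioGRID TAB interaction export
#'
#' Expects a tab-delimited file whose header includes the two official gene
#' symbol columns and `Experimental System Type`. Builds an
#' order-insensitive symbol-pair lookup mapping to evidence classes:
#' `physical` and `genetic` are kept as-is, any other system type maps to
#' `indirect`. Duplicate rows are collapsed; malformed rows are skipped
#' with a message naming their line numbers.
#'
#' @param path BioGRID TAB file.
#' @return an object of class `epi_biogrid` (a data.frame of unique
#'   pair/evidence combinations with a `key` column).
#' @export
read_biogrid <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  pick <- function(pat) grep(pat, names(df), value = TRUE)[1L]
  ca <- pick("Official Symbol.*A"); cb <- pick("Official Symbol.*B")
  ct <- pick("Experimental System Type")
  if (anyNA(c(ca, cb, ct)))
    stop("BioGRID file must contain the official symbol columns and ",
         "'Experimental System Type'")
  a <- toupper(trimws(df[[ca]])); b <- toupper(trimws(df[[cb]]))
  ty <- tolower(trimws(df[[ct]]))
  bad <- !nzchar(a) | !nzchar(b) | is.na(a) | is.na(b)
  if (any(bad))
    message("skipping ", sum(bad), " malformed BioGRID row(s) at line(s): ",
            paste(head(which(bad) + 1L, 10L), collapse = ", "))
  a <- a[!bad]; b <- b[!bad]; ty <- ty[!bad]
  ev <- ifelse(ty %in% c("physical", "genetic"), ty, "indirect")
  key <- paste(pmin(a, b), pmax(a, b), sep = "|")
  out <- unique(data.frame(key = key, evidence = ev, stringsAsFactors = FALSE))
  class(out) <- c("epi_biogrid", "data.frame")
  out
}

#' Evidence classes recorded for a TF pair
#'
#' @param biogrid an `epi_biogrid` lookup (or `NULL`).
#' @param tf_a,tf_b gene symbols (order-insensitive).
#' @return a character vector of evidence classes, or `"unvalidated"` when
#'   the pair is absent (or no lookup was supplied).
#' @export
biogrid_evidence <- function(biogrid, tf_a, tf_b) {
  if (is.null(biogrid)) return("unvalidated")
  key <- paste(pmin(toupper(tf_a), toupper(tf_b)),
               pmax(toupper(tf_a), toupper(tf_b)), sep = "|")
  hit <- biogrid$evidence[biogrid$key == key]
  if (!length(hit)) "unvalidated" else sort(unique(hit))
}

#' Assemble the TF-TF interaction table
#'
#' Joins the ranked region pairs of each cell line with that cell's
#' retained TOMTOM hits: a region pair contributes the interaction
#' `(TF_enhancer, TF_promoter)` when both of its regions have a retained
#' motif hit (the lowest-E-value hit names the region's TF). Interactions
#' are aggregated across cell lines into explicit cell sets and, when a
#' BioGRID lookup is supplied, annotated with evidence classes. Pairs with
#' an unmatched region are reported in a side list rather than dropped
#' silently.
#'
#' @param pairs_by_cell named list (cell line -> [top_region_pairs()]
#'   data.frame).
#' @param hits_by_cell named list (cell line -> [read_tomtom()] data.frame);
#'   `Query_ID`s must use the region naming `enh_r<i>` / `prom_r<j>`.
#' @param biogrid optional [read_biogrid()] lookup.
#' @return a list with `interactions` (data.frame `tf_enh, tf_prom, cells,
#'   n_cells, evidence`) and `unassigned` (data.frame `cell, enh_region,
#'   prom_region, missing`).
#' @export
build_interaction_table <- function(pairs_by_cell, hits_by_cell, biogrid = NULL) {
  cells <- names(pairs_by_cell)
  if (is.null(cells) || !all(cells %in% names(hits_by_cell)))
    stop("pairs_by_cell and hits_by_cell must be named by the same cell lines")
  found <- list()
  unassigned <- data.frame(cell = character(), enh_region = integer(),
                           prom_region = integer(), missing = character(),
                           stringsAsFactors = FALSE)
  for (cell in cells) {
    hits <- hits_by_cell[[cell]]
    best_tf <- function(qid) {
      h <- hits[hits$query == qid, , drop = FALSE]
      if (!nrow(h)) NA_character_ else h$target[which.min(h$evalue)]
    }
    prs <- pairs_by_cell[[cell]]
    for (i in seq_len(nrow(prs))) {
      tfe <- best_tf(sprintf("enh_r%d", prs$enh_region[i]))
      tfp <- best_tf(sprintf("prom_r%d", prs$prom_region[i]))
      if (is.na(tfe) || is.na(tfp)) {
        missing <- paste(c(if (is.na(tfe)) "enhancer", if (is.na(tfp)) "promoter"),
                         collapse = "+")
        unassigned <- rbind(unassigned, data.frame(
          cell = cell, enh_region = prs$enh_region[i],
          prom_region = prs$prom_region[i], missing = missing,
          stringsAsFactors = FALSE))
        next
      }
      key <- paste(tfe, tfp, sep = "\r")
      found[[key]] <- sort(unique(c(found[[key]], cell)))
    }
  }
  if (!length(found)) {
    interactions <- data.frame(tf_enh = character(), tf_prom = character(),
                               cells = character(), n_cells = integer(),
                               evidence = character(), stringsAsFactors = FALSE)
  } else {
    tf <- do.call(rbind, strsplit(names(found), "\r", fixed = TRUE))
    interactions <- data.frame(
      tf_enh = tf[, 1L], tf_prom = tf[, 2L],
      cells = vapply(found, paste, "", collapse = ","),
      n_cells = vapply(found, length, 1L),
      evidence = vapply(seq_len(nrow(tf)), function(i)
        paste(biogrid_evidence(biogrid, tf[i, 1L], tf[i, 2L]), collapse = ","), ""),
      stringsAsFactors = FALSE, row.names = NULL)
    interactions <- interactions[order(-interactions$n_cells,
                                       interactions$tf_enh, interactions$tf_prom), ]
    rownames(interactions) <- NULL
  }
  list(interactions = interactions, unassigned = unassigned)
}
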