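#' Read a species-labelled protein FASTA file
#'
#' One record per FASTA entry. The protein identifier is the first
#' whitespace-delimited token of the header; the remainder becomes the
#' description. Sequences are uppercased, whitespace is removed and
#' trailing stop characters (\code{*}) are stripped; an internal
#' \code{*} is an error. The species label is always supplied by the
#' caller — header dialects vary too much to parse it reliably, and the
#' species is the unit of disjointness for the whole workflow.
#'
#' @param path Path to a FASTA file (single- or multi-line sequences).
#' @param species Species label attached to every record.
#' @param onNonstandard \code{"error"} (default) or \code{"warn"} for
#'   residues outside the 20 standard amino acids and the ambiguity
#'   codes B, X, Z, U, O.
#' @return A [Proteome].
#' @examples
#' fa <- tempfile(fileext = ".faa")
#' writeLines(c(">p1 hypothetical", "MKRAAAK", ">p2", "SSSSSSSK"), fa)
#' readFasta(fa, species = "A")
#' @export
readFasta <- function(path, species, onNonstandard = c("error", "warn")) {
  onNonstandard <- match.arg(onNonstandard)
  if (!file.exists(path)) stop("no such file: ", path)
  seqs <- Biostrings::readAAStringSet(path)
  if (length(seqs) == 0L) stop("empty FASTA file: ", path)
  headers <- names(seqs)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers),
                 sub("^\\S+\\s+", "", headers), "")
  if (anyDuplicated(ids))
    stop("duplicate protein identifier(s) in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  s <- as.character(seqs)
  names(s) <- ids
  Proteome(species, s, descriptions = desc, onNonstandard = onNonstandard)
}

#' Write a Proteome to FASTA
#'
#' Sequences are wrapped at 60 columns. Records with empty sequences
#' (possible after trimming) are omitted from the file with a warning;
#' they remain visible in trim reports. Round trip with [readFasta()]
#' reproduces identifiers, descriptions, sequences and order.
#'
#' @param proteome A [Proteome].
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
writeFasta <- function(proteome, path) {
  stopifnot(is(proteome, "Proteome"))
  seqs <- proteome@sequences
  hdr <- ifelse(nzchar(proteome@descriptions),
                paste(names(seqs), proteome@descriptions), names(seqs))
  names(seqs) <- hdr
  keep <- Biostrings::width(seqs) > 0L
  if (!all(keep)) {
    warning(sum(!keep), " empty-sequence record(s) omitted from ", path)
    seqs <- seqs[keep]
  }
  if (length(seqs) == 0L) warning("writing FASTA with zero records: ", path)
  Biostrings::writeXStringSet(seqs, filepath = path, width = 60L)
  invisible(path)
}

#' Write a tabular report as TSV
#'
#' Tab-separated UTF-8 with a header line. Rows are written in a
#' deterministic order: sorted by \code{species}, then
#' \code{protein_id}, then \code{start}, for whichever of those columns
#' are present.
#'
#' @param rows A data.frame.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
writeTable <- function(rows, path) {
  stopifnot(is.data.frame(rows))
  keys <- intersect(c("species", "protein_id", "start"), names(rows))
  if (length(keys) && nrow(rows))
    rows <- rows[do.call(order, rows[keys]), , drop = FALSE]
  utils::write.table(rows, file = path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a wide protein-intensity table
#'
#' Expects a TSV whose first (or named) column holds protein
#' identifiers and whose remaining columns are samples. With
#' \code{lfqPrefix} set, only columns starting with that prefix are
#' used and the prefix is stripped from the sample names — this reads
#' the LFQ intensity block of a MaxQuant proteinGroups.txt directly.
#' Zeros are converted to missing values (a zero LFQ intensity is a
#' non-detection, not a measurement).
#'
#' @param path TSV path.
#' @param idColumn Column holding protein ids (default: first column).
#' @param lfqPrefix Optional sample-column prefix, e.g.
#'   \code{"LFQ intensity "}.
#' @param log2Transform Apply [logTransform()] to the values
#'   (default FALSE: the table is assumed to be on the scale you want).
#' @return Numeric matrix, rows = proteins, columns = samples.
#' @export
readIntensityTable <- function(path, idColumn = NULL, lfqPrefix = NULL,
                               log2Transform = FALSE) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (is.null(idColumn)) idColumn <- names(df)[1L]
  if (!idColumn %in% names(df)) stop("no column '", idColumn, "' in ", path)
  ids <- as.character(df[[idColumn]])
  if (is.null(lfqPrefix)) {
    cols <- setdiff(names(df), idColumn)
  } else {
    cols <- grep(paste0("^", lfqPrefix), names(df), value = TRUE)
    if (!length(cols)) stop("no columns with prefix '", lfqPrefix, "'")
  }
  m <- as.matrix(df[cols])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  if (!is.null(lfqPrefix))
    colnames(m) <- sub(paste0("^", lfqPrefix), "", cols)
  m[m == 0] <- NA_real_
  if (log2Transform) m <- logTransform(m) else m
}

#' Read a two-column sample design table
#'
#' @param path TSV with columns \code{sample_id} and \code{group}.
#' @return Named character vector mapping sample id to group.
#' @export
readDesign <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "group") %in% names(df)))
    stop("design table needs columns sample_id, group")
  if (anyDuplicated(df$sample_id)) stop("duplicate sample_id in design")
  stats::setNames(as.character(df$group), df$sample_id)
}

#' Read a protein-to-pathway annotation table
#'
#' @param path TSV with columns \code{protein_id}, \code{pathway_id}
#'   and optionally \code{pathway_name} (RAST subsystem export-like).
#' @return data.frame with those columns.
#' @export
readAnnotation <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("protein_id", "pathway_id") %in% names(df)))
    stop("annotation table needs columns protein_id, pathway_id")
  if (!"pathway_name" %in% names(df)) df$pathway_name <- df$pathway_id
  df[c("protein_id", "pathway_id", "pathway_name")]
}
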