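#' Read a spectrum from two-column text or CSV
#'
#' Reads one strain-replicate profile exported as plain text: two numeric
#' columns (m/z, intensity), whitespace- or comma-delimited, `#` comment
#' lines ignored.  Rows with non-numeric fields are dropped with a
#' warning.  The m/z axis must be strictly increasing -- a descending or
#' duplicated axis usually signals a corrupt export and is an error.
#'
#' @param path file to read.
#' @param format `"auto"` (default; sniffs a comma), `"text"` or `"csv"`.
#' @param label spectrum label; defaults to a `# label:` header comment
#'   when present, else the file name without extension.
#' @return a [Spectrum] at stage `"raw"`.
#' @seealso [writeSpectrum()]
#' @export
readSpectrum <- function(path, format = c("auto", "text", "csv"), label = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("spectrum file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  comments <- lines[grepl("^\\s*#", lines)]
  labelHdr <- sub("^\\s*#\\s*label:\\s*", "",
                  grep("^\\s*#\\s*label:", comments, value = TRUE))
  if (is.null(label) && length(labelHdr)) label <- labelHdr[1]
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (!length(lines)) stop("empty spectrum file: ", path)
  sep_comma <- if (format == "auto") grepl(",", lines[1], fixed = TRUE)
               else format == "csv"
  parts <- if (sep_comma) strsplit(lines, "\\s*,\\s*")
           else strsplit(trimws(lines), "\\s+")
  bad <- vapply(parts, function(p) length(p) < 2L ||
                  anyNA(suppressWarnings(as.numeric(p[1:2]))), logical(1))
  if (all(bad)) stop("no numeric (m/z, intensity) rows in ", path)
  if (any(bad))
    warning(sum(bad), " non-numeric row(s) rejected in ", path)
  parts <- parts[!bad]
  mz <- vapply(parts, function(p) as.numeric(p[1]), numeric(1))
  it <- vapply(parts, function(p) as.numeric(p[2]), numeric(1))
  if (any(diff(mz) <= 0)) stop("non-monotonic m/z in ", path)
  if (is.null(label))
    label <- sub("\\.[^.]*$", "", basename(path))
  Spectrum(label, mz, it, stage = "raw")
}

#' Write a spectrum as two-column text
#'
#' Values are serialized with enough digits to round-trip to at least six
#' significant figures; label and processing stage go into `#` header
#' comments along with any extra header lines supplied.
#'
#' @param spectrum a [Spectrum].
#' @param path output file.
#' @param headers optional character vector of extra `#` header lines
#'   (e.g. provenance from the synthetic generator).
#' @return `path`, invisibly.
#' @export
writeSpectrum <- function(spectrum, path, headers = character()) {
  stopifnot(is(spectrum, "Spectrum"))
  con <- file(path, "w")
  on.exit(close(con))
  hdr <- c(sprintf("# label: %s", spectrum@label),
           sprintf("# stage: %s", spectrum@stage),
           if (length(headers)) paste("#", headers))
  writeLines(hdr, con)
  writeLines(sprintf("%.10g %.10g", spectrum@mz, spectrum@intensity), con)
  invisible(path)
}

#' Read sequences from FASTA
#'
#' Thin wrapper over Biostrings readers that enforces unique, non-empty
#' records.  Nucleotide mode accepts aligned sequences containing gaps.
#'
#' @param path FASTA file.
#' @param alphabet `"protein"` or `"nucleotide"`.
#' @return an `AAStringSet` or `DNAStringSet`, in file order.
#' @export
readFastaSequences <- function(path, alphabet = c("protein", "nucleotide")) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  seqs <- if (alphabet == "protein") Biostrings::readAAStringSet(path)
          else Biostrings::readDNAStringSet(path)
  ids <- names(seqs)
  if (anyDuplicated(ids))
    stop("duplicate sequence ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  if (any(Biostrings::width(seqs) == 0L))
    stop("empty sequence(s): ",
         paste(ids[Biostrings::width(seqs) == 0L], collapse = ", "))
  seqs
}

#' Write/read a labelled similarity or peak matrix as CSV
#'
#' Matrices are written with row names in the first column so that the
#' clustering and Mantel functions can re-read them losslessly.
#'
#' @param m numeric matrix with dimnames (or a [SimilarityMatrix]).
#' @param path CSV file.
#' @return `writeMatrixCsv` returns `path` invisibly; `readMatrixCsv`
#'   returns a numeric matrix with dimnames.
#' @export
writeMatrixCsv <- function(m, path) {
  if (is(m, "SimilarityMatrix")) m <- as.matrix(m)
  utils::write.csv(as.data.frame(m), path, row.names = TRUE)
  invisible(path)
}

#' @rdname writeMatrixCsv
#' @export
readMatrixCsv <- function(path) {
  if (!file.exists(path)) stop("matrix file not found: ", path)
  df <- utils::read.csv(path, row.names = 1, check.names = FALSE)
  as.matrix(df)
}

#' Write a peak matrix (aligned or binary) as CSV
#'
#' Rows are consensus m/z positions, columns spectra.
#'
#' @param x an [AlignedPeakMatrix] or [BinaryPeakMatrix].
#' @param path CSV file.
#' @return `path`, invisibly.
#' @export
writePeakMatrixCsv <- function(x, path) {
  v <- if (is(x, "BinaryPeakMatrix")) peakPresence(x) else peakIntensities(x)
  df <- data.frame(mz = peakPositions(x), v, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Export a dendrogram as Newick
#'
#' Converts a [SpectralDendrogram] to `ape`'s `phylo` representation and
#' writes Newick with branch lengths.  A two-leaf tree merged at height
#' `h` serializes as `(A:h,B:h);`.
#'
#' @param tree a [SpectralDendrogram].
#' @param path output file; if missing the Newick string is returned.
#' @return the Newick string, invisibly when written to file.
#' @export
writeNewickTree <- function(tree, path) {
  ph <- ape::as.phylo(asHclust(tree))
  if (missing(path)) return(ape::write.tree(ph))
  ape::write.tree(ph, file = path)
  invisible(ape::write.tree(ph))
}
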