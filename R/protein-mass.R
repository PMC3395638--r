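#' Theoretical average molecular mass of a protein
#'
#' Sum of the standard average residue masses plus one water.  Vectorized
#' over sequences.
#'
#' @param sequence character vector of protein sequences over the
#'   20-letter alphabet (case-insensitive).
#' @return numeric vector of average masses in Da.
#' @export
#' @examples
#' averageMass("G")  # 75.0672
averageMass <- function(sequence) {
  res <- massConstants()$residues
  vapply(toupper(as.character(sequence)), function(s) {
    if (!nzchar(s)) stop("empty protein sequence")
    aa <- strsplit(s, "")[[1]]
    unknown <- setdiff(aa, names(res))
    if (length(unknown))
      stop("unknown residue letter(s): ", paste(unknown, collapse = ", "))
    sum(res[aa]) + massConstants()$water
  }, numeric(1), USE.NAMES = FALSE)
}

#' N-terminal methionine excision rule
#'
#' The initiator methionine is removed iff the second residue is one of
#' the seven small residues G, A, S, C, T, P, V (the canonical methionine
#' aminopeptidase specificity).  Sequences not starting with M are
#' returned unchanged.
#'
#' @param sequence character vector of protein sequences.
#' @param smallResidues the residue set triggering excision.
#' @return a `data.frame` with columns `input`, `sequence` (processed) and
#'   `met_loss` (logical).
#' @export
#' @examples
#' applyNTermRule(c("MGK", "MKG", "AGK"))$met_loss  # TRUE FALSE FALSE
applyNTermRule <- function(sequence,
                           smallResidues = massConstants()$metLossResidues) {
  sequence <- toupper(as.character(sequence))
  if (any(!nzchar(sequence))) stop("empty protein sequence")
  loss <- substr(sequence, 1, 1) == "M" &
    substr(sequence, 2, 2) %in% smallResidues
  data.frame(input = sequence,
             sequence = ifelse(loss, substr(sequence, 2, nchar(sequence)),
                               sequence),
             met_loss = loss, stringsAsFactors = FALSE)
}

#' Predict mature-protein average masses
#'
#' Applies the N-terminal Met-excision rule, then computes the
#' theoretical average mass of the processed (unmodified) chain.
#'
#' @param sequences named character vector or `Biostrings::AAStringSet`
#'   of protein sequences.
#' @return a `data.frame` with one row per input: `id`, `length`
#'   (residues, as translated), `second_residue`, `met_loss`,
#'   `theoretical_mass` (Da, after Met excision, unmodified).
#' @export
predictMasses <- function(sequences) {
  if (is(sequences, "AAStringSet")) {
    seqs <- as.character(sequences)
  } else {
    seqs <- as.character(sequences)
    names(seqs) <- names(sequences)
  }
  if (is.null(names(seqs)))
    names(seqs) <- sprintf("protein_%d", seq_along(seqs))
  rule <- applyNTermRule(seqs)
  data.frame(id = names(seqs),
             length = nchar(seqs),
             second_residue = substr(seqs, 2, 2),
             met_loss = rule$met_loss,
             theoretical_mass = averageMass(rule$sequence),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Annotate observed peaks with protein-mass hypotheses
#'
#' Pairs each observed peak with the hypothesis minimizing the absolute
#' mass error, where the hypothesis space is every protein's unmodified
#' theoretical mass plus (optionally) each modification delta.  A match
#' is reported only when the best |error| is within `tolerance`.  Errors
#' are signed (observed minus theoretical); for modified matches the
#' error is additionally reported against the unmodified mass
#' (`error_vs_unmodified`), the convention used when quoting, e.g., a
#' methylated subunit against its unmodified predicted mass.
#'
#' @param observed observed peak m/z values: a numeric vector or a
#'   [PeakList].
#' @param records `data.frame` of protein records with columns `id` and
#'   `theoretical_mass` (e.g. from [predictMasses()] or
#'   [am1RibosomalProteins()]); extra columns are carried through.
#' @param tolerance maximum |error| in Da (default 5).
#' @param modifications logical: include the modification hypotheses.
#' @param modificationDeltas named deltas in Da; user-extensible.
#'
#' @details When `records` carries a `known_modifications` column
#' (comma-separated hypothesis names, empty for none), each modification
#' hypothesis is restricted to the proteins annotated as carrying it --
#' the situation where modification states are known from homology, as
#' for the ribosomal proteins of the packaged reference set.  Without
#' that column every modification is tried on every protein (generic
#' screening), which can attribute a peak to a spurious modified
#' neighbour when an unmodified protein lies almost as close.
#' @return a list with `matches` (data.frame: `observed_mz`, `id`,
#'   `modification`, `hypothesis_mass`, `error`, `error_vs_unmodified`,
#'   plus carried record columns) and `unmatched` (numeric vector of
#'   unannotated peaks).
#' @export
annotatePeaks <- function(observed, records, tolerance = 5,
                          modifications = TRUE,
                          modificationDeltas = massConstants()$modifications) {
  if (is(observed, "PeakList")) observed <- mz(observed)
  observed <- as.numeric(observed)
  if (!is.data.frame(records) || !nrow(records))
    stop("records must be a non-empty data.frame")
  if (!all(c("id", "theoretical_mass") %in% names(records)))
    stop("records needs columns 'id' and 'theoretical_mass'")
  if (tolerance <= 0) stop("tolerance must be positive")

  deltas <- c(none = 0,
              if (modifications) modificationDeltas)
  hyp <- expand.grid(rec = seq_len(nrow(records)),
                     mod = seq_along(deltas))
  if (modifications && "known_modifications" %in% names(records)) {
    allowed <- strsplit(ifelse(is.na(records$known_modifications), "",
                               records$known_modifications), "\\s*,\\s*")
    ok <- vapply(seq_len(nrow(hyp)), function(i) {
      hyp$mod[i] == 1L ||
        names(deltas)[hyp$mod[i]] %in% allowed[[hyp$rec[i]]]
    }, logical(1))
    hyp <- hyp[ok, , drop = FALSE]
  }
  hyp$mass <- records$theoretical_mass[hyp$rec] + deltas[hyp$mod]

  extra <- setdiff(names(records), c("id", "theoretical_mass"))
  rows <- lapply(observed, function(omz) {
    err <- omz - hyp$mass
    best <- which.min(abs(err))
    if (abs(err[best]) > tolerance) return(NULL)
    rec <- hyp$rec[best]
    cbind(data.frame(observed_mz = omz,
                     id = records$id[rec],
                     modification = names(deltas)[hyp$mod[best]],
                     hypothesis_mass = hyp$mass[best],
                     error = err[best],
                     error_vs_unmodified = omz - records$theoretical_mass[rec],
                     stringsAsFactors = FALSE),
          records[rec, extra, drop = FALSE])
  })
  ok <- !vapply(rows, is.null, logical(1))
  matches <- if (any(ok)) do.call(rbind, rows[ok])
             else data.frame(observed_mz = numeric(0), id = character(0),
                             modification = character(0),
                             hypothesis_mass = numeric(0), error = numeric(0),
                             error_vs_unmodified = numeric(0))
  rownames(matches) <- NULL
  list(matches = matches, unmatched = observed[!ok])
}

#' Per-channel detection summary
#'
#' Counts the distinct proteins matched in each measurement channel (e.g.
#' whole-cell versus purified-ribosome spectra) and lists the proteins
#' whose theoretical mass lies inside the acquisition range but which
#' were not detected in a channel.
#'
#' @param annotations named list of [annotatePeaks()] results, one per
#'   channel.
#' @param records the protein record `data.frame` used for annotation.
#' @param range acquisition m/z range used for the in-range tally
#'   (default 2,000-20,000 Da).
#' @return a list with `summary` (data.frame: `channel`,
#'   `proteins_detected`), `detected` (named list of id vectors),
#'   `undetected_in_range` (named list of id vectors) and `n_in_range`.
#' @export
detectionReport <- function(annotations, records, range = c(2000, 20000)) {
  stopifnot(is.list(annotations), !is.null(names(annotations)))
  inRange <- records$id[records$theoretical_mass >= range[1] &
                        records$theoretical_mass <= range[2]]
  detected <- lapply(annotations, function(a) unique(a$matches$id))
  list(summary = data.frame(channel = names(annotations),
                            proteins_detected = vapply(detected, length,
                                                       integer(1)),
                            row.names = NULL, stringsAsFactors = FALSE),
       detected = detected,
       undetected_in_range = lapply(detected, function(d)
         setdiff(inRange, d)),
       n_in_range = length(inRange))
}

#' Shared theoretical masses across species
#'
#' Given per-species protein mass tables, reports masses (within a
#' tolerance) shared by more than one species -- the check that no single
#' ribosomal mass is a universal biomarker across a genus.
#'
#' @param massTables named list of numeric mass vectors, one per species.
#' @param tolerance masses closer than this are considered shared (Da).
#' @return a `data.frame` with `mass` (mean of the shared group) and
#'   `species` (comma-separated), one row per mass shared by >= 2 species.
#' @export
sharedMassReport <- function(massTables, tolerance = 0.005) {
  stopifnot(is.list(massTables), !is.null(names(massTables)))
  df <- data.frame(
    mass = unlist(massTables, use.names = FALSE),
    species = rep(names(massTables), lengths(massTables)))
  df <- df[order(df$mass), , drop = FALSE]
  grp <- cumsum(c(1, diff(df$mass) > tolerance))
  out <- lapply(split(df, grp), function(g) {
    sp <- unique(g$species)
    if (length(sp) < 2L) return(NULL)
    data.frame(mass = mean(g$mass), species = paste(sort(sp), collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(out)) out <- data.frame(mass = numeric(0), species = character(0))
  rownames(out) <- NULL
  out
}

#' Ribosomal protein reference table for M. extorquens AM1
#'
#' The packaged machine-readable reference set of the 54 ribosomal
#' subunit proteins annotated in the Methylobacterium extorquens AM1
#' genome: locus tag, gene, subunit, chain length, second residue,
#' reported Met-loss status, theoretical average molecular mass, and the
#' observed MALDI-TOF m/z (with reported signed errors) in the whole-cell
#' and purified-ribosome channels, plus modification remarks.
#'
#' @return a `data.frame` with 54 rows; observed columns contain `NA`
#'   where a protein was not detected in that channel.  The `id` column
#'   duplicates `locus_tag` for use with [annotatePeaks()], and
#'   `known_modifications` encodes the homology-documented modification
#'   state of each subunit (methylated L33, beta-methylthiolated S12,
#'   acetylated S18) so annotation only entertains those hypotheses.
#' @export
am1RibosomalProteins <- function() {
  path <- system.file("extdata", "am1_ribosomal_proteins.csv",
                      package = "wcms", mustWork = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$id <- as.character(df$locus_tag)
  df$known_modifications <- ""
  df$known_modifications[df$subunit == "L33"] <- "methylation"
  df$known_modifications[df$subunit == "S12"] <- "beta_methylthiolation"
  df$known_modifications[df$subunit == "S18"] <- "acetylation"
  df
}
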