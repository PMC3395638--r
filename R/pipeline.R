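#' Assemble and validate a pipeline run configuration
#'
#' Collects every stage's parameters into one validated list that
#' [runPipeline()] consumes and serializes (with an MD5 hash) alongside
#' its outputs.
#'
#' @param input input spectra: a directory (scanned for `.txt`/`.tsv`/
#'   `.dat` two-column exports), a character vector of files, or a named
#'   list of [Spectrum] objects.
#' @param outdir output directory.
#' @param groups optional named list mapping strain names to the spectrum
#'   labels that are replicates of that strain; replicates are averaged
#'   into one spectrum per strain before peak picking.  Default: every
#'   spectrum is its own strain.
#' @param preprocess a [preprocessConfig()].
#' @param minRelIntensity,minProminence peak-picking thresholds (percent).
#' @param maxShift peak-matching radius, Da.
#' @param threshold,window binarization threshold (percent, strict) and
#'   m/z window (Da).
#' @param libraryLabels optional strain labels forming the reference
#'   library; remaining strains are treated as identification queries.
#' @param noveltyThreshold similarity cut for candidate-novel calls.
#' @param compareMatrix optional path to (or matrix of) an external
#'   similarity matrix, e.g. 16S identities, for a Mantel test.
#' @param mantelPermutations,seed Mantel permutation count and seed.
#' @return a validated list of class `RunConfig`.
#' @export
runConfig <- function(input, outdir = "wcms_out", groups = NULL,
                      preprocess = preprocessConfig(),
                      minRelIntensity = 1, minProminence = 1,
                      maxShift = 20, threshold = 5, window = c(3500, 20000),
                      libraryLabels = NULL, noveltyThreshold = 0.5,
                      compareMatrix = NULL, mantelPermutations = 9999,
                      seed = NULL) {
  if (missing(input)) stop("input is required")
  if (!inherits(preprocess, "PreprocessConfig"))
    stop("preprocess must be a preprocessConfig()")
  if (threshold < 0 || maxShift <= 0 || length(window) != 2L ||
      window[1] >= window[2])
    stop("invalid peak-matrix parameters")
  structure(list(input = input, outdir = outdir, groups = groups,
                 preprocess = preprocess,
                 minRelIntensity = minRelIntensity,
                 minProminence = minProminence, maxShift = maxShift,
                 threshold = threshold, window = window,
                 libraryLabels = libraryLabels,
                 noveltyThreshold = noveltyThreshold,
                 compareMatrix = compareMatrix,
                 mantelPermutations = mantelPermutations, seed = seed),
            class = "RunConfig")
}

.loadInputSpectra <- function(input) {
  if (is.list(input) && all(vapply(input, is, logical(1), "Spectrum")))
    return(input)
  ## a directory is scanned for .txt/.tsv/.dat spectrum exports only, so
  ## companion tables (truth.csv etc.) are not mistaken for spectra; CSV
  ## spectra can still be passed as an explicit file vector
  files <- if (length(input) == 1L && dir.exists(input))
    list.files(input, pattern = "\\.(txt|tsv|dat)$", full.names = TRUE)
  else as.character(input)
  if (!length(files)) stop("no input spectra found")
  for (f in files)
    if (!file.exists(f)) stop("missing input file: ", f)
  sp <- lapply(files, readSpectrum)
  names(sp) <- vapply(sp, spectrumLabels, character(1))
  sp
}

#' Run the whole-cell fingerprinting pipeline
#'
#' Chains the stages end to end: preprocessing of every replicate,
#' optional per-strain averaging, peak picking, cross-spectrum matching,
#' binarization, binary-Pearson proximity, UPGMA dendrogram, and -- when
#' configured -- novelty calls against a reference library and a Mantel
#' test against an external similarity matrix.  Every stage's output is
#' persisted under `outdir` (similarity CSV, Newick tree, aligned and
#' binary peak matrices, novelty JSON lines) together with the serialized
#' configuration and its MD5 hash; re-running the same configuration and
#' seed reproduces the outputs byte for byte.  Any stage failure aborts
#' with the stage name in the error.
#'
#' @param config a [runConfig()].
#' @return invisibly, a list with the in-memory artifacts: `spectra`,
#'   `peakLists`, `aligned`, `binary`, `similarity`, `tree`, `novelty`,
#'   `mantel`, and `files` (paths written).
#' @export
runPipeline <- function(config) {
  if (!inherits(config, "RunConfig")) stop("config must be a runConfig()")
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "': ", conditionMessage(e), call. = FALSE))
  }
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)

  spectra <- stage("input", .loadInputSpectra(config$input))
  rel <- stage("preprocess",
               lapply(spectra, preprocessSpectrum, config = config$preprocess))

  strains <- if (!is.null(config$groups)) {
    stage("average", {
      out <- lapply(names(config$groups), function(g) {
        members <- rel[config$groups[[g]]]
        if (any(vapply(members, is.null, logical(1))))
          stop("group '", g, "' names unknown spectra")
        toRelative(averageSpectra(members, label = g))
      })
      names(out) <- names(config$groups)
      out
    })
  } else rel

  peakLists <- stage("peaks",
                     lapply(strains, pickPeaks,
                            minRelIntensity = config$minRelIntensity,
                            minProminence = config$minProminence))
  aligned <- stage("align", alignPeaks(unname(peakLists),
                                       maxShift = config$maxShift))
  binary <- stage("binarize", binarizePeaks(aligned,
                                            threshold = config$threshold,
                                            window = config$window))
  similarity <- stage("proximity", proximityMatrix(binary))
  tree <- stage("cluster", upgmaTree(similarity))

  novelty <- NULL
  if (!is.null(config$libraryLabels)) {
    novelty <- stage("identify", {
      queries <- setdiff(spectrumLabels(binary), config$libraryLabels)
      callNovelty(binary, queries, config$libraryLabels,
                  threshold = config$noveltyThreshold)
    })
  }

  mantel <- NULL
  if (!is.null(config$compareMatrix)) {
    mantel <- stage("mantel", {
      other <- if (is.character(config$compareMatrix))
        readMatrixCsv(config$compareMatrix) else as.matrix(config$compareMatrix)
      labs <- spectrumLabels(similarity)
      mantelTest(as.matrix(similarity), other[labs, labs],
                 nPermutations = config$mantelPermutations,
                 seed = config$seed)
    })
  }

  files <- stage("write", {
    cfgPath <- file.path(config$outdir, "run_config.json")
    cfg <- config
    cfg$input <- if (is.character(config$input)) config$input else "<in-memory>"
    cfg$compareMatrix <- if (is.character(config$compareMatrix))
      config$compareMatrix else if (is.null(config$compareMatrix)) NULL
      else "<in-memory>"
    jsonlite::write_json(cfg, cfgPath, auto_unbox = TRUE, digits = NA,
                         force = TRUE, pretty = TRUE)
    hash <- unname(tools::md5sum(cfgPath))
    writeLines(hash, file.path(config$outdir, "run_config.md5"))
    out <- c(config = cfgPath,
             similarity = writeMatrixCsv(similarity,
               file.path(config$outdir, "similarity.csv")),
             tree = {
               p <- file.path(config$outdir, "dendrogram.nwk")
               writeNewickTree(tree, p); p
             },
             aligned = writePeakMatrixCsv(aligned,
               file.path(config$outdir, "aligned_peaks.csv")),
             binary = writePeakMatrixCsv(binary,
               file.path(config$outdir, "binary_peaks.csv")))
    if (!is.null(novelty)) {
      p <- file.path(config$outdir, "novelty.jsonl")
      writeLines(vapply(seq_len(nrow(novelty)), function(i)
        jsonlite::toJSON(c(as.list(novelty[i, ]), config_md5 = hash),
                         auto_unbox = TRUE, digits = NA),
        character(1)), p)
      out <- c(out, novelty = p)
    }
    if (!is.null(mantel)) {
      p <- file.path(config$outdir, "mantel.json")
      jsonlite::write_json(list(r = mantel@statistic, p_value = mantel@pValue,
                                n_permutations = mantel@nPermutations,
                                seed = mantel@seed, config_md5 = hash),
                           p, auto_unbox = TRUE, digits = NA)
      out <- c(out, mantel = p)
    }
    out
  })

  invisible(list(spectra = rel, strains = strains, peakLists = peakLists,
                 aligned = aligned, binary = binary, similarity = similarity,
                 tree = tree, novelty = novelty, mantel = mantel,
                 files = files))
}
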