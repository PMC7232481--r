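## Delimited-text input/output for the streams the analysis consumes.

# Comma/tab auto-detection on the header line.
.readDelim <- function(path) {
  header <- readLines(path, n = 1)
  sep <- if (lengths(regmatches(header, gregexpr("\t", header))) > 0) "\t" else ","
  utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                    stringsAsFactors = FALSE)
}

#' Read a gas time series from delimited text
#'
#' One record per sample; comma- or tab-delimited with a header. Column
#' names can be remapped through `columns`; the time column may hold
#' minutes since start or ISO-8601 timestamps (converted to minutes from
#' the first stamp).
#'
#' @param path file path.
#' @param columns named list mapping the slots `time`, `flow`,
#'   `ch4Fraction`, `temperature`, `pressure`, `waterSaturated` to column
#'   names in the file; entries absent from the file fall back to the
#'   defaults of [gasTimeSeries()].
#' @return a [GasTimeSeries-class].
#' @export
readGasSeries <- function(path, columns = list()) {
  defaults <- list(time = "time", flow = "flow", ch4Fraction = "ch4Fraction",
                   temperature = "temperature", pressure = "pressure",
                   waterSaturated = "waterSaturated")
  columns <- utils::modifyList(defaults, columns)
  d <- .readDelim(path)
  if (!columns$time %in% names(d) || !columns$flow %in% names(d))
    stop("missing required column(s): ", columns$time, " / ", columns$flow)
  tm <- d[[columns$time]]
  if (is.character(tm)) {
    stamps <- as.POSIXct(tm, tz = "UTC",
                         tryFormats = c("%Y-%m-%dT%H:%M:%OS",
                                        "%Y-%m-%d %H:%M:%OS"))
    if (anyNA(stamps)) stop("unparseable ISO-8601 timestamps in '", columns$time, "'")
    tm <- as.numeric(difftime(stamps, stamps[1], units = "mins"))
  }
  pick <- function(nm, default) if (columns[[nm]] %in% names(d)) d[[columns[[nm]]]] else default
  gasTimeSeries(tm, d[[columns$flow]],
                pick("ch4Fraction", 0), pick("temperature", 0),
                pick("pressure", 1013.25), pick("waterSaturated", FALSE))
}

#' Write a gas time series as delimited text
#'
#' @param gts a [GasTimeSeries-class].
#' @param path output path (tab-delimited).
#' @export
writeGasSeries <- function(gts, path) {
  utils::write.table(as.data.frame(gts), path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read an ASV count table from delimited text
#'
#' Accepts taxa x samples or samples x taxa orientation (auto-detected from
#' the header: a `taxonomy` column marks taxa rows). Taxonomy is a
#' semicolon-delimited rank string. Sample metadata (`reactor`, `day`) is
#' parsed from sample ids of the form `<reactor>_d<day>` when no metadata
#' file is given.
#'
#' @param path count table path.
#' @param metadata optional path of a delimited metadata table with columns
#'   `sample`, `reactor`, `day`.
#' @return an [ASVExperiment-class].
#' @export
readAsvTable <- function(path, metadata = NULL) {
  d <- .readDelim(path)
  if (!"taxonomy" %in% names(d))
    stop("expected a 'taxonomy' column in the ASV table")
  idCol <- names(d)[1]
  tax <- d$taxonomy
  counts <- as.matrix(d[, setdiff(names(d), c(idCol, "taxonomy")), drop = FALSE])
  rownames(counts) <- d[[idCol]]
  meta <- if (!is.null(metadata)) {
    m <- .readDelim(metadata)
    rownames(m) <- m$sample
    m[colnames(counts), , drop = FALSE]
  } else {
    ids <- colnames(counts)
    parsed <- regmatches(ids, regexec("^(.*)_d([0-9]+)$", ids))
    data.frame(
      sample = ids,
      reactor = vapply(parsed, function(p) if (length(p) == 3) p[2] else NA_character_, character(1)),
      day = vapply(parsed, function(p) if (length(p) == 3) as.numeric(p[3]) else NA_real_, numeric(1))
    )
  }
  asvExperiment(counts, taxonomy = tax, metadata = meta)
}

#' Write an ASV table as delimited text
#'
#' @param x an [ASVExperiment-class].
#' @param path output path (tab-delimited; taxa rows, `taxonomy` column,
#'   one count column per sample).
#' @export
writeAsvTable <- function(x, path) {
  counts <- SummarizedExperiment::assay(x, "counts")
  rd <- as.data.frame(SummarizedExperiment::rowData(x))
  tax <- apply(rd, 1, paste, collapse = ";")
  out <- data.frame(asv = rownames(counts), taxonomy = tax,
                    as.data.frame(counts, check.names = FALSE),
                    check.names = FALSE)
  utils::write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a simulation bundle as delimited text files
#'
#' Emits, under `dir`: one gas series per reactor
#' (`gas_<reactor>.tsv`), `vfa.tsv`, `ph.tsv`, `te_<reactor>.tsv` (day and
#' one nM column per element), `asv_bacteria.tsv`, `asv_archaea.tsv`,
#' `events.tsv` and `ledger.tsv` — the same formats the analysis readers
#' consume.
#'
#' @param bundle a [SimBundle-class].
#' @param dir output directory (created when missing).
#' @return `dir`, invisibly.
#' @export
writeBundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(d, f)
    utils::write.table(d, file.path(dir, f), sep = "\t", row.names = FALSE,
                       quote = FALSE)
  for (r in names(bundle@gas))
    writeGasSeries(bundle@gas[[r]], file.path(dir, paste0("gas_", r, ".tsv")))
  wt(bundle@vfa, "vfa.tsv")
  wt(bundle@ph, "ph.tsv")
  for (r in names(bundle@te)) {
    ser <- lapply(bundle@te[[r]], function(s) s@series$nM)
    d <- data.frame(day = bundle@te[[r]][[1]]@series$day, ser)
    wt(d, paste0("te_", r, ".tsv"))
  }
  writeAsvTable(bundle@asv, file.path(dir, "asv_bacteria.tsv"))
  writeAsvTable(bundle@asvArchaea, file.path(dir, "asv_archaea.tsv"))
  wt(bundle@events, "events.tsv")
  wt(codLedger(bundle), "ledger.tsv")
  invisible(dir)
}
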