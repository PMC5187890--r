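#' Write and read trace CSV files with JSON metadata sidecars
#'
#' Traces travel as two-column CSV (`time_s`, `value`) plus a `<path>.json`
#' sidecar holding instrument settings, condition labels and any generative
#' ground truth, so that synthetic datasets remain self-describing on disk.
#'
#' @param trace a [ShrinkageTrace-class] or [DecayTrace-class].
#' @param path CSV file path; the sidecar is written next to it.
#' @return `writeTraceCsv` returns `path` invisibly; `readTraceCsv` returns
#'   an object of the class recorded in the sidecar.
#' @export
writeTraceCsv <- function(trace, path) {
  if (is(trace, "ShrinkageTrace")) {
    df <- data.frame(time_s = trace@times, value = trace@fluorescence)
    meta <- list(class = "ShrinkageTrace",
                 instrument = list(deadTime = trace@instrument@deadTime,
                                   duration = trace@instrument@duration,
                                   sampleRate = trace@instrument@sampleRate,
                                   noiseSd = trace@instrument@noiseSd,
                                   fluorOffset = trace@instrument@fluorOffset,
                                   fluorGain = trace@instrument@fluorGain,
                                   seed = trace@instrument@seed),
                 temperature = trace@temperature,
                 condition = trace@condition,
                 groundTruth = trace@groundTruth)
  } else if (is(trace, "DecayTrace")) {
    df <- data.frame(time_s = trace@times, value = trace@values)
    meta <- list(class = "DecayTrace", mode = trace@mode,
                 C0Nominal = trace@C0Nominal, condition = trace@condition,
                 groundTruth = trace@groundTruth,
                 nClipped = trace@nClipped)
  } else stop("unsupported trace class")
  utils::write.csv(df, path, row.names = FALSE)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname writeTraceCsv
#' @export
readTraceCsv <- function(path) {
  df <- utils::read.csv(path)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  gt <- as.list(meta$groundTruth %||% list())
  cond <- as.list(meta$condition %||% list())
  if (identical(meta$class, "ShrinkageTrace")) {
    ins <- meta$instrument
    new("ShrinkageTrace", times = df$time_s, fluorescence = df$value,
        instrument = instrumentSpec(ins$deadTime, ins$duration,
                                    ins$sampleRate, ins$noiseSd,
                                    ins$fluorOffset, ins$fluorGain,
                                    ins$seed),
        temperature = meta$temperature, condition = cond,
        groundTruth = gt)
  } else if (identical(meta$class, "DecayTrace")) {
    new("DecayTrace", times = df$time_s, values = df$value,
        mode = meta$mode, C0Nominal = meta$C0Nominal, condition = cond,
        groundTruth = gt, nClipped = as.integer(meta$nClipped %||% 0L))
  } else stop("sidecar does not describe a known trace class")
}

#' Write and read tidy plate tables
#'
#' The plate interchange format: columns `well`, `role` (`standard`,
#' `unknown` or `blank`), `concentration`, `reading`.
#'
#' @param plate a plate data.frame.
#' @param path CSV file path.
#' @return `writePlateCsv` returns `path` invisibly; `readPlateCsv` the
#'   data.frame.
#' @export
writePlateCsv <- function(plate, path) {
  utils::write.csv(plate, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writePlateCsv
#' @export
readPlateCsv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
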