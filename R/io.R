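## Plain-text I/O: progress curves, TA maps and structured config blocks.
## Delimited text is deliberate: datasets are small (<= 1e5 points) and
## human-diffable fixtures matter more than speed.

#' Read a rate set from a YAML config file
#'
#' Rate sets are named blocks whose fields are the [MicroRates-class] labels.
#'
#' @param path Path to the YAML file.
#' @param name Name of the block to read; with `name = NULL` the names of all
#'   available blocks are returned.
#' @return A [MicroRates-class] object, or a character vector of block names.
#' @export
readRateSet <- function(path, name = NULL) {
  cfg <- yaml::read_yaml(path)
  if (is.null(name)) return(names(cfg))
  if (!name %in% names(cfg))
    stop("unknown rate set '", name, "'; available: ",
         paste(names(cfg), collapse = ", "), call. = FALSE)
  do.call(MicroRates, lapply(cfg[[name]], as.numeric))
}

#' Read a proton-linkage cycle from a YAML config file
#'
#' Cycle blocks have fields `pka_open`, `pka_closed` and `K_D`.
#'
#' @param path Path to the YAML file; defaults to the shipped cycle table.
#' @param name Block name; with `name = NULL` the available names are
#'   returned.
#' @return A [CycleParameters-class] object, or a character vector of names.
#' @examples
#' readCycleSet(name = "NP4")
#' @export
readCycleSet <- function(path = system.file("extdata", "cycles.yaml",
                                            package = "nprebind"),
                         name = NULL) {
  cfg <- yaml::read_yaml(path)
  if (is.null(name)) return(names(cfg))
  if (!name %in% names(cfg))
    stop("unknown cycle '", name, "'; available: ",
         paste(names(cfg), collapse = ", "), call. = FALSE)
  b <- cfg[[name]]
  CycleParameters(b$pka_open, b$pka_closed, b$K_D)
}

#' Read and write rebinding progress curves
#'
#' Curves are tab-delimited text with a header and columns `time_s`,
#' `n_unliganded` and optionally `sigma`. Reading enforces numeric cells and
#' strictly increasing times; errors report the offending line.
#'
#' @param path File path.
#' @param curve A [ProgressCurve-class] (for writing).
#' @return `readCurve` returns a [ProgressCurve-class]; `writeCurve`
#'   invisibly returns `path`.
#' @export
readCurve <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 2L)
    stop("curve file '", path, "': need a header and at least one row",
         call. = FALSE)
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  if (length(header) < 2L || header[1] != "time_s")
    stop("curve file '", path, "', line 1: expected header starting ",
         "'time_s<TAB>n_unliganded'", call. = FALSE)
  body <- strsplit(lines[-1], "\t", fixed = TRUE)
  n <- length(header)
  vals <- matrix(NA_real_, length(body), n)
  for (i in seq_along(body)) {
    if (length(body[[i]]) != n)
      stop("curve file '", path, "', line ", i + 1L, ": expected ", n,
           " fields, found ", length(body[[i]]), call. = FALSE)
    v <- suppressWarnings(as.numeric(body[[i]]))
    if (any(is.na(v)))
      stop("curve file '", path, "', line ", i + 1L, ": non-numeric cell",
           call. = FALSE)
    vals[i, ] <- v
  }
  if (any(diff(vals[, 1]) <= 0)) {
    bad <- which(diff(vals[, 1]) <= 0)[1] + 2L
    stop("curve file '", path, "', line ", bad,
         ": times must be strictly increasing", call. = FALSE)
  }
  sigma <- if ("sigma" %in% header) vals[, match("sigma", header)]
           else numeric(0)
  ProgressCurve(vals[, 1], vals[, 2], sigma)
}

#' @rdname readCurve
#' @export
writeCurve <- function(curve, path) {
  methods::validObject(curve)
  hasSigma <- length(curve@sigma) > 0
  header <- c("time_s", "n_unliganded", if (hasSigma) "sigma")
  m <- cbind(curve@times, curve@fraction,
             if (hasSigma) curve@sigma)
  rows <- apply(m, 1L, function(r)
    paste(formatC(r, format = "g", digits = 17), collapse = "\t"))
  writeLines(c(paste(header, collapse = "\t"), rows), path)
  invisible(path)
}

#' Read and write transient-absorption maps
#'
#' Maps are tab-delimited matrices: the first row holds the delays (s) with
#' an empty leading cell, the first column the wavelengths (nm), the body the
#' differential absorbance. Ragged rows are a parse error; single-delay maps
#' are accepted for spectra-only workflows.
#'
#' @param path File path.
#' @param map A [TAMap-class] (for writing).
#' @return `readMap` returns a [TAMap-class]; `writeMap` invisibly returns
#'   `path`.
#' @export
readMap <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 2L)
    stop("map file '", path, "': need a delay row and at least one ",
         "wavelength row", call. = FALSE)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  n <- length(parts[[1]])
  delays <- suppressWarnings(as.numeric(parts[[1]][-1]))
  if (any(is.na(delays)))
    stop("map file '", path, "', line 1: non-numeric delay", call. = FALSE)
  wl <- numeric(length(lines) - 1L)
  dA <- matrix(NA_real_, length(lines) - 1L, n - 1L)
  for (i in seq_along(wl)) {
    row <- parts[[i + 1L]]
    if (length(row) != n)
      stop("map file '", path, "', line ", i + 1L, ": ragged row (", n,
           " fields expected, ", length(row), " found)", call. = FALSE)
    v <- suppressWarnings(as.numeric(row))
    if (any(is.na(v)))
      stop("map file '", path, "', line ", i + 1L, ": non-numeric cell",
           call. = FALSE)
    wl[i] <- v[1]
    dA[i, ] <- v[-1]
  }
  TAMap(wl, delays, dA)
}

#' @rdname readMap
#' @export
writeMap <- function(map, path) {
  methods::validObject(map)
  fmt <- function(x) formatC(x, format = "g", digits = 17)
  head <- paste(c("", fmt(map@delays)), collapse = "\t")
  rows <- vapply(seq_along(map@wavelengths), function(i)
    paste(c(fmt(map@wavelengths[i]), fmt(map@deltaA[i, ])), collapse = "\t"),
    character(1))
  writeLines(c(head, rows), path)
  invisible(path)
}
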