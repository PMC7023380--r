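# Plain-text spectrum interchange.
#
# Native dialect: comment header lines "# key=value" carrying the acquisition
# parameters and label, followed by two whitespace-separated columns
# (ppm, intensity), descending ppm. A minimal JCAMP-DX-style reader (AFFN
# XYDATA tables) is provided read-only.

.ACQ_KEYS <- c("td", "sw_hz", "sw_ppm", "sfo_mhz", "ns", "ds", "d1_s", "aq_s",
               "si", "rg", "temp_k", "lb_hz")

#' Write a spectrum to the tabular text dialect
#'
#' @param spectrum a real [NMRSpectrum-class]
#' @param path output file
#' @return `path`, invisibly
#' @export
writeSpectrum <- function(spectrum, path) {
  if (is.complex(spectrum@intensities))
    stop("only real (phased) spectra are written", call. = FALSE)
  p <- spectrum@params
  hdr <- c(
    sprintf("# %s=%s", .ACQ_KEYS,
            vapply(.ACQ_KEYS, function(k) format(slot(p, k), digits = 17),
                   character(1))),
    sprintf("# device=%s", p@device),
    sprintf("# label=%s", if (length(spectrum@label)) spectrum@label else "")
  )
  body <- paste(format(spectrum@ppm, digits = 17, trim = TRUE, scientific = TRUE),
                format(spectrum@intensities, digits = 17, trim = TRUE,
                       scientific = TRUE))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a spectrum from text
#'
#' Supports the package's tabular dialect (written by [writeSpectrum()]) and
#' minimal JCAMP-DX-style files (`##XYDATA=(X++(Y..Y))`, AFFN fixed-point
#' tables). Format `"auto"` sniffs the first non-blank line.
#'
#' @param path input file
#' @param format `"auto"`, `"tsv"` or `"jcamp"`
#' @return an [NMRSpectrum-class]
#' @export
readSpectrum <- function(path, format = c("auto", "tsv", "jcamp")) {
  format <- match.arg(format)
  lines <- readLines(path, warn = FALSE)
  if (format == "auto") {
    first <- lines[nzchar(trimws(lines))][1]
    format <- if (!is.na(first) && startsWith(trimws(first), "##")) "jcamp" else "tsv"
  }
  if (format == "jcamp") .readJcamp(lines, path) else .readTabular(lines, path)
}

.readTabular <- function(lines, path) {
  is_hdr <- startsWith(lines, "#")
  kv <- list()
  for (h in lines[is_hdr]) {
    m <- regmatches(h, regexec("^#\\s*([A-Za-z0-9_]+)=(.*)$", h))[[1]]
    if (length(m) == 3) kv[[m[2]]] <- m[3]
  }
  body <- lines[!is_hdr & nzchar(trimws(lines))]
  if (!length(body))
    stop(sprintf("%s: no data lines", path), call. = FALSE)
  parts <- strsplit(trimws(body), "\\s+")
  nf <- lengths(parts)
  if (any(nf != 2)) {
    bad <- which(nf != 2)[1]
    stop(sprintf("%s: line %d has %d fields, expected 2 (ppm intensity)",
                 path, which(!is_hdr & nzchar(trimws(lines)))[bad], nf[bad]),
         call. = FALSE)
  }
  mat <- matrix(as.numeric(unlist(parts)), ncol = 2, byrow = TRUE)
  if (anyNA(mat))
    stop(sprintf("%s: non-numeric data value", path), call. = FALSE)
  args <- lapply(kv[intersect(.ACQ_KEYS, names(kv))], as.numeric)
  names(args) <- sub("^sfo_mhz$", "sfo_mhz", names(args))
  params <- do.call(acquisitionParameters,
                    c(args, list(device = kv[["device"]] %||% "unknown")))
  new("NMRSpectrum", intensities = mat[, 2], ppm = mat[, 1], params = params,
      label = kv[["label"]] %||% "", meta = list(source = path))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.readJcamp <- function(lines, path) {
  getld <- function(key) {
    hit <- grep(sprintf("^##%s=", key), lines, value = TRUE)
    if (!length(hit)) return(NULL)
    trimws(sub(sprintf("^##%s=", key), "", hit[1]))
  }
  npoints <- as.numeric(getld("NPOINTS"))
  firstx <- as.numeric(getld("FIRSTX"))
  lastx <- as.numeric(getld("LASTX"))
  xfactor <- as.numeric(getld("XFACTOR") %||% "1")
  yfactor <- as.numeric(getld("YFACTOR") %||% "1")
  start <- grep("^##XYDATA=", lines)
  if (!length(start))
    stop(sprintf("%s: no ##XYDATA block", path), call. = FALSE)
  if (is.na(npoints) || !length(npoints))
    stop(sprintf("%s: missing ##NPOINTS", path), call. = FALSE)
  stopi <- grep("^##END", lines)
  stopi <- if (length(stopi)) min(stopi[stopi > start[1]]) else length(lines) + 1
  tab <- lines[(start[1] + 1):(stopi - 1)]
  tab <- tab[nzchar(trimws(tab))]
  ys <- numeric(0)
  for (i in seq_along(tab)) {
    f <- as.numeric(strsplit(trimws(tab[i]), "[[:space:]]+")[[1]])
    if (anyNA(f) || length(f) < 2)
      stop(sprintf("%s: malformed XYDATA line %d", path,
                   start[1] + i), call. = FALSE)
    ys <- c(ys, f[-1])
  }
  if (length(ys) != npoints)
    stop(sprintf("%s: NPOINTS=%d but %d intensities found", path,
                 npoints, length(ys)), call. = FALSE)
  x <- seq(firstx, lastx, length.out = npoints) * xfactor
  y <- ys * yfactor
  if (x[1] < x[npoints]) { x <- rev(x); y <- rev(y) }
  sw_ppm <- abs(firstx - lastx) * xfactor
  params <- acquisitionParameters(td = 2 * npoints, sw_hz = sw_ppm * 400,
                                  sw_ppm = sw_ppm, si = npoints,
                                  device = "jcamp")
  new("NMRSpectrum", intensities = y, ppm = x, params = params,
      label = getld("TITLE") %||% "", meta = list(source = path))
}
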