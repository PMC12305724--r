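#' Read spectra from delimited text or JCAMP-DX
#'
#' The delimited layout is wide: first column the wavenumber grid (cm^-1,
#' ascending), one column per replicate scan with header `sample.rep`
#' (e.g. `S001.1`). JCAMP-DX files (one spectrum per file) are parsed from
#' either `##XYDATA=(X++(Y..Y))` tables — with the grid reconstructed from
#' `FIRSTX`/`DELTAX`/`NPOINTS` when per-line abscissae are compressed — or
#' `##XYPOINTS=(XY..XY)` pair tables.
#'
#' @param path File path.
#' @param format `"auto"` (by extension: `.dx`/`.jdx` is JCAMP), `"csv"` or
#'   `"jcamp"`.
#' @return A `spectra_set`.
#' @export
read_spectra <- function(path, format = c("auto", "csv", "jcamp")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (tolower(tools::file_ext(path)) %in% c("dx", "jdx"))
      "jcamp" else "csv"
  }
  if (format == "jcamp") return(read_jcampdx(path))
  df <- read.csv(path, check.names = FALSE)
  grid <- df[[1]]
  if (is.unsorted(grid, strictly = TRUE)) {
    stop("wavenumber grid must be strictly increasing", call. = FALSE)
  }
  A <- t(as.matrix(df[, -1, drop = FALSE]))
  if (anyNA(A)) stop("ragged or non-numeric spectra columns", call. = FALSE)
  ids <- rownames(A)
  sample_id <- sub("\\.[^.]*$", "", ids)
  replicate <- suppressWarnings(as.integer(sub("^.*\\.", "", ids)))
  replicate[is.na(replicate)] <- 1L
  structure(list(grid = as.numeric(grid), A = A, sample_id = sample_id,
                 replicate = replicate, clipped = 0L),
            class = "spectra_set")
}

#' Write a spectra set as wide delimited text
#'
#' @param spectra A `spectra_set`.
#' @param path Output path (CSV).
#' @return `path`, invisibly.
#' @export
write_spectra <- function(spectra, path) {
  stopifnot(inherits(spectra, "spectra_set"))
  df <- data.frame(wavenumber = spectra$grid, t(spectra$A),
                   check.names = FALSE)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname read_spectra
#' @param spectrum Numeric vector of absorbances for [write_jcampdx()].
#' @param grid Wavenumber vector for [write_jcampdx()].
#' @param title JCAMP TITLE record.
#' @export
write_jcampdx <- function(spectrum, grid, path, title = "anthoNIR spectrum") {
  stopifnot(length(spectrum) == length(grid))
  lines <- c(
    paste0("##TITLE=", title),
    "##JCAMP-DX=4.24",
    "##DATA TYPE=NEAR INFRARED SPECTRUM",
    "##XUNITS=1/CM",
    "##YUNITS=ABSORBANCE",
    "##XFACTOR=1",
    "##YFACTOR=1",
    sprintf("##FIRSTX=%.10g", grid[1]),
    sprintf("##LASTX=%.10g", grid[length(grid)]),
    sprintf("##DELTAX=%.10g", (grid[length(grid)] - grid[1]) / (length(grid) - 1)),
    sprintf("##NPOINTS=%d", length(grid)),
    sprintf("##FIRSTY=%.10g", spectrum[1]),
    "##XYDATA=(X++(Y..Y))"
  )
  per_line <- 6L
  starts <- seq(1L, length(grid), by = per_line)
  data_lines <- vapply(starts, function(s) {
    idx <- s:min(s + per_line - 1L, length(grid))
    paste(c(sprintf("%.10g", grid[s]), sprintf("%.8g", spectrum[idx])),
          collapse = " ")
  }, character(1))
  writeLines(c(lines, data_lines, "##END="), path)
  invisible(path)
}

read_jcampdx <- function(path) {
  txt <- readLines(path, warn = FALSE)
  hdr <- function(key) {
    ln <- grep(paste0("^##", key, "="), txt, value = TRUE)
    if (!length(ln)) return(NA_real_)
    as.numeric(sub(paste0("^##", key, "="), "", ln[1]))
  }
  xfac <- hdr("XFACTOR"); if (is.na(xfac)) xfac <- 1
  yfac <- hdr("YFACTOR"); if (is.na(yfac)) yfac <- 1
  ix <- grep("^##XYDATA=", txt)
  ip <- grep("^##XYPOINTS=", txt)
  iend <- grep("^##END", txt)
  if (!length(iend)) iend <- length(txt) + 1L
  if (length(ix)) {
    body <- txt[(ix[1] + 1L):(min(iend[iend > ix[1]]) - 1L)]
    toks <- lapply(strsplit(trimws(body), "[,; \t]+"), as.numeric)
    firstx <- hdr("FIRSTX"); npts <- hdr("NPOINTS"); deltax <- hdr("DELTAX")
    if (is.na(deltax)) {
      lastx <- hdr("LASTX")
      deltax <- (lastx - firstx) / (npts - 1)
    }
    y <- unlist(lapply(toks, `[`, -1L))
    x_check <- vapply(toks, `[`, numeric(1), 1L) * xfac
    grid <- (firstx + deltax * (seq_along(y) - 1)) * xfac
    # per-line leading X values must agree with the DELTAX reconstruction
    nper <- vapply(toks, function(t) length(t) - 1L, integer(1))
    line_start <- cumsum(c(0L, nper[-length(nper)])) + 1L
    if (any(abs(grid[line_start] - x_check) > abs(deltax) * 0.5)) {
      stop("JCAMP-DX abscissae inconsistent with DELTAX encoding",
           call. = FALSE)
    }
  } else if (length(ip)) {
    body <- txt[(ip[1] + 1L):(min(iend[iend > ip[1]]) - 1L)]
    toks <- lapply(strsplit(trimws(body), "[,; \t]+"), as.numeric)
    xy <- do.call(rbind, lapply(toks, function(t) matrix(t, ncol = 2L,
                                                         byrow = TRUE)))
    grid <- xy[, 1] * xfac
    y <- xy[, 2]
  } else {
    stop("no XYDATA or XYPOINTS table in ", path, call. = FALSE)
  }
  if (is.unsorted(grid, strictly = TRUE)) {
    stop("JCAMP-DX grid is not strictly increasing", call. = FALSE)
  }
  A <- matrix(y * yfac, nrow = 1L)
  rownames(A) <- "S1.1"
  structure(list(grid = grid, A = A, sample_id = "S1", replicate = 1L,
                 clipped = 0L),
            class = "spectra_set")
}

# ---- model serialization ----------------------------------------------

#' Save and load a calibration model as structured text
#'
#' Serialises a fitted PLS1 model together with its fitted preprocessing
#' chain and the full-resolution grid as JSON at full double precision, so a
#' save/load round trip reproduces predictions bitwise.
#'
#' @param model A `pls1_model`.
#' @param chain The fitted `preprocess_chain` the model was trained behind.
#' @param grid The full (pre-window) wavenumber grid.
#' @param path Output path.
#' @return `path` invisibly for [save_model()]; a list with `model`, `chain`,
#'   `grid` for [load_model()].
#' @export
save_model <- function(model, chain, grid, path) {
  stopifnot(inherits(model, "pls1_model"), inherits(chain, "preprocess_chain"))
  chain$x <- NULL  # do not embed the training matrix
  payload <- list(
    format = "anthoNIR-pls1",
    analyte = chain$analyte,
    grid = grid,
    chain = unclass(chain),
    model = unclass(model)
  )
  # I(17) significant digits: doubles survive the text round trip exactly
  jsonlite::write_json(payload, path, digits = I(17), auto_unbox = TRUE,
                       pretty = FALSE)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE,
                                 simplifyDataFrame = FALSE,
                                 simplifyMatrix = TRUE)
  if (!identical(payload$format, "anthoNIR-pls1")) {
    stop("not an anthoNIR model file: ", path, call. = FALSE)
  }
  ch <- payload$chain
  ch$steps <- lapply(ch$steps, function(s) {
    if (!is.null(s$windows)) {
      s$windows <- matrix(as.numeric(s$windows), ncol = 2L)
    }
    if (!is.null(s$mask)) s$mask <- as.logical(s$mask)
    if (!is.null(s$reference)) s$reference <- as.numeric(s$reference)
    s
  })
  chain <- structure(ch, class = "preprocess_chain")
  m <- payload$model
  for (f in c("W", "P", "Tscores", "B")) {
    m[[f]] <- as.matrix(m[[f]])
  }
  for (f in c("q", "intercepts", "xmeans")) m[[f]] <- as.numeric(m[[f]])
  m$rank <- as.integer(m$rank)
  model <- structure(m, class = "pls1_model")
  list(model = model, chain = chain, grid = as.numeric(payload$grid),
       analyte = payload$analyte)
}
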