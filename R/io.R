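#' Read and write spectra as wide CSV
#'
#' The canonical interchange format: UTF-8, comma separated, one row per
#' scan. Header = the metadata columns (at least
#' `bag_id,cultivar,endophyte_strain,endophyte_status,scan_index`) followed
#' by one column per wavenumber, headers being plain decimal wavenumbers in
#' cm-1, descending. Any additional non-numeric-named column is carried as
#' extra metadata. Values round-trip losslessly at 9+ significant digits.
#'
#' @param path File path.
#' @param s A [spectra_set()].
#' @return `read_spectra_csv()` returns a [spectra_set()];
#'   `write_spectra_csv()` returns `path` invisibly.
#' @export
read_spectra_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (nrow(df) < 1L) stop("CSV '", path, "' contains no scans")
  hdr <- names(df)
  wn <- suppressWarnings(as.numeric(hdr))
  is_wave <- !is.na(wn)
  if (sum(is_wave) < 2L)
    stop("CSV '", path, "' has fewer than two wavenumber columns")
  meta <- df[, !is_wave, drop = FALSE]
  X <- as.matrix(df[, is_wave, drop = FALSE])
  if (!is.numeric(X)) {
    bad <- which(!vapply(df[, is_wave, drop = FALSE], is.numeric, logical(1)))[1]
    stop("wavenumber column '", hdr[is_wave][bad], "' is not numeric")
  }
  pts <- wn[is_wave]
  d <- diff(pts)
  if (any(d >= 0))
    stop("wavenumber headers must be strictly descending; violation near column '",
         hdr[is_wave][which(d >= 0)[1] + 1], "'")
  sp <- -d
  if (max(sp) - min(sp) > 1e-6 * max(sp))
    stop("non-uniform wavenumber grid in '", path, "' (spacing varies from ",
         min(sp), " to ", max(sp), ")")
  g <- nir_grid(pts[1], pts[length(pts)], mean(sp))
  spectra_set(X, meta, g)
}

#' @rdname read_spectra_csv
#' @export
write_spectra_csv <- function(s, path) {
  stopifnot(inherits(s, "spectra_set"))
  df <- cbind(s$metadata,
              as.data.frame(s$absorbance, check.names = FALSE))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a single-spectrum JCAMP-DX file
#'
#' Minimal JCAMP-DX reader for linear AFFN data: supports
#' `##XYDATA=(X++(Y..Y))` and `##XYPOINTS=(XY..XY)` records with optional
#' `##XFACTOR`/`##YFACTOR` scaling. Compressed (SQZ/DIF/DUP) encodings and
#' multi-block files are not supported. The result is a one-scan
#' [spectra_set()]; class metadata are `NA` (JCAMP carries none).
#'
#' @param path File path.
#' @return A one-scan [spectra_set()].
#' @export
read_jcampdx <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\\$\\$.*$", "", lines)  # strip comments
  labels <- grep("^##", lines)
  get_field <- function(name) {
    i <- grep(paste0("^##", name, "="), lines, ignore.case = TRUE)
    if (!length(i)) return(NULL)
    trimws(sub("^##[^=]*=", "", lines[i[1]]))
  }
  xfactor <- as.numeric(get_field("XFACTOR") %||% "1")
  yfactor <- as.numeric(get_field("YFACTOR") %||% "1")
  title <- get_field("TITLE") %||% "jcampdx"

  xy_i <- grep("^##(XYDATA|XYPOINTS)=", lines, ignore.case = TRUE)
  if (!length(xy_i))
    stop("'", path, "' has no ##XYDATA or ##XYPOINTS record")
  start <- xy_i[1]
  form <- toupper(trimws(sub("^##[^=]*=", "", lines[start])))
  stop_i <- labels[labels > start]
  end <- if (length(stop_i)) min(stop_i) - 1L else length(lines)
  body <- lines[(start + 1L):end]
  body <- body[nzchar(trimws(body))]

  if (grepl("XYPOINTS", lines[start], ignore.case = TRUE) ||
      grepl("XY", form, fixed = TRUE) && !grepl("\\+\\+", form)) {
    toks <- as.numeric(unlist(strsplit(trimws(body), "[,;[:space:]]+")))
    if (anyNA(toks) || length(toks) %% 2 != 0)
      stop("malformed XYPOINTS data in '", path, "'")
    x <- toks[seq(1, length(toks), 2)] * xfactor
    y <- toks[seq(2, length(toks), 2)] * yfactor
  } else {
    x <- numeric(0); y <- numeric(0)
    for (ln in body) {
      toks <- as.numeric(strsplit(trimws(ln), "[,;[:space:]]+")[[1]])
      if (anyNA(toks) || length(toks) < 2)
        stop("malformed XYDATA line in '", path, "': ", ln)
      y <- c(y, toks[-1])
      x <- c(x, toks[1])
    }
    # x holds each line's abscissa; expand to the full axis afterwards
    firstx <- as.numeric(get_field("FIRSTX") %||% as.character(x[1] * xfactor))
    lastx <- as.numeric(get_field("LASTX"))
    npt <- as.numeric(get_field("NPOINTS") %||% as.character(length(y)))
    if (npt != length(y))
      stop("NPOINTS=", npt, " but ", length(y), " Y values found in '", path, "'")
    if (is.null(lastx) || is.na(lastx))
      stop("'", path, "' XYDATA requires ##LASTX")
    x <- seq(firstx, lastx, length.out = npt)
    y <- y * yfactor
  }
  ord <- order(x, decreasing = TRUE)
  x <- x[ord]; y <- y[ord]
  sp <- -diff(x)
  if (max(sp) - min(sp) > 1e-6 * max(sp))
    stop("non-uniform abscissa in '", path, "'")
  g <- nir_grid(x[1], x[length(x)], mean(sp))
  md <- data.frame(bag_id = title, cultivar = NA_character_,
                   endophyte_strain = NA_character_,
                   endophyte_status = NA_character_,
                   scan_index = 1L, stringsAsFactors = FALSE)
  spectra_set(matrix(y, nrow = 1), md, g)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
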