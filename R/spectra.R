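# Validate the per-scan metadata contract. NA class labels are tolerated
# (e.g. a JCAMP-DX import with no class information); non-NA labels must be
# drawn from the known sets, and the strain/status invariant WE <=> E- holds
# wherever both fields are non-NA.
validate_scan_metadata <- function(md) {
  required <- c("bag_id", "cultivar", "endophyte_strain",
                "endophyte_status", "scan_index")
  missing <- setdiff(required, names(md))
  if (length(missing))
    stop("metadata is missing column(s): ", paste(missing, collapse = ", "))
  bad <- which(!is.na(md$cultivar) & !(md$cultivar %in% CULTIVARS))
  if (length(bad))
    stop("row ", bad[1], ": unknown cultivar '", md$cultivar[bad[1]], "'")
  bad <- which(!is.na(md$endophyte_status) &
                 !(md$endophyte_status %in% ENDOPHYTE_STATUSES))
  if (length(bad))
    stop("row ", bad[1], ": unknown endophyte_status '",
         md$endophyte_status[bad[1]], "'")
  both <- !is.na(md$endophyte_strain) & !is.na(md$endophyte_status)
  bad <- which(both & (md$endophyte_strain == "WE") != (md$endophyte_status == "E-"))
  if (length(bad))
    stop("row ", bad[1], ": strain '", md$endophyte_strain[bad[1]],
         "' inconsistent with endophyte_status '", md$endophyte_status[bad[1]],
         "' (strain WE must pair with E- and vice versa)")
  si <- md$scan_index
  bad <- which(!is.na(si) & (si < 1 | si != round(si)))
  if (length(bad))
    stop("row ", bad[1], ": scan_index must be a positive integer, got ",
         si[bad[1]])
  invisible(md)
}

#' NIR spectra on a shared wavenumber grid
#'
#' The central data container: an absorbance matrix (one row per scan, one
#' column per wavenumber) together with its [nir_grid()] and one metadata row
#' per scan (`bag_id`, `cultivar`, `endophyte_strain`, `endophyte_status`,
#' `scan_index`, plus any extra columns). A bag of seed is scanned several
#' times (sub-samples); scans of a bag share its `bag_id` and class labels.
#'
#' @param absorbance Numeric matrix, `n_scans x n_points`, no missing values.
#' @param metadata `data.frame` with `nrow(absorbance)` rows and at least the
#'   five canonical columns. The strain label `"WE"` (without endophyte) must
#'   pair with status `"E-"` and vice versa.
#' @param grid A [nir_grid()] whose length equals `ncol(absorbance)`.
#' @return An object of class `"spectra_set"`.
#' @export
spectra_set <- function(absorbance, metadata, grid) {
  stopifnot(inherits(grid, "nir_grid"))
  absorbance <- as.matrix(absorbance)
  if (!is.numeric(absorbance)) stop("absorbance must be numeric")
  if (nrow(absorbance) < 1L) stop("spectra_set needs at least one scan")
  if (ncol(absorbance) != length(grid$points))
    stop("absorbance has ", ncol(absorbance), " columns but the grid has ",
         length(grid$points), " points")
  if (anyNA(absorbance) || any(!is.finite(absorbance)))
    stop("absorbance contains missing or non-finite values")
  metadata <- as.data.frame(metadata)
  if (nrow(metadata) != nrow(absorbance))
    stop("metadata has ", nrow(metadata), " rows for ", nrow(absorbance),
         " scans")
  validate_scan_metadata(metadata)
  rownames(metadata) <- NULL
  dimnames(absorbance) <- list(NULL, format_wavenumber(grid$points))
  structure(list(grid = grid, absorbance = absorbance, metadata = metadata),
            class = "spectra_set")
}

format_wavenumber <- function(w) formatC(w, format = "fg", digits = 10)

#' @export
print.spectra_set <- function(x, ...) {
  cat(sprintf("<spectra_set> %d scan(s) x %d points, %g to %g cm-1\n",
              nrow(x$absorbance), ncol(x$absorbance), x$grid$high, x$grid$low))
  cv <- table(x$metadata$cultivar, useNA = "ifany")
  cat("  cultivars: ", paste(sprintf("%s=%d", names(cv), cv), collapse = ", "),
      "\n", sep = "")
  st <- table(x$metadata$endophyte_status, useNA = "ifany")
  cat("  endophyte: ", paste(sprintf("%s=%d", names(st), st), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' @export
summary.spectra_set <- function(object, ...) {
  md <- object$metadata
  cat(sprintf("spectra_set: %d scans, %d bags, %d points (%g-%g cm-1)\n",
              nrow(md), length(unique(md$bag_id)),
              length(object$grid$points), object$grid$high, object$grid$low))
  print(table(cultivar = md$cultivar, status = md$endophyte_status))
  invisible(object)
}

#' @export
dim.spectra_set <- function(x) dim(x$absorbance)

#' Subset scans of a spectra_set
#'
#' @param x A [spectra_set()].
#' @param i Scan (row) index.
#' @param ... Ignored.
#' @return A `spectra_set` with the selected scans, same grid.
#' @export
`[.spectra_set` <- function(x, i, ...) {
  spectra_set(x$absorbance[i, , drop = FALSE],
              x$metadata[i, , drop = FALSE], x$grid)
}

#' @export
plot.spectra_set <- function(x, col = NULL, max_scans = 60, ...) {
  n <- nrow(x$absorbance)
  idx <- if (n > max_scans) round(seq(1, n, length.out = max_scans)) else seq_len(n)
  if (is.null(col)) {
    cl <- factor(x$metadata$cultivar[idx], levels = CULTIVARS)
    col <- c("#D7263D", "#1B998B", "#2E294E", "#4FB0C6")[as.integer(cl)]
    col[is.na(col)] <- "grey40"
  }
  graphics::matplot(x$grid$points, t(x$absorbance[idx, , drop = FALSE]),
                    type = "l", lty = 1, col = col,
                    xlim = rev(range(x$grid$points)),
                    xlab = expression(Wavenumber ~ (cm^-1)),
                    ylab = "Absorbance", ...)
  invisible(x)
}

#' Trim a spectra_set to a wavenumber window
#'
#' Retains exactly the grid points whose wavenumber lies in `[low, high]`,
#' inclusive on both ends. The standard modelling window 9000--3952 cm-1
#' keeps 632 of the 949 acquisition points, dropping the noisy high-
#' wavenumber end. Metadata are unchanged and the input is not modified.
#'
#' @param s A [spectra_set()].
#' @param high,low Window bounds in cm-1.
#' @return A new `spectra_set` on the trimmed grid.
#' @examples
#' \dontrun{
#' trimmed <- trim_spectra(s, 9000, 3952)
#' }
#' @export
trim_spectra <- function(s, high, low) {
  stopifnot(inherits(s, "spectra_set"), high >= low)
  keep <- s$grid$points <= high & s$grid$points >= low
  if (!any(keep))
    stop("trim window [", low, ", ", high,
         "] does not intersect the grid range [", s$grid$low, ", ",
         s$grid$high, "]")
  pts <- s$grid$points[keep]
  g <- nir_grid(max(pts), min(pts), s$grid$spacing)
  spectra_set(s$absorbance[, keep, drop = FALSE], s$metadata, g)
}
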