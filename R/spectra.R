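#' Construct a mass spectrum
#'
#' A spectrum is a set of centroided (m/z, intensity) peaks from a
#' unit-resolution GC-MS instrument. On construction, peaks are sorted by m/z,
#' m/z values are rounded to the nearest integer (nominal-mass convention for a
#' single-quadrupole instrument) and duplicate m/z arising from the rounding
#' are merged by summing their intensities.
#'
#' @param id Character identifier for the compound / query.
#' @param mz Numeric vector of mass-to-charge values (Da).
#' @param intensity Numeric vector of non-negative intensities (arbitrary
#'   units); at least one must be positive.
#' @param meta Optional named list of free-text metadata (e.g. extra MSP
#'   header fields).
#' @param mz_window Length-2 numeric giving the retained m/z range; peaks
#'   outside it are dropped with a message. Defaults to the 50--550 Da
#'   acquisition range of a typical single-quadrupole GC-MS method.
#'
#' @return An object of class `spectrum`: a list with elements `id`, `mz`
#'   (strictly increasing integers), `intensity` and `meta`.
#' @export
#' @examples
#' s <- spectrum("alanine", mz = c(116, 73, 147), intensity = c(40, 100, 25))
#' s$mz
spectrum <- function(id, mz, intensity, meta = list(), mz_window = c(50, 550)) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  if (length(mz) != length(intensity)) {
    stop("spectrum '", id, "': mz and intensity lengths differ", call. = FALSE)
  }
  if (length(mz) == 0L) stop("spectrum '", id, "': no peaks", call. = FALSE)
  if (any(!is.finite(mz)) || any(!is.finite(intensity))) {
    stop("spectrum '", id, "': non-finite peak values", call. = FALSE)
  }
  if (any(intensity < 0)) {
    stop("spectrum '", id, "': negative intensities", call. = FALSE)
  }
  mz <- round(mz)
  keep <- mz >= mz_window[1] & mz <= mz_window[2]
  if (!all(keep)) {
    message("spectrum '", id, "': dropped ", sum(!keep),
            " peak(s) outside m/z window [", mz_window[1], ", ", mz_window[2], "]")
    mz <- mz[keep]
    intensity <- intensity[keep]
  }
  if (length(mz) == 0L) {
    stop("spectrum '", id, "': no peaks left inside the m/z window", call. = FALSE)
  }
  # merge duplicate nominal masses, then sort
  agg <- rowsum(intensity, group = mz)
  mz <- as.numeric(rownames(agg))
  intensity <- as.numeric(agg[, 1L])
  ord <- order(mz)
  mz <- mz[ord]
  intensity <- intensity[ord]
  if (all(intensity == 0)) {
    stop("spectrum '", id, "': all intensities are zero", call. = FALSE)
  }
  structure(list(id = id, mz = mz, intensity = intensity, meta = meta),
            class = "spectrum")
}

#' @export
print.spectrum <- function(x, ...) {
  cat("<spectrum> ", x$id, ": ", length(x$mz), " peaks, m/z ",
      min(x$mz), "-", max(x$mz), "\n", sep = "")
  invisible(x)
}

is_spectrum <- function(x) inherits(x, "spectrum")

#' Scale spectrum intensities to abundances
#'
#' Scales the intensities of a spectrum either by their sum (`"sum"`, total
#' intensity) or by the spectrum maximum (`"max"`). Scaled intensities are
#' referred to as abundances throughout the package. Scaling is always applied
#' per spectrum, before any query/reference join, so the zeros introduced by
#' alignment never change the scale.
#'
#' @param s A [spectrum()].
#' @param mode `"sum"` or `"max"`.
#' @return A `spectrum` whose intensities sum to 1 (`"sum"`) or have maximum 1
#'   (`"max"`).
#' @export
#' @examples
#' s <- spectrum("x", c(70, 85, 99), c(2, 3, 5))
#' normalize_spectrum(s, "sum")$intensity  # 0.2 0.3 0.5
normalize_spectrum <- function(s, mode = c("sum", "max")) {
  stopifnot(is_spectrum(s))
  mode <- match.arg(mode)
  denom <- if (mode == "sum") sum(s$intensity) else max(s$intensity)
  if (denom <= 0) stop("spectrum '", s$id, "': cannot normalize all-zero intensities",
                       call. = FALSE)
  s$intensity <- s$intensity / denom
  s
}

#' Align a query and a reference spectrum on a shared m/z grid
#'
#' Performs the full (outer) join by nominal m/z: the grid is the union of the
#' two spectra's m/z values and positions absent from one spectrum carry
#' abundance 0 in that spectrum's vector. Each spectrum is normalized
#' (see [normalize_spectrum()]) before the join.
#'
#' @param query,reference [spectrum()] objects.
#' @param mode Normalization mode, `"sum"` or `"max"`.
#' @return An object of class `aligned_pair`: list with `mz` (shared grid),
#'   `P` (query abundances), `Q` (reference abundances), `normalization`,
#'   `query_id`, `reference_id`.
#' @export
#' @examples
#' q <- spectrum("q", c(70, 85), c(1, 1))
#' r <- spectrum("r", c(85, 99), c(1, 1))
#' align_spectra(q, r)$mz  # 70 85 99
align_spectra <- function(query, reference, mode = c("sum", "max")) {
  mode <- match.arg(mode)
  query <- normalize_spectrum(query, mode)
  reference <- normalize_spectrum(reference, mode)
  grid <- sort(unique(c(query$mz, reference$mz)))
  P <- numeric(length(grid))
  Q <- numeric(length(grid))
  P[match(query$mz, grid)] <- query$intensity
  Q[match(reference$mz, grid)] <- reference$intensity
  structure(list(mz = grid, P = P, Q = Q, normalization = mode,
                 query_id = query$id, reference_id = reference$id),
            class = "aligned_pair")
}

#' @export
print.aligned_pair <- function(x, ...) {
  cat("<aligned_pair> ", x$query_id, " vs ", x$reference_id, ": ",
      length(x$mz), " grid points (", x$normalization, "-scaled)\n", sep = "")
  invisible(x)
}

#' Read spectra from an MSP or long-format CSV file
#'
#' MSP is the NIST-style text format: records separated by blank lines, each
#' with a `Name:` field, a `Num Peaks:` count and peak lines of
#' whitespace- or semicolon-separated "mz intensity" pairs. Unrecognized
#' header keys are kept as free-text metadata. CSV must carry the columns
#' `id`, `mz`, `intensity` (one row per peak).
#'
#' @param path Path to the file.
#' @param format `"msp"` or `"csv"`; default guesses from the file extension.
#' @param mz_window Retained m/z range, passed to [spectrum()].
#' @return A list of [spectrum()] objects (empty, with a warning, for an
#'   empty file).
#' @export
read_spectra <- function(path, format = c("auto", "msp", "csv"),
                         mz_window = c(50, 550)) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "auto") {
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "msp"
  }
  if (format == "csv") read_spectra_csv(path, mz_window) else read_spectra_msp(path, mz_window)
}

read_spectra_csv <- function(path, mz_window) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "mz", "intensity")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("CSV ", path, " missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(df) == 0L) {
    warning("empty spectrum file: ", path)
    return(list())
  }
  ids <- unique(df$id)
  lapply(ids, function(i) {
    sub <- df[df$id == i, , drop = FALSE]
    spectrum(as.character(i), sub$mz, sub$intensity, mz_window = mz_window)
  })
}

read_spectra_msp <- function(path, mz_window) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\\s+$", "", lines)
  if (!length(lines) || all(lines == "")) {
    warning("empty spectrum file: ", path)
    return(list())
  }
  # split into blocks at blank lines
  blank <- lines == ""
  block_id <- cumsum(c(TRUE, diff(blank) == -1L))
  block_id[blank] <- NA
  blocks <- split(lines[!blank], block_id[!blank])
  out <- lapply(blocks, parse_msp_block, mz_window = mz_window)
  unname(out)
}

parse_msp_block <- function(block, mz_window) {
  is_header <- grepl("^[A-Za-z][A-Za-z0-9_ #/.-]*:", block)
  headers <- block[is_header]
  peak_lines <- block[!is_header]
  keys <- tolower(sub(":.*$", "", headers))
  vals <- sub("^[^:]*:\\s*", "", headers)
  name <- vals[match("name", keys)]
  if (is.na(name)) stop("MSP block without a Name field", call. = FALSE)
  npk <- vals[match("num peaks", keys)]
  if (is.na(npk)) stop("MSP record '", name, "': missing Num Peaks", call. = FALSE)
  npk <- as.integer(npk)
  # peak lines: "mz intensity" pairs separated by whitespace or ';'
  tokens <- unlist(strsplit(paste(peak_lines, collapse = " "), "[;[:space:]]+"))
  tokens <- tokens[nzchar(tokens)]
  if (length(tokens) %% 2L != 0L) {
    stop("MSP record '", name, "': odd number of peak tokens", call. = FALSE)
  }
  mz <- as.numeric(tokens[c(TRUE, FALSE)])
  intensity <- as.numeric(tokens[c(FALSE, TRUE)])
  if (anyNA(mz) || anyNA(intensity)) {
    stop("MSP record '", name, "': non-numeric peak values", call. = FALSE)
  }
  if (length(mz) != npk) {
    stop("MSP record '", name, "': declares ", npk, " peaks but lists ",
         length(mz), call. = FALSE)
  }
  extra <- !(keys %in% c("name", "num peaks"))
  meta <- as.list(vals[extra])
  names(meta) <- sub(":.*$", "", headers[extra])
  spectrum(name, mz, intensity, meta = meta, mz_window = mz_window)
}

#' Write spectra to an MSP or long-format CSV file
#'
#' Round-trips with [read_spectra()]: m/z and intensities are written with
#' enough digits to reproduce values to at least 6 significant figures.
#'
#' @param spectra List of [spectrum()] objects.
#' @param path Output path.
#' @param format `"msp"` or `"csv"`; default guesses from the extension.
#' @return `path`, invisibly.
#' @export
write_spectra <- function(spectra, path, format = c("auto", "msp", "csv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "msp"
  }
  stopifnot(all(vapply(spectra, is_spectrum, logical(1))))
  if (format == "csv") {
    df <- do.call(rbind, lapply(spectra, function(s) {
      data.frame(id = s$id, mz = s$mz,
                 intensity = signif(s$intensity, 12),
                 stringsAsFactors = FALSE)
    }))
    utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    for (s in spectra) {
      writeLines(paste0("Name: ", s$id), con)
      for (k in names(s$meta)) writeLines(paste0(k, ": ", s$meta[[k]]), con)
      writeLines(paste0("Num Peaks: ", length(s$mz)), con)
      writeLines(paste(format(s$mz, trim = TRUE, scientific = FALSE),
                       signif(s$intensity, 12)), con)
      writeLines("", con)
    }
  }
  invisible(path)
}
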