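#' Read MS/MS spectra from MGF or MSP files
#'
#' Parses a peak-list file into a spectra tibble. The MGF dialect uses
#' `BEGIN IONS`/`END IONS` records with `PEPMASS=`, `TITLE=` and optional
#' `SMILES=`/`STRUCTUREKEY=` headers; the MSP dialect uses `Name:`,
#' `PrecursorMZ:` and `Num Peaks:` headers with blank-line-separated
#' records. Peaks are returned raw (no rounding or filtering); apply
#' [preprocess_spectra()] before encoding.
#'
#' @param path Path to the spectra file.
#' @param format `"auto"` (by file extension), `"mgf"` or `"msp"`.
#' @return A spectra tibble with columns `spectrum_id`, `precursor_mz`,
#'   `structure_key`, `smiles` and `peaks`. A missing precursor field
#'   yields `NA` (an error is raised only when neutral losses are derived).
#' @seealso [write_spectra()], [preprocess_spectra()]
#' @export
read_spectra <- function(path, format = c("auto", "mgf", "msp")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, mgf = "mgf", msp = "msp",
                     abort(sprintf("cannot infer format from extension '%s'", ext)))
  }
  lines <- readLines(path, warn = FALSE)
  recs <- if (format == "mgf") parse_mgf(lines) else parse_msp(lines)
  if (!length(recs)) {
    return(as_ms2_spectra(tibble::tibble(
      spectrum_id = character(), precursor_mz = double(),
      structure_key = character(), smiles = character(), peaks = list()
    )))
  }
  out <- tibble::tibble(
    spectrum_id = purrr::map_chr(recs, "spectrum_id"),
    precursor_mz = purrr::map_dbl(recs, "precursor_mz"),
    structure_key = purrr::map_chr(recs, "structure_key"),
    smiles = purrr::map_chr(recs, "smiles"),
    peaks = purrr::map(recs, "peaks")
  )
  as_ms2_spectra(out)
}

parse_peak_lines <- function(lines, rec_idx) {
  if (!length(lines)) {
    return(tibble::tibble(mz = double(), intensity = double()))
  }
  parts <- strsplit(trimws(lines), "[ \t]+")
  bad <- vapply(parts, function(p) length(p) < 2L ||
                  anyNA(suppressWarnings(as.numeric(p[1:2]))), logical(1))
  if (any(bad)) {
    abort(sprintf("malformed peak line in record %d: '%s'",
                  rec_idx, lines[which(bad)[1L]]))
  }
  tibble::tibble(
    mz = vapply(parts, function(p) as.numeric(p[1L]), double(1)),
    intensity = vapply(parts, function(p) as.numeric(p[2L]), double(1))
  )
}

parse_mgf <- function(lines) {
  begins <- grep("^\\s*BEGIN IONS\\s*$", lines)
  ends <- grep("^\\s*END IONS\\s*$", lines)
  if (length(begins) != length(ends) || any(ends < begins)) {
    abort("malformed MGF: unbalanced BEGIN IONS/END IONS")
  }
  purrr::map2(begins, ends, function(b, e) {
    i <- match(b, begins)
    body <- lines[(b + 1L):(e - 1L)][b + 1L <= e - 1L]
    body <- body[nzchar(trimws(body))]
    is_header <- grepl("^[A-Za-z][A-Za-z0-9_]*=", body)
    headers <- body[is_header]
    keys <- toupper(sub("=.*$", "", headers))
    vals <- sub("^[^=]*=", "", headers)
    get <- function(k) if (k %in% keys) vals[match(k, keys)] else NA_character_
    pep <- get("PEPMASS")
    precursor <- if (is.na(pep)) NA_real_ else
      suppressWarnings(as.numeric(strsplit(trimws(pep), "[ \t]+")[[1L]][1L]))
    if (!is.na(pep) && is.na(precursor)) {
      abort(sprintf("malformed PEPMASS in MGF record %d", i))
    }
    title <- get("TITLE")
    list(
      spectrum_id = if (is.na(title)) sprintf("spectrum_%05d", i) else title,
      precursor_mz = precursor,
      structure_key = get("STRUCTUREKEY"),
      smiles = get("SMILES"),
      peaks = parse_peak_lines(body[!is_header], i)
    )
  })
}

parse_msp <- function(lines) {
  lines <- c(lines, "")
  name_at <- grep("^Name:", lines, ignore.case = TRUE)
  if (!length(name_at)) return(list())
  bounds <- c(name_at, length(lines) + 1L)
  purrr::map(seq_along(name_at), function(i) {
    body <- lines[bounds[i]:(bounds[i + 1L] - 1L)]
    body <- body[nzchar(trimws(body))]
    is_header <- grepl("^[A-Za-z][A-Za-z0-9_ ]*:", body)
    headers <- body[is_header]
    keys <- toupper(gsub("[ _]", "", sub(":.*$", "", headers)))
    vals <- trimws(sub("^[^:]*:", "", headers))
    get <- function(k) if (k %in% keys) vals[match(k, keys)] else NA_character_
    precursor <- suppressWarnings(as.numeric(get("PRECURSORMZ")))
    npk <- suppressWarnings(as.integer(get("NUMPEAKS")))
    peaks <- parse_peak_lines(body[!is_header], i)
    if (!is.na(npk) && nrow(peaks) != npk) {
      abort(sprintf("MSP record %d declares %d peaks but has %d", i, npk, nrow(peaks)))
    }
    nm <- get("NAME")
    list(
      spectrum_id = if (is.na(nm)) sprintf("spectrum_%05d", i) else nm,
      precursor_mz = precursor,
      structure_key = get("STRUCTUREKEY"),
      smiles = get("SMILES"),
      peaks = peaks
    )
  })
}

#' Write spectra to MGF or MSP
#'
#' @param spectra A spectra tibble (see [as_ms2_spectra()]).
#' @param path Output file path.
#' @param format `"auto"` (by extension), `"mgf"` or `"msp"`.
#' @return `path`, invisibly.
#' @export
write_spectra <- function(spectra, path, format = c("auto", "mgf", "msp")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)), mgf = "mgf", msp = "msp",
                     abort("cannot infer format from extension"))
  }
  spectra <- as_ms2_spectra(spectra)
  fmt_num <- function(x) trimws(formatC(x, format = "fg", digits = 10))
  blocks <- purrr::pmap(spectra, function(spectrum_id, precursor_mz,
                                          structure_key, peaks, ...) {
    extra <- list(...)
    pk <- sprintf("%s %s", fmt_num(peaks$mz), fmt_num(peaks$intensity))
    if (format == "mgf") {
      c("BEGIN IONS",
        paste0("TITLE=", spectrum_id),
        if (!is.na(precursor_mz)) paste0("PEPMASS=", fmt_num(precursor_mz)),
        if (!is.na(structure_key)) paste0("STRUCTUREKEY=", structure_key),
        if (!is.null(extra$smiles) && !is.na(extra$smiles)) paste0("SMILES=", extra$smiles),
        pk, "END IONS", "")
    } else {
      c(paste0("Name: ", spectrum_id),
        if (!is.na(precursor_mz)) paste0("PrecursorMZ: ", fmt_num(precursor_mz)),
        if (!is.na(structure_key)) paste0("StructureKey: ", structure_key),
        if (!is.null(extra$smiles) && !is.na(extra$smiles)) paste0("SMILES: ", extra$smiles),
        paste0("Num Peaks: ", nrow(peaks)),
        pk, "")
    }
  })
  writeLines(unlist(blocks), path)
  invisible(path)
}

#' Preprocess peak lists
#'
#' Applies the standard cleaning pipeline to every spectrum: (1) round m/z
#' to two decimal places, merging equal-m/z peaks by keeping the larger
#' intensity; (2) rescale intensities to percent of the base peak;
#' (3) drop peaks below `min_rel_intensity` percent; (4) drop peaks with
#' m/z outside `[mz_min, mz_max]`; (5) denoise with a `window`-Da sliding
#' window that keeps only the locally highest peak (greedy non-maximum
#' suppression with radius `window / 2`, descending intensity, intensity
#' ties broken towards the lower m/z). Intensities are rescaled once more
#' at the end so the surviving base peak is exactly 100.
#'
#' The pipeline is idempotent and never moves a peak: output peaks are a
#' subset of the rounded input peaks.
#'
#' @param spectra A spectra tibble.
#' @param min_rel_intensity Relative-intensity threshold in percent.
#' @param mz_min,mz_max Retained m/z range in Da.
#' @param window Sliding-window width in Da.
#' @param on_empty What to do when every peak of a spectrum is removed:
#'   `"error"` (default) or `"drop"` the spectrum.
#' @return The spectra tibble with cleaned `peaks`.
#' @export
preprocess_spectra <- function(spectra, min_rel_intensity = 0.1,
                               mz_min = 10, mz_max = 1000, window = 3,
                               on_empty = c("error", "drop")) {
  on_empty <- match.arg(on_empty)
  spectra <- as_ms2_spectra(spectra)
  spectra$peaks <- purrr::map2(spectra$peaks, spectra$spectrum_id, function(p, id) {
    out <- preprocess_peaks(p, min_rel_intensity, mz_min, mz_max, window)
    if (!nrow(out) && on_empty == "error") {
      abort(sprintf("empty spectrum after preprocessing: '%s'", id))
    }
    out
  })
  if (on_empty == "drop") {
    spectra <- spectra[vapply(spectra$peaks, nrow, integer(1)) > 0L, ]
  }
  spectra
}

## Single peak table; the workhorse behind preprocess_spectra().
preprocess_peaks <- function(peaks, min_rel_intensity = 0.1,
                             mz_min = 10, mz_max = 1000, window = 3) {
  peaks <- tibble::as_tibble(peaks)
  if (!nrow(peaks)) abort("spectrum has no peaks")
  mz <- round(peaks$mz, 2)
  int <- peaks$intensity
  ## merge duplicate m/z after rounding, keeping the larger intensity
  o <- order(mz, -int)
  mz <- mz[o]; int <- int[o]
  keep <- !duplicated(mz)
  mz <- mz[keep]; int <- int[keep]
  ## relative abundance in % of base peak
  int <- 100 * int / max(int)
  keep <- int >= min_rel_intensity & mz >= mz_min & mz <= mz_max
  mz <- mz[keep]; int <- int[keep]
  if (!length(mz)) return(tibble::tibble(mz = double(), intensity = double()))
  ## greedy non-maximum suppression, radius window/2
  o <- order(-int, mz)
  mz <- mz[o]; int <- int[o]
  kept_mz <- numeric(0)
  kept <- logical(length(mz))
  for (i in seq_along(mz)) {
    if (!length(kept_mz) || all(abs(kept_mz - mz[i]) > window / 2)) {
      kept[i] <- TRUE
      kept_mz <- c(kept_mz, mz[i])
    }
  }
  mz <- mz[kept]; int <- int[kept]
  int <- 100 * int / max(int)
  o <- order(mz)
  tibble::tibble(mz = mz[o], intensity = int[o])
}
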