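# Fluorophore library reading/writing.
#
# Canonical dialect: long-format CSV with columns
#   fluorophore, kind, wavelength_nm, intensity     (kind in {ex, em})
# and an optional brightness CSV with columns
#   fluorophore, brightness
# A few common alternative column spellings are accepted on read.

.library_col_shims <- c(
  fluorophore = "fluorophore", name = "fluorophore", fluor = "fluorophore",
  kind = "kind", type = "kind",
  wavelength_nm = "wavelength_nm", wavelength = "wavelength_nm",
  lambda = "wavelength_nm",
  intensity = "intensity", value = "intensity"
)

.canonical_library_cols <- function(df, path) {
  names(df) <- tolower(names(df))
  hit <- .library_col_shims[names(df)]
  names(df)[!is.na(hit)] <- hit[!is.na(hit)]
  need <- c("fluorophore", "kind", "wavelength_nm", "intensity")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("'", path, "': missing column(s): ", paste(missing, collapse = ", "))
  df[need]
}

#' Read a fluorophore library
#'
#' Reads a long-format CSV of excitation (`kind = "ex"`) and emission
#' (`kind = "em"`) sample points, one fluorophore per name. Spectra are
#' resampled to the working grid and peak-normalized. If a brightness table
#' is supplied, brightness values are rescaled so the brightest fluorophore
#' has brightness exactly 1 (the convention of normalizing to the brightest
#' library member).
#'
#' @param path CSV with columns `fluorophore,kind,wavelength_nm,intensity`.
#' @param brightness_path Optional CSV with columns `fluorophore,brightness`.
#' @return A `fluorophore_library`: a named list of [fluorophore()] objects.
#' @export
read_fluorophore_library <- function(path, brightness_path = NULL) {
  if (!file.exists(path)) stop("library file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df <- .canonical_library_cols(df, path)
  df$kind <- tolower(df$kind)
  if (!all(df$kind %in% c("ex", "em")))
    stop("'", path, "': kind must be 'ex' or 'em'")
  nms <- unique(df$fluorophore)
  if (any(!nzchar(nms))) stop("'", path, "': empty fluorophore name")
  lib <- vector("list", length(nms))
  names(lib) <- nms
  for (nm in nms) {
    sub <- df[df$fluorophore == nm, ]
    for (k in c("ex", "em")) {
      if (!any(sub$kind == k))
        stop("fluorophore '", nm, "' has no '", k, "' rows")
    }
    mk <- function(k) {
      rows <- sub[sub$kind == k, ]
      rows <- rows[order(rows$wavelength_nm), ]
      if (anyDuplicated(rows$wavelength_nm))
        stop("fluorophore '", nm, "': duplicate ", k, " wavelength")
      spectrum(rows$wavelength_nm, rows$intensity)
    }
    lib[[nm]] <- fluorophore(nm, mk("ex"), mk("em"))
  }
  if (!is.null(brightness_path)) {
    lib <- .apply_brightness(lib, brightness_path)
  }
  structure(lib, class = "fluorophore_library")
}

.apply_brightness <- function(lib, brightness_path) {
  if (!file.exists(brightness_path))
    stop("brightness file not found: ", brightness_path)
  bdf <- utils::read.csv(brightness_path, stringsAsFactors = FALSE)
  names(bdf) <- tolower(names(bdf))
  if (!all(c("fluorophore", "brightness") %in% names(bdf)))
    stop("brightness file needs columns fluorophore,brightness")
  unknown <- setdiff(bdf$fluorophore, names(lib))
  if (length(unknown))
    stop("brightness given for unknown fluorophore(s): ",
         paste(unknown, collapse = ", "))
  if (anyDuplicated(bdf$fluorophore))
    stop("duplicate fluorophore in brightness file")
  if (any(!is.finite(bdf$brightness)) || any(bdf$brightness <= 0))
    stop("brightness values must be positive and finite")
  b <- bdf$brightness / max(bdf$brightness)
  names(b) <- bdf$fluorophore
  for (nm in names(b)) lib[[nm]]$brightness <- unname(b[[nm]])
  lib
}

#' Coerce a list of fluorophores to a library
#' @param fluors List of [fluorophore()] objects with distinct names.
#' @return A `fluorophore_library`.
#' @export
fluorophore_library <- function(fluors) {
  stopifnot(length(fluors) >= 1L,
            all(vapply(fluors, inherits, logical(1), "fluorophore")))
  nms <- vapply(fluors, `[[`, character(1), "name")
  if (anyDuplicated(nms)) stop("duplicate fluorophore names in library")
  names(fluors) <- nms
  structure(fluors, class = "fluorophore_library")
}

#' Write a fluorophore library
#'
#' Writes the canonical long-format CSV (full working grid) and, when any
#' fluorophore carries a brightness, an accompanying brightness CSV.
#'
#' @param lib A `fluorophore_library`.
#' @param path Output CSV path.
#' @param brightness_path Optional output path for the brightness table.
#' @return `path`, invisibly.
#' @export
write_fluorophore_library <- function(lib, path, brightness_path = NULL) {
  g <- working_grid()
  rows <- lapply(lib, function(f) {
    rbind(
      data.frame(fluorophore = f$name, kind = "ex", wavelength_nm = g,
                 intensity = f$excitation$intensities),
      data.frame(fluorophore = f$name, kind = "em", wavelength_nm = g,
                 intensity = f$emission$intensities)
    )
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  if (!is.null(brightness_path)) {
    b <- vapply(lib, function(f) f$brightness %||% NA_real_, numeric(1))
    keep <- !is.na(b)
    utils::write.csv(
      data.frame(fluorophore = names(lib)[keep], brightness = b[keep]),
      brightness_path, row.names = FALSE)
  }
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.fluorophore_library <- function(x, ...) {
  cat(sprintf("<fluorophore_library> %d fluorophores: %s\n", length(x),
              paste(utils::head(names(x), 8), collapse = ", ")))
  invisible(x)
}
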