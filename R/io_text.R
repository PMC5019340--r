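#' Read and write the MSI text dialect
#'
#' The package's interchange format for pixel-resolved spectra is a plain
#' text file, one line per pixel, with a self-describing header:
#'
#' ```
#' #desilasso-msi v1
#' #sample S1 patient P1
#' #grid 32 40
#' #spacing 200
#' #mz 90 90.0834 ...          (one value per channel)
#' 0 0 12 31 0 ...             (row col, 0-based, then one intensity/channel)
#' ```
#'
#' Coordinates are 0-based `(row, col)`; pixels with no spectrum line are
#' marked background with all-zero intensities. Glass-slide pixels are
#' imaged too, so the writer keeps their (noise) spectra and flags them on
#' `#background r c r c ...` header lines; the reader marks a pixel
#' background when it is either flagged or missing. Intensities are written
#' with 17 significant digits so a write/read cycle reproduces them
#' exactly.
#'
#' @param path File path.
#' @return `read_msi_text()` returns an [msi_sample()];
#'   `write_msi_text()` returns `path` invisibly.
#' @export
read_msi_text <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  hdr <- grepl("^#", lines)
  header <- lines[hdr]
  body <- lines[!hdr]
  body <- body[nzchar(trimws(body))]

  get1 <- function(key, required = TRUE) {
    hit <- grep(paste0("^#", key, " "), header, value = TRUE)
    if (!length(hit)) {
      if (required) stop("parse error: missing header line #", key)
      return(NULL)
    }
    sub(paste0("^#", key, " +"), "", hit[1])
  }
  gr <- strsplit(trimws(get1("grid")), "[[:space:]]+")[[1]]
  if (length(gr) != 2L || anyNA(suppressWarnings(as.integer(gr))))
    stop("parse error in header line '#grid': expected '#grid ROWS COLS'")
  grid <- as.integer(gr)
  mzs <- suppressWarnings(as.numeric(
    strsplit(trimws(get1("mz")), "[[:space:]]+")[[1]]))
  if (anyNA(mzs)) stop("parse error in header line '#mz': non-numeric value")
  axis <- mass_axis(mzs)

  sample_id <- "S1"; patient_id <- "P1"
  sp <- get1("sample", required = FALSE)
  if (!is.null(sp)) {
    tok <- strsplit(trimws(sp), "[[:space:]]+")[[1]]
    sample_id <- tok[1]
    if (length(tok) >= 3L && tok[2] == "patient") patient_id <- tok[3]
  }
  spacing <- get1("spacing", required = FALSE)
  spacing <- if (is.null(spacing)) 200 else as.numeric(spacing)

  n_pix <- prod(grid)
  flagged_bg <- rep(FALSE, n_pix)
  for (bl in grep("^#background ", header, value = TRUE)) {
    co <- suppressWarnings(as.integer(
      strsplit(trimws(sub("^#background +", "", bl)), "[[:space:]]+")[[1]]))
    if (anyNA(co) || length(co) %% 2L != 0L)
      stop("parse error in header line '#background'")
    if (length(co))
      flagged_bg[pixel_index(co[c(TRUE, FALSE)], co[c(FALSE, TRUE)],
                             grid)] <- TRUE
  }
  intens <- matrix(0, n_pix, length(axis))
  seen <- rep(FALSE, n_pix)
  for (ln in body) {
    vals <- suppressWarnings(as.numeric(strsplit(trimws(ln), "[[:space:]]+")[[1]]))
    if (anyNA(vals)) stop("parse error: non-numeric value in line starting '",
                          substr(ln, 1, 30), "'")
    r <- as.integer(vals[1]); c <- as.integer(vals[2])
    if (r < 0 || r >= grid[1] || c < 0 || c >= grid[2])
      stop(sprintf("pixel (%d,%d) outside the %dx%d grid", r, c,
                   grid[1], grid[2]))
    if (length(vals) - 2L != length(axis))
      stop(sprintf(
        "dimension error at pixel (%d,%d): %d intensities, expected %d",
        r, c, length(vals) - 2L, length(axis)))
    i <- pixel_index(r, c, grid)
    intens[i, ] <- vals[-(1:2)]
    seen[i] <- TRUE
  }
  msi_sample(intens, grid, axis, sample_id = sample_id,
             patient_id = patient_id, pixel_spacing = spacing,
             background = !seen | flagged_bg)
}

#' @param sample An [msi_sample()].
#' @rdname read_msi_text
#' @export
write_msi_text <- function(sample, path) {
  stopifnot(inherits(sample, "msi_sample"))
  con <- file(path, open = "wt")
  on.exit(close(con))
  hdr <- c(
    "#desilasso-msi v1",
    sprintf("#sample %s patient %s", sample$sample_id, sample$patient_id),
    sprintf("#grid %d %d", sample$grid[1], sample$grid[2]),
    sprintf("#spacing %.17g", sample$pixel_spacing),
    paste0("#mz ", paste(sprintf("%.17g", as.numeric(sample$mz)),
                         collapse = " ")))
  if (any(sample$background)) {
    rows <- rep(seq_len(sample$grid[1]) - 1L, each = sample$grid[2])
    cols <- rep(seq_len(sample$grid[2]) - 1L, times = sample$grid[1])
    bg <- which(sample$background)
    hdr <- c(hdr, paste0("#background ",
                         paste(rbind(rows[bg], cols[bg]), collapse = " ")))
  }
  writeLines(hdr, con)
  for (r in seq_len(sample$grid[1]) - 1L) {
    for (c in seq_len(sample$grid[2]) - 1L) {
      i <- pixel_index(r, c, sample$grid)
      writeLines(paste(r, c, paste(sprintf("%.17g", sample$intensities[i, ]),
                                   collapse = " ")), con)
    }
  }
  invisible(path)
}

#' Read and write annotation masks as CSV
#'
#' The label grid is stored as a headerless CSV of label strings (one row
#' per grid row). The optional region table travels in a companion file
#' (columns `region_id, f_cancer, f_glands, f_stroma`), and the region map
#' as a headerless CSV of integer region ids (empty cells outside regions).
#'
#' @param path CSV path for the label grid.
#' @param regions_path,region_map_path Optional companion CSV paths.
#' @return `read_annotation_csv()` returns an [annotation_mask()];
#'   `write_annotation_csv()` returns `path` invisibly.
#' @export
read_annotation_csv <- function(path, regions_path = NULL,
                                region_map_path = NULL) {
  labels <- as.matrix(read.csv(path, header = FALSE,
                               colClasses = "character"))
  dimnames(labels) <- NULL
  labels[] <- trimws(labels)
  regions <- if (!is.null(regions_path)) read.csv(regions_path) else NULL
  region_map <- NULL
  if (!is.null(region_map_path)) {
    region_map <- as.matrix(read.csv(region_map_path, header = FALSE))
    dimnames(region_map) <- NULL
    mode(region_map) <- "integer"
  }
  annotation_mask(labels, regions = regions, region_map = region_map)
}

#' @param mask An [annotation_mask()].
#' @rdname read_annotation_csv
#' @export
write_annotation_csv <- function(mask, path, regions_path = NULL,
                                 region_map_path = NULL) {
  write.table(mask$labels, path, sep = ",", row.names = FALSE,
              col.names = FALSE, quote = FALSE)
  if (!is.null(regions_path) && !is.null(mask$regions))
    write.csv(mask$regions, regions_path, row.names = FALSE)
  if (!is.null(region_map_path) && !is.null(mask$region_map))
    write.table(mask$region_map, region_map_path, sep = ",",
                row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}
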