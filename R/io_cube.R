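#' Write / read a TCSPC cube (multi-page TIFF + JSON sidecar)
#'
#' The cube is stored as a multi-page 32-bit-float TIFF (one page per time
#' bin) with counts scaled into \[0,1\] by the maximum count, plus a JSON
#' sidecar (`<path>.json`) holding `period_ns`, `bin_width_ns`,
#' `pixel_size_um`, `frequency_mhz`, the scale and the dimensions.
#' Counts round-trip exactly (integer counts are far below float32's
#' 2^24 integer limit).
#'
#' @param cube a [tcspc_cube()].
#' @param path `.tif` output path; the sidecar is written next to it.
#' @return `path`, invisibly.
#' @export
write_cube <- function(cube, path) {
  stopifnot(inherits(cube, "tcspc_cube"))
  d <- dim(cube$counts)
  scale <- max(cube$counts, 1)
  pages <- lapply(seq_len(d[3]), function(k) cube$counts[, , k] / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 32, reduce = FALSE)
  meta <- list(container = "flimfret-cube", version = 1L,
               period_ns = cube$period,
               bin_width_ns = diff(cube$bin_edges)[1],
               n_bins = d[3], rows = d[1], cols = d[2],
               pixel_size_um = cube$pixel_size_um,
               frequency_mhz = cube$frequency_mhz, scale = scale)
  jsonlite::write_json(meta, sidecar(path), auto_unbox = TRUE,
                       digits = NA, na = "null")
  invisible(path)
}

#' @rdname write_cube
#' @export
read_cube <- function(path) {
  meta <- read_sidecar(path, c("period_ns", "bin_width_ns", "n_bins",
                               "rows", "cols", "scale"))
  pages <- tiff::readTIFF(path, all = TRUE)
  if (length(pages) != meta$n_bins)
    stop("cube has ", length(pages), " pages; sidecar says ", meta$n_bins)
  counts <- array(0, c(meta$rows, meta$cols, meta$n_bins))
  for (k in seq_along(pages)) counts[, , k] <- round(pages[[k]] * meta$scale)
  tcspc_cube(counts, period = meta$period_ns,
             bin_edges = seq(0, by = meta$bin_width_ns,
                             length.out = meta$n_bins + 1L),
             pixel_size_um = meta$pixel_size_um %||% NA_real_,
             frequency_mhz = meta$frequency_mhz %||% NULL)
}

#' Write / read a 2-D map (32-bit-float TIFF + JSON sidecar)
#'
#' Values are scaled into \[0,1\] by `scale = max(|x|, na.rm)` recorded in
#' the sidecar. For lifetime maps (`kind = "lifetime"`) undefined pixels
#' (`NA`) are encoded as 0 on disk (lifetimes are strictly positive) and
#' restored to `NA` on read.
#'
#' @param x numeric matrix (lifetime in ns, or intensity counts).
#' @param path `.tif` output path.
#' @param kind `"lifetime"` (NA-aware) or `"intensity"`.
#' @return `path` invisibly; `read_map` returns the matrix.
#' @export
write_map <- function(x, path, kind = c("lifetime", "intensity")) {
  kind <- match.arg(kind)
  stopifnot(is.matrix(x))
  v <- x
  if (kind == "lifetime") v[is.na(v)] <- 0
  if (any(is.na(v))) stop("intensity maps cannot contain NA")
  if (any(v < 0)) stop("map values must be non-negative")
  scale <- max(v, 1e-12)
  tiff::writeTIFF(v / scale, path, bits.per.sample = 32, reduce = FALSE)
  jsonlite::write_json(list(container = "flimfret-map", version = 1L,
                            kind = kind, scale = scale,
                            rows = nrow(x), cols = ncol(x)),
                       sidecar(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_map
#' @export
read_map <- function(path) {
  meta <- read_sidecar(path, c("kind", "scale"))
  v <- tiff::readTIFF(path) * meta$scale
  if (meta$kind == "lifetime") v[v == 0] <- NA_real_
  v
}

sidecar <- function(path) paste0(path, ".json")

read_sidecar <- function(path, required) {
  sc <- sidecar(path)
  if (!file.exists(sc)) stop("missing metadata sidecar: ", sc)
  meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
  miss <- setdiff(required, names(meta))
  if (length(miss))
    stop("sidecar is missing attribute(s): ", paste(miss, collapse = ", "))
  meta
}

CELL_TABLE_COLUMNS <- c("cell", "donor", "condition", "apparent_lifetime_ns",
                        "fret_percent", "acceptor_intensity", "tau_p_ns",
                        "tau_i_ns", "n_photons")

#' Write / read a per-cell results table (CSV)
#'
#' Fixed documented header: `cell, donor, condition, apparent_lifetime_ns,
#' fret_percent, acceptor_intensity, tau_p_ns, tau_i_ns, n_photons`
#' (missing quantities as `NA`); numbers at 15 significant digits.
#'
#' @param table data.frame containing the columns above (extra columns are
#'   kept).
#' @param path `.csv` output path.
#' @return `path` invisibly; `read_cell_table` returns the data.frame.
#' @export
write_cell_table <- function(table, path) {
  miss <- setdiff(CELL_TABLE_COLUMNS, names(table))
  for (m in miss) table[[m]] <- NA
  table <- table[, c(CELL_TABLE_COLUMNS,
                     setdiff(names(table), CELL_TABLE_COLUMNS)),
                 drop = FALSE]
  write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cell_table
#' @export
read_cell_table <- function(path) {
  tab <- read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(CELL_TABLE_COLUMNS, names(tab))
  if (length(miss))
    stop("cell table is missing column(s): ", paste(miss, collapse = ", "))
  tab
}
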