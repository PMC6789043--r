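# Plain-text readers/writers for the package's containers: tidy CSV for
# traces and OCR assays, YAML for presets, Matrix Market for UMI counts,
# JSON for ground-truth lists, multi-page TIFF for image stacks.

#' Write / read a fluorescence or voltage trace as tidy CSV
#'
#' Columns `time_s`, `value` (full double precision); voltage traces add a
#' `kind` column. Round-trips losslessly.
#'
#' @param trace A [fluor_trace] or [voltage_trace].
#' @param path File path.
#' @export
write_trace_csv <- function(trace, path) {
  df <- as.data.frame(trace)
  df$time_s <- format(df$time_s, digits = 17, trim = TRUE)
  df$value <- format(df$value, digits = 17, trim = TRUE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trace_csv
#' @export
read_trace_csv <- function(path) {
  df <- utils::read.csv(path)
  if ("kind" %in% names(df))
    voltage_trace(df$time_s, df$value, df$kind[1])
  else
    fluor_trace(df$time_s, df$value, background_corrected = NA)
}

#' Write / read an OCR assay as tidy CSV
#'
#' Long format with columns `time_s`, `value`, `well`, `segment`,
#' `cell_count`; the reader reassembles the timepoints x wells matrix.
#'
#' @param assay An [ocr_assay].
#' @param path File path.
#' @export
write_ocr_csv <- function(assay, path) {
  stopifnot(inherits(assay, "ocr_assay"))
  n_t <- nrow(assay$ocr); n_w <- ncol(assay$ocr)
  df <- data.frame(
    time_s = format(rep(assay$time, n_w), digits = 17, trim = TRUE),
    value = format(as.numeric(assay$ocr), digits = 17, trim = TRUE),
    well = rep(colnames(assay$ocr), each = n_t),
    segment = rep(assay$segments, n_w),
    cell_count = if (is.null(assay$cell_counts)) NA else
      rep(assay$cell_counts, each = n_t))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_ocr_csv
#' @export
read_ocr_csv <- function(path) {
  df <- utils::read.csv(path)
  wells <- unique(df$well)
  first <- df[df$well == wells[1], ]
  ocr <- vapply(wells, function(w) df$value[df$well == w],
                numeric(nrow(first)))
  colnames(ocr) <- wells
  counts <- if (all(is.na(df$cell_count))) NULL else
    vapply(wells, function(w) df$cell_count[df$well == w][1], numeric(1))
  ocr_assay(ocr, time = first$time_s, segments = first$segment,
            cell_counts = counts)
}

#' Write / read an image stack as multi-page TIFF
#'
#' One page per frame, 16-bit, scaled by the stack maximum; quantization to
#' 16 bits is the only loss. The intensity scale, frame rate and pixel size
#' travel in a plain-text JSON sidecar (`<path>.meta.json`).
#'
#' @param stack A [ca_stack].
#' @param path File path.
#' @export
write_stack_tiff <- function(stack, path) {
  stopifnot(inherits(stack, "ca_stack"))
  mx <- max(stack$frames)
  if (mx <= 0) mx <- 1
  pages <- lapply(seq_len(dim(stack$frames)[1]),
                  function(i) pmin(pmax(stack$frames[i, , ] / mx, 0), 1))
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
  write_truth_json(list(scale = mx, frame_rate = stack$frame_rate,
                        pixel_size = stack$pixel_size),
                   paste0(path, ".meta.json"))
  invisible(path)
}

#' @rdname write_stack_tiff
#' @export
read_stack_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  meta_path <- paste0(path, ".meta.json")
  meta <- if (file.exists(meta_path)) read_truth_json(meta_path)
          else list(scale = 1, frame_rate = 20, pixel_size = 1)
  frames <- array(0, dim = c(length(pages), nrow(pages[[1]]),
                             ncol(pages[[1]])))
  for (i in seq_along(pages)) frames[i, , ] <- pages[[i]] * meta$scale
  ca_stack(frames, frame_rate = meta$frame_rate,
           pixel_size = meta$pixel_size)
}

#' Write / read a sparse UMI matrix as Matrix Market + TSVs
#'
#' Writes `<prefix>.mtx` (genes stored column-major as cells x genes),
#' `<prefix>.barcodes.tsv` (cell ids) and `<prefix>.features.tsv` (gene
#' ids).
#'
#' @param counts Cells x genes sparse `Matrix` with dimnames.
#' @param prefix Path prefix.
#' @export
write_counts_mtx <- function(counts, prefix) {
  Matrix::writeMM(methods::as(counts, "CsparseMatrix"),
                  paste0(prefix, ".mtx"))
  writeLines(rownames(counts), paste0(prefix, ".barcodes.tsv"))
  writeLines(colnames(counts), paste0(prefix, ".features.tsv"))
  invisible(prefix)
}

#' @rdname write_counts_mtx
#' @export
read_counts_mtx <- function(prefix) {
  counts <- Matrix::readMM(paste0(prefix, ".mtx"))
  dimnames(counts) <- list(readLines(paste0(prefix, ".barcodes.tsv")),
                           readLines(paste0(prefix, ".features.tsv")))
  methods::as(counts, "CsparseMatrix")
}

#' Write / read a ground-truth list as JSON
#'
#' Serializes nested lists of numbers/strings (the generators' `truth`
#' objects) with full double precision.
#'
#' @param truth A list.
#' @param path File path.
#' @export
write_truth_json <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       null = "null", dataframe = "columns")
  invisible(path)
}

#' @rdname write_truth_json
#' @export
read_truth_json <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
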