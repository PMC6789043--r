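# Extracellular-flux (Seahorse) analysis: per-cell normalization and
# decomposition of the mitostress and palmitate assays into respiration
# components.

MITOSTRESS_SEGMENTS <- c("basal", "oligomycin", "FCCP", "antimycin_rotenone")
PALMITATE_SEGMENTS <- c("baseline", "palmitate1", "palmitate2", "etomoxir")

#' Plate OCR assay container
#'
#' @param ocr Numeric matrix, timepoints x wells, of oxygen consumption
#'   rates (pmol O2/min per well, or per cell after [normalize_ocr()]).
#' @param time Timepoints in minutes.
#' @param segments Character vector (one label per timepoint) in injection
#'   order: `basal`, `oligomycin`, `FCCP`, `antimycin_rotenone` for the
#'   mitostress assay, or `baseline`, `palmitate1`, `palmitate2`,
#'   `etomoxir` for the palmitate assay.
#' @param cell_counts Cells per well (named or positional), all positive.
#' @param normalized Whether OCR values are already per cell.
#' @return An object of class `ocr_assay`.
#' @export
ocr_assay <- function(ocr, time = seq_len(nrow(ocr)), segments,
                      cell_counts = NULL, normalized = FALSE) {
  ocr <- as.matrix(ocr)
  if (length(segments) != nrow(ocr))
    stop("one segment label per timepoint is required")
  segments <- as.character(segments)
  runs <- rle(segments)$values
  if (anyDuplicated(runs))
    stop("segment labels must appear in injection order (contiguous blocks)")
  if (any(rle(segments)$lengths < 2L))
    warning("fewer than 2 timepoints in some segments")
  if (!is.null(cell_counts)) {
    if (length(cell_counts) != ncol(ocr))
      stop("one cell count per well is required")
    if (any(!is.finite(cell_counts) | cell_counts <= 0))
      stop("cell counts must be positive")
  }
  if (is.null(colnames(ocr)))
    colnames(ocr) <- sprintf("well_%02d", seq_len(ncol(ocr)))
  structure(list(ocr = ocr, time = as.numeric(time), segments = segments,
                 cell_counts = cell_counts, normalized = isTRUE(normalized)),
            class = "ocr_assay")
}

#' @export
print.ocr_assay <- function(x, ...) {
  cat(sprintf("<ocr_assay> %d wells x %d timepoints (%s)%s\n",
              ncol(x$ocr), nrow(x$ocr),
              paste(rle(x$segments)$values, collapse = " > "),
              if (x$normalized) ", per-cell units" else ""))
  invisible(x)
}

#' Normalize OCR to the number of cells per well
#'
#' Divides every OCR value by its well's cell count; units become
#' pmoles/min/cell.
#'
#' @param assay An [ocr_assay] with cell counts.
#' @return The assay in per-cell units.
#' @export
normalize_ocr <- function(assay) {
  stopifnot(inherits(assay, "ocr_assay"))
  if (assay$normalized) return(assay)
  if (is.null(assay$cell_counts)) stop("cell counts are missing")
  assay$ocr <- sweep(assay$ocr, 2, assay$cell_counts, "/")
  assay$normalized <- TRUE
  assay
}

segment_summary <- function(assay, summary = c("mean", "last")) {
  summary <- match.arg(summary)
  segs <- unique(assay$segments)
  out <- vapply(segs, function(s) {
    rows <- which(assay$segments == s)
    if (summary == "mean") colMeans(assay$ocr[rows, , drop = FALSE])
    else assay$ocr[max(rows), ]
  }, numeric(ncol(assay$ocr)))
  if (is.null(dim(out))) out <- matrix(out, 1L, dimnames = list(NULL, segs))
  out
}

#' Mitostress respiration metrics
#'
#' Segment OCR levels (mean of the timepoints in each injection segment, or
#' the last point per segment with `summary = "last"`) are combined into:
#' basal respiration; maximal OCR (FCCP response minus post-oligomycin);
#' ATP production (basal minus post-oligomycin); proton leak
#' (post-oligomycin minus post-antimycin/rotenone); and non-mitochondrial
#' respiration (post-antimycin/rotenone level). By construction
#' `atp_production + proton_leak + non_mito = basal` exactly.
#'
#' @param assay An [ocr_assay] with the four mitostress segments.
#' @param summary `"mean"` (default) or `"last"` (last rate before the next
#'   injection, the vendor convention).
#' @return A list of class `mito_metrics` with `per_well` (data frame) and
#'   `mean` (across-well means of basal, max_ocr, atp_production,
#'   proton_leak, non_mito).
#' @export
mitostress_metrics <- function(assay, summary = c("mean", "last")) {
  stopifnot(inherits(assay, "ocr_assay"))
  missing <- setdiff(MITOSTRESS_SEGMENTS, unique(assay$segments))
  if (length(missing))
    stop("missing mitostress segment(s): ", paste(missing, collapse = ", "))
  seg <- segment_summary(assay, summary)
  if (any(seg < 0))
    warning("negative segment mean OCR; metrics computed anyway")
  per_well <- data.frame(
    well = colnames(assay$ocr),
    basal = seg[, "basal"],
    max_ocr = seg[, "FCCP"] - seg[, "oligomycin"],
    atp_production = seg[, "basal"] - seg[, "oligomycin"],
    proton_leak = seg[, "oligomycin"] - seg[, "antimycin_rotenone"],
    non_mito = seg[, "antimycin_rotenone"],
    row.names = NULL)
  structure(list(per_well = per_well,
                 mean = colMeans(per_well[, -1]),
                 units = if (assay$normalized) "pmoles/min/cell"
                         else "pmol/min/well",
                 summary = match.arg(summary)),
            class = "mito_metrics")
}

#' @export
print.mito_metrics <- function(x, ...) {
  cat(sprintf("<mito_metrics> %d wells (%s), segment summary '%s'\n",
              nrow(x$per_well), x$units, x$summary))
  print(round(x$mean, 3))
  invisible(x)
}

#' Palmitate utilization
#'
#' The capacity to oxidize exogenous palmitate: the mean OCR over the
#' second-palmitate segment minus the final respiration value before the
#' second palmitate addition (last timepoint of the first-palmitate
#' segment).
#'
#' @param assay An [ocr_assay] with the palmitate-assay segments.
#' @return A list of class `palmitate_metrics` with `per_well` and `mean`
#'   utilization.
#' @export
palmitate_utilization <- function(assay) {
  stopifnot(inherits(assay, "ocr_assay"))
  if (!"palmitate2" %in% assay$segments)
    stop("missing palmitate2 segment")
  if (!"palmitate1" %in% assay$segments)
    stop("missing palmitate1 segment")
  p2 <- colMeans(assay$ocr[assay$segments == "palmitate2", , drop = FALSE])
  p1_last <- assay$ocr[max(which(assay$segments == "palmitate1")), ]
  util <- p2 - p1_last
  structure(list(per_well = data.frame(well = colnames(assay$ocr),
                                       utilization = util, row.names = NULL),
                 mean = mean(util),
                 units = if (assay$normalized) "pmoles/min/cell"
                         else "pmol/min/well"),
            class = "palmitate_metrics")
}

#' @export
print.palmitate_metrics <- function(x, ...) {
  cat(sprintf("<palmitate_metrics> mean utilization %.3f %s over %d wells\n",
              x$mean, x$units, nrow(x$per_well)))
  invisible(x)
}

#' Generate a synthetic plate OCR assay
#'
#' Builds per-segment plateau time courses whose noiseless metric
#' decomposition returns the preset targets exactly. For the mitostress
#' assay the per-cell plateaus are reconstructed from the preset's printed
#' differences (`max_ocr`, `atp_production`, `proton_leak`) on top of a
#' non-mitochondrial floor that the source does not print (`non_mito`
#' argument, default 10 pmoles/min/cell). Well-level OCR is plateau x cell
#' count plus optional Gaussian noise.
#'
#' @param preset Preset object or name (mitostress assay).
#' @param assay `"mitostress"` or `"palmitate"`.
#' @param wells Number of wells.
#' @param cells_per_well Cells per well (seeding density 50,000 in the
#'   source protocol).
#' @param points_per_segment Timepoints per injection segment.
#' @param non_mito Non-mitochondrial per-cell OCR plateau (mitostress).
#' @param palmitate_baseline,palmitate_step1,palmitate_utilization Per-cell
#'   plateaus for the palmitate assay (no values are printed in the source;
#'   synthetic defaults).
#' @param noise A [noise_model()] on well-level OCR.
#' @return A list of class `ocr_sim` with `assay` ([ocr_assay], well-level
#'   units) and `truth` (per-cell plateaus and the exact metric values).
#' @export
gen_ocr <- function(preset = "WT_12D_GlcFA",
                    assay = c("mitostress", "palmitate"),
                    wells = 6L, cells_per_well = 50000,
                    points_per_segment = 3L, non_mito = 10,
                    palmitate_baseline = 50, palmitate_step1 = 5,
                    palmitate_utilization = 20,
                    noise = noise_model("none")) {
  assay <- match.arg(assay)
  stopifnot(inherits(noise, "noise_model"))
  if (wells < 1L) stop("at least one well is required")
  if (assay == "mitostress") {
    preset <- cp_preset(preset)
    leak <- preset_value(preset, "proton_leak")
    atp <- preset_value(preset, "atp_production")
    maxo <- preset_value(preset, "max_ocr")
    plateaus <- c(basal = non_mito + leak + atp,
                  oligomycin = non_mito + leak,
                  FCCP = non_mito + leak + maxo,
                  antimycin_rotenone = non_mito)
    segments <- rep(MITOSTRESS_SEGMENTS, each = points_per_segment)
    truth_metrics <- list(basal = unname(plateaus["basal"]),
                          max_ocr = maxo, atp_production = atp,
                          proton_leak = leak, non_mito = non_mito)
    preset_name <- preset$name
  } else {
    plateaus <- c(baseline = palmitate_baseline,
                  palmitate1 = palmitate_baseline + palmitate_step1,
                  palmitate2 = palmitate_baseline + palmitate_step1 +
                    palmitate_utilization,
                  etomoxir = palmitate_baseline)
    segments <- rep(PALMITATE_SEGMENTS, each = points_per_segment)
    truth_metrics <- list(utilization = palmitate_utilization)
    preset_name <- NA_character_
  }
  if (any(plateaus < 0)) stop("negative OCR plateau")
  per_cell <- rep(plateaus, each = points_per_segment)
  ocr <- matrix(per_cell * cells_per_well, nrow = length(per_cell),
                ncol = wells)
  ocr <- matrix(apply_noise(as.numeric(ocr), noise), nrow = nrow(ocr))
  out <- ocr_assay(ocr, time = 6.5 * seq_len(nrow(ocr)), segments = segments,
                   cell_counts = rep(cells_per_well, wells))
  structure(list(assay = out,
                 truth = c(list(preset = preset_name, plateaus = plateaus,
                                cells_per_well = cells_per_well),
                           truth_metrics)),
            class = "ocr_sim")
}
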