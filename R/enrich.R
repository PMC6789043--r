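# Transcriptomic scoring: fold-change DE sets, hypergeometric pathway
# enrichment, the pathway x condition net-benefit maturation matrix,
# single-cell QC filtering, and cluster z-score summaries.

#' Expression table container
#'
#' @param expr Non-negative numeric matrix, genes x samples, of normalized
#'   expression. Gene ids (rownames) must be unique.
#' @param condition Condition label per sample (the control is conventionally
#'   `"EV"`).
#' @return An object of class `expression_table`.
#' @export
expression_table <- function(expr, condition) {
  expr <- as.matrix(expr)
  if (any(expr < 0)) stop("expression values must be non-negative")
  if (is.null(rownames(expr)) || anyDuplicated(rownames(expr)))
    stop("unique gene ids are required as rownames")
  if (length(condition) != ncol(expr))
    stop("one condition label per sample is required")
  structure(list(expr = expr, condition = as.character(condition)),
            class = "expression_table")
}

#' @export
print.expression_table <- function(x, ...) {
  cat(sprintf("<expression_table> %d genes x %d samples (%s)\n",
              nrow(x$expr), ncol(x$expr),
              paste(unique(x$condition), collapse = ", ")))
  invisible(x)
}

#' Fold-change differential expression sets
#'
#' Mean normalized expression per group with a pseudocount; genes with
#' total expression at or below the floor (summed over the two groups'
#' samples) are excluded. Upregulated: fold strictly greater than
#' `fold_threshold`; downregulated: fold strictly less than
#' `1/fold_threshold` (the ratio-scale reading of a -1.5-fold change).
#' A fold of exactly 1.5 falls in neither set.
#'
#' @param table An [expression_table].
#' @param condition,control Condition labels to compare.
#' @param fold_threshold Fold-change threshold (1.5).
#' @param pseudocount Added to both group means before the ratio.
#' @param min_total Expression floor: genes kept when their total normalized
#'   expression across the compared samples exceeds this value.
#' @return A list of class `de_sets`: `up`, `down` (character vectors),
#'   `fold` (named vector over tested genes), `tested`.
#' @export
de_sets <- function(table, condition, control = "EV", fold_threshold = 1.5,
                    pseudocount = 1, min_total = 1) {
  stopifnot(inherits(table, "expression_table"))
  for (g in c(condition, control))
    if (!g %in% table$condition) stop(sprintf("condition '%s' absent", g))
  cols <- table$condition %in% c(condition, control)
  keep <- rowSums(table$expr[, cols, drop = FALSE]) > min_total
  m_cond <- rowMeans(table$expr[keep, table$condition == condition,
                                drop = FALSE])
  m_ctrl <- rowMeans(table$expr[keep, table$condition == control,
                                drop = FALSE])
  fold <- (m_cond + pseudocount) / (m_ctrl + pseudocount)
  structure(list(up = names(fold)[fold > fold_threshold],
                 down = names(fold)[fold < 1 / fold_threshold],
                 fold = fold, tested = names(fold),
                 condition = condition, control = control),
            class = "de_sets")
}

#' @export
print.de_sets <- function(x, ...) {
  cat(sprintf("<de_sets> %s vs %s: %d up, %d down of %d tested genes\n",
              x$condition, x$control, length(x$up), length(x$down),
              length(x$tested)))
  invisible(x)
}

#' Upper-tail hypergeometric enrichment p-value
#'
#' Probability of observing at least the actual overlap between a gene set
#' and a pathway when drawing `|set|` genes without replacement from the
#' universe: `P(X >= overlap)` with population `|universe|`, successes
#' `|pathway|`, draws `|set|`.
#'
#' @param set,pathway Character vectors, both subsets of `universe`.
#' @param universe Character vector of all eligible genes.
#' @return The p-value in (0, 1].
#' @export
hypergeom_enrichment <- function(set, pathway, universe) {
  universe <- unique(universe)
  if (!length(universe)) stop("empty universe")
  set <- unique(set); pathway <- unique(pathway)
  if (length(setdiff(set, universe)) || length(setdiff(pathway, universe)))
    stop("set and pathway must be subsets of the universe")
  k <- length(intersect(set, pathway))
  stats::phyper(k - 1, length(pathway), length(universe) - length(pathway),
                length(set), lower.tail = FALSE)
}

#' Pathway collection
#'
#' @param sets Named list of gene-id vectors.
#' @param universe All eligible gene ids; every set must be a subset.
#' @return An object of class `pathway_collection`.
#' @export
pathway_collection <- function(sets, universe) {
  universe <- unique(universe)
  if (is.null(names(sets)) || anyDuplicated(names(sets)))
    stop("pathway sets must be uniquely named")
  sets <- lapply(sets, function(s) unique(as.character(s)))
  bad <- vapply(sets, function(s) length(setdiff(s, universe)) > 0, logical(1))
  if (any(bad))
    stop("pathways outside the universe: ", paste(names(sets)[bad],
                                                  collapse = ", "))
  structure(list(sets = sets, universe = universe),
            class = "pathway_collection")
}

#' Net-benefit maturation score matrix
#'
#' For every (pathway, condition) pair, hypergeometric enrichment p-values
#' are computed separately for the up- and downregulated gene sets of the
#' condition-vs-control comparison, and combined into the net-benefit score
#' `-log10(p_up / p_down) = log10(p_down) - log10(p_up)`. Positive scores
#' mean the treatment preferentially upregulates the pathway's genes;
#' swapping the up and down sets flips the sign.
#'
#' @param table An [expression_table].
#' @param collection A [pathway_collection] (the curated maturation
#'   collection has 7 pathways).
#' @param conditions Conditions to score; defaults to every non-control
#'   condition in the table.
#' @param control Control label.
#' @param ... Passed to [de_sets()].
#' @return A list of class `net_benefit`: matrices `score`, `p_up`,
#'   `p_down` (pathways x conditions).
#' @export
net_benefit_matrix <- function(table, collection, conditions = NULL,
                               control = "EV", ...) {
  stopifnot(inherits(table, "expression_table"),
            inherits(collection, "pathway_collection"))
  if (is.null(conditions))
    conditions <- setdiff(unique(table$condition), control)
  if (!length(conditions)) stop("at least one condition is required")
  m <- length(collection$sets); n <- length(conditions)
  score <- p_up <- p_down <- matrix(
    NA_real_, m, n, dimnames = list(names(collection$sets), conditions))
  for (j in seq_len(n)) {
    de <- de_sets(table, conditions[j], control, ...)
    uni <- intersect(collection$universe, de$tested)
    up <- intersect(de$up, uni); down <- intersect(de$down, uni)
    for (i in seq_len(m)) {
      pw <- intersect(collection$sets[[i]], uni)
      p_up[i, j] <- hypergeom_enrichment(up, pw, uni)
      p_down[i, j] <- hypergeom_enrichment(down, pw, uni)
      score[i, j] <- log10(p_down[i, j]) - log10(p_up[i, j])
    }
  }
  structure(list(score = score, p_up = p_up, p_down = p_down,
                 control = control),
            class = "net_benefit")
}

#' @export
print.net_benefit <- function(x, ...) {
  cat(sprintf("<net_benefit> %d pathways x %d conditions (vs %s)\n",
              nrow(x$score), ncol(x$score), x$control))
  print(round(x$score, 3))
  invisible(x)
}

#' Write / read a net-benefit matrix as CSV
#'
#' Serializes the score matrix with row (pathway) and column (condition)
#' labels; the reader restores the labeled matrix.
#' @param x A `net_benefit` object or a labeled numeric matrix.
#' @param path File path.
#' @export
write_net_benefit_csv <- function(x, path) {
  m <- if (inherits(x, "net_benefit")) x$score else as.matrix(x)
  utils::write.csv(data.frame(pathway = rownames(m),
                              m, check.names = FALSE),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_net_benefit_csv
#' @export
read_net_benefit_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' Single-cell QC filter
#'
#' A cell is kept iff its mitochondrial read fraction is at most `max_mito`
#' AND it has at least `min_genes` detected genes AND at least `min_umis`
#' total UMIs ("more than"/"less than" removal thresholds are strict, so a
#' cell exactly at a boundary passes).
#'
#' @param counts Cells x genes matrix of UMI counts (dense or sparse
#'   `Matrix`), with gene names as colnames.
#' @param mito_genes Character vector of mitochondrial gene ids, or `NULL`
#'   to match `mito_pattern` against the gene names.
#' @param mito_pattern Regular expression identifying mitochondrial genes.
#' @param max_mito,min_genes,min_umis QC thresholds (0.40, 200, 2000).
#' @return A list of class `qc_filter`: `counts` (filtered matrix),
#'   `per_cell` (data frame of UMIs, detected genes, mito fraction, keep
#'   flag and failure reasons), `removed` (named counts by reason, plus
#'   `total`).
#' @export
qc_filter_cells <- function(counts, mito_genes = NULL, mito_pattern = "^MT-",
                            max_mito = 0.40, min_genes = 200L,
                            min_umis = 2000L) {
  if (is.null(colnames(counts))) stop("gene names are required as colnames")
  if (is.null(mito_genes))
    mito_genes <- grep(mito_pattern, colnames(counts), value = TRUE)
  if (!length(mito_genes)) stop("no mitochondrial gene annotation available")
  umis <- Matrix::rowSums(counts)
  genes <- Matrix::rowSums(counts > 0)
  mito <- Matrix::rowSums(counts[, colnames(counts) %in% mito_genes,
                                 drop = FALSE]) / pmax(umis, 1)
  fail_mito <- mito > max_mito
  fail_genes <- genes < min_genes
  fail_umis <- umis < min_umis
  keep <- !(fail_mito | fail_genes | fail_umis)
  reason <- ifelse(keep, "",
                   paste0(ifelse(fail_mito, "mito;", ""),
                          ifelse(fail_genes, "genes;", ""),
                          ifelse(fail_umis, "umis;", "")))
  per_cell <- data.frame(cell = if (is.null(rownames(counts)))
                           seq_len(nrow(counts)) else rownames(counts),
                         umis = as.numeric(umis), genes = as.numeric(genes),
                         mito_fraction = as.numeric(mito),
                         keep = keep, reason = sub(";$", "", reason),
                         row.names = NULL)
  structure(list(counts = counts[keep, , drop = FALSE],
                 per_cell = per_cell,
                 removed = c(mito = sum(fail_mito), genes = sum(fail_genes),
                             umis = sum(fail_umis), total = sum(!keep))),
            class = "qc_filter")
}

#' @export
print.qc_filter <- function(x, ...) {
  cat(sprintf("<qc_filter> kept %d of %d cells (removed: %d mito, %d genes, %d umis)\n",
              nrow(x$counts), nrow(x$per_cell),
              x$removed["mito"], x$removed["genes"], x$removed["umis"]))
  invisible(x)
}

#' Marker x cluster z-score matrix
#'
#' Each marker gene's expression is z-scored across all cells, then averaged
#' within each cluster (the normalization used for cluster heat maps).
#' Zero-variance genes cannot be z-scored; their rows are returned as `NA`
#' and flagged rather than propagating `NaN`.
#'
#' @param expr Cells x genes expression matrix.
#' @param clusters Cluster label per cell.
#' @param markers Marker gene ids (must be columns of `expr`).
#' @return A list of class `cluster_zscores`: `z` (markers x clusters mean
#'   z-scores), `flagged` (zero-variance markers).
#' @export
cluster_zscores <- function(expr, clusters, markers) {
  if (length(clusters) != nrow(expr))
    stop("one cluster label per cell is required")
  missing <- setdiff(markers, colnames(expr))
  if (length(missing)) stop("markers absent from the matrix: ",
                            paste(missing, collapse = ", "))
  cl <- sort(unique(as.character(clusters)))
  z <- matrix(NA_real_, length(markers), length(cl),
              dimnames = list(markers, cl))
  flagged <- character(0)
  for (g in markers) {
    x <- as.numeric(expr[, g])
    s <- stats::sd(x)
    if (!is.finite(s) || s == 0) { flagged <- c(flagged, g); next }
    zx <- (x - mean(x)) / s
    z[g, ] <- vapply(cl, function(k) mean(zx[clusters == k]), numeric(1))
  }
  structure(list(z = z, flagged = flagged), class = "cluster_zscores")
}

#' @export
print.cluster_zscores <- function(x, ...) {
  cat(sprintf("<cluster_zscores> %d markers x %d clusters%s\n",
              nrow(x$z), ncol(x$z),
              if (length(x$flagged))
                paste0(" (flagged zero-variance: ",
                       paste(x$flagged, collapse = ", "), ")") else ""))
  print(round(x$z, 3))
  invisible(x)
}
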