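# Synthetic omics tables: bulk expression with planted fold changes, sparse
# cell x gene UMI matrices with planted QC failures, and lipid tables in the
# package's species dialect.

#' Generate synthetic omics inputs with known ground truth
#'
#' \describe{
#'   \item{`bulk_expr`}{Normalized genes x samples expression with planted
#'     up-/downregulated genes whose fold changes exceed the 1.5-fold
#'     threshold by construction (after the analysis pseudocount).}
#'   \item{`sc_counts`}{Sparse cells x genes UMI matrix with planted
#'     QC-failing cells that violate exactly one stated threshold each
#'     (mitochondrial fraction above 0.40, fewer than 200 detected genes, or
#'     fewer than 2000 UMIs); all other cells pass comfortably.}
#'   \item{`lipid_table`}{Abundance table whose species names cover every
#'     summarized class (cardiolipins including `tetra[18:2]-CL`,
#'     acyl-carnitines plain and hydroxylated, triglycerides, free fatty
#'     acids, plus an unidentified feature), with planted group effects.}
#' }
#'
#' @param kind One of `"bulk_expr"`, `"sc_counts"`, `"lipid_table"`.
#' @param seed Integer seed; generation is reproducible given the seed.
#' @param n_genes,samples_per_group Bulk design (`samples_per_group` is a
#'   named vector; the first name is the control).
#' @param n_up,n_down,up_fold,down_fold Planted differential genes.
#' @param noise_cv Multiplicative log-normal noise CV (0 for exact means).
#' @param n_cells,n_sc_genes,n_mito_genes Single-cell design.
#' @param fail_mito,fail_genes,fail_umis Planted QC-failing cell counts.
#' @param lipid_groups Named vector of samples per lipid group (first is the
#'   reference).
#' @return A list with the generated `table`/`counts` and a `truth` list
#'   naming every planted effect.
#' @export
gen_omics <- function(kind = c("bulk_expr", "sc_counts", "lipid_table"),
                      seed = 1L,
                      n_genes = 200L,
                      samples_per_group = c(EV = 3L, MiMaC = 3L),
                      n_up = 10L, n_down = 10L,
                      up_fold = 2, down_fold = 0.5, noise_cv = 0,
                      n_cells = 60L, n_sc_genes = 400L, n_mito_genes = 10L,
                      fail_mito = 3L, fail_genes = 2L, fail_umis = 2L,
                      lipid_groups = c(WT = 3L, Mut = 3L, KO = 3L)) {
  kind <- match.arg(kind)
  switch(kind,
         bulk_expr = gen_bulk_expr(seed, n_genes, samples_per_group,
                                   n_up, n_down, up_fold, down_fold,
                                   noise_cv),
         sc_counts = gen_sc_counts(seed, n_cells, n_sc_genes, n_mito_genes,
                                   fail_mito, fail_genes, fail_umis),
         lipid_table = gen_lipid_table(seed, lipid_groups))
}

gen_bulk_expr <- function(seed, n_genes, samples_per_group, n_up, n_down,
                          up_fold, down_fold, noise_cv) {
  if (!length(samples_per_group) || any(samples_per_group < 1L))
    stop("empty design")
  if (n_up + n_down > n_genes) stop("more planted genes than genes")
  if (up_fold <= 1.5 || down_fold >= 1 / 1.5)
    stop("planted folds must exceed the 1.5-fold detection threshold")
  groups <- rep(names(samples_per_group), samples_per_group)
  control <- names(samples_per_group)[1]
  with_seed(seed, {
    base <- stats::rlnorm(n_genes, meanlog = 4, sdlog = 1) + 5
    genes <- sprintf("G%04d", seq_len(n_genes))
    up <- genes[seq_len(n_up)]
    down <- genes[n_up + seq_len(n_down)]
    expr <- matrix(base, n_genes, length(groups),
                   dimnames = list(genes, NULL))
    for (j in which(groups != control)) {
      expr[up, j] <- base[seq_len(n_up)] * up_fold
      expr[down, j] <- base[n_up + seq_len(n_down)] * down_fold
    }
    if (noise_cv > 0)
      expr <- expr * matrix(stats::rlnorm(length(expr),
                                          sdlog = sqrt(log(1 + noise_cv^2))),
                            nrow(expr))
    colnames(expr) <- sprintf("%s_%d", groups, stats::ave(seq_along(groups),
                                                          groups,
                                                          FUN = seq_along))
    list(table = expression_table(expr, groups),
         truth = list(up = up, down = down, control = control,
                      up_fold = up_fold, down_fold = down_fold))
  })
}

gen_sc_counts <- function(seed, n_cells, n_genes, n_mito_genes,
                          fail_mito, fail_genes, fail_umis) {
  n_fail <- fail_mito + fail_genes + fail_umis
  if (n_fail >= n_cells) stop("more planted failures than cells")
  if (n_genes <= n_mito_genes + 250L)
    stop("need enough nuclear genes for passing cells")
  genes <- c(sprintf("MT-%d", seq_len(n_mito_genes)),
             sprintf("GENE%04d", seq_len(n_genes - n_mito_genes)))
  nuclear <- setdiff(genes, grep("^MT-", genes, value = TRUE))
  with_seed(seed, {
    rows <- list()
    add_cell <- function(cell, n_detect, total, mito_frac) {
      n_mito_umi <- round(total * mito_frac)
      n_nuc_umi <- total - n_mito_umi
      picked <- sample(nuclear, n_detect - 1L)
      alloc <- stats::rmultinom(1, n_nuc_umi, rep(1, length(picked)))[, 1]
      # guarantee every picked gene is detected
      zero <- alloc == 0
      alloc[zero] <- 1L
      alloc[which.max(alloc)] <- alloc[which.max(alloc)] -
        (sum(alloc) - n_nuc_umi)
      data.frame(cell = cell,
                 gene = c(picked, "MT-1"),
                 count = c(alloc, n_mito_umi))
    }
    cell_id <- 0L
    truth <- data.frame(cell = character(0), reason = character(0))
    for (i in seq_len(n_cells - n_fail)) {
      cell_id <- cell_id + 1L
      rows[[cell_id]] <- add_cell(sprintf("CELL%03d", cell_id),
                                  n_detect = 300L, total = 4000L,
                                  mito_frac = 0.05)
    }
    plant <- function(k, reason, n_detect, total, mito_frac) {
      for (i in seq_len(k)) {
        cell_id <<- cell_id + 1L
        nm <- sprintf("CELL%03d", cell_id)
        rows[[cell_id]] <<- add_cell(nm, n_detect, total, mito_frac)
        truth <<- rbind(truth, data.frame(cell = nm, reason = reason))
      }
    }
    plant(fail_mito, "mito", n_detect = 300L, total = 4000L,
          mito_frac = 0.45)
    plant(fail_genes, "genes", n_detect = 150L, total = 4000L,
          mito_frac = 0.05)
    plant(fail_umis, "umis", n_detect = 300L, total = 1500L,
          mito_frac = 0.05)
    long <- do.call(rbind, rows)
    counts <- Matrix::sparseMatrix(
      i = match(long$cell, unique(long$cell)),
      j = match(long$gene, genes),
      x = long$count,
      dims = c(cell_id, length(genes)),
      dimnames = list(unique(long$cell), genes))
    list(counts = counts,
         truth = list(failing = truth,
                      n_pass = n_cells - n_fail,
                      removed = c(mito = fail_mito, genes = fail_genes,
                                  umis = fail_umis, total = n_fail)))
  })
}

gen_lipid_table <- function(seed, lipid_groups) {
  if (!length(lipid_groups) || any(lipid_groups < 1L)) stop("empty design")
  species <- c("tetra[18:2]-CL", "[18:1][18:1][18:2][18:2]",
               "CL(14:0/18:1/18:2/18:2)", "CL(16:0/18:1/18:2/20:2)",
               "MLCL(18:1/18:2/18:2)",
               "AC(16:0)", "AC(18:1)", "AC(8:0)",
               "AC(16:0-OH)", "AC(18:1-OH)", "AC(8:0-OH)",
               "TG(16:0/18:1/18:2)", "TG(18:1/18:1/18:2)",
               "FFA(16:1)", "FFA(18:1)",
               "unknown_feature_001")
  groups <- rep(names(lipid_groups), lipid_groups)
  # planted group effects on the disease-relevant classes (multiplicative)
  effect <- function(sp, g) {
    if (g == names(lipid_groups)[1]) return(1)
    long_ac <- grepl("^AC\\(1[4-9]|^AC\\(2\\d", sp)
    if (long_ac && !grepl("-OH", sp)) return(3)
    if (long_ac && grepl("-OH", sp)) return(10)
    if (grepl("^TG", sp)) return(2)
    if (sp == "tetra[18:2]-CL") return(0.4)
    if (grepl("14:0", sp)) return(2.5)
    1
  }
  with_seed(seed, {
    base <- stats::rlnorm(length(species), meanlog = 8, sdlog = 0.5)
    ab <- matrix(0, length(species), length(groups),
                 dimnames = list(species,
                                 sprintf("%s_%d", groups,
                                         stats::ave(seq_along(groups), groups,
                                                    FUN = seq_along))))
    for (j in seq_along(groups))
      ab[, j] <- base * vapply(species, effect, numeric(1), g = groups[j]) *
        stats::rlnorm(length(species), sdlog = 0.05)
    tab <- lipid_table(ab, groups)
    list(table = tab,
         truth = list(base = stats::setNames(base, species),
                      reference = names(lipid_groups)[1]))
  })
}
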