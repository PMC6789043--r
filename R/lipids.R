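# Lipidomics: annotation parsing for cardiolipins, acyl-carnitines,
# triglycerides and free fatty acids; mTIC normalization; class summaries
# and cardiolipin acyl-chain queries.

CHAIN_COUNT <- c(CL = 4L, MLCL = 3L, TG = 3L, AC = 1L, FFA = 1L)

parse_chain_token <- function(tok, raw, pos) {
  m <- regmatches(tok, regexec("^(\\d+):(\\d+)(-OH)?$", tok))[[1]]
  if (!length(m))
    stop(lipid_parse_error(raw, pos,
                           sprintf("malformed acyl chain '%s'", tok)))
  list(carbons = as.integer(m[2]), double_bonds = as.integer(m[3]),
       hydroxyl = m[4] == "-OH")
}

lipid_parse_error <- function(raw, position, msg) {
  structure(class = c("lipid_parse_error", "error", "condition"),
            list(message = sprintf("cannot parse '%s' at position %d: %s",
                                   raw, position, msg),
                 call = NULL, raw = raw, position = position))
}

#' Parse a lipid species annotation
#'
#' Grammar (the dialect used for cardiolipin and fatty-acid species):
#' `"CL(a:b/c:d/e:f/g:h)"`, the 4-chain bracket shorthand
#' `"[a:b][c:d][e:f][g:h]"`, the symmetric form `"tetra[a:b]-CL"` (expands
#' to four identical chains), `"MLCL(a:b/c:d/e:f)"`, `"TG(a:b/c:d/e:f)"`,
#' `"AC(a:b)"`, `"FFA(a:b)"`. Any chain may carry an `-OH` suffix marking
#' hydroxylation, e.g. `"AC(16:0-OH)"`. Chain counts are enforced per
#' class: CL 4, MLCL 3, TG 3, AC and FFA 1.
#'
#' @param raw Species name string.
#' @return An object of class `lipid_species`: `raw_name`, `lipid_class`,
#'   and `chains` (data frame of `carbons`, `double_bonds`, `hydroxyl`).
#'   Unparseable names raise a typed condition (`lipid_parse_error`) with
#'   the failing position.
#' @export
parse_lipid_name <- function(raw) {
  stopifnot(is.character(raw), length(raw) == 1L)
  m <- regmatches(raw, regexec("^tetra\\[(\\d+:\\d+(-OH)?)\\]-CL$", raw))[[1]]
  if (length(m)) {
    ch <- parse_chain_token(m[2], raw, 7L)
    return(new_lipid_species(raw, "CL", rep(list(ch), 4L)))
  }
  if (grepl("^\\[", raw)) {
    toks <- regmatches(raw, gregexpr("\\[([^]]*)\\]", raw))[[1]]
    if (nchar(paste(toks, collapse = "")) != nchar(raw))
      stop(lipid_parse_error(raw, 1L, "stray text around bracket chains"))
    if (length(toks) != 4L)
      stop(lipid_parse_error(raw, 1L,
                             "bracket shorthand requires 4 chains (CL)"))
    chains <- lapply(seq_along(toks), function(i)
      parse_chain_token(gsub("\\[|\\]", "", toks[i]), raw, i))
    return(new_lipid_species(raw, "CL", chains))
  }
  m <- regmatches(raw, regexec("^(CL|MLCL|TG|AC|FFA)\\(([^)]*)\\)$", raw))[[1]]
  if (!length(m))
    stop(lipid_parse_error(raw, 1L, "unrecognized lipid class or syntax"))
  cls <- m[2]
  toks <- strsplit(m[3], "/", fixed = TRUE)[[1]]
  want <- CHAIN_COUNT[[cls]]
  if (length(toks) != want)
    stop(lipid_parse_error(raw, nchar(cls) + 2L,
                           sprintf("%s requires %d chain(s), got %d",
                                   cls, want, length(toks))))
  chains <- lapply(seq_along(toks), function(i)
    parse_chain_token(toks[i], raw, nchar(cls) + 1L + i))
  new_lipid_species(raw, cls, chains)
}

new_lipid_species <- function(raw, cls, chains) {
  df <- do.call(rbind, lapply(chains, function(ch)
    data.frame(carbons = ch$carbons, double_bonds = ch$double_bonds,
               hydroxyl = ch$hydroxyl)))
  if (any(df$carbons <= 0)) stop(lipid_parse_error(raw, 1L, "carbons must be positive"))
  structure(list(raw_name = raw, lipid_class = cls, chains = df),
            class = "lipid_species")
}

#' Render a lipid species in canonical form
#'
#' The canonical form is `CLASS(a:b/c:d/...)` with `-OH` suffixes preserved
#' (`tetra[a:b]-CL` is kept for symmetric cardiolipins). `parse -> render ->
#' parse` is the identity on the species.
#'
#' @param species A `lipid_species`.
#' @return A character string.
#' @export
render_lipid_name <- function(species) {
  stopifnot(inherits(species, "lipid_species"))
  ch <- species$chains
  tok <- paste0(ch$carbons, ":", ch$double_bonds,
                ifelse(ch$hydroxyl, "-OH", ""))
  if (species$lipid_class == "CL" && length(unique(tok)) == 1L)
    sprintf("tetra[%s]-CL", tok[1])
  else
    sprintf("%s(%s)", species$lipid_class, paste(tok, collapse = "/"))
}

#' @export
print.lipid_species <- function(x, ...) {
  cat(sprintf("<lipid_species> %s [%s] %s\n", x$raw_name, x$lipid_class,
              paste(sprintf("%d:%d%s", x$chains$carbons,
                            x$chains$double_bonds,
                            ifelse(x$chains$hydroxyl, "-OH", "")),
                    collapse = " / ")))
  invisible(x)
}

#' Lipid abundance table
#'
#' @param abundance Species x samples matrix of peak heights (>= 0), with
#'   species names as rownames.
#' @param groups Sample group label per column.
#' @param identified Logical per species: annotated ("known") species enter
#'   the mTIC sum; unknowns are carried along. Defaults to whether the name
#'   parses under the species grammar.
#' @return An object of class `lipid_table` with parsed species in
#'   `$species` (`NULL` entries for unknowns).
#' @export
lipid_table <- function(abundance, groups, identified = NULL) {
  abundance <- as.matrix(abundance)
  if (any(abundance < 0)) stop("abundances must be non-negative")
  if (is.null(rownames(abundance))) stop("species names required as rownames")
  if (length(groups) != ncol(abundance))
    stop("one group label per sample is required")
  species <- lapply(rownames(abundance), function(nm)
    tryCatch(parse_lipid_name(nm), lipid_parse_error = function(e) NULL))
  names(species) <- rownames(abundance)
  if (is.null(identified))
    identified <- !vapply(species, is.null, logical(1))
  if (!any(identified)) stop("at least one identified species is required")
  structure(list(abundance = abundance, groups = as.character(groups),
                 identified = identified, species = species,
                 normalized = FALSE),
            class = "lipid_table")
}

#' @export
print.lipid_table <- function(x, ...) {
  cat(sprintf("<lipid_table> %d species (%d identified) x %d samples (%s)%s\n",
              nrow(x$abundance), sum(x$identified), ncol(x$abundance),
              paste(unique(x$groups), collapse = ", "),
              if (x$normalized) ", mTIC-normalized" else ""))
  invisible(x)
}

#' mTIC normalization
#'
#' Scales each sample so its summed signal over identified (known) species
#' equals the cross-sample mean of those sums; unknown species are scaled by
#' the same per-sample factor.
#'
#' @param table A [lipid_table].
#' @return The normalized table.
#' @export
mtic_normalize <- function(table) {
  stopifnot(inherits(table, "lipid_table"))
  sums <- colSums(table$abundance[table$identified, , drop = FALSE])
  if (any(sums <= 0)) stop("zero identified-species sum in a sample")
  table$abundance <- sweep(table$abundance, 2, mean(sums) / sums, "*")
  table$normalized <- TRUE
  table
}

#' Lipid species predicate
#'
#' Builds a predicate over parsed species for [class_summaries()]. All
#' supplied conditions are combined with AND; chain conditions use
#' any-chain semantics. "Long-chain" is conventionally carbons >= 14 and
#' "medium-chain" 6-12.
#'
#' @param lipid_class Restrict to a class (`"CL"`, `"AC"`, `"TG"`, `"FFA"`,
#'   `"MLCL"`).
#' @param min_chain_carbons,max_chain_carbons Keep species with at least one
#'   chain whose carbon count is within these bounds.
#' @param hydroxyl `TRUE` to require a hydroxylated chain, `FALSE` to
#'   require none.
#' @param contains_chain Length-2 integer `c(carbons, double_bonds)`: keep
#'   species with at least one matching chain (e.g. `c(14, 0)` for myristic
#'   acid).
#' @return An object of class `lipid_query`.
#' @export
lipid_query <- function(lipid_class = NULL, min_chain_carbons = NULL,
                        max_chain_carbons = NULL, hydroxyl = NULL,
                        contains_chain = NULL) {
  structure(list(lipid_class = lipid_class,
                 min_chain_carbons = min_chain_carbons,
                 max_chain_carbons = max_chain_carbons,
                 hydroxyl = hydroxyl, contains_chain = contains_chain),
            class = "lipid_query")
}

query_matches <- function(query, species) {
  if (is.null(species)) return(FALSE)   # unknowns never match
  ch <- species$chains
  if (!is.null(query$lipid_class) &&
      !species$lipid_class %in% query$lipid_class) return(FALSE)
  chain_ok <- rep(TRUE, nrow(ch))
  if (!is.null(query$min_chain_carbons))
    chain_ok <- chain_ok & ch$carbons >= query$min_chain_carbons
  if (!is.null(query$max_chain_carbons))
    chain_ok <- chain_ok & ch$carbons <= query$max_chain_carbons
  if (!is.null(query$contains_chain))
    chain_ok <- chain_ok & ch$carbons == query$contains_chain[1] &
      ch$double_bonds == query$contains_chain[2]
  if (!is.null(query$min_chain_carbons) || !is.null(query$max_chain_carbons) ||
      !is.null(query$contains_chain)) {
    if (!any(chain_ok)) return(FALSE)
  }
  if (!is.null(query$hydroxyl)) {
    if (isTRUE(query$hydroxyl) && !any(ch$hydroxyl)) return(FALSE)
    if (isFALSE(query$hydroxyl) && any(ch$hydroxyl)) return(FALSE)
  }
  TRUE
}

#' Per-sample class sums under a species predicate
#'
#' Sums abundances over the species matched by `query`, per sample.
#' Canonical uses: sum of long-chain acyl-carnitines
#' (`lipid_query("AC", min_chain_carbons = 14)`), sum of hydroxylated
#' long-chain acyl-carnitines (add `hydroxyl = TRUE`), sum of
#' triglycerides, sum of cardiolipins containing a myristic (14:0) chain
#' (`lipid_query("CL", contains_chain = c(14, 0))`), cardiolipins with a
#' chain of >= 20 carbons.
#'
#' @param table A [lipid_table] (normalize first with [mtic_normalize()]).
#' @param query A [lipid_query()].
#' @return A data frame with `sample`, `group`, `sum`; matched species names
#'   in `attr(, "species")`.
#' @export
class_summaries <- function(table, query) {
  stopifnot(inherits(table, "lipid_table"), inherits(query, "lipid_query"))
  hit <- vapply(table$species, function(s) query_matches(query, s),
                logical(1))
  sums <- colSums(table$abundance[hit, , drop = FALSE])
  out <- data.frame(sample = colnames(table$abundance) %||%
                      sprintf("S%d", seq_along(sums)),
                    group = table$groups, sum = as.numeric(sums),
                    row.names = NULL)
  attr(out, "species") <- rownames(table$abundance)[hit]
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Relative amount of one cardiolipin species within the CL pool
#'
#' @param table A [lipid_table].
#' @param species Species name (e.g. `"tetra[18:2]-CL"`); matched on the
#'   parsed species, so any equivalent spelling works.
#' @return Data frame `sample`, `group`, `fraction` (species abundance over
#'   the summed CL-class abundance, per sample).
#' @export
cl_relative_amount <- function(table, species = "tetra[18:2]-CL") {
  target <- parse_lipid_name(species)
  same <- vapply(table$species, function(s) {
    !is.null(s) && s$lipid_class == target$lipid_class &&
      isTRUE(all.equal(s$chains[order(s$chains$carbons,
                                      s$chains$double_bonds), ],
                       target$chains[order(target$chains$carbons,
                                           target$chains$double_bonds), ],
                       check.attributes = FALSE))
  }, logical(1))
  if (!any(same)) stop(sprintf("species '%s' not in the table", species))
  cls <- class_summaries(table, lipid_query(target$lipid_class))
  num <- colSums(table$abundance[same, , drop = FALSE])
  data.frame(sample = cls$sample, group = cls$group,
             fraction = as.numeric(num) / cls$sum, row.names = NULL)
}

#' Species fold-change matrix against a reference group
#'
#' Every species' abundance is divided by its mean in the reference group,
#' so the reference columns average to 1. Species with zero reference mean
#' are flagged (`NA` rows) rather than producing infinities.
#'
#' @param table A [lipid_table].
#' @param reference_group Group label of the reference (e.g. the wild-type
#'   condition).
#' @return A species x samples matrix with flagged species names in
#'   `attr(, "flagged")`.
#' @export
fold_change_matrix <- function(table, reference_group) {
  stopifnot(inherits(table, "lipid_table"))
  ref_cols <- table$groups == reference_group
  if (!any(ref_cols)) stop(sprintf("reference group '%s' absent",
                                   reference_group))
  ref_mean <- rowMeans(table$abundance[, ref_cols, drop = FALSE])
  flagged <- rownames(table$abundance)[ref_mean == 0]
  if (length(flagged))
    warning("zero reference mean for some species; rows flagged NA")
  fc <- sweep(table$abundance, 1, ref_mean, "/")
  fc[ref_mean == 0, ] <- NA_real_
  attr(fc, "flagged") <- flagged
  fc
}

#' Group-presence filter
#'
#' Keeps species detected (abundance > 0) in at least `min_frac` of the
#' samples of every group, the standard reporting filter for untargeted
#' features.
#'
#' @param table A [lipid_table].
#' @param min_frac Minimum detected fraction per group.
#' @return The filtered table.
#' @export
filter_presence <- function(table, min_frac = 0.5) {
  stopifnot(inherits(table, "lipid_table"))
  keep <- rep(TRUE, nrow(table$abundance))
  for (g in unique(table$groups)) {
    cols <- table$groups == g
    frac <- rowMeans(table$abundance[, cols, drop = FALSE] > 0)
    keep <- keep & frac >= min_frac
  }
  table$abundance <- table$abundance[keep, , drop = FALSE]
  table$identified <- table$identified[keep]
  table$species <- table$species[keep]
  table
}
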