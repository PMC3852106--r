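#' Sample-level quality filtering of a CT table
#'
#' Drops samples with a failed melt-curve (no single product-specific peak)
#' or with primer dimers, then drops every sample of any cell in which the
#' reference gene GAPDH was not detected ("no GAPDH" cells are not further
#' analyzed). The cell key is `linked_cell_id` when present, otherwise
#' `sample_id`.
#'
#' @param samples Tidy CT data.frame (see [generate_qpcr_dataset()] for the
#'   expected columns; `melt_ok`/`primer_dimer` are optional and default to
#'   pass).
#' @param reference_gene Reference gene name (default `"GAPDH"`).
#' @return List with `kept` (data.frame) and `dropped` (data.frame with an
#'   added `reason` column).
#' @export
qc_filter <- function(samples, reference_gene = "GAPDH") {
  stopifnot(is.data.frame(samples), all(c("gene", "CT") %in% names(samples)))
  s <- samples
  if (is.null(s$melt_ok)) s$melt_ok <- TRUE
  if (is.null(s$primer_dimer)) s$primer_dimer <- FALSE
  if (is.null(s$detected)) s$detected <- !is.na(s$CT)
  key <- if (!is.null(s$linked_cell_id)) s$linked_cell_id else s$sample_id
  reason <- rep(NA_character_, nrow(s))
  reason[!s$melt_ok] <- "melt curve"
  reason[s$primer_dimer] <- "primer dimer"
  gap_ok_cells <- unique(key[s$gene == reference_gene & s$detected])
  has_gap_row <- key %in% unique(key[s$gene == reference_gene])
  no_gap <- is.na(reason) & (!(key %in% gap_ok_cells)) & has_gap_row
  reason[no_gap] <- paste0("no ", reference_gene)
  dropped <- s[!is.na(reason), , drop = FALSE]
  dropped$reason <- reason[!is.na(reason)]
  list(kept = s[is.na(reason), , drop = FALSE], dropped = dropped)
}

#' Primer amplification efficiency from a dilution series
#'
#' Linear regression of CT vs log10 template concentration over at least
#' five 10-fold dilutions. Reported as the conventional per-cycle gain
#' `E = 10^(-1/slope) - 1` (1 = perfect doubling), which is the reading
#' consistent with the acceptance band 0.9-1.05; the raw amplification
#' factor `10^(-1/slope)` (2 = perfect doubling) is returned alongside.
#'
#' @param log10_concentration Log10 of template concentrations.
#' @param CT Measured CT values.
#' @param band Acceptance band for `E` (default `c(0.9, 1.05)`).
#' @return List with `slope`, `E` (conventional), `amplification_factor`,
#'   `in_band` and `flagged`.
#' @export
primer_efficiency <- function(log10_concentration, CT, band = c(0.9, 1.05)) {
  stopifnot(length(log10_concentration) == length(CT))
  if (length(CT) < 5L)
    stop("insufficient data: at least five dilution points are required")
  slope <- unname(coef(lm(CT ~ log10_concentration))["log10_concentration"])
  amp <- 10^(-1 / slope)
  E <- amp - 1
  in_band <- E >= band[1] & E <= band[2]
  list(slope = slope, E = E, amplification_factor = amp,
       in_band = in_band, flagged = !in_band)
}

#' Relative quantification by the delta-delta-CT method
#'
#' `dCT = mean CT(target) - mean CT(reference)` per group,
#' `ddCT = dCT(case) - dCT(control)`, and
#' `fold = (1 + E)^(-ddCT)` with per-cycle efficiency `E` defaulting to 1
#' (perfect doubling). Without a reference gene (`ct_ref = NULL`) absolute
#' CT values are compared directly (`method = "dct_only"`), the convention
#' used at the pearl and single-cell levels.
#'
#' @param ct_target Target-gene CT values (censored values as `NA` are
#'   excluded from means).
#' @param groups Group label per element of `ct_target`.
#' @param case,control Labels of the case and control groups.
#' @param ct_ref Optional reference-gene CTs, with `ref_groups` labels.
#' @param ref_groups Group labels for `ct_ref`.
#' @param efficiency Per-cycle efficiency E (default 1).
#' @param gene,reference_gene Names carried into the result.
#' @return A `fold_change_result` list with `gene`, `dCT` (per group),
#'   `ddCT`, `fold`, `reference_gene` and `method`.
#' @export
ddct_fold <- function(ct_target, groups, case, control, ct_ref = NULL,
                      ref_groups = groups, efficiency = 1,
                      gene = "target", reference_gene = "GAPDH") {
  gmean <- function(ct, g, lev) mean(ct[g == lev], na.rm = TRUE)
  d_case <- gmean(ct_target, groups, case)
  d_ctrl <- gmean(ct_target, groups, control)
  if (!is.null(ct_ref)) {
    d_case <- d_case - gmean(ct_ref, ref_groups, case)
    d_ctrl <- d_ctrl - gmean(ct_ref, ref_groups, control)
    method <- "ddct"
  } else method <- "dct_only"
  ddct <- d_case - d_ctrl
  structure(list(gene = gene,
                 dCT = c(case = d_case, control = d_ctrl),
                 ddCT = ddct, fold = (1 + efficiency)^(-ddct),
                 reference_gene = if (method == "ddct") reference_gene else NA,
                 method = method),
            class = "fold_change_result")
}

#' Relative abundance ranking by mean CT
#'
#' Per-gene mean CT (+/- sem) over detected samples at one quantification
#' level, ranked by ascending CT (lower CT = higher abundance).
#'
#' @param samples Tidy CT data.frame.
#' @param level Optional level filter (`"tissue"`, `"pearl"`,
#'   `"single_cell"`).
#' @param group Optional group filter.
#' @return data.frame with `gene`, `mean_CT`, `sem`, `n`, ordered by
#'   ascending mean CT.
#' @export
sc_abundance <- function(samples, level = NULL, group = NULL) {
  s <- samples
  if (!is.null(level)) s <- s[s$level == level, , drop = FALSE]
  if (!is.null(group)) s <- s[s$group == group, , drop = FALSE]
  s <- s[!is.na(s$CT), , drop = FALSE]
  if (!nrow(s)) stop("no detected samples after filtering")
  agg <- do.call(rbind, lapply(split(s, s$gene), function(d)
    data.frame(gene = d$gene[1], mean_CT = mean(d$CT),
               sem = sd(d$CT) / sqrt(nrow(d)), n = nrow(d))))
  agg <- agg[order(agg$mean_CT), , drop = FALSE]
  rownames(agg) <- NULL
  agg
}

#' Pairwise co-expression of genes via z-scored CT values
#'
#' CT values (already a log2-domain quantity) are standardized per gene
#' across cells (subtract the gene mean, divide by the gene SD) and Pearson
#' correlations are computed over cells in which both genes were detected.
#'
#' @param samples Tidy single-cell CT data.frame.
#' @param genes Genes to include (default: all present).
#' @return List with matrices `r` (Pearson), `n` (pairwise cells) and `p`
#'   (two-sided, via the t transform).
#' @export
zscore_coexpression <- function(samples, genes = NULL) {
  s <- samples[!is.na(samples$CT), , drop = FALSE]
  if (is.null(genes)) genes <- sort(unique(s$gene))
  key <- if (!is.null(s$linked_cell_id)) s$linked_cell_id else s$sample_id
  cells <- unique(key)
  M <- matrix(NA_real_, length(cells), length(genes),
              dimnames = list(cells, genes))
  for (i in seq_len(nrow(s))) {
    if (s$gene[i] %in% genes) M[key[i], s$gene[i]] <- s$CT[i]
  }
  Z <- scale(M)
  ng <- length(genes)
  r <- diag(1, ng); n <- matrix(NA_real_, ng, ng); p <- matrix(NA_real_, ng, ng)
  dimnames(r) <- dimnames(n) <- dimnames(p) <- list(genes, genes)
  for (i in seq_len(ng)) for (j in seq_len(ng)) {
    ok <- stats::complete.cases(Z[, c(i, j)])
    n[i, j] <- sum(ok)
    if (i == j) { p[i, j] <- 0; next }
    if (n[i, j] >= 3) {
      r[i, j] <- cor(Z[ok, i], Z[ok, j])
      p[i, j] <- pearson_significance(r[i, j], n[i, j])$p
    } else r[i, j] <- NA_real_
  }
  list(r = r, n = n, p = p)
}

#' Correlate an electrophysiological phenotype with gene expression
#'
#' Pearson correlation of a per-cell feature (e.g. AP response delay)
#' against the expression of one gene, over cells present in both tables.
#' Expression is taken as `-CT` (lower CT = more transcript), so a positive
#' r means the feature increases with transcript abundance.
#'
#' @param features data.frame with columns `cell_id` and the feature column.
#' @param samples Tidy CT data.frame with `linked_cell_id`.
#' @param gene Gene to correlate.
#' @param feature Feature column name (default `"delay"`).
#' @param sign `"minus_ct"` (default, expression scale) or `"ct"`.
#' @return List with `r`, `n`, `p` and the joined data.
#' @export
correlate_phenotype_expression <- function(features, samples, gene,
                                           feature = "delay",
                                           sign = c("minus_ct", "ct")) {
  sign <- match.arg(sign)
  s <- samples[samples$gene == gene & !is.na(samples$CT), , drop = FALSE]
  key <- if (!is.null(s$linked_cell_id)) s$linked_cell_id else s$sample_id
  j <- match(features$cell_id, key)
  ok <- !is.na(j) & !is.na(features[[feature]])
  if (!any(ok)) stop("join error: no cells shared between features and samples")
  x <- features[[feature]][ok]
  ct <- s$CT[j[ok]]
  expr <- if (sign == "minus_ct") -ct else ct
  n <- length(x)
  if (n < 3) stop("need at least 3 joined cells")
  r <- cor(x, expr)
  list(r = r, n = n, p = pearson_significance(r, n)$p,
       data = data.frame(cell_id = features$cell_id[ok], feature = x,
                         CT = ct))
}
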