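#' Compare two rhythmic-gene result tables
#'
#' Intersects the rhythmic calls of two [detect_rhythmic()] result tables
#' from the same gene universe and bins the shared genes by circular
#' peak-phase distance: same ZT bin (0 h), within 4 h, and 8 h or more
#' off-cycle.
#'
#' @param res_a,res_b Data frames with columns `gene_id`, `is_rhythmic`,
#'   `peak_zt` over the same gene universe.
#' @param period Period in hours for circular distance.
#' @return List with `shared`, `a_only`, `b_only` (gene id vectors),
#'   `n_union`, `concordance` (named counts: `same_time`, `within_4h`,
#'   `off_cycle`) and `shared_phase` (data frame of per-gene peak phases and
#'   circular distances).
#' @export
compare_rhythmic_sets <- function(res_a, res_b, period = 24) {
  if (!setequal(res_a$gene_id, res_b$gene_id))
    stop("result tables come from different gene universes")
  a_set <- res_a$gene_id[res_a$is_rhythmic]
  b_set <- res_b$gene_id[res_b$is_rhythmic]
  shared <- intersect(a_set, b_set)
  a_only <- setdiff(a_set, b_set)
  b_only <- setdiff(b_set, a_set)

  pa <- res_a$peak_zt[match(shared, res_a$gene_id)]
  pb <- res_b$peak_zt[match(shared, res_b$gene_id)]
  raw <- abs(pa - pb) %% period
  dist <- pmin(raw, period - raw)
  conc <- c(same_time = sum(dist == 0),
            within_4h = sum(dist > 0 & dist <= 4),
            off_cycle = sum(dist > 4))
  list(shared = shared, a_only = a_only, b_only = b_only,
       n_union = length(a_set) + length(b_set) - length(shared),
       concordance = conc,
       shared_phase = data.frame(gene_id = shared, peak_a = pa, peak_b = pb,
                                 circular_distance = dist))
}

# internal: per-gene mean log2(ZT0) - mean log2(ZT12) for one group, plus
# Welch p-values if requested
zt_delta <- function(v, meta, group, with_p = FALSE) {
  s0 <- meta$sample_id[meta$group == group & meta$zt == 0]
  s12 <- meta$sample_id[meta$group == group & meta$zt == 12]
  s0 <- intersect(s0, colnames(v)); s12 <- intersect(s12, colnames(v))
  if (length(s0) == 0L || length(s12) == 0L)
    stop("group '", group, "' lacks ZT0 or ZT12 samples")
  delta <- rowMeans(v[, s0, drop = FALSE]) - rowMeans(v[, s12, drop = FALSE])
  if (!with_p) return(list(delta = delta))
  p <- apply(v, 1, function(y) {
    x0 <- y[s0]; x12 <- y[s12]
    if (stats::sd(x0) == 0 && stats::sd(x12) == 0)
      return(if (mean(x0) == mean(x12)) 1 else 0)
    stats::t.test(x0, x12)$p.value
  })
  list(delta = delta, p = p)
}

#' Select the diurnal remission-correction gene panel
#'
#' Identifies genes whose ZT0 vs ZT12 expression differs in young mice and
#' whose day/night contrast is altered in nephritic mice. On the log2 scale a
#' fold-change threshold of `fold` becomes `log2(fold)`; membership requires
#' `|delta_young| >= log2(fold)`, a BH-adjusted two-sided Welch test of
#' young ZT0 vs ZT12 with `q < alpha`, and
#' `|delta_young - delta_neph| >= log2(fold)` (the log of the ratio of
#' ZT0:ZT12 ratios).
#'
#' @param m Merged log2 `expr_matrix` with ZT0 and ZT12 samples for the
#'   young and nephritic groups.
#' @param meta Metadata data frame.
#' @param fold Fold-change threshold (default 1.25, i.e. a 25% difference).
#' @param alpha FDR threshold of the young ZT0-vs-ZT12 test.
#' @param young,nephritic Group labels.
#' @return Data frame of panel genes: `gene_id`, `delta_young`,
#'   `delta_neph`, `p_delta_young`, `q_delta_young`, `in_panel` (all `TRUE`).
#' @export
select_correction_panel <- function(m, meta, fold = 1.25, alpha = 0.05,
                                    young = "young", nephritic = "nephritic") {
  stopifnot(inherits(m, "expr_matrix"))
  v <- m$values
  dy <- zt_delta(v, meta, young, with_p = TRUE)
  dn <- zt_delta(v, meta, nephritic)
  q <- stats::p.adjust(dy$p, method = "BH")
  thr <- log2(fold)
  keep <- abs(dy$delta) >= thr & q < alpha & abs(dy$delta - dn$delta) >= thr
  data.frame(gene_id = rownames(v)[keep],
             delta_young = unname(dy$delta[keep]),
             delta_neph = unname(dn$delta[keep]),
             p_delta_young = unname(dy$p[keep]),
             q_delta_young = unname(q[keep]),
             in_panel = TRUE, row.names = NULL)
}

#' Score remission correction of panel genes
#'
#' For each panel gene, computes the remission-group ZT0 - ZT12 contrast and
#' the correction fraction
#' `c = (delta_rem - delta_neph) / (delta_young - delta_neph)`: 0 means the
#' remission contrast equals the nephritic one, 1 means full return to the
#' young contrast. A gene is `corrected` when `c >= threshold` (boundary
#' inclusive).
#'
#' @param panel Panel table from [select_correction_panel()].
#' @param m Merged log2 `expr_matrix` containing remission ZT0/ZT12 samples.
#' @param meta Metadata data frame.
#' @param threshold Correction-fraction cutoff (default 0.5).
#' @param remission Remission group label.
#' @return The panel table with added columns `delta_rem`, `correction` and
#'   `corrected`.
#' @export
classify_correction <- function(panel, m, meta, threshold = 0.5,
                                remission = "remission") {
  stopifnot(inherits(m, "expr_matrix"))
  if (nrow(panel) == 0L) {
    panel$delta_rem <- numeric(0)
    panel$correction <- numeric(0)
    panel$corrected <- logical(0)
    return(panel)
  }
  dr <- zt_delta(m$values, meta, remission)
  idx <- match(panel$gene_id, rownames(m$values))
  if (anyNA(idx)) stop("panel gene(s) missing from matrix")
  denom <- panel$delta_young - panel$delta_neph
  if (any(denom == 0))
    stop("delta_young equals delta_neph for panel gene(s); ",
         "correction fraction undefined")
  panel$delta_rem <- unname(dr$delta[idx])
  panel$correction <- (panel$delta_rem - panel$delta_neph) / denom
  # boundary inclusive; small tolerance so c = threshold survives rounding
  panel$corrected <- panel$correction >= threshold - 1e-9
  panel
}

#' Classify blood-pressure dipper status
#'
#' Computes, per mouse, the mean systolic pressure in the active (dark,
#' ZT12-24) and rest (light, ZT0-12) phases and the dip fraction
#' `d = (mean_active - mean_rest) / mean_active`. Status follows the
#' ambulatory-monitoring convention: `dipper` when `d >= dip_threshold`
#' (default 10%), `non-dipper` when `0 <= d < dip_threshold`, `reverse` when
#' `d < 0` (nocturnal pressure above active-phase pressure).
#'
#' @param bp Data frame of readings with columns `mouse_id`, `zt`, `sbp`.
#' @param dip_threshold Dip fraction defining a dipper.
#' @param lights_off ZT hour at which the active (dark) phase starts.
#' @return Data frame with one row per mouse: `mouse_id`, `mean_active_sbp`,
#'   `mean_rest_sbp`, `dip_fraction`, `status`.
#' @export
classify_dipper <- function(bp, dip_threshold = 0.10, lights_off = 12) {
  need <- c("mouse_id", "zt", "sbp")
  miss <- setdiff(need, names(bp))
  if (length(miss) > 0L)
    stop("BP table missing column(s): ", paste(miss, collapse = ", "))
  rows <- lapply(split(bp, bp$mouse_id), function(tr) {
    active <- tr$sbp[tr$zt >= lights_off]
    rest <- tr$sbp[tr$zt < lights_off]
    if (length(active) < 2L || length(rest) < 2L)
      stop("mouse ", tr$mouse_id[1],
           ": need >= 2 readings in each of the light and dark phases")
    ma <- mean(active); mr <- mean(rest)
    d <- (ma - mr) / ma
    status <- if (d >= dip_threshold) "dipper"
              else if (d >= 0) "non-dipper" else "reverse"
    data.frame(mouse_id = tr$mouse_id[1], mean_active_sbp = ma,
               mean_rest_sbp = mr, dip_fraction = d, status = status)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Rank-based group comparison of an analyte
#'
#' Convenience wrapper: two-sided Mann-Whitney (Wilcoxon rank-sum) test for
#' two groups, Kruskal-Wallis for three or more.
#'
#' @param table Long data frame with columns `group`, `analyte`, `value`.
#' @param analyte Analyte to test.
#' @param groups Groups to compare (default: all present).
#' @return p-value.
#' @export
analyte_group_test <- function(table, analyte, groups = NULL) {
  sub <- table[table$analyte == analyte, , drop = FALSE]
  if (nrow(sub) == 0L) stop("analyte '", analyte, "' not found")
  if (is.null(groups)) groups <- unique(sub$group)
  sub <- sub[sub$group %in% groups, , drop = FALSE]
  counts <- table(factor(sub$group, levels = groups))
  if (any(counts < 2L))
    stop("each group needs >= 2 observations; offending: ",
         paste(names(counts)[counts < 2], collapse = ", "))
  if (length(groups) == 2L) {
    suppressWarnings(stats::wilcox.test(
      value ~ factor(group, levels = groups), data = sub)$p.value)
  } else {
    stats::kruskal.test(sub$value, factor(sub$group))$p.value
  }
}
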