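#' Differential-expression thresholds
#'
#' The calling rule is |log2FC| > `lfc` together with a class-specific raw
#' p-value cut: `alpha_default` for mRNA/lncRNA/circRNA and the stricter
#' `alpha_mirna` for miRNA. BH-adjusted q-values are reported alongside but
#' do not drive the call by default.
#'
#' @param lfc Absolute log2 fold-change threshold (default 1).
#' @param alpha_default Raw p threshold for non-miRNA classes (default 0.05).
#' @param alpha_mirna Raw p threshold for miRNA (default 0.01).
#' @param pseudocount Added to both normalised means before the log-ratio
#'   (default 0.5) so zero-count features stay finite.
#' @return A `de_thresholds` object.
#' @export
de_thresholds <- function(lfc = 1, alpha_default = 0.05, alpha_mirna = 0.01,
                          pseudocount = 0.5) {
  if (lfc <= 0 || alpha_default <= 0 || alpha_mirna <= 0 || pseudocount < 0) {
    stop_domain("thresholds must be positive (pseudocount >= 0)")
  }
  if (alpha_default >= 1 || alpha_mirna >= 1) stop_domain("alpha must be < 1")
  structure(list(lfc = lfc, alpha_default = alpha_default,
                 alpha_mirna = alpha_mirna, pseudocount = pseudocount),
            class = "de_thresholds")
}

alpha_for_class <- function(thresholds, class) {
  if (class == "miRNA") thresholds$alpha_mirna else thresholds$alpha_default
}

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Conditional on both margins, sums the hypergeometric probabilities of all
#' tables whose probability does not exceed that of the observed table (the
#' minimum-likelihood two-sided rule, the convention of `fisher.test`).
#'
#' @param a,b,c,d Non-negative integer cells, rows = groups: `(a, b)` and
#'   `(c, d)`.
#' @return Two-sided p-value in (0, 1].
#' @export
fisher_exact_2x2 <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  if (any(is.na(cells)) || any(cells < 0) || any(cells != floor(cells))) {
    stop_domain("fisher_exact_2x2: cells must be non-negative integers")
  }
  r1 <- a + b; r2 <- c + d; c1 <- a + c
  if (r1 + r2 == 0) stop_domain("fisher_exact_2x2: all margins are zero")
  if (r1 == 0 || r2 == 0 || c1 == 0 || (b + d) == 0) return(1)
  support <- max(0, c1 - r2):min(r1, c1)
  dens <- dhyper(support, r1, r2, c1)
  obs <- dhyper(a, r1, r2, c1)
  # relative tolerance guards ties against floating-point noise (same guard
  # as stats::fisher.test)
  min(1, sum(dens[dens <= obs * (1 + 1e-7)]))
}

#' Build the pooled-count 2x2 table for one feature
#'
#' Rows are groups, columns are (feature reads, all other mapped reads):
#' `[[gene_case, total_case - gene_case], [gene_ctrl, total_ctrl - gene_ctrl]]`.
#'
#' @param counts_case,counts_ctrl Feature reads pooled over samples within
#'   each group.
#' @param total_case,total_ctrl Mapped-read totals pooled within each group.
#' @return A 2x2 integer matrix.
#' @export
build_gene_table <- function(counts_case, total_case, counts_ctrl, total_ctrl) {
  if (counts_case > total_case || counts_ctrl > total_ctrl) {
    stop_domain("feature count exceeds its group total")
  }
  if (min(counts_case, counts_ctrl, total_case, total_ctrl) < 0) {
    stop_domain("counts and totals must be non-negative")
  }
  matrix(c(counts_case, total_case - counts_case,
           counts_ctrl, total_ctrl - counts_ctrl),
         nrow = 2, byrow = TRUE,
         dimnames = list(c("case", "control"), c("feature", "rest")))
}

#' Log2 fold change of normalised means (case over control)
#'
#' @param mean_case,mean_ctrl Non-negative normalised abundances.
#' @param pseudocount Non-negative stabiliser added to both means.
#' @return `log2((mean_case + pseudocount) / (mean_ctrl + pseudocount))`;
#'   antisymmetric under group swap. Vectorised.
#' @export
log2_fold_change <- function(mean_case, mean_ctrl, pseudocount = 0.5) {
  if (pseudocount < 0) stop_domain("pseudocount must be >= 0")
  if (any(mean_case < 0) || any(mean_ctrl < 0)) stop_domain("means must be >= 0")
  log2((mean_case + pseudocount) / (mean_ctrl + pseudocount))
}

#' SRPBM: spliced (back-splice junction) reads per billion mapped
#'
#' @param junction_reads Back-splice junction read count(s).
#' @param mapped_total Mapped-read total(s); must be positive.
#' @return `junction_reads * 1e9 / mapped_total`. Vectorised.
#' @export
srpbm <- function(junction_reads, mapped_total) {
  if (any(mapped_total <= 0)) stop_domain("mapped_total must be positive")
  if (any(junction_reads < 0)) stop_domain("junction_reads must be >= 0")
  junction_reads * 1e9 / mapped_total
}

cpm <- function(counts, mapped_total) {
  sweep(counts, 2, mapped_total, function(x, t) x * 1e6 / t)
}

#' Call differential expression per RNA class
#'
#' For every feature, counts are pooled within group and tested against the
#' pooled mapped totals with [fisher_exact_2x2()]; the fold change is the
#' log2 ratio of group-mean normalised abundances (SRPBM for circRNA, CPM
#' otherwise) with a pseudocount. Direction is `up`/`down` when
#' |log2FC| > `lfc` and p is below the class alpha, else `ns`.
#'
#' @param counts A [count_matrix()] or a named list of them (one per class).
#' @param sample_map `data.frame` with `sample_id`, `group` in
#'   `{case, control}`.
#' @param mapped_totals Named numeric vector of per-sample mapped totals.
#' @param thresholds A [de_thresholds()].
#' @return `data.frame` with columns `feature_id`, `class`, `mean_case`,
#'   `mean_ctrl`, `log2fc`, `p`, `q`, `direction` (BH q within class).
#' @export
call_differential <- function(counts, sample_map,
                              mapped_totals, thresholds = de_thresholds()) {
  if (inherits(counts, "count_matrix")) counts <- list(counts)
  res <- lapply(counts, call_differential_one, sample_map = sample_map,
                mapped_totals = mapped_totals, thresholds = thresholds)
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

call_differential_one <- function(cm, sample_map, mapped_totals, thresholds) {
  stopifnot(inherits(cm, "count_matrix"), inherits(thresholds, "de_thresholds"))
  if (!all(cm$sample_ids %in% sample_map$sample_id)) {
    stop_domain("count matrix samples missing from the sample map")
  }
  if (!all(cm$sample_ids %in% names(mapped_totals))) {
    stop_domain("count matrix samples missing from mapped totals")
  }
  groups <- sample_map$group[match(cm$sample_ids, sample_map$sample_id)]
  case <- cm$sample_ids[groups == "case"]
  ctrl <- cm$sample_ids[groups == "control"]
  if (length(case) == 0L || length(ctrl) == 0L) {
    stop_domain("need at least one sample per group")
  }
  m <- cm$counts
  if (nrow(m) == 0L) {
    return(data.frame(feature_id = character(0), class = character(0),
                      mean_case = numeric(0), mean_ctrl = numeric(0),
                      log2fc = numeric(0), p = numeric(0), q = numeric(0),
                      direction = character(0), stringsAsFactors = FALSE))
  }
  pooled_case <- rowSums(m[, case, drop = FALSE])
  pooled_ctrl <- rowSums(m[, ctrl, drop = FALSE])
  tot_case <- sum(mapped_totals[case])
  tot_ctrl <- sum(mapped_totals[ctrl])

  norm <- if (cm$class == "circRNA") {
    sweep(m, 2, mapped_totals[cm$sample_ids], srpbm)
  } else {
    cpm(m, mapped_totals[cm$sample_ids])
  }
  mean_case <- rowMeans(norm[, case, drop = FALSE])
  mean_ctrl <- rowMeans(norm[, ctrl, drop = FALSE])
  log2fc <- log2_fold_change(mean_case, mean_ctrl, thresholds$pseudocount)

  p <- vapply(seq_len(nrow(m)), function(i) {
    fisher_exact_2x2(pooled_case[i], tot_case - pooled_case[i],
                     pooled_ctrl[i], tot_ctrl - pooled_ctrl[i])
  }, numeric(1))
  q <- p.adjust(p, method = "BH")
  alpha <- alpha_for_class(thresholds, cm$class)
  direction <- ifelse(abs(log2fc) > thresholds$lfc & p < alpha,
                      ifelse(log2fc > 0, "up", "down"), "ns")
  data.frame(feature_id = cm$feature_ids, class = cm$class,
             mean_case = unname(mean_case), mean_ctrl = unname(mean_ctrl),
             log2fc = unname(log2fc), p = p, q = q, direction = direction,
             stringsAsFactors = FALSE)
}

#' Relative expression by the comparative 2^-ddCt method
#'
#' @param ct_target_case,ct_ref_case Target and reference-gene Ct in the
#'   case condition.
#' @param ct_target_ctrl,ct_ref_ctrl The same in the control condition.
#' @return `2^-((ct_target_case - ct_ref_case) - (ct_target_ctrl - ct_ref_ctrl))`.
#' @export
ddct_relative_expression <- function(ct_target_case, ct_ref_case,
                                     ct_target_ctrl, ct_ref_ctrl) {
  vals <- c(ct_target_case, ct_ref_case, ct_target_ctrl, ct_ref_ctrl)
  if (any(!is.finite(vals))) stop_domain("Ct values must be finite")
  ddct <- (ct_target_case - ct_ref_case) - (ct_target_ctrl - ct_ref_ctrl)
  2^(-ddct)
}

#' Genomic-source proportions of circRNAs
#'
#' @param origins Character vector of origins in
#'   `{exon, intron, intergenic}`, optionally named by circRNA id.
#' @param group Optional grouping factor of the same length; proportions are
#'   computed per group and sum to 1 within each.
#' @return Named numeric vector of proportions, or a list of them per group.
#' @export
circ_source_summary <- function(origins, group = NULL) {
  valid <- c("exon", "intron", "intergenic")
  if (length(origins) == 0L) stop_domain("no circRNA origin labels supplied")
  if (any(is.na(origins)) || !all(origins %in% valid)) {
    stop_domain("every circRNA needs an origin in {exon, intron, intergenic}")
  }
  prop <- function(x) {
    tab <- table(factor(x, levels = valid))
    p <- setNames(as.numeric(tab) / length(x), valid)
    p[p > 0]
  }
  if (is.null(group)) return(prop(origins))
  lapply(split(origins, group), prop)
}
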