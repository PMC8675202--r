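# Transcriptome analysis downstream of the count matrix: median-of-ratios
# size factors, the "truly expressed" filter (normalized count > 10 in at
# least 50% of samples), a simplified negative-binomial Wald test for
# differential expression at each day versus the control genotype
# (method-of-moments gene-wise dispersion shrunk toward a fitted
# mean-dispersion trend), the curated-gene candidate funnel, rescue
# classification of candidates under rapamycin, z-score matrices,
# complete-linkage Euclidean clustering with a deterministic tie-break, and
# sample-level PCA.

#' Count matrix with sample-condition map
#'
#' @param counts Integer matrix, genes in rows, samples in columns; both
#'   dimnames required.
#' @param condition Character vector mapping each sample (column) to a
#'   condition label.
#' @return An object of class `count_matrix`.
#' @export
count_matrix <- function(counts, condition) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("counts must carry gene and sample names")
  }
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers")
  }
  if (length(condition) != ncol(counts)) {
    stop("one condition label per sample required")
  }
  structure(list(counts = counts, condition = as.character(condition)),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("<count_matrix> %d genes x %d samples; conditions: %s\n",
              nrow(x$counts), ncol(x$counts),
              paste(unique(x$condition), collapse = ", ")))
  invisible(x)
}

#' Median-of-ratios size factors
#'
#' For each sample, the size factor is the median across genes of the ratio
#' of its count to the geometric-mean pseudo-reference, computed over genes
#' with no zero count in any sample. Factors are rescaled so the median
#' factor is 1, anchoring normalized counts to the scale of a typical
#' library (a sample with exactly doubled counts gets factor 2 while the
#' rest stay at 1).
#'
#' @param c A [count_matrix()].
#' @return Named numeric vector of per-sample size factors.
#' @export
size_factors <- function(c) {
  stopifnot(inherits(c, "count_matrix"))
  k <- c$counts
  all_pos <- rowSums(k == 0) == 0
  if (!any(all_pos)) {
    stop("no gene with nonzero counts in every sample; ",
         "consider adding a pseudocount upstream")
  }
  lg <- log(k[all_pos, , drop = FALSE])
  ref <- rowMeans(lg)
  sf <- apply(lg, 2L, function(col) exp(stats::median(col - ref)))
  sf / stats::median(sf)
}

#' Normalized counts
#' @param c A [count_matrix()].
#' @param sf Optional precomputed size factors.
#' @return Matrix of counts divided by their sample's size factor.
#' @export
normalized_counts <- function(c, sf = size_factors(c)) {
  sweep(c$counts, 2L, sf, "/")
}

#' Funnel configuration
#'
#' @param expression_floor Normalized-count floor; a gene is "truly
#'   expressed" when strictly above this in at least `sample_fraction` of
#'   samples (default: higher than 10 in 50% of all samples).
#' @param sample_fraction See above.
#' @param alpha Adjusted-p threshold for the DE flag.
#' @param lfc_threshold Absolute log2-fold-change threshold for the DE flag.
#' @param use_adjusted_p Flag DE on BH-adjusted p (default) or raw p.
#' @param candidate_alpha Raw-p threshold of the per-gene one-way ANOVA
#'   across conditions in the funnel.
#' @param candidate_adjust Apply BH across the curated genes' ANOVA p
#'   values before thresholding (default `FALSE`, mirroring a direct
#'   per-gene comparison).
#' @param rescue_p_floor Minimum (control-comparison adjusted) p for the
#'   treated-vs-control comparison of a rescued gene.
#' @param rescue_lfc_bound Maximum |log2FC| of a rescued gene versus
#'   control.
#' @return An object of class `funnel_config`.
#' @export
funnel_config <- function(expression_floor = 10, sample_fraction = 0.5,
                          alpha = 0.05, lfc_threshold = 0.5,
                          use_adjusted_p = TRUE,
                          candidate_alpha = 0.05, candidate_adjust = FALSE,
                          rescue_p_floor = 0.05, rescue_lfc_bound = 0.5) {
  stopifnot(expression_floor >= 0, sample_fraction > 0, sample_fraction <= 1,
            alpha > 0, lfc_threshold >= 0, candidate_alpha > 0,
            rescue_p_floor > 0, rescue_lfc_bound >= 0)
  structure(list(expression_floor = expression_floor,
                 sample_fraction = sample_fraction, alpha = alpha,
                 lfc_threshold = lfc_threshold,
                 use_adjusted_p = use_adjusted_p,
                 candidate_alpha = candidate_alpha,
                 candidate_adjust = candidate_adjust,
                 rescue_p_floor = rescue_p_floor,
                 rescue_lfc_bound = rescue_lfc_bound),
            class = "funnel_config")
}

#' Expression filter
#'
#' Keeps genes whose normalized count is strictly greater than the floor in
#' at least the configured fraction of all samples.
#'
#' @param c A [count_matrix()].
#' @param cfg A [funnel_config()].
#' @param sf Optional precomputed size factors.
#' @return Character vector of kept gene ids.
#' @export
expression_filter <- function(c, cfg = funnel_config(), sf = size_factors(c)) {
  nc <- normalized_counts(c, sf)
  frac <- rowMeans(nc > cfg$expression_floor)
  rownames(nc)[frac >= cfg$sample_fraction]
}

# Gene-wise method-of-moments NB dispersion on normalized counts, shrunk in
# log space toward a fitted mean-dispersion trend a0 + a1/mu. Per group the
# sample variance s2_g estimates mu_g + alpha * mu_g^2; the per-gene raw
# alpha solves the relation across groups by least squares through the
# origin, so large between-group fold changes do not inflate the estimate.
estimate_dispersions <- function(nc, group, shrink_weight = 0.5) {
  lev <- unique(group)
  num <- den <- 0
  mu_bar <- rowMeans(nc)
  for (g in lev) {
    sub <- nc[, group == g, drop = FALSE]
    mu_g <- rowMeans(sub)
    s2_g <- rowSums((sub - mu_g)^2) / (ncol(sub) - 1L)
    num <- num + (s2_g - mu_g) * mu_g^2
    den <- den + mu_g^4
  }
  raw <- num / pmax(den, 1e-300)
  ok <- is.finite(raw) & raw > 0 & mu_bar > 0
  # trend: alpha(mu) = a0 + a1/mu fitted on the raw estimates
  a0 <- 0.1; a1 <- 1
  if (sum(ok) >= 10) {
    X <- cbind(1, 1 / mu_bar[ok])
    cf <- stats::lm.fit(X, raw[ok])$coefficients
    a0 <- max(cf[1L], 1e-4); a1 <- max(cf[2L], 0)
  }
  trend <- a0 + a1 / pmax(mu_bar, 1e-8)
  disp <- trend
  disp[ok] <- exp(shrink_weight * log(raw[ok]) +
                    (1 - shrink_weight) * log(trend[ok]))
  pmax(disp, 1e-8)
}

#' Negative-binomial Wald test of one condition versus control
#'
#' Counts are normalized by median-of-ratios size factors; per-gene NB
#' dispersions are method-of-moments estimates pooled across every
#' condition in the matrix (the full design supplies the residual degrees
#' of freedom) and shrunk toward a fitted mean-dispersion trend. The log2
#' fold change contrasts the two group
#' means of normalized counts (with a small prior count guarding empty
#' groups); its standard error follows from the NB mean-variance relation,
#' and the Wald statistic is referred to a t distribution with the
#' within-group degrees of freedom. P values are BH-adjusted across tested
#' genes. A gene is flagged DE when the (adjusted) p is below `alpha` and
#' |log2FC| exceeds `lfc_threshold`.
#'
#' @param c A [count_matrix()].
#' @param condition Condition label to test.
#' @param control Control condition label.
#' @param cfg A [funnel_config()].
#' @param sf Optional precomputed size factors (for the full matrix).
#' @return A data frame of class `de_result`: `gene`, `base_mean`,
#'   `log2fc`, `p`, `padj`, `de`. Genes with all-zero counts in both groups
#'   are excluded and listed in the `excluded_genes` attribute.
#' @export
de_test <- function(c, condition, control, cfg = funnel_config(),
                    sf = size_factors(c)) {
  stopifnot(inherits(c, "count_matrix"))
  sel <- c$condition %in% c(condition, control)
  if (sum(c$condition == condition) < 2L || sum(c$condition == control) < 2L) {
    stop("both conditions need >= 2 samples")
  }
  nc_all <- normalized_counts(c, sf)
  nc <- nc_all[, sel, drop = FALSE]
  grp <- c$condition[sel]
  sf_sel <- sf[sel]
  zero <- rowSums(c$counts[, sel, drop = FALSE]) == 0
  nc_t <- nc[!zero, , drop = FALSE]

  # dispersions are estimated across every condition in the matrix (the
  # full design contributes residual degrees of freedom, as in standard
  # NB DE practice), then shrunk toward the mean-dispersion trend
  disp_df <- ncol(nc_all) - length(unique(c$condition))
  disp <- estimate_dispersions(nc_all[!zero, , drop = FALSE], c$condition)
  is_b <- grp == condition
  sf_a <- sf_sel[!is_b]; sf_b <- sf_sel[is_b]
  # group mean of the underlying normalized intensity q: weighted by size
  # factors (MLE for NB with common q across samples at fixed dispersion 0)
  k <- c$counts[!zero, sel, drop = FALSE]
  q_a <- rowSums(k[, !is_b, drop = FALSE]) / sum(sf_a)
  q_b <- rowSums(k[, is_b, drop = FALSE]) / sum(sf_b)
  prior <- 0.5 / mean(sf)
  lfc <- log2((q_b + prior) / (q_a + prior))
  # Var(q_hat) = (q * sum(sf) + disp * q^2 * sum(sf^2)) / sum(sf)^2
  v_log <- function(q, sfv) {
    vq <- (pmax(q, prior) * sum(sfv) + disp * pmax(q, prior)^2 * sum(sfv^2)) /
      sum(sfv)^2
    vq / pmax(q, prior)^2
  }
  se_ln <- sqrt(v_log(q_a, sf_a) + v_log(q_b, sf_b))
  wald <- (log(q_b + prior) - log(q_a + prior)) / se_ln
  # moderated reference: dispersion shrinkage (weight 0.5 toward the trend)
  # contributes about as much information as the gene-wise estimate, so the
  # Wald statistic is referred to t with twice the dispersion residual df
  df <- max(2L, disp_df) / 0.5
  p <- 2 * stats::pt(abs(wald), df, lower.tail = FALSE)
  padj <- stats::p.adjust(p, method = "BH")
  pcrit <- if (cfg$use_adjusted_p) padj else p
  out <- data.frame(gene = rownames(nc_t),
                    base_mean = rowMeans(nc_t),
                    log2fc = lfc, p = p, padj = padj,
                    de = pcrit < cfg$alpha & abs(lfc) > cfg$lfc_threshold,
                    row.names = NULL)
  attr(out, "excluded_genes") <- rownames(nc)[zero]
  class(out) <- c("de_result", "data.frame")
  out
}

#' Run the curated-gene candidate funnel
#'
#' Stages, in order: (1) all genes; (2) "truly expressed" genes per the
#' expression filter; (3) genes DE at the reference day versus control;
#' (4) intersection with the curated list; (5) genes significant in a
#' per-gene one-way ANOVA of log2 normalized counts across the untreated
#' conditions. [rescue_classify()] then splits stage-5 candidates into
#' rescued / not rescued under the treated arm.
#'
#' @param c A [count_matrix()] spanning all conditions.
#' @param curated Character vector of curated gene ids.
#' @param cfg A [funnel_config()].
#' @param reference_day Condition tested for DE (default `"d13"`).
#' @param control Control condition label (default `"Cre-"`).
#' @param anova_conditions Conditions entering the per-gene ANOVA;
#'   default all untreated conditions (control plus days).
#' @param rap_condition Treated-arm label used for rescue classification
#'   (default `"Rap4"`); set `NULL` to skip rescue.
#' @param seed Seed for the Monte-Carlo post hoc used in rescue
#'   classification.
#' @return A list of class `funnel_report`: `stage_counts` (named integer
#'   vector), `candidates` (data frame with per-day log2FC, ANOVA p,
#'   rescue flags), `de_result` (the reference-day `de_result`),
#'   `n_up`/`n_down`/`n_de` at the reference day.
#' @export
run_funnel <- function(c, curated, cfg = funnel_config(),
                       reference_day = "d13", control = "Cre-",
                       anova_conditions = NULL, rap_condition = "Rap4",
                       seed = 1) {
  stopifnot(inherits(c, "count_matrix"))
  if (!length(curated)) stop("empty curated gene list")
  conds <- unique(c$condition)
  if (is.null(anova_conditions)) {
    anova_conditions <- setdiff(conds, rap_condition)
  }
  sf <- size_factors(c)
  expressed <- expression_filter(c, cfg, sf)
  sub <- count_matrix(c$counts[expressed, , drop = FALSE], c$condition)
  de <- de_test(sub, reference_day, control, cfg, sf = sf[colnames(sub$counts)])
  de_genes <- de$gene[de$de]
  hits <- intersect(de_genes, curated)

  nc <- normalized_counts(c, sf)
  lg <- log2(nc + 1)
  sel <- c$condition %in% anova_conditions
  grp <- factor(c$condition[sel], levels = intersect(conds, anova_conditions))
  anova_p <- vapply(hits, function(g) {
    stats::oneway.test(lg[g, sel] ~ grp, var.equal = TRUE)$p.value
  }, numeric(1))
  pa <- if (cfg$candidate_adjust) stats::p.adjust(anova_p, "BH") else anova_p
  cand <- hits[is.finite(pa) & pa < cfg$candidate_alpha]

  day_conds <- setdiff(anova_conditions, control)
  lfc_days <- sapply(day_conds, function(d) {
    m_d <- rowMeans(nc[cand, c$condition == d, drop = FALSE])
    m_c <- rowMeans(nc[cand, c$condition == control, drop = FALSE])
    log2((m_d + 0.5) / (m_c + 0.5))
  })
  if (length(cand) == 1L) lfc_days <- matrix(lfc_days, nrow = 1L,
                                             dimnames = list(cand, day_conds))
  candidates <- data.frame(gene = cand,
                           anova_p = anova_p[cand],
                           row.names = NULL)
  if (length(cand)) {
    candidates <- cbind(candidates,
                        stats::setNames(as.data.frame(lfc_days),
                                        paste0("log2fc_", day_conds)))
  }
  rescued <- NULL
  if (!is.null(rap_condition) && rap_condition %in% conds && length(cand)) {
    rescued <- rescue_classify(cand, c, cfg, control = control,
                               rap_condition = rap_condition, seed = seed)
    candidates$rescued <- rescued$rescued[match(cand, rescued$gene)]
    candidates$rap_log2fc <- rescued$rap_log2fc[match(cand, rescued$gene)]
  }
  stage_counts <- c(input = nrow(c$counts),
                    expressed = length(expressed),
                    de_reference_day = length(de_genes),
                    curated_intersect = length(hits),
                    anova_significant = length(cand))
  if (!is.null(rescued)) {
    stage_counts <- c(stage_counts,
                      rescued = sum(candidates$rescued),
                      not_rescued = sum(!candidates$rescued))
  }
  structure(list(stage_counts = stage_counts, candidates = candidates,
                 de_result = de,
                 n_up = sum(de$de & de$log2fc > 0),
                 n_down = sum(de$de & de$log2fc < 0),
                 n_de = length(de_genes)),
            class = "funnel_report")
}

#' @export
print.funnel_report <- function(x, ...) {
  cat("<funnel_report>\n")
  for (nm in names(x$stage_counts)) {
    cat(sprintf("  %-18s %d\n", nm, x$stage_counts[[nm]]))
  }
  cat(sprintf("  reference-day DE: %d up + %d down = %d\n",
              x$n_up, x$n_down, x$n_de))
  invisible(x)
}

#' Classify candidate genes as rescued under treatment
#'
#' A candidate is rescued when its treated-arm expression is statistically
#' and practically indistinguishable from control: the control-comparison
#' adjusted p of the treated-vs-control contrast (Dunnett many-to-one
#' across all non-control conditions) is at least `rescue_p_floor`, and the
#' empirical-Bayes shrunken |log2FC| of treated versus control is at most
#' `rescue_lfc_bound`. Both criteria are needed because non-significance
#' alone cannot assert equivalence; the shrinkage keeps the
#' practical-equivalence bound from being crossed by small-n sampling
#' noise alone.
#'
#' @param genes Character vector of candidate gene ids.
#' @param c A [count_matrix()] including the treated arm.
#' @param cfg A [funnel_config()].
#' @param control,rap_condition Condition labels.
#' @param seed Seed for the Monte-Carlo Dunnett adjustment.
#' @return Data frame: `gene`, `rap_log2fc` (raw), `rap_log2fc_shrunk`,
#'   `rap_p_adjusted`, `rescued`.
#' @export
rescue_classify <- function(genes, c, cfg = funnel_config(),
                            control = "Cre-", rap_condition = "Rap4",
                            seed = 1) {
  stopifnot(inherits(c, "count_matrix"))
  if (!rap_condition %in% c$condition) {
    stop("missing treated-arm samples: ", rap_condition)
  }
  sf <- size_factors(c)
  nc <- normalized_counts(c, sf)
  lg <- log2(nc + 1)
  conds <- unique(c$condition)
  others <- setdiff(conds, control)

  # empirical-Bayes shrinkage of the treated-vs-control log2 fold change:
  # a zero-centered normal prior whose scale is matched to the upper
  # quantile of the genome-wide raw fold changes damps the sampling noise
  # of small-n group means, so a truly rescued gene is not pushed over the
  # practical-equivalence bound by chance
  is_r <- c$condition == rap_condition
  is_c <- c$condition == control
  prior <- 0.5
  m_r_all <- rowMeans(nc[, is_r, drop = FALSE])
  m_c_all <- rowMeans(nc[, is_c, drop = FALSE])
  lfc_all <- log2((m_r_all + prior) / (m_c_all + prior))
  disp <- estimate_dispersions(nc, c$condition)
  n_r <- sum(is_r); n_c <- sum(is_c)
  v_ln <- function(q, n) (1 / pmax(q, prior) + disp) / n
  se2 <- (v_ln(m_r_all, n_r) + v_ln(m_c_all, n_c)) / log(2)^2
  s_prior <- max(0.1, stats::quantile(abs(lfc_all), 0.95) / stats::qnorm(0.95))
  shrunk_all <- lfc_all * s_prior^2 / (s_prior^2 + se2)

  res <- lapply(genes, function(g) {
    grp_list <- lapply(c(control, others), function(cc) lg[g, c$condition == cc])
    names(grp_list) <- c(control, others)
    ph <- one_way_anova_control(grp_list, control = 1L, method = "dunnett",
                                seed = seed)$posthoc
    rap_p <- ph$p_adjusted[ph$comparison == paste(rap_condition, "vs", control)]
    lfc <- lfc_all[[g]]
    lfc_s <- shrunk_all[[g]]
    data.frame(gene = g, rap_log2fc = lfc, rap_log2fc_shrunk = lfc_s,
               rap_p_adjusted = rap_p,
               rescued = rap_p >= cfg$rescue_p_floor &
                 abs(lfc_s) <= cfg$rescue_lfc_bound)
  })
  do.call(rbind, res)
}

#' Gene x sample z-score matrix
#'
#' Per gene, z-scores across samples of `log2(normalized count + 1)`.
#' Zero-variance rows are dropped with a warning.
#'
#' @param c A [count_matrix()].
#' @param genes Gene ids to include.
#' @param sf Optional precomputed size factors.
#' @return Numeric matrix, one row per retained gene.
#' @export
zscore_matrix <- function(c, genes, sf = size_factors(c)) {
  stopifnot(all(genes %in% rownames(c$counts)))
  lg <- log2(normalized_counts(c, sf)[genes, , drop = FALSE] + 1)
  sds <- apply(lg, 1L, stats::sd)
  if (any(sds == 0)) {
    warning("dropping ", sum(sds == 0), " constant gene row(s)")
    lg <- lg[sds > 0, , drop = FALSE]
    sds <- sds[sds > 0]
  }
  (lg - rowMeans(lg)) / sds
}

#' Complete-linkage hierarchical clustering with deterministic tie-break
#'
#' Agglomerative clustering under Euclidean distance and complete linkage
#' (clusters merge at the maximum pairwise member distance, which makes the
#' merge-height sequence non-decreasing). Ties in the minimum inter-cluster
#' distance are broken toward the pair containing the smallest original
#' item index. Rows of `m` are the clustered items.
#'
#' @param m Numeric matrix (no NAs), items in rows.
#' @param axis Cluster `"rows"` (default) or `"columns"` (transpose first).
#' @return A list of class `cluster_tree`: `merge` and `height` in
#'   [stats::hclust()] encoding, `order`, `labels`, `linkage`, `metric`.
#' @export
hclust_complete <- function(m, axis = c("rows", "columns")) {
  axis <- match.arg(axis)
  if (axis == "columns") m <- t(m)
  if (anyNA(m)) stop("NaN/NA in clustering input")
  n <- nrow(m)
  if (n < 2L) stop("need at least 2 items to cluster")
  labels <- rownames(m)
  if (is.null(labels)) labels <- as.character(seq_len(n))
  D <- as.matrix(stats::dist(m))
  diag(D) <- Inf
  # active clusters: id < 0 encodes singleton -i, > 0 encodes merge row
  active <- seq_len(n)
  code <- -seq_len(n)
  members <- as.list(seq_len(n))
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  min_member <- seq_len(n)  # smallest original item index per cluster
  for (s in seq_len(n - 1L)) {
    na <- length(active)
    best <- c(Inf, NA, NA)
    best_key <- c(Inf, Inf)
    for (i in seq_len(na - 1L)) for (j in (i + 1L):na) {
      dij <- D[active[i], active[j]]
      if (dij < best[1L] - 1e-12) {
        best <- c(dij, i, j)
        best_key <- sort(c(min_member[i], min_member[j]))
      } else if (dij < best[1L] + 1e-12) {
        key <- sort(c(min_member[i], min_member[j]))
        if (key[1L] < best_key[1L] ||
            (key[1L] == best_key[1L] && key[2L] < best_key[2L])) {
          best <- c(dij, i, j)
          best_key <- key
        }
      }
    }
    i <- best[2L]; j <- best[3L]
    merge[s, ] <- c(code[i], code[j])
    height[s] <- best[1L]
    # complete linkage: new distances are maxima
    new_m <- c(members[[i]], members[[j]])
    keep <- setdiff(seq_len(na), c(i, j))
    newD <- vapply(keep, function(kk) max(D[active[i], active[kk]],
                                          D[active[j], active[kk]]),
                   numeric(1))
    rep_id <- active[i]
    D[rep_id, active[keep]] <- newD
    D[active[keep], rep_id] <- newD
    D[rep_id, rep_id] <- Inf
    active <- c(active[keep], rep_id)
    code <- c(code[keep], s)
    members <- c(members[keep], list(new_m))
    min_member <- c(min_member[keep], min(new_m))
  }
  hc <- list(merge = merge, height = height, order = integer(0),
             labels = labels, method = "complete",
             dist.method = "euclidean", call = match.call())
  class(hc) <- "hclust"
  hc$order <- hclust_order(merge, n)
  structure(list(merge = merge, height = height, order = hc$order,
                 labels = labels, linkage = "complete",
                 metric = "euclidean", hclust = hc),
            class = "cluster_tree")
}

# leaf order by depth-first traversal of the merge tree
hclust_order <- function(merge, n) {
  leaves <- function(row) {
    out <- integer(0)
    for (v in merge[row, ]) {
      out <- c(out, if (v < 0) -v else leaves(v))
    }
    out
  }
  leaves(n - 1L)
}

#' Export a cluster tree as a Newick string
#'
#' Branch lengths are differences of merge heights (leaf branches span from
#' height 0 to their first merge), so root-to-leaf path lengths equal the
#' root merge height.
#'
#' @param tree A `cluster_tree` from [hclust_complete()].
#' @param path Optional file to write.
#' @return The Newick string, invisibly when `path` is given.
#' @export
write_newick <- function(tree, path = NULL) {
  stopifnot(inherits(tree, "cluster_tree"))
  m <- tree$merge; h <- tree$height; lab <- tree$labels
  node <- function(v, parent_h) {
    if (v < 0) {
      sprintf("%s:%g", lab[-v], parent_h)
    } else {
      sprintf("(%s,%s):%g", node(m[v, 1L], h[v]), node(m[v, 2L], h[v]),
              parent_h - h[v])
    }
  }
  root <- nrow(m)
  nwk <- sprintf("(%s,%s);", node(m[root, 1L], h[root]),
                 node(m[root, 2L], h[root]))
  if (!is.null(path)) {
    writeLines(nwk, path)
    return(invisible(nwk))
  }
  nwk
}

#' PCA of samples on log-transformed normalized counts
#'
#' Samples are observations; variables are per-gene `log2(normalized + 1)`
#' values, centered per gene. Scores and the fraction of variance per
#' component are returned.
#'
#' @param c A [count_matrix()].
#' @param sf Optional precomputed size factors.
#' @param ntop Optionally restrict to the `ntop` most variable genes
#'   (`NULL` = all genes).
#' @return List of class `pca_result`: `scores` (samples x components),
#'   `var_fraction`, `condition`.
#' @export
pca_samples <- function(c, sf = size_factors(c), ntop = NULL) {
  stopifnot(inherits(c, "count_matrix"))
  if (nrow(c$counts) < 2L) stop("need at least 2 genes for PCA")
  if (ncol(c$counts) < 2L) stop("need at least 2 samples for PCA")
  lg <- log2(normalized_counts(c, sf) + 1)
  if (!is.null(ntop)) {
    rv <- apply(lg, 1L, stats::var)
    lg <- lg[order(rv, decreasing = TRUE)[seq_len(min(ntop, nrow(lg)))], ,
             drop = FALSE]
  }
  pr <- stats::prcomp(t(lg), center = TRUE, scale. = FALSE)
  vf <- pr$sdev^2 / sum(pr$sdev^2)
  structure(list(scores = pr$x, var_fraction = vf, condition = c$condition),
            class = "pca_result")
}
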