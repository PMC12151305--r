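# Layer-wise statistical comparison of threshold-free AUC measures.

#' One-way ANOVA
#'
#' Classical one-way F test across groups. Degenerate inputs follow fixed
#' conventions: when within-group variance is (numerically) zero and the
#' group means agree, `F = 0, p = 1`; when within-group variance is zero
#' but means differ, `p = 0` is returned as a sentinel with a warning.
#'
#' @param groups list of numeric vectors (>= 2 groups, each >= 2 values).
#' @return List with `F`, `p`, `df_between`, `df_within`.
#' @export
one_way_anova <- function(groups) {
  if (length(groups) < 2 || any(lengths(groups) < 2)) {
    stop_invalid("invalid-argument: need >= 2 groups with >= 2 observations each")
  }
  y <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), lengths(groups)))
  tab <- summary(aov(y ~ g))[[1L]]
  ssb <- tab[1L, "Sum Sq"]
  ssw <- tab[2L, "Sum Sq"]
  df1 <- tab[1L, "Df"]
  df2 <- tab[2L, "Df"]
  eps <- 1e-12 * max(1, sum(y^2))
  if (ssw <= eps) {
    if (ssb <= eps) return(list(F = 0, p = 1, df_between = df1, df_within = df2))
    warning("zero within-group variance with unequal means; p = 0 sentinel")
    return(list(F = Inf, p = 0, df_between = df1, df_within = df2))
  }
  list(F = tab[1L, "F value"], p = tab[1L, "Pr(>F)"],
       df_between = df1, df_within = df2)
}

#' Multiple-comparison adjustment with rejection flags
#'
#' Benjamini-Hochberg step-up (false discovery rate) or Holm step-down
#' (family-wise error rate) adjusted p-values; a test is rejected when its
#' adjusted p-value is at most `alpha`.
#'
#' @param pvals p-values in \[0, 1\].
#' @param method `"benjamini_hochberg"` or `"holm"`.
#' @param alpha rejection level.
#' @return List with `p_adjusted` and logical `rejected`.
#' @export
adjust_pvalues <- function(pvals, method = c("benjamini_hochberg", "holm"),
                           alpha = 0.05) {
  method <- match.arg(method)
  if (anyNA(pvals) || any(pvals < 0 | pvals > 1)) {
    stop_invalid("invalid-argument: p-values must lie in [0, 1]")
  }
  adj <- p.adjust(pvals, method = switch(method,
                                         benjamini_hochberg = "BH",
                                         holm = "holm"))
  list(p_adjusted = adj, rejected = adj <= alpha)
}

#' Compare AUC measures across layers
#'
#' Global scope: one one-way ANOVA per measure with the D layers as groups
#' and participants as replicates, Benjamini-Hochberg correction across
#' measures (default alpha 0.05). Nodal scope: one ANOVA per (measure, node)
#' across the D depth copies, Holm correction across nodes within each
#' measure (default alpha 0.01). Each result carries the peak layer
#' (argmax of layer-mean AUC; ties go to the most superficial layer).
#'
#' @param auc_table long `data.frame` with columns `participant`, `measure`,
#'   `layer`, `auc`, and `node` for nodal scope.
#' @param scope `"global"` or `"nodal"`.
#' @param method correction method, see [adjust_pvalues()].
#' @param alpha rejection level (default 0.05 global, 0.01 nodal).
#' @return `data.frame` with `measure`, `scope`, `node`, `F`, `p`,
#'   `p_adjusted`, `significant`, `peak_layer`.
#' @export
compare_layers <- function(auc_table, scope = c("global", "nodal"),
                           method = NULL, alpha = NULL) {
  scope <- match.arg(scope)
  if (is.null(method)) {
    method <- if (scope == "global") "benjamini_hochberg" else "holm"
  }
  if (is.null(alpha)) alpha <- if (scope == "global") 0.05 else 0.01
  needed <- c("participant", "measure", "layer", "auc")
  if (scope == "nodal") needed <- c(needed, "node")
  missing_cols <- setdiff(needed, names(auc_table))
  if (length(missing_cols)) {
    stop_invalid("incompatible-input: auc_table lacks columns: %s",
                 paste(missing_cols, collapse = ", "))
  }
  run_anova <- function(sub) {
    sub <- sub[!is.na(sub$auc), , drop = FALSE]
    groups <- split(sub$auc, sub$layer)
    if (length(groups) < 2 || any(lengths(groups) < 2)) {
      return(list(F = NA_real_, p = NA_real_, peak = NA_integer_))
    }
    res <- suppressWarnings(one_way_anova(groups))
    means <- vapply(groups, mean, 0)
    peak <- as.integer(names(groups)[which.max(means)])
    list(F = res$F, p = res$p, peak = peak)
  }
  if (scope == "global") {
    measures <- unique(auc_table$measure)
    rows <- lapply(measures, function(m) {
      a <- run_anova(auc_table[auc_table$measure == m, ])
      data.frame(measure = m, scope = "global", node = NA_integer_,
                 F = a$F, p = a$p, peak_layer = a$peak,
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    out <- adjust_within(out, rep(1L, nrow(out)), method, alpha)
  } else {
    combos <- unique(auc_table[, c("measure", "node")])
    rows <- lapply(seq_len(nrow(combos)), function(i) {
      sub <- auc_table[auc_table$measure == combos$measure[i] &
                         auc_table$node == combos$node[i], ]
      a <- run_anova(sub)
      data.frame(measure = combos$measure[i], scope = "nodal",
                 node = combos$node[i], F = a$F, p = a$p,
                 peak_layer = a$peak, stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    # Holm family = the nodes of one measure
    out <- adjust_within(out, match(out$measure, unique(out$measure)),
                         method, alpha)
  }
  rownames(out) <- NULL
  out
}

adjust_within <- function(df, family, method, alpha) {
  df$p_adjusted <- NA_real_
  df$significant <- FALSE
  for (f in unique(family)) {
    idx <- which(family == f & !is.na(df$p))
    if (!length(idx)) next
    adj <- adjust_pvalues(df$p[idx], method, alpha)
    df$p_adjusted[idx] <- adj$p_adjusted
    df$significant[idx] <- adj$rejected
  }
  df
}

#' Tabulate significant nodes by brain region and hemisphere
#'
#' @param results nodal `data.frame` from [compare_layers()] (`node` holds
#'   `roi_id`).
#' @param atlas atlas table.
#' @return `data.frame` with `measure`, `region`, `hemisphere`,
#'   `n_significant`, `n_total`.
#' @export
tabulate_regions <- function(results, atlas) {
  if (any(!results$node %in% atlas$roi_id)) {
    stop_invalid("incompatible-input: results contain ROIs absent from atlas")
  }
  groups <- unique(atlas[, c("region", "hemisphere")])
  out <- do.call(rbind, lapply(unique(results$measure), function(m) {
    sub <- results[results$measure == m, ]
    sig_rois <- sub$node[sub$significant]
    do.call(rbind, lapply(seq_len(nrow(groups)), function(i) {
      rois <- atlas$roi_id[atlas$region == groups$region[i] &
                             atlas$hemisphere == groups$hemisphere[i]]
      data.frame(measure = m, region = groups$region[i],
                 hemisphere = groups$hemisphere[i],
                 n_significant = sum(sig_rois %in% rois),
                 n_total = length(rois), stringsAsFactors = FALSE)
    }))
  }))
  rownames(out) <- NULL
  out
}

#' Cortical-thickness confound test
#'
#' For each nodal measure with more than `min_nodes` significant nodes,
#' compares mean ROI cortical thickness between significant and
#' nonsignificant node sets with a two-sample t test (pooled variance).
#' Measures at or below the node threshold are reported as skipped.
#'
#' @param results nodal `data.frame` from [compare_layers()].
#' @param atlas atlas table with `thickness_mm`.
#' @param min_nodes minimum significant-node count (strictly greater than
#'   this to run; default 10).
#' @return `data.frame` with `measure`, `n_significant`, `t`, `p`, `run`,
#'   `reason`.
#' @export
thickness_confound_test <- function(results, atlas, min_nodes = 10) {
  thick <- atlas$thickness_mm[match(results$node, atlas$roi_id)]
  out <- lapply(unique(results$measure), function(m) {
    sub <- results$measure == m
    sig <- results$significant & sub
    nonsig <- !results$significant & sub
    n_sig <- sum(sig)
    row <- data.frame(measure = m, n_significant = n_sig, t = NA_real_,
                      p = NA_real_, run = FALSE, reason = "",
                      stringsAsFactors = FALSE)
    if (n_sig <= min_nodes) {
      row$reason <- sprintf("<= %d significant nodes", min_nodes)
      return(row)
    }
    if (sum(nonsig) < 2 || n_sig < 2) {
      row$reason <- "fewer than 2 nodes per group"
      return(row)
    }
    a <- thick[sig]
    b <- thick[nonsig]
    if (sd(c(a, b)) == 0) {
      row$t <- 0
      row$p <- 1
      row$run <- TRUE
      return(row)
    }
    tt <- t.test(a, b, var.equal = TRUE)
    row$t <- unname(tt$statistic)
    row$p <- tt$p.value
    row$run <- TRUE
    row
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
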