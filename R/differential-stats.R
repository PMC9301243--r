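# The quantitative analysis layer: accumulation profiles, t-test +
# fold-change differential calling, hierarchical clustering on Pearson
# distance, autoscaled PCA.

.check_im <- function(im) {
  stopifnot(inherits(im, "intensity_matrix"))
  if (any(im$values < 0)) stop("intensities must be non-negative")
  need <- c("cultivar", "tissue", "treatment", "replicate")
  miss <- setdiff(need, names(im$meta))
  if (length(miss)) stop("sample metadata lacks: ", paste(miss, collapse = ", "))
  invisible(im)
}

#' Relative abundance of flavonoid families per sample group
#'
#' For each tissue x cultivar group (control samples by default), the
#' percentage of total summed intensity contributed by each aglycone
#' family.  Percentages sum to 100 within a group.
#'
#' @param im An `intensity_matrix`.
#' @param lib A `suspect_library` supplying the compound -> family map
#'   (every matrix column must be a library compound).
#' @param treatment Treatment arm to profile (default `"control"`).
#' @return data.frame: `tissue`, `cultivar`, `family`, `pct`.
#' @export
family_relative_abundance <- function(im, lib, treatment = "control") {
  .check_im(im)
  fam <- lib$compounds$family[match(colnames(im$values), lib$compounds$name)]
  if (anyNA(fam)) stop("matrix contains compounds missing from the library")
  .group_shares(im, fam, treatment, "family")
}

#' Glycosylation-degree profile per sample group
#'
#' As [family_relative_abundance()] but over the glycosylation classes
#' Agly / Gly / GlyGly / GlyGlyGly, plus the acylated share of total
#' signal (acylation cuts across the glyco classes, so it is reported
#' separately, not as part of the 100%).
#'
#' @inheritParams family_relative_abundance
#' @return data.frame: `tissue`, `cultivar`, `glyco_class`, `pct`, with
#'   the acylated share attached as attribute `"acylated_pct"`
#'   (data.frame `tissue`, `cultivar`, `pct`).
#' @export
glyco_profile <- function(im, lib, treatment = "control") {
  .check_im(im)
  idx <- match(colnames(im$values), lib$compounds$name)
  if (anyNA(idx)) stop("matrix contains compounds missing from the library")
  cls <- lib$compounds$glyco_class[idx]
  out <- .group_shares(im, cls, treatment, "glyco_class")
  acy <- .group_shares(im, ifelse(lib$compounds$acylated[idx], "Acy", "non"),
                       treatment, "k")
  acy <- acy[acy$k == "Acy", c("tissue", "cultivar", "pct")]
  rownames(acy) <- NULL
  attr(out, "acylated_pct") <- acy
  out
}

.group_shares <- function(im, labels, treatment, label_name) {
  meta <- im$meta
  sel <- meta$treatment == treatment
  if (!any(sel)) stop("no samples in treatment arm: ", treatment)
  rows <- list()
  for (t in unique(meta$tissue[sel])) for (cv in unique(meta$cultivar[sel])) {
    g <- sel & meta$tissue == t & meta$cultivar == cv
    if (!any(g)) next
    tot_by <- tapply(colSums(im$values[g, , drop = FALSE]), labels, sum)
    total <- sum(tot_by)
    if (total <= 0) stop("zero total intensity in group ", cv, "/", t)
    df <- data.frame(tissue = t, cultivar = cv,
                     label = names(tot_by), pct = 100 * as.vector(tot_by) / total,
                     stringsAsFactors = FALSE)
    names(df)[names(df) == "label"] <- label_name
    rows[[paste(t, cv)]] <- df
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Total leaf over root intensity ratio per cultivar
#'
#' @param im An `intensity_matrix` containing both tissues.
#' @param treatment Treatment arm (default `"control"`).
#' @return Named numeric vector of ratios, one per cultivar.
#' @export
leaf_root_ratio <- function(im, treatment = "control") {
  .check_im(im)
  meta <- im$meta
  sel <- meta$treatment == treatment
  out <- c()
  for (cv in unique(meta$cultivar[sel])) {
    lf <- sel & meta$cultivar == cv & meta$tissue == "leaf"
    rt <- sel & meta$cultivar == cv & meta$tissue == "root"
    if (!any(lf) || !any(rt)) stop("both tissues required for cultivar ", cv)
    # per-sample means so unbalanced sample counts do not bias the ratio
    num <- mean(rowSums(im$values[lf, , drop = FALSE]))
    den <- mean(rowSums(im$values[rt, , drop = FALSE]))
    if (den <= 0) stop("zero root total for cultivar ", cv)
    out[cv] <- num / den
  }
  out
}

#' Derived log2 equivalent of a linear fold-change threshold
#'
#' @param fc Linear fold-change cutoff (e.g. 2.5).
#' @return `log2(fc)`.
#' @export
log2_fc_threshold <- function(fc) log2(fc)

#' Differential accumulation test (t-test + fold change)
#'
#' Per compound, a two-sample t-test on log2-transformed intensities
#' (Welch by default) between the two treatment arms inside one tissue x
#' cultivar cell, with the fold change computed on linear means.  A
#' compound is called `up` when `fc > fc_up` and `p < p_cut`, `down`
#' when `fc < fc_down` and `p < p_cut`, else `unchanged`; the log2
#' thresholds are derived from the linear cutoffs, never hard-coded.
#'
#' @param im An `intensity_matrix` (injection-level or already
#'   averaged).
#' @param tissue,cultivar The group to test (must select >= 2 biological
#'   replicates per arm).
#' @param average_injections Collapse analytical injections to their
#'   biological replicate mean first (default `TRUE`).
#' @param var_equal `FALSE` for Welch (default), `TRUE` for Student.
#' @param p_cut,fc_up,fc_down Calling thresholds (defaults 0.05, 2.5,
#'   0.4).
#' @param fdr Also report Benjamini-Hochberg adjusted p-values.
#' @param zero_offset Small constant added when an arm mean is zero
#'   (default: half the smallest nonzero intensity); affected compounds
#'   are flagged in `zero_imputed`.
#' @return data.frame per compound: `compound`, `mean_control`,
#'   `mean_treated`, `fc`, `log2fc`, `p_value` (and `p_adj` if `fdr`),
#'   `regulation`, `zero_imputed`.
#' @export
differential_test <- function(im, tissue, cultivar,
                              average_injections = TRUE,
                              var_equal = FALSE, p_cut = 0.05,
                              fc_up = 2.5, fc_down = 0.4, fdr = FALSE,
                              zero_offset = NULL) {
  .check_im(im)
  if (average_injections && "injection" %in% names(im$meta))
    im <- flavomics::average_injections(im)
  meta <- im$meta
  g <- meta$tissue == tissue & meta$cultivar == cultivar
  ctl <- g & meta$treatment == "control"
  trt <- g & meta$treatment != "control"
  if (sum(ctl) < 2 || sum(trt) < 2)
    stop("need >= 2 replicates per arm in ", cultivar, "/", tissue)
  X <- im$values
  if (is.null(zero_offset)) {
    nz <- X[X > 0]
    zero_offset <- if (length(nz)) min(nz) / 2 else 1
  }
  res <- lapply(colnames(X), function(cp) {
    a <- X[ctl, cp]; b <- X[trt, cp]
    m_c <- mean(a); m_t <- mean(b)
    imputed <- m_c == 0 || m_t == 0
    fc <- (m_t + if (imputed) zero_offset else 0) /
          (m_c + if (imputed) zero_offset else 0)
    la <- log2(a + if (any(c(a, b) == 0)) zero_offset else 0)
    lb <- log2(b + if (any(c(a, b) == 0)) zero_offset else 0)
    p <- if (stats::sd(la) == 0 && stats::sd(lb) == 0) {
      if (isTRUE(all.equal(mean(la), mean(lb)))) 1 else 0
    } else stats::t.test(lb, la, var.equal = var_equal)$p.value
    data.frame(compound = cp, mean_control = m_c, mean_treated = m_t,
               fc = fc, log2fc = log2(fc), p_value = p,
               zero_imputed = imputed, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  if (fdr) out$p_adj <- stats::p.adjust(out$p_value, "BH")
  out$regulation <- ifelse(out$fc > fc_up & out$p_value < p_cut, "up",
                    ifelse(out$fc < fc_down & out$p_value < p_cut, "down",
                           "unchanged"))
  rownames(out) <- NULL
  out
}

#' Hierarchical clustering with Pearson distance, complete linkage
#'
#' Distance between rows is `1 - Pearson r`; merges use complete
#' linkage (the pairing used for the sample/compound heatmaps of this
#' analysis style).  Rows with zero variance have no defined
#' correlation and are excluded with a warning.
#'
#' @param x Numeric matrix; rows are the objects to cluster.
#' @return A `cluster_result`: list with `hclust` (stats::hclust
#'   object), `dropped` (zero-variance row names).
#' @export
hierarchical_cluster <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 2) stop("need at least 2 rows to cluster")
  v <- apply(x, 1, stats::sd)
  dropped <- rownames(x)[v == 0]
  if (length(dropped)) {
    warning("excluding zero-variance row(s): ", paste(dropped, collapse = ", "))
    x <- x[v > 0, , drop = FALSE]
  }
  if (nrow(x) < 2) stop("fewer than 2 rows with nonzero variance")
  d <- stats::as.dist(1 - stats::cor(t(x)))
  structure(list(hclust = stats::hclust(d, method = "complete"),
                 dropped = dropped),
            class = "cluster_result")
}

#' Export a clustering as a Newick tree string
#'
#' @param cl A `cluster_result`.
#' @param path Optional file; when given the tree is written there.
#' @return The Newick string, invisibly when writing to file.
#' @export
cluster_newick <- function(cl, path = NULL) {
  stopifnot(inherits(cl, "cluster_result"))
  tree <- ape::as.phylo(cl$hclust)
  if (is.null(path)) return(ape::write.tree(tree))
  ape::write.tree(tree, file = path)
  invisible(ape::write.tree(tree))
}

#' Principal component analysis on autoscaled data
#'
#' Each variable (column) is mean-centered and divided by its standard
#' deviation before eigendecomposition, so every compound contributes
#' equal a-priori variance.  Zero-variance variables are dropped with a
#' warning.  Component signs follow the convention that the
#' largest-magnitude loading of each component is positive.
#'
#' @param x Samples x variables numeric matrix (>= 2 samples, >= 2
#'   variables with nonzero variance).
#' @return A `pca_result`: list with `scores` (samples x components),
#'   `loadings` (variables x components), `explained_variance`
#'   (fractions, non-increasing), `scaled` (the autoscaled matrix),
#'   `dropped`.
#' @export
pca_autoscaled <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 2 || ncol(x) < 2) stop("need >= 2 samples and >= 2 variables")
  v <- apply(x, 2, stats::sd)
  dropped <- colnames(x)[v == 0]
  if (length(dropped)) {
    warning("dropping zero-variance variable(s): ",
            paste(dropped, collapse = ", "))
    x <- x[, v > 0, drop = FALSE]
  }
  if (ncol(x) < 2) stop("fewer than 2 variables with nonzero variance")
  xs <- scale(x, center = TRUE, scale = TRUE)
  s <- svd(xs)
  k <- sum(s$d > max(s$d) * 1e-12)
  scores <- s$u[, seq_len(k), drop = FALSE] %*% diag(s$d[seq_len(k)], k)
  loadings <- s$v[, seq_len(k), drop = FALSE]
  # sign convention: largest-|loading| entry positive per component
  for (j in seq_len(k)) {
    i <- which.max(abs(loadings[, j]))
    if (loadings[i, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  ev <- s$d[seq_len(k)]^2 / sum(s$d^2)
  dimnames(scores) <- list(rownames(x), paste0("PC", seq_len(k)))
  dimnames(loadings) <- list(colnames(x), paste0("PC", seq_len(k)))
  structure(list(scores = scores, loadings = loadings,
                 explained_variance = ev,
                 scaled = xs, dropped = dropped),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat("<pca_result> explained variance (%):",
      paste(sprintf("%.1f", 100 * utils::head(x$explained_variance, 5)),
            collapse = ", "), "\n")
  invisible(x)
}
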