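#' Per-gene mean and variance across tissues
#'
#' Arithmetic mean and sample variance (n - 1 denominator) of each gene's
#' TPM across tissues. All-zero genes are retained with mean 0 and
#' variance 0. At least 3 tissues are required for the downstream variance
#' screen to be defined.
#'
#' @param x A `SummarizedExperiment` with a `tpm` assay, or a numeric
#'   genes x tissues matrix with rownames.
#' @return A `DataFrame` with columns `gene_id`, `mean_tpm`, `var_tpm`;
#'   the tissue count is kept in `metadata(.)$n_tissues`.
#' @export
geneStats <- function(x) {
    mat <- if (is(x, "SummarizedExperiment")) assay(x, "tpm") else as.matrix(x)
    if (ncol(mat) < 3L)
        stop("at least 3 tissues are required (got ", ncol(mat), ")")
    if (any(mat < 0)) stop("TPM values must be non-negative")
    m <- rowMeans(mat)
    v <- rowSums((mat - m)^2) / (ncol(mat) - 1L)
    out <- S4Vectors::DataFrame(gene_id = rownames(mat), mean_tpm = unname(m),
                                var_tpm = unname(v))
    S4Vectors::metadata(out)$n_tissues <- ncol(mat)
    out
}

#' Fit the mean-variance trend by lowess
#'
#' Fits variance as a nonparametric function of mean expression with
#' [stats::lowess()] and records each gene's fitted value in `trend_var`.
#' Robustness iterations are off by default because the chi-squared screen
#' downstream treats the trend as the conditional mean of total variance.
#' Fitted values are floored at a small positive constant; genes with a
#' mean outside the fitted range get the nearest-endpoint fitted value.
#'
#' @param stats Output of [geneStats()].
#' @param span Lowess span (fraction of genes per local fit; default 0.3).
#' @param iter Lowess robustness iterations (default 0).
#' @param floor Lower bound applied to fitted values (default 1e-8).
#' @return `stats` with a `trend_var` column added.
#' @export
fitVarianceTrend <- function(stats, span = 0.3, iter = 0L, floor = 1e-8) {
    if (nrow(stats) < 30L)
        stop("need at least 30 genes to fit a variance trend (got ",
             nrow(stats), ")")
    x <- stats$mean_tpm; y <- stats$var_tpm
    if (diff(range(x)) == 0)
        stop("degenerate input: all gene means are identical")
    lo <- stats::lowess(x, y, f = span, iter = iter)
    fitted <- stats::approx(lo$x, lo$y, xout = x, rule = 2, ties = mean)$y
    stats$trend_var <- pmax(fitted, floor)
    stats
}

#' Chi-squared variability screen against the trend
#'
#' Under the null that a gene's total variance equals the trend at its
#' mean, the statistic `s = (T - 1) * var_tpm / trend_var` follows a
#' chi-squared distribution with `T - 1` degrees of freedom (`T` tissues).
#' `p_hvg` is the upper-tail probability of that distribution at `s` --
#' small for highly variable genes, near 1 for quiet genes -- and
#' `fdr_hvg` its Benjamini-Hochberg adjustment over all genes. The
#' housekeeping screen keeps the *non*-variable end (`fdr_hvg > 0.9`).
#'
#' @param stats Output of [fitVarianceTrend()].
#' @param nTissues Number of tissues; defaults to the count recorded by
#'   [geneStats()].
#' @return `stats` with `p_hvg` and `fdr_hvg` columns added.
#' @export
hvgFdr <- function(stats, nTissues = NULL) {
    if (is.null(stats$trend_var)) stop("run fitVarianceTrend() first")
    if (is.null(nTissues)) nTissues <- S4Vectors::metadata(stats)$n_tissues
    if (is.null(nTissues) || nTissues < 3L)
        stop("nTissues must be at least 3")
    if (any(stats$trend_var <= 0)) stop("trend_var must be positive")
    df <- nTissues - 1L
    s <- df * stats$var_tpm / stats$trend_var
    stats$p_hvg <- stats::pchisq(s, df = df, lower.tail = FALSE)
    stats$fdr_hvg <- stats::p.adjust(stats$p_hvg, method = "BH")
    stats
}

#' Select ubiquitously expressed, low-variance housekeeping genes
#'
#' A gene is selected when it is expressed everywhere (`mean_tpm >=
#' meanTpmMin`, inclusive), not significantly variable (`fdr_hvg >
#' fdrMin`, strict), and -- by default -- its variance lies below the
#' smoothed trend. The trend comparison uses the gene's own fitted value;
#' `trendComparison = "global"` compares to the mean of all fitted values
#' instead.
#'
#' @param stats Output of [hvgFdr()].
#' @param fdrMin FDR threshold, exclusive (default 0.9).
#' @param meanTpmMin Mean-TPM threshold, inclusive (default 5).
#' @param requireVarBelowTrend Require `var_tpm < trend_var` (default TRUE).
#' @param trendComparison `"pointwise"` (default) or `"global"`.
#' @return Character vector of selected gene ids.
#' @export
selectHousekeeping <- function(stats, fdrMin = 0.9, meanTpmMin = 5,
                               requireVarBelowTrend = TRUE,
                               trendComparison = c("pointwise", "global")) {
    trendComparison <- match.arg(trendComparison)
    need <- c("gene_id", "mean_tpm", "var_tpm", "trend_var", "fdr_hvg")
    if (!all(need %in% colnames(stats)))
        stop("stats must carry columns: ", paste(need, collapse = ", "))
    ref <- if (trendComparison == "pointwise") stats$trend_var
           else rep(mean(stats$trend_var), nrow(stats))
    sel <- stats$fdr_hvg > fdrMin & stats$mean_tpm >= meanTpmMin
    if (requireVarBelowTrend) sel <- sel & stats$var_tpm < ref
    as.character(stats$gene_id[sel])
}

#' One-call housekeeping-gene selection
#'
#' Convenience wrapper running [geneStats()], [fitVarianceTrend()],
#' [hvgFdr()] and [selectHousekeeping()] on an expression matrix.
#'
#' @inheritParams geneStats
#' @inheritParams fitVarianceTrend
#' @inheritParams selectHousekeeping
#' @param log1p Apply `log1p` to the TPM values before computing
#'   statistics (off by default; statistics are computed on TPM as given).
#' @return A list with elements `stats` (the annotated `DataFrame`) and
#'   `genes` (selected gene ids).
#' @export
screenHousekeeping <- function(x, span = 0.3, fdrMin = 0.9, meanTpmMin = 5,
                               requireVarBelowTrend = TRUE, log1p = FALSE,
                               trendComparison = c("pointwise", "global")) {
    mat <- if (is(x, "SummarizedExperiment")) assay(x, "tpm") else as.matrix(x)
    if (log1p) {
        lmat <- log1p(mat)
        st <- geneStats(lmat)
        # the mean filter keeps its TPM-scale meaning
        st$mean_tpm_raw <- rowMeans(mat)[match(st$gene_id, rownames(mat))]
    } else {
        st <- geneStats(mat)
    }
    st <- fitVarianceTrend(st, span = span)
    st <- hvgFdr(st)
    if (log1p) {
        sel <- st$fdr_hvg > fdrMin & st$mean_tpm_raw >= meanTpmMin
        if (requireVarBelowTrend) sel <- sel & st$var_tpm < st$trend_var
        genes <- as.character(st$gene_id[sel])
    } else {
        genes <- selectHousekeeping(st, fdrMin = fdrMin,
                                    meanTpmMin = meanTpmMin,
                                    requireVarBelowTrend = requireVarBelowTrend,
                                    trendComparison = match.arg(trendComparison))
    }
    st$selected <- st$gene_id %in% genes
    list(stats = st, genes = genes)
}
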