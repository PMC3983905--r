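# Statistical comparison layer: two-sample Kolmogorov-Smirnov, Welch t
# and Pearson correlation, as used for all pairwise comparisons of
# per-gene window averages. Thin wrappers over the stats package with
# the degenerate-input contracts made explicit.

#' Two-sample Kolmogorov-Smirnov test
#'
#' Two-sided KS test: `D` is the supremum over x of the absolute ECDF
#' difference; the p-value uses the asymptotic Kolmogorov distribution
#' with effective sample size `n_a * n_b / (n_a + n_b)` (the samples
#' compared here are hundreds to thousands of genes, where the
#' asymptotic approximation is accurate). Ties between genic window
#' averages are harmless for D and are tolerated silently.
#'
#' @param a,b numeric samples, each of size >= 2.
#' @return List with `method`, `statistic` (D), `p.value`, `n` (the two
#'   sample sizes).
#' @examples
#' ksTwoSample(c(1, 2, 3, 4), c(3, 4, 5, 6))$statistic   # 0.5
#' @export
ksTwoSample <- function(a, b) {
    if (length(a) < 2 || length(b) < 2)
        stop("each sample must contain at least 2 values")
    ht <- suppressWarnings(ks.test(a, b, exact = FALSE))
    list(method = "ks", statistic = unname(ht$statistic),
         p.value = min(unname(ht$p.value), 1),
         n = c(length(a), length(b)))
}

#' Pearson product-moment correlation
#'
#' @param x,y numeric vectors of equal length >= 3 with non-zero
#'   variance.
#' @return The correlation coefficient in `[-1, 1]`.
#' @export
pearsonR <- function(x, y) {
    if (length(x) != length(y)) stop("x and y must have equal length")
    if (length(x) < 3) stop("need at least 3 pairs")
    if (sd(x) == 0) stop("zero variance in x")
    if (sd(y) == 0) stop("zero variance in y")
    cor(x, y)
}

#' Welch two-sample t test
#'
#' Unequal-variance t statistic with Welch-Satterthwaite degrees of
#' freedom, two-sided.
#'
#' @param a,b numeric samples, each of size >= 2; at least one must
#'   have non-zero variance.
#' @return List with `method`, `statistic` (t), `p.value`, `df`, `n`.
#' @export
tTestWelch <- function(a, b) {
    if (length(a) < 2 || length(b) < 2)
        stop("each sample must contain at least 2 values")
    if (sd(a) == 0 && sd(b) == 0)
        stop("both samples have zero variance")
    ht <- t.test(a, b, var.equal = FALSE)
    list(method = "welch_t", statistic = unname(ht$statistic),
         p.value = unname(ht$p.value),
         df = unname(ht$parameter), n = c(length(a), length(b)))
}

#' Serialize test results to a TSV report
#'
#' @param results named list of test-result lists (from
#'   [ksTwoSample()] / [tTestWelch()]).
#' @param path output path.
#' @param header optional `#`-prefixed provenance lines.
#' @return `path`, invisibly.
#' @export
writeTestReport <- function(results, path, header = character(0)) {
    df <- do.call(rbind, lapply(names(results), function(nm) {
        r <- results[[nm]]
        data.frame(comparison = nm, method = r$method,
                   statistic = r$statistic, p.value = r$p.value,
                   n_a = r$n[1], n_b = r$n[2])
    }))
    con <- file(path, "w")
    on.exit(close(con))
    if (length(header)) writeLines(header, con)
    write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}
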