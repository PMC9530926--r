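#' TMM normalization factors
#'
#' Trimmed-mean-of-M-values between-sample normalization: the reference is
#' the sample whose upper quartile is closest to the mean upper quartile;
#' each sample's factor is 2 to the precision-weighted mean of the log2
#' expression ratios (M values) after trimming the most extreme `trim_m` of
#' M and `trim_a` of A values and excluding zero-count genes, and factors
#' are rescaled to geometric mean 1.  Computed with edgeR.
#'
#' @param counts A [count_matrix()] or genes x samples matrix (>= 2
#'   samples, no all-zero sample).
#' @param trim_m Fraction of M values trimmed (default 0.30).
#' @param trim_a Fraction of A values trimmed (default 0.05).
#' @return If given a `count_matrix`, the same object with `norm_factors`
#'   filled in; otherwise a named numeric vector of factors.
#' @export
tmm_factors <- function(counts, trim_m = 0.30, trim_a = 0.05) {
  obj <- NULL
  if (inherits(counts, "count_matrix")) {
    obj <- counts
    counts <- counts$counts
  }
  if (ncol(counts) < 2L) abort("TMM needs at least 2 samples")
  zero <- colSums(counts) == 0
  if (any(zero)) {
    abort(sprintf("sample(s) with all-zero counts: %s",
                  paste(colnames(counts)[zero], collapse = ", ")))
  }
  f <- edgeR::calcNormFactors(counts, method = "TMM",
                              logratioTrim = trim_m, sumTrim = trim_a)
  f <- setNames(as.numeric(f), colnames(counts))
  if (is.null(obj)) return(f)
  obj$norm_factors <- f
  obj
}

#' Log2 counts per million on TMM-effective library sizes
#'
#' @param counts A [count_matrix()]; TMM factors are computed if absent.
#' @param prior Pseudo-count added before the log (default 1).
#' @return Matrix of `log2(cpm + prior)`, genes x samples.
#' @export
log_cpm <- function(counts, prior = 1) {
  stopifnot(inherits(counts, "count_matrix"))
  if (is.null(counts$norm_factors)) counts <- tmm_factors(counts)
  eff <- colSums(counts$counts) * counts$norm_factors
  log2(sweep(counts$counts, 2, eff / 1e6, `/`) + prior)
}

#' Negative-binomial Wald test for one gene
#'
#' Fits a log-link negative-binomial regression of the gene's counts on
#' condition (exposed vs control) with an offset of log(library size x TMM
#' factor).  The per-gene dispersion is estimated by method of moments on
#' the offset-normalized counts (floored at 1e-8); the condition
#' coefficient, divided by log 2, is the log2 fold change, with its Wald
#' standard error and two-sided normal p value.
#'
#' @param counts A [count_matrix()] with both conditions non-empty.
#' @param gene Gene name (row of the count matrix).
#' @return One-row tibble: `gene`, `base_mean`, `log2fc`, `se`, `stat`,
#'   `p`, `regulation` (`"up"`/`"down"` relative to control), `dispersion`.
#'   All-zero genes return `NA` statistics with `tested = FALSE`.
#' @export
nb_wald_test <- function(counts, gene) {
  stopifnot(inherits(counts, "count_matrix"))
  if (!gene %in% rownames(counts$counts)) {
    abort(sprintf("unknown gene: %s", gene))
  }
  if (is.null(counts$norm_factors)) counts <- tmm_factors(counts)
  if (any(table(counts$condition) == 0)) {
    abort("both conditions must be non-empty")
  }
  y <- counts$counts[gene, ]
  eff <- colSums(counts$counts) * counts$norm_factors
  nb_wald_fit(y, counts$condition, eff, gene)
}

nb_wald_fit <- function(y, condition, eff, gene) {
  na_row <- tibble(
    gene = gene, base_mean = mean(y / eff * mean(eff)),
    log2fc = NA_real_, se = NA_real_, stat = NA_real_, p = NA_real_,
    regulation = NA_character_, dispersion = NA_real_, tested = FALSE
  )
  if (all(y == 0)) return(na_row)

  s <- eff / exp(mean(log(eff)))  # geometric-mean-centred size factors
  z <- y / s
  # method-of-moments dispersion pooled across conditions:
  # Var(z) ~ mu * E[1/s] + phi * mu^2 within each group
  phi_hat <- 0; df_tot <- 0
  for (g in levels(condition)) {
    zg <- z[condition == g]
    sg <- s[condition == g]
    if (length(zg) < 2L) next
    m <- mean(zg)
    v <- var(zg)
    if (m > 0) {
      phi_hat <- phi_hat + (length(zg) - 1) * (v - m * mean(1 / sg)) / m^2
      df_tot <- df_tot + (length(zg) - 1)
    }
  }
  phi <- max(if (df_tot > 0) phi_hat / df_tot else 0, 1e-8)

  fit <- tryCatch(
    suppressWarnings(stats::glm(
      y ~ condition, offset = log(eff),
      family = MASS::negative.binomial(theta = 1 / phi)
    )),
    error = function(e) NULL
  )
  if (is.null(fit)) return(na_row)
  cf <- summary(fit)$coefficients
  if (nrow(cf) < 2L) return(na_row)
  beta <- cf[2, 1]
  se <- cf[2, 2]
  zstat <- beta / se
  tibble(
    gene = gene, base_mean = mean(y / eff * mean(eff)),
    log2fc = beta / log(2), se = se / log(2), stat = zstat,
    p = 2 * pnorm(-abs(zstat)),
    regulation = ifelse(beta >= 0, "up", "down"),
    dispersion = phi, tested = TRUE
  )
}

#' Differential-expression test over all genes
#'
#' Runs the negative-binomial Wald test ([nb_wald_test()]) for every gene,
#' excludes all-zero genes from the testing universe, and attaches
#' Benjamini--Hochberg adjusted p values (denominator = number of genes
#' actually tested).
#'
#' @param counts A [count_matrix()].
#' @return Tibble with one row per gene, ordered as the count matrix, with
#'   `p_adj` added.
#' @export
de_test <- function(counts) {
  stopifnot(inherits(counts, "count_matrix"))
  if (is.null(counts$norm_factors)) counts <- tmm_factors(counts)
  if (any(table(counts$condition) == 0)) {
    abort("both conditions must be non-empty")
  }
  eff <- colSums(counts$counts) * counts$norm_factors
  res <- purrr::map_dfr(rownames(counts$counts), function(g) {
    nb_wald_fit(counts$counts[g, ], counts$condition, eff, g)
  })
  res$p_adj <- NA_real_
  res$p_adj[res$tested] <- bh_adjust(res$p[res$tested])
  res
}

#' Benjamini--Hochberg step-up adjustment
#'
#' @param p Numeric p values in `[0, 1]`.
#' @return Adjusted p values (monotone in rank, capped at 1).
#' @export
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03))  # all 0.03
bh_adjust <- function(p) {
  if (any(!is.finite(p)) || any(p < 0 | p > 1)) {
    abort("p values must lie in [0, 1]")
  }
  p.adjust(p, method = "BH")
}

#' Select differentially expressed genes
#'
#' @param results Tibble from [de_test()].
#' @param alpha Adjusted-p threshold (default 0.01).
#' @return Rows with `p_adj <= alpha`, sorted by p.
#' @export
select_de <- function(results, alpha = 0.01) {
  stopifnot(all(c("gene", "p", "p_adj") %in% names(results)))
  results %>%
    filter(!is.na(.data$p_adj), .data$p_adj <= alpha) %>%
    arrange(.data$p)
}
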