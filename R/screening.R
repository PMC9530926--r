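#' Per-band correlations between microRNAs and an audiological outcome
#'
#' Pearson correlation of each microRNA's `log2(normalized count + 1)` with
#' the outcome level in each frequency band, over the common subjects.
#' A constant microRNA or band yields an undefined correlation, recorded as
#' `NA` and treated as non-passing downstream.
#'
#' @param expr Matrix of expression values, microRNAs x subjects (e.g. from
#'   [log_cpm()]), or a [count_matrix()] (log-CPM is taken).
#' @param outcomes Wide tibble: `subject` column plus one numeric column per
#'   band (dB).
#' @return Tibble with columns `mirna`, `band`, `r`.
#' @export
correlation_matrix <- function(expr, outcomes) {
  if (inherits(expr, "count_matrix")) expr <- log_cpm(expr)
  stopifnot(is.matrix(expr), "subject" %in% names(outcomes))
  subj <- outcomes$subject
  if (!all(subj %in% colnames(expr)) || !all(colnames(expr) %in% subj)) {
    abort("subject sets of expression matrix and outcome table must match")
  }
  if (length(subj) < 3L) abort("need at least 3 subjects to correlate")
  expr <- expr[, subj, drop = FALSE]
  bands <- setdiff(names(outcomes), "subject")
  out <- suppressWarnings(
    cor(t(expr), as.matrix(outcomes[bands]), method = "pearson")
  )
  as_tibble(out, rownames = "mirna") %>%
    tidyr::pivot_longer(-"mirna", names_to = "band", values_to = "r")
}

#' Screen microRNAs by the multi-band correlation rule
#'
#' A microRNA is selected for an outcome when its correlation exceeds the
#' threshold in absolute value (`|r| > threshold`, strictly) in at least
#' `min_bands` different frequency bands.  Applied independently per
#' outcome; the dominant sign is the sign of the median passing correlation
#' (`"mixed"` when passing signs disagree).
#'
#' @param correlations Tibble from [correlation_matrix()] (`mirna`, `band`,
#'   `r`), optionally with an `outcome` column to screen per outcome.
#' @param threshold Absolute-correlation threshold (default 0.3).
#' @param min_bands Minimum number of passing bands (default 3).
#' @return Tibble with one row per microRNA (x outcome): `n_bands_passing`,
#'   `selected`, `dominant_sign` (`"positive"`, `"negative"`, `"mixed"`,
#'   or `NA` when nothing passes).
#' @export
#' @examples
#' co <- tibble::tibble(
#'   mirna = "miR-x", band = paste0("b", 1:5),
#'   r = c(0.4, 0.35, -0.31, 0, 0)
#' )
#' screen_mirnas(co)
screen_mirnas <- function(correlations, threshold = 0.3, min_bands = 3L) {
  stopifnot(all(c("mirna", "band", "r") %in% names(correlations)))
  if (!"outcome" %in% names(correlations)) {
    correlations$outcome <- NA_character_
  }
  n_bands <- correlations %>%
    group_by(.data$outcome) %>%
    summarise(nb = dplyr::n_distinct(.data$band), .groups = "drop")
  if (any(min_bands > n_bands$nb)) {
    abort("min_bands exceeds the number of frequency bands")
  }
  correlations %>%
    group_by(.data$mirna, .data$outcome) %>%
    summarise(
      n_bands_passing = sum(!is.na(.data$r) & abs(.data$r) > threshold),
      dominant_sign = {
        pass <- .data$r[!is.na(.data$r) & abs(.data$r) > threshold]
        if (length(pass) == 0L) NA_character_
        else if (all(pass > 0)) "positive"
        else if (all(pass < 0)) "negative"
        else if (median(sign(pass)) > 0) "positive"
        else if (median(sign(pass)) < 0) "negative"
        else "mixed"
      },
      .groups = "drop"
    ) %>%
    mutate(selected = .data$n_bands_passing >= min_bands) %>%
    arrange(desc(.data$n_bands_passing), .data$mirna)
}
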