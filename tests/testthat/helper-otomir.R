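# shared fixtures, all generated in code

tiny_cohort <- function(seed = 1L, n_genes = 120L, ...) {
  cfg <- cohort_config(seed = seed, ...)
  eff <- planted_effects(n_genes = n_genes)
  subjects <- generate_subjects(cfg)
  aud <- generate_audiology(subjects, eff, seed = seed + 1L)
  counts <- generate_counts(subjects, eff, mean_depth = 2e5, seed = seed + 2L)
  list(subjects = subjects, hl = aud$hl, dpoae = aud$dpoae,
       counts = counts, effects = eff)
}

# screening simulation: a latent auditory-damage factor u drives 6 correlated
# outcome bands (inter-band correlation 0.4); 12 coupled microRNAs attain a
# per-band correlation of ~0.6 (alternating sign), 44 are independent noise
sim_screen_data <- function(n = 17L, seed = 1L, n_coupled = 12L,
                            n_null = 44L, n_bands = 6L) {
  set.seed(seed)
  u <- rnorm(n)
  bands <- vapply(seq_len(n_bands),
                  function(b) u + rnorm(n, 0, sqrt(1.5)), numeric(n))
  colnames(bands) <- paste0("b", seq_len(n_bands))
  coupled <- t(vapply(seq_len(n_coupled), function(k) {
    (-1)^k * u + rnorm(n, 0, sqrt(0.111))
  }, numeric(n)))
  null <- matrix(rnorm(n_null * n), n_null)
  expr <- rbind(coupled, null)
  rownames(expr) <- c(paste0("coupled", seq_len(n_coupled)),
                      paste0("null", seq_len(n_null)))
  colnames(expr) <- paste0("s", seq_len(n))
  outcomes <- tibble::as_tibble(bands)
  outcomes <- dplyr::bind_cols(tibble::tibble(subject = colnames(expr)),
                               outcomes)
  list(expr = expr, outcomes = outcomes,
       coupled = rownames(expr)[seq_len(n_coupled)],
       null = rownames(expr)[-seq_len(n_coupled)])
}

# long repeated-measures data with a known per-band microRNA slope
sim_long_data <- function(n_subj = 200L, n_bands = 11L, beta = -2,
                          subj_sd = 3, resid_sd = 2, seed = 1L,
                          genotype_effect = c(wt = 0, het = 0, mut = 0)) {
  set.seed(seed)
  subj <- sprintf("s%03d", seq_len(n_subj))
  m <- rnorm(n_subj)
  b0 <- rnorm(n_subj, 0, subj_sd)
  geno <- factor(sample(c("wt", "het", "mut"), n_subj, replace = TRUE,
                        prob = c(0.49, 0.42, 0.09)),
                 levels = c("wt", "het", "mut"))
  bands <- paste0("F", seq_len(n_bands))
  beta <- rep_len(beta, n_bands)
  wide <- tibble::tibble(subject = subj)
  for (k in seq_len(n_bands)) {
    wide[[bands[k]]] <- 20 + k + b0 + beta[k] * m +
      genotype_effect[as.character(geno)] +
      rnorm(n_subj, 0, resid_sd)
  }
  covars <- tibble::tibble(subject = subj, mirna_level = m,
                           hOGG1 = as.character(geno))
  list(wide = wide, covars = covars, beta = beta)
}

# exhaustive minimum spanning tree by Pruefer-sequence enumeration (n <= 6)
brute_force_mst <- function(d) {
  n <- nrow(d)
  stopifnot(n >= 2, n <= 6)
  if (n == 2) return(d[1, 2])
  tree_weight <- function(pruefer) {
    deg <- rep(1L, n)
    for (s in pruefer) deg[s] <- deg[s] + 1L
    total <- 0
    avail <- rep(TRUE, n)
    for (s in pruefer) {
      leaf <- which(avail & deg == 1L)[1]
      total <- total + d[leaf, s]
      deg[leaf] <- 0L
      avail[leaf] <- FALSE
      deg[s] <- deg[s] - 1L
    }
    last <- which(avail & deg == 1L)
    total + d[last[1], last[2]]
  }
  seqs <- as.matrix(expand.grid(rep(list(seq_len(n)), n - 2)))
  min(apply(seqs, 1, tree_weight))
}

random_distance_matrix <- function(n, seed) {
  set.seed(seed)
  d <- matrix(0, n, n)
  d[upper.tri(d)] <- runif(n * (n - 1) / 2, 0.05, 1)
  d <- d + t(d)
  diag(d) <- NA_real_
  dimnames(d) <- list(LETTERS[seq_len(n)], LETTERS[seq_len(n)])
  d
}
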