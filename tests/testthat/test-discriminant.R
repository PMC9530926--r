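test_that("dichotomization applies the strict thresholds with boundary to normal", {
  subjects <- tibble::tibble(
    id = c("a", "b", "c", "d"),
    hOGG1 = factor(c("wt", "het", "mut", "wt"), c("wt", "het", "mut")),
    XRCC1 = factor(c("wt", "het", "wt", "mut"), c("wt", "het", "mut"))
  )
  hl <- tibble::tibble(subject = subjects$id,
                       F500 = c(30, 29, 28, 40), F1000 = c(30, 29, 28, 40))
  dp <- tibble::tibble(subject = subjects$id,
                       DP1153 = c(15, 16, 17, 10), DP1452 = c(15, 16, 17, 10))

  gh <- dichotomize(subjects, "HL_mean", hl = hl)
  expect_equal(gh$label, c("impaired", "normal", "normal", "impaired"))
  expect_equal(unique(gh$threshold), 29)

  gd <- dichotomize(subjects, "DPOAE_mean", dpoae = dp)
  expect_equal(gd$label, c("impaired", "normal", "normal", "impaired"))
  expect_equal(unique(gd$threshold), 16)

  gg <- dichotomize(subjects, "hOGG1")
  expect_equal(gg$label, c("wt", "mut_het", "mut_het", "wt"))
  gx <- dichotomize(subjects, "XRCC1")
  expect_equal(gx$label, c("wt_mut", "het", "wt_mut", "wt_mut"))

  expect_error(dichotomize(subjects, "HL_mean", hl = hl[1:3, ]), "missing")
  same <- dplyr::mutate(hl, F500 = 10, F1000 = 10)
  expect_warning(dichotomize(subjects, "HL_mean", hl = same), "empty group")
})

test_that("sparse PLS-DA selects the separating variable and matches the dense oracle", {
  set.seed(1)
  n <- 24
  labels <- rep(c("A", "B"), each = n / 2)
  x <- matrix(rnorm(n * 8), n, dimnames = list(NULL, paste0("v", 1:8)))
  x[, 3] <- ifelse(labels == "B", 3, -3) + rnorm(n, 0, 0.2)

  m1 <- fit_spls_da(x, labels, n_components = 2, keep = 1)
  expect_equal(m1$selected[[1]], "v3")
  expect_equal(sum(m1$weights[, 1] != 0), 1)

  # dense limit: component-1 weights proportional to the X'y oracle
  md <- fit_spls_da(x, labels, n_components = 2, keep = 8)
  x0 <- scale(x)
  y <- ifelse(labels == "B", 1, -1); y <- y - mean(y)
  w_oracle <- drop(crossprod(x0, y))
  w_oracle <- w_oracle / sqrt(sum(w_oracle^2))
  if (sign(w_oracle[which.max(abs(w_oracle))]) < 0) w_oracle <- -w_oracle
  expect_equal(unname(md$weights[, 1]), unname(w_oracle), tolerance = 1e-6)

  # scores invariant (up to the fixed sign convention) under column reordering
  perm <- sample(ncol(x))
  mp <- fit_spls_da(x[, perm], labels, n_components = 2, keep = 8)
  expect_equal(abs(unname(mp$scores[, 1])), abs(unname(md$scores[, 1])),
               tolerance = 1e-8)

  expect_error(fit_spls_da(x, labels, keep = 9), "exceeds")
  expect_error(fit_spls_da(x, rep("A", n), keep = 2), "two levels")
  expect_error(fit_spls_da(x, c("B", rep("A", n - 1)), keep = 2),
               "at least 2 subjects")
})

test_that("planted discriminators are recovered on component 1 across seeds", {
  hits <- vapply(seq_len(50), function(seed) {
    set.seed(seed)
    n <- 34
    labels <- rep(c("normal", "impaired"), each = 17)
    x <- matrix(rnorm(n * 56), n, dimnames = list(NULL, paste0("m", 1:56)))
    for (j in 1:5) {
      x[, j] <- x[, j] + ifelse(labels == "impaired", 1, -1)  # shift = 2 SD
    }
    m <- fit_spls_da(x, labels, n_components = 2, keep = 5)
    sum(m$selected[[1]] %in% paste0("m", 1:5))
  }, numeric(1))
  expect_gte(mean(hits >= 4), 0.9)
})

test_that("shuffled labels collapse the score separation to the permutation null", {
  set.seed(7)
  n <- 30
  labels <- rep(c("A", "B"), each = n / 2)
  x <- matrix(rnorm(n * 20), n, dimnames = list(NULL, paste0("v", 1:20)))
  x[, 1:3] <- x[, 1:3] + ifelse(labels == "B", 1.5, -1.5)

  sep <- function(lab) {
    m <- fit_spls_da(x, lab, n_components = 2, keep = 5)
    s <- m$scores[, 1]
    abs(mean(s[lab == unique(lab)[1]]) - mean(s[lab == unique(lab)[2]])) /
      sd(s)
  }
  real <- sep(labels)
  nulls <- vapply(1:30, function(i) {
    set.seed(100 + i)
    sep(sample(labels))
  }, numeric(1))
  expect_gt(real, max(nulls))
})

test_that("component 1 selection agrees with an independent sPLS-DA implementation", {
  skip_if_not_installed("mixOmics")
  set.seed(11)
  n <- 40
  labels <- rep(c("A", "B"), each = n / 2)
  x <- matrix(rnorm(n * 30), n, dimnames = list(NULL, paste0("v", 1:30)))
  for (j in 1:4) x[, j] <- x[, j] + ifelse(labels == "B", 1.2, -1.2)
  mine <- fit_spls_da(x, labels, n_components = 2, keep = 5)
  ref <- mixOmics::splsda(x, factor(labels), ncomp = 2, keepX = c(5, 5))
  ref_sel <- mixOmics::selectVar(ref, comp = 1)$name
  expect_setequal(mine$selected[[1]], ref_sel)
})

test_that("biplot tables filter arrows and orient the discrimination direction", {
  set.seed(21)
  n <- 40
  labels <- rep(c("normal", "impaired"), each = n / 2)
  x <- matrix(rnorm(n * 10), n, dimnames = list(NULL, paste0("v", 1:10)))
  x[, 2] <- x[, 2] + ifelse(labels == "impaired", 2, -2)
  m <- fit_spls_da(x, labels, n_components = 2, keep = 3)
  tabs <- biplot_tables(m, corr_cutoff = 0.75)

  expect_true("v2" %in% tabs$arrows$variable)
  # noise variables uncorrelated with the scores are excluded at 0.75
  expect_false("v7" %in% tabs$arrows$variable)
  # cutoff zero keeps every variable
  expect_equal(nrow(biplot_tables(m, corr_cutoff = 0)$arrows), 10)
  # unit direction; the planted discriminator points toward the group it
  # elevates (impaired is the second factor level here: "normal" < "impaired"
  # alphabetically reversed), so its arrow projects positively on the
  # centroid-difference direction toward impaired
  expect_equal(sum(tabs$direction^2), 1, tolerance = 1e-9)
  arrow_v2 <- unlist(tabs$arrows[tabs$arrows$variable == "v2",
                                 c("cor1", "cor2")])
  dir_to_impaired <- unlist(tabs$direction) *
    (if (m$levels[2] == "impaired") 1 else -1)
  expect_gt(sum(arrow_v2 * dir_to_impaired), 0)

  m1 <- fit_spls_da(x, labels, n_components = 1, keep = 3)
  expect_error(biplot_tables(m1), "2 components")
})
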