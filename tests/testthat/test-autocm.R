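test_that("scaling to [0,1] with complements satisfies the exact-sum contract", {
  df <- tibble::tibble(
    id = paste0("s", 1:3),
    x = c(0, 5, 10),
    geno = factor(c("wt", "het", "mut")),
    flat = c(2, 2, 2)
  )
  expect_warning(sc <- scale_with_complements(df), "flat")
  expect_equal(unname(sc$data[, "Max_x"]), c(0, 0.5, 1))
  expect_equal(unname(sc$data[, "Min_x"]), c(1, 0.5, 0))
  # Max + Min identically 1, every cell in [0, 1]
  p <- ncol(sc$data) / 2
  expect_equal(sc$data[, 1:p] + sc$data[, p + 1:p],
               matrix(1, 3, p), ignore_attr = TRUE)
  expect_true(all(sc$data >= 0 & sc$data <= 1))
  # genotype expanded to per-variant indicators tagged as polymorphism
  expect_true(all(c("Max_geno_wt", "Max_geno_het", "Max_geno_mut") %in%
                    colnames(sc$data)))
  expect_equal(unique(sc$meta$provenance[sc$meta$base == "geno_wt"]),
               "polymorphism")
})

test_that("autocm training is bounded, monotone, deterministic and co-activation driven", {
  # all-zero data: no updates at all
  z <- matrix(0, 5, 3, dimnames = list(NULL, c("a", "b", "c")))
  mz <- train_autocm(z, max_epochs = 3)
  expect_equal(unique(as.vector(mz$W)), mz$C / 1e6)

  set.seed(1)
  x <- matrix(runif(40 * 6), 40, dimnames = list(NULL, paste0("v", 1:6)))
  m1 <- train_autocm(x, max_epochs = 30)
  m2 <- train_autocm(x, max_epochs = 30)
  expect_identical(m1$W, m2$W)  # bit-identical given record order
  expect_true(all(m1$W >= 0 & m1$W < m1$C))
  expect_true(all(m1$v >= 0 & m1$v < m1$C))

  # monotone growth: weights after more epochs dominate earlier weights
  m_short <- train_autocm(x, max_epochs = 5)
  expect_true(all(m1$W - m_short$W >= -1e-12))

  # duplicated columns attain the dominant mutual association in their rows
  set.seed(2)
  y <- matrix(runif(200 * 8), 200)
  y[, 2] <- y[, 1]
  colnames(y) <- paste0("v", 1:8)
  md <- train_autocm(y, max_epochs = 30)
  wb <- (md$W + t(md$W)) / 2
  diag(wb) <- NA
  expect_equal(which.max(wb[1, ]), c(v2 = 2L))
  expect_equal(which.max(wb[2, ]), c(v1 = 1L))

  expect_error(train_autocm(matrix(c(0.5, 1.5), 1)), "\\[0, 1\\]")
  expect_error(train_autocm(x, C = -1), "positive")
})

test_that("weight-to-distance conversion is a monotone symmetric map", {
  set.seed(3)
  x <- matrix(runif(30 * 5), 30, dimnames = list(NULL, paste0("v", 1:5)))
  m <- train_autocm(x, max_epochs = 20)
  d <- weights_to_distances(m)
  expect_true(all(is.na(diag(d))))
  expect_equal(d, t(d))
  wb <- (m$W + t(m$W)) / 2
  off <- upper.tri(d)
  # larger weight => smaller distance; strength C maps to distance 0
  expect_equal(d[off], 1 - wb[off] / m$C)
  expect_true(all(d[off] > 0 & d[off] <= 1))
  ord_w <- order(wb[off])
  expect_equal(ord_w, order(-d[off]))
})

test_that("Kruskal MST matches the hand example and brute-force enumeration", {
  d <- matrix(NA_real_, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  d["A", "B"] <- d["B", "A"] <- 1
  d["A", "C"] <- d["C", "A"] <- 2
  d["A", "D"] <- d["D", "A"] <- 3
  d["B", "C"] <- d["C", "B"] <- 4
  d["B", "D"] <- d["D", "B"] <- 5
  d["C", "D"] <- d["D", "C"] <- 6
  g <- minimum_spanning_tree(d)
  expect_equal(nrow(g$edges), 3)
  expect_setequal(paste(g$edges$from, g$edges$to), c("A B", "A C", "A D"))
  expect_equal(g$total_distance, 6)

  # exhaustive oracle on random complete graphs up to 6 vertices
  for (case in 1:60) {
    n <- 3 + case %% 4
    dm <- random_distance_matrix(n, seed = case)
    mst <- minimum_spanning_tree(dm)
    expect_equal(nrow(mst$edges), n - 1)
    expect_equal(mst$total_distance, brute_force_mst(dm), tolerance = 1e-12)
  }

  # vertex-permutation equivariance
  dm <- random_distance_matrix(6, seed = 123)
  perm <- c(4, 2, 6, 1, 3, 5)
  dp <- dm[perm, perm]
  e1 <- minimum_spanning_tree(dm)$edges
  e2 <- minimum_spanning_tree(dp)$edges
  canon <- function(e) sort(paste(pmin(e$from, e$to), pmax(e$from, e$to)))
  expect_equal(canon(e1), canon(e2))
})

test_that("igraph agrees with the Kruskal MST total distance", {
  dm <- random_distance_matrix(6, seed = 77)
  mst <- minimum_spanning_tree(dm)
  g <- igraph::graph_from_adjacency_matrix(
    replace(dm, is.na(dm), 0), mode = "undirected", weighted = TRUE
  )
  ref <- igraph::mst(g, weights = igraph::E(g)$weight)
  expect_equal(mst$total_distance, sum(igraph::E(ref)$weight),
               tolerance = 1e-12)
})

test_that("spinnet reaches the two-node closed form and contracts geometrically", {
  W <- matrix(c(0, 2, 2, 0), 2, dimnames = list(c("A", "B"), c("A", "B")))
  model <- structure(
    list(v = c(0, 0), W = W, C = 10, epochs = 1L, history = 0,
         variables = c("A", "B"), meta = NULL),
    class = "autocm_model"
  )
  q <- spinnet_query(model, "A", damping = 0.9)
  expect_equal(q$activation[q$variable == "A"], 1)
  expect_equal(q$activation[q$variable == "B"], 0.9, tolerance = 1e-12)
  expect_equal(q$variable[1], "A")  # clamped variable ranks first

  # geometric contraction of successive differences on a larger system
  set.seed(4)
  x <- matrix(runif(30 * 8), 30, dimnames = list(NULL, paste0("v", 1:8)))
  m <- train_autocm(x, max_epochs = 20)
  wb <- (m$W + t(m$W)) / 2; diag(wb) <- 0
  wt <- wb / rowSums(wb)
  a <- setNames(numeric(8), m$variables); a["v1"] <- 1
  deltas <- numeric(12)
  for (it in 1:12) {
    a_new <- setNames(pmin(1, 0.95 * drop(crossprod(wt, a))), names(a))
    a_new["v1"] <- 1
    deltas[it] <- max(abs(a_new - a))
    a <- a_new
  }
  expect_true(all(diff(log(deltas[3:12])) < 0))

  full <- spinnet_query(m, "v1", damping = 0.95)
  expect_true(all(full$activation >= 0 & full$activation <= 1))
  expect_gt(attr(full, "cycles"), 1)
  expect_error(spinnet_query(m, character(0)), "at least one")
  expect_error(spinnet_query(m, "v1", damping = 1), "strictly in")
  expect_error(spinnet_query(m, "nope"), "not in the model")
})

test_that("spinnet activation ranks MST-adjacent variables above distant ones", {
  # planted block structure: v1..v4 strongly co-vary, v5..v10 independent
  set.seed(5)
  n <- 120
  u <- runif(n)
  x <- cbind(
    vapply(1:4, function(k) pmin(1, pmax(0, u + rnorm(n, 0, 0.08))),
           numeric(n)),
    matrix(runif(n * 6), n)
  )
  colnames(x) <- paste0("v", 1:10)
  m <- train_autocm(x, max_epochs = 30)
  mst <- minimum_spanning_tree(m)
  q <- spinnet_query(m, "v1")
  top4 <- q$variable[!q$clamped][1:3]
  expect_true(all(top4 %in% paste0("v", 2:4)))
})

test_that("graph export round-trips through GraphML with attributes", {
  set.seed(6)
  x <- matrix(runif(30 * 5), 30, dimnames = list(NULL, paste0("v", 1:5)))
  sc_meta <- tibble::tibble(variable = paste0("v", 1:5),
                            provenance = c("HL", "HL", "DPOAE", "microRNA",
                                           "microRNA"))
  m <- train_autocm(x, max_epochs = 20)
  m$meta <- sc_meta
  mst <- minimum_spanning_tree(m)
  path <- withr::local_tempfile(fileext = ".graphml")
  export_graph(mst, path)
  back <- import_graph(path)
  canon <- function(e) {
    dplyr::arrange(
      dplyr::transmute(e, a = pmin(from, to), b = pmax(from, to),
                       d = round(distance, 10)), a, b)
  }
  expect_equal(canon(back$edges), canon(mst$edges))
  expect_setequal(back$vertices$name, mst$vertices$name)
  expect_equal(
    back$vertices$provenance[match(mst$vertices$name, back$vertices$name)],
    mst$vertices$provenance
  )
  expect_equal(back$total_distance, mst$total_distance, tolerance = 1e-9)

  # DOT export is accepted too; unknown extensions and degenerate graphs not
  dot <- withr::local_tempfile(fileext = ".dot")
  export_graph(mst, dot)
  expect_true(file.size(dot) > 0)
  expect_error(export_graph(mst, "x.csv"), "unsupported")
  empty <- structure(list(vertices = tibble::tibble(name = character()),
                          edges = tibble::tibble()),
                     class = "association_graph")
  expect_error(export_graph(empty, path), "empty")
  dup <- mst
  dup$vertices$name[2] <- dup$vertices$name[1]
  expect_error(export_graph(dup, path), "duplicate")
})
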