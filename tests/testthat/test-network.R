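test_that("binarize thresholds symmetric coherence matrices", {
  set.seed(1)
  m <- matrix(runif(25, 0.1, 0.9), 5)
  m <- (m + t(m)) / 2
  diag(m) <- 1
  g <- binarize(m, 0.6)
  expect_true(all(g$adjacency %in% c(0, 1)))
  expect_true(all(diag(g$adjacency) == 0))
  expect_equal(g$adjacency, t(g$adjacency))

  expect_equal(sum(binarize(m, 1.0)$adjacency), 0)
  complete <- binarize(m, 0.0)$adjacency
  expect_equal(sum(complete), 5 * 4)

  bad <- m
  bad[1, 2] <- bad[1, 2] + 1e-6
  expect_error(binarize(bad), "symmetric")
  expect_error(binarize(m * 2), "0, 1|\\[0, 1\\]")
})

test_that("known small graphs give textbook metrics", {
  k4 <- matrix(1, 4, 4) - diag(4)
  g <- structure(list(adjacency = k4, labels = letters[1:4],
                      band = NA, threshold = NA), class = "binary_graph")
  m <- graph_metrics(g)
  expect_equal(m$strength, 3)
  expect_equal(m$cc, 1)
  expect_equal(m$L, 1)

  path3 <- matrix(c(0, 1, 0, 1, 0, 1, 0, 1, 0), 3)
  gp <- structure(list(adjacency = path3, labels = letters[1:3],
                       band = NA, threshold = NA), class = "binary_graph")
  mp <- graph_metrics(gp)
  expect_equal(mp$strength, 4 / 3)
  expect_equal(mp$cc, 0)
  expect_equal(mp$L, 4 / 3)

  empty <- structure(list(adjacency = matrix(0, 3, 3), labels = letters[1:3],
                          band = NA, threshold = NA), class = "binary_graph")
  me <- graph_metrics(empty)
  expect_equal(me$strength, 0)
  expect_equal(me$cc, 0)
  expect_true(is.na(me$L))
})

test_that("metrics agree exactly with brute-force oracles on random graphs", {
  set.seed(42)
  for (i in 1:30) {
    n <- sample(3:12, 1)
    adj <- random_adjacency(n)
    g <- structure(list(adjacency = adj, labels = paste0("n", 1:n),
                        band = NA, threshold = NA), class = "binary_graph")
    got <- graph_metrics(g)
    want <- graph_metrics_oracle(adj)
    expect_identical(is.na(got$L), is.na(want$L))
    expect_equal(got$strength, want$strength)
    expect_equal(got$cc, want$cc)
    if (!is.na(want$L)) expect_equal(got$L, want$L)
  }
})

test_that("adding an edge never increases L nor decreases strength", {
  set.seed(7)
  for (i in 1:20) {
    adj <- random_adjacency(8, p = 0.3)
    off <- which(adj == 0 & upper.tri(adj), arr.ind = TRUE)
    if (nrow(off) == 0) next
    pick <- off[sample(nrow(off), 1), ]
    adj2 <- adj
    adj2[pick[1], pick[2]] <- adj2[pick[2], pick[1]] <- 1
    g1 <- graph_metrics_oracle(adj)
    mk <- function(a) structure(list(adjacency = a, labels = paste0("n", 1:8),
                                     band = NA, threshold = NA),
                                class = "binary_graph")
    m1 <- graph_metrics(mk(adj))
    m2 <- graph_metrics(mk(adj2))
    expect_gte(m2$strength, m1$strength)
    if (!is.na(m1$L) && !is.na(m2$L) && m1$unreachable_fraction == 0) {
      expect_lte(m2$L, m1$L)
    }
  }
})

test_that("network features produce 3 indices per band", {
  cohs <- lapply(resteeg:::.default_bands(), function(be) {
    m <- matrix(0.7, 4, 4)
    diag(m) <- 1
    dimnames(m) <- list(letters[1:4], letters[1:4])
    m
  })
  v <- network_features(cohs, threshold = 0.6)
  expect_length(v, 15)
  expect_true(all(grepl("^net:(delta|theta|alpha|beta|gamma):(strength|CC|L)$",
                        names(v))))
  expect_equal(unname(v["net:alpha:strength"]), 3)
  expect_equal(unname(v["net:alpha:CC"]), 1)
})
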