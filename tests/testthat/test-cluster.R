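chain_adj <- function(labels) {
  # simple chain adjacency: each electrode neighbours the next
  nb <- stats::setNames(vector("list", length(labels)), labels)
  for (i in seq_along(labels)) {
    nb[[i]] <- labels[c(i - 1, i + 1)[c(i - 1, i + 1) >= 1 &
                                      c(i - 1, i + 1) <= length(labels)]]
  }
  structure(nb, class = "sbc_adjacency")
}

mk_tmap <- function(t, df = 9) {
  structure(list(t = t, df = df), class = "sbc_tmap")
}

# independent flood-fill over the cell grid for the component oracle
oracle_clusters <- function(t, tcrit, adj_labels, freq_adjacent = TRUE) {
  nch <- nrow(t); nb <- ncol(t)
  supra <- abs(t) > tcrit
  comp <- matrix(0L, nch, nb); cid <- 0L
  for (c0 in seq_len(nch)) for (b0 in seq_len(nb)) {
    if (!supra[c0, b0] || comp[c0, b0] != 0) next
    cid <- cid + 1L
    queue <- list(c(c0, b0)); comp[c0, b0] <- cid
    while (length(queue)) {
      cell <- queue[[1]]; queue <- queue[-1]
      ch <- cell[1]; b <- cell[2]
      cand <- lapply(which(rownames(t) %in% adj_labels[[rownames(t)[ch]]]),
                     function(cc) c(cc, b))
      if (freq_adjacent) {
        if (b > 1) cand <- c(cand, list(c(ch, b - 1)))
        if (b < nb) cand <- c(cand, list(c(ch, b + 1)))
      }
      for (cc in cand) {
        if (supra[cc[1], cc[2]] && comp[cc[1], cc[2]] == 0 &&
            sign(t[cc[1], cc[2]]) == sign(t[ch, b])) {
          comp[cc[1], cc[2]] <- cid
          queue <- c(queue, list(cc))
        }
      }
    }
  }
  comp
}

test_that("template adjacency is symmetric with a plausible neighbour count", {
  lay <- channel_layout()
  adj <- build_adjacency(lay)
  expect_setequal(names(adj), lay$label)
  for (l in names(adj)) {
    expect_false(l %in% adj[[l]])
    for (nb in adj[[l]]) expect_true(l %in% adj[[nb]])
  }
  expect_gte(median(lengths(adj)), 4)
  expect_lte(median(lengths(adj)), 8)
  # two electrodes at quantile 1 are mutual neighbours
  adj2 <- build_adjacency(channel_layout(c("Cz", "Pz")), 1)
  expect_equal(adj2$Cz, "Pz")
  # degenerate quantile empties the graph with a warning
  expect_warning(a0 <- build_adjacency(lay, 0), "isolated")
  expect_true(any(lengths(a0) == 0))
})

test_that("the paired t-map matches the textbook formula", {
  set.seed(12)
  a <- array(rnorm(5 * 1 * 1), c(5, 1, 1))
  b <- array(rnorm(5 * 1 * 1), c(5, 1, 1))
  tm <- paired_tmap(a, b)
  d <- a[, 1, 1] - b[, 1, 1]
  expect_equal(tm$t[1, 1], mean(d) / (sd(d) / sqrt(5)))
  expect_equal(tm$df, 4)
  # identical inputs give a zero map; a constant shift has the right sign
  expect_true(all(paired_tmap(a, a)$t == 0))
  expect_gt(paired_tmap(a + 5, a)$t[1, 1], 0)
  # cross-check against stats::t.test
  expect_equal(tm$t[1, 1],
               unname(stats::t.test(a[, 1, 1], b[, 1, 1], paired = TRUE)$statistic))
})

test_that("cluster finding equals an exhaustive flood fill on hand-set maps", {
  labels <- c("e1", "e2", "e3")
  adj <- chain_adj(labels)
  t <- matrix(c(5, 4, 0.1,
                -4, 0.2, 6), nrow = 3,
              dimnames = list(labels, NULL))
  tm <- mk_tmap(t)
  tcrit <- qt(0.975, tm$df)
  cl <- find_clusters(tm, adj)
  comp <- oracle_clusters(t, tcrit, adj)
  expect_equal(length(cl), max(comp))
  for (c_i in cl) {
    cells <- comp[cbind(match(c_i$members$channel, labels), c_i$members$bin)]
    expect_equal(length(unique(cells)), 1)  # one oracle component each
    expect_equal(c_i$mass, sum(t[cbind(match(c_i$members$channel, labels),
                                       c_i$members$bin)]))
  }
  # adjacent supra-threshold cells of opposite sign stay distinct
  t2 <- matrix(c(5, -5, 0), nrow = 3, dimnames = list(labels, NULL))
  cl2 <- find_clusters(mk_tmap(t2), adj)
  expect_equal(length(cl2), 2)
  expect_setequal(vapply(cl2, `[[`, numeric(1), "sign"), c(1, -1))
  # sub-threshold maps produce no clusters
  expect_equal(find_clusters(mk_tmap(t2 * 0.01), adj), list())
})

test_that("randomised fuzz maps agree with the flood-fill oracle", {
  labels <- paste0("e", 1:4)
  adj <- chain_adj(labels)
  set.seed(21)
  for (i in 1:20) {
    t <- matrix(rnorm(4 * 3, sd = 3), 4, dimnames = list(labels, NULL))
    fa <- i %% 2 == 0
    cl <- find_clusters(mk_tmap(t), adj, freq_adjacent = fa)
    comp <- oracle_clusters(t, qt(0.975, 9), adj, freq_adjacent = fa)
    expect_equal(length(cl), max(comp))
    expect_equal(sum(lengths(lapply(cl, function(c) c$members$bin))),
                 sum(comp > 0))
  }
})

test_that("the Monte-Carlo permutation p matches exhaustive sign-flipping", {
  labels <- c("e1", "e2")
  adj <- chain_adj(labels)
  set.seed(33)
  a <- matrix(rnorm(5 * 2, mean = 1.6), 5, 2, dimnames = list(NULL, labels))
  b <- matrix(rnorm(5 * 2), 5, 2, dimnames = list(NULL, labels))
  res <- permutation_test(a, b, adj, n_perm = 2000, escalate_to = 2000,
                          seed = 1)
  expect_gt(length(res$clusters), 0)
  # oracle: all 2^5 = 32 sign-flip assignments, exhaustively
  d <- a - b
  obs_mass <- abs(res$clusters[[1]]$mass)
  flips <- as.matrix(expand.grid(rep(list(c(-1, 1)), 5)))
  maxmass <- apply(flips, 1, function(f) {
    tm <- paired_tmap(array(f * d, c(5, 2, 1), list(NULL, labels, NULL)),
                      array(0, c(5, 2, 1), list(NULL, labels, NULL)))
    cl <- find_clusters(tm, adj)
    if (length(cl) == 0) 0 else max(abs(vapply(cl, `[[`, numeric(1), "mass")))
  })
  p_exact <- mean(maxmass >= obs_mass)
  p_mc <- res$clusters[[1]]$p
  se <- sqrt(p_exact * (1 - p_exact) / 2000)
  expect_lt(abs(p_mc - p_exact), 2 * se + 2 / 2001)
})

test_that("identical conditions never produce spuriously certain clusters", {
  labels <- c("e1", "e2")
  adj <- chain_adj(labels)
  set.seed(40)
  a <- matrix(rnorm(8 * 2), 8, 2, dimnames = list(NULL, labels))
  res <- permutation_test(a, a, adj, n_perm = 200, escalate_to = 200)
  expect_equal(min_cluster_p(res), 1)  # no clusters at all: t == 0
  # a strong uniform shift spans all cells at the smallest attainable p
  res2 <- permutation_test(a + 10, a, adj, n_perm = 200, escalate_to = 200,
                           seed = 2)
  expect_equal(length(res2$clusters), 1)
  expect_equal(nrow(res2$clusters[[1]]$members), 2)
  expect_equal(res2$clusters[[1]]$p,
               (sum(res2$max_null >= abs(res2$clusters[[1]]$mass)) + 1) / 201)
})

test_that("the permutation distribution is symmetric under relabelling", {
  labels <- c("e1", "e2")
  adj <- chain_adj(labels)
  set.seed(55)
  a <- matrix(rnorm(6 * 2, 1), 6, 2, dimnames = list(NULL, labels))
  b <- matrix(rnorm(6 * 2), 6, 2, dimnames = list(NULL, labels))
  r1 <- permutation_test(a, b, adj, n_perm = 500, escalate_to = 500, seed = 7)
  r2 <- permutation_test(b, a, adj, n_perm = 500, escalate_to = 500, seed = 7)
  expect_identical(r1$max_null, r2$max_null)
  expect_equal(vapply(r1$clusters, `[[`, numeric(1), "p"),
               vapply(r2$clusters, `[[`, numeric(1), "p"))
  expect_equal(vapply(r1$clusters, `[[`, numeric(1), "sign"),
               -vapply(r2$clusters, `[[`, numeric(1), "sign"))
  # seed determinism
  r3 <- permutation_test(a, b, adj, n_perm = 500, escalate_to = 500, seed = 7)
  expect_identical(r1$max_null, r3$max_null)
})
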