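test_that("spearman maps reproduce perfect concordance and discordance", {
  x <- c(1, 2, 3, 4, 5, 6)
  Y <- array(0, c(6, 2, 2))
  Y[, 1, 1] <- x * 3 + 2          # identical ordering
  Y[, 1, 2] <- -x                 # reversed
  Y[, 2, 1] <- rnorm(6)
  Y[, 2, 2] <- 7                  # zero variance
  m <- spearman_map(x, Y)
  expect_equal(m$rho[1, 1], 1)
  expect_equal(m$rho[1, 2], -1)
  expect_true(is.na(m$rho[2, 2]) && is.na(m$p[2, 2]))
  expect_error(spearman_map(rep(1, 6), Y), "zero variance")
  expect_error(spearman_map(x[1:4], Y[1:4, , , drop = FALSE]), "at least 5")
})

test_that("n = 6 maps agree with exhaustive rank enumeration", {
  set.seed(51)
  x <- rnorm(6)
  Y <- array(rnorm(6 * 3 * 4), c(6, 3, 4))
  Y[, 2, 2] <- round(Y[, 2, 2])   # induce possible ties
  m <- spearman_map(x, Y)
  rx <- rank(x)
  for (i in 1:3) for (j in 1:4) {
    ry <- rank(Y[, i, j])
    obs <- cor(rx, ry)
    # brute force over all 720 assignments
    perms <- tacsbeta:::.all_permutations(6)
    null <- apply(perms, 1, function(pp) cor(rx[pp], ry))
    expect_equal(m$rho[i, j], obs, tolerance = 1e-12)
    expect_equal(m$p[i, j], mean(abs(null) >= abs(obs) - 1e-12),
                 tolerance = 1e-12)
  }
})

test_that("large-n p-values use the t approximation", {
  set.seed(52)
  x <- rnorm(12)
  Y <- array(rnorm(12 * 2 * 2), c(12, 2, 2))
  m <- spearman_map(x, Y)
  for (i in 1:2) for (j in 1:2) {
    r <- cor(x, Y[, i, j], method = "spearman")
    tt <- r * sqrt(10 / (1 - r^2))
    expect_equal(m$p[i, j], 2 * pt(-abs(tt), 10), tolerance = 1e-12)
  }
})

test_that("clustering follows 4-adjacency with sign separation and |rho| mass", {
  rho <- matrix(0, 4, 4)
  p <- matrix(1, 4, 4)
  rho[1, 1] <- 0.6; rho[1, 2] <- 0.7; rho[2, 1] <- 0.55; rho[2, 2] <- 0.65
  p[1:2, 1:2] <- 0.01
  map <- structure(list(rho = rho, p = p, n = 10), class = "correlation_map")
  cr <- threshold_clusters(map)
  expect_length(cr$clusters, 1)
  expect_equal(cr$clusters[[1]]$mass, 2.5)
  # diagonal touch does not join
  rho2 <- matrix(0, 4, 4); p2 <- matrix(1, 4, 4)
  rho2[1, 1] <- 0.6; rho2[2, 2] <- 0.6; p2[1, 1] <- p2[2, 2] <- 0.01
  cr2 <- threshold_clusters(structure(list(rho = rho2, p = p2, n = 10),
                                      class = "correlation_map"))
  expect_length(cr2$clusters, 2)
  # adjacent pixels of opposite sign stay separate
  rho3 <- matrix(0, 4, 4); p3 <- matrix(1, 4, 4)
  rho3[1, 1] <- 0.6; rho3[1, 2] <- -0.6; p3[1, 1:2] <- 0.01
  cr3 <- threshold_clusters(structure(list(rho = rho3, p = p3, n = 10),
                                      class = "correlation_map"))
  expect_length(cr3$clusters, 2)
  expect_setequal(vapply(cr3$clusters, `[[`, numeric(1), "sign"), c(1, -1))
  # no supra-threshold pixel -> no clusters
  cr4 <- threshold_clusters(structure(list(rho = rho, p = matrix(1, 4, 4),
                                           n = 10),
                                      class = "correlation_map"))
  expect_length(cr4$clusters, 0)
})

test_that("connected components match an igraph oracle on random grids", {
  skip_if_not_installed("igraph")
  set.seed(53)
  for (rep in 1:10) {
    mask <- matrix(runif(25) < 0.4, 5, 5)
    lab <- tacsbeta:::.label_components(mask)
    # oracle: lattice graph over supra pixels, 4-neighbour edges
    idx <- which(mask, arr.ind = TRUE)
    if (nrow(idx) == 0) {
      expect_equal(max(lab), 0)
      next
    }
    g <- igraph::make_empty_graph(n = nrow(idx), directed = FALSE)
    if (nrow(idx) > 1) {
      edges <- c()
      for (a in seq_len(nrow(idx) - 1)) for (b in (a + 1):nrow(idx)) {
        if (sum(abs(idx[a, ] - idx[b, ])) == 1) edges <- c(edges, a, b)
      }
      if (length(edges)) g <- igraph::add_edges(g, edges)
    }
    comp <- igraph::components(g)
    expect_equal(max(lab), comp$no)
    # same partition: pixels share a label iff they share a component
    labs <- lab[idx]
    expect_true(all(outer(labs, labs, "==") ==
                      outer(comp$membership, comp$membership, "==")))
  }
})

test_that("cluster mass grows monotonically when adjacent pixels join", {
  rho <- matrix(0, 4, 4); p <- matrix(1, 4, 4)
  rho[2, 2] <- 0.6; p[2, 2] <- 0.01
  m1 <- threshold_clusters(structure(list(rho = rho, p = p, n = 10),
                                     class = "correlation_map"))
  rho[2, 3] <- 0.4; p[2, 3] <- 0.02
  m2 <- threshold_clusters(structure(list(rho = rho, p = p, n = 10),
                                     class = "correlation_map"))
  expect_length(m2$clusters, 1)
  expect_gt(m2$clusters[[1]]$mass, m1$clusters[[1]]$mass)
})

test_that("the permutation test is deterministic and sign-symmetric", {
  set.seed(54)
  x <- rnorm(12)
  Y <- array(rnorm(12 * 8 * 8), c(12, 8, 8))
  r1 <- permutation_cluster_test(x, Y, n_permutations = 150, seed = 7)
  r2 <- permutation_cluster_test(x, Y, n_permutations = 150, seed = 7)
  expect_identical(r1$null_distribution, r2$null_distribution)
  expect_identical(r1$significant, r2$significant)
  # negating x mirrors cluster signs exactly
  rneg <- permutation_cluster_test(-x, Y, n_permutations = 150, seed = 7)
  s1 <- vapply(r1$clusters, `[[`, numeric(1), "sign")
  s2 <- vapply(rneg$clusters, `[[`, numeric(1), "sign")
  m1 <- vapply(r1$clusters, `[[`, numeric(1), "mass")
  m2 <- vapply(rneg$clusters, `[[`, numeric(1), "mass")
  expect_equal(sort(m1), sort(m2), tolerance = 1e-12)
  expect_equal(sum(s1), -sum(s2))
  expect_error(permutation_cluster_test(x, Y, n_permutations = 50),
               "at least 100")
})

test_that("Monte-Carlo nulls match full enumeration on small problems", {
  set.seed(55)
  x <- rnorm(6)
  Y <- array(rnorm(6 * 4 * 4), c(6, 4, 4))
  res <- permutation_cluster_test(x, Y, n_permutations = 600, seed = 9)
  # exact null: every one of the 720 assignments
  perms <- tacsbeta:::.all_permutations(6)
  exact <- apply(perms, 1, function(pp) {
    m <- spearman_map(x[pp], Y)
    cl <- tacsbeta:::.find_clusters(m, 0.05)
    if (length(cl)) max(vapply(cl, `[[`, numeric(1), "mass")) else 0
  })
  obs_masses <- vapply(res$clusters, `[[`, numeric(1), "mass")
  if (length(obs_masses)) {
    p_exact <- vapply(obs_masses, function(m) mean(exact >= m), numeric(1))
    p_mc <- res$p_rank
    expect_lt(max(abs(p_exact - p_mc)), 0.08)
  }
  expect_lt(abs(quantile(exact, 0.975) - res$threshold),
            max(0.2, 0.2 * res$threshold) + 1e-9)
})

test_that("the factorial battery covers 72 cells and skips missing ones", {
  sim <- sim_cluster_battery(n_subj = 6, nf = 4, nt = 4, seed = 56)
  out <- run_cluster_analysis(sim$scalars, sim$maps, n_permutations = 100,
                              seed = 3)
  expect_equal(nrow(out$summary), 3 * 2 * 4 * 3)
  expect_length(out$results, 72)
  # dropping one cell's subjects skips exactly that cell
  sim$maps$movement$C4$sham$pre_post1 <- NULL
  out2 <- run_cluster_analysis(sim$scalars, sim$maps, n_permutations = 100,
                               seed = 3)
  expect_equal(nrow(out2$summary), 71)
})
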