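# The five-node mediation topology used below has paths
# X -> A -> Y (a, g), X -> B -> D -> Y (b, d, h), X -> A -> B -> D -> Y
# (a, c, d, h) and no direct X -> Y edge.
mediation_net <- function(a = 1, b = 1, c = 1, d = 1, g = 1, h = 1) {
  tibble::tibble(
    from = c("X", "A", "X", "A", "B", "D"),
    to = c("A", "Y", "B", "B", "D", "Y"),
    coefficient = c(a, g, b, c, d, h))
}

test_that("path enumeration: chain, empty, and the mediation topology", {
  net <- mediation_net()
  ps <- enumerate_paths(net, "X", "Y")
  expect_equal(nrow(ps), 3L)
  expect_equal(sum(ps$product), 3)  # ag + bdh + acdh with unit weights
  chain <- tibble::tibble(from = c("A", "B"), to = c("B", "C"),
                          coefficient = c(2, 3))
  pc <- enumerate_paths(chain, "A", "C")
  expect_equal(pc$path, "A -> B -> C")
  expect_equal(pc$product, 6)
  expect_equal(nrow(enumerate_paths(chain, "C", "A")), 0L)
})

test_that("worked decomposition: gene MET on systolic blood pressure", {
  net <- tibble::tibble(
    from = c("MET", "MET", "DBP"),
    to = c("SBP", "DBP", "SBP"),
    coefficient = c(-0.0596, 0.0621, 0.605))
  dec <- decompose_effects(net, "MET", "SBP")
  expect_equal(round(dec$indirect, 4), 0.0376)
  expect_equal(round(dec$total, 3), -0.022)
  expect_equal(dec$direct, -0.0596)
  expect_equal(dec$total, dec$direct + dec$indirect, tolerance = 1e-12)
})

test_that("reported effect tables satisfy total = direct + indirect", {
  # rows with both direct and indirect components
  rows <- tibble::tribble(
    ~direct, ~indirect, ~total,
    0.9458, 0.0161, 0.9619,   # LDL on total cholesterol
    0.0631, -0.0119, 0.0512)  # PIK3R5 on BMI
  expect_equal(round(rows$direct + rows$indirect, 4), rows$total)
})

test_that("edge-only relation and closed-form total-effect oracle", {
  single <- tibble::tibble(from = "A", to = "B", coefficient = 0.7)
  dec <- decompose_effects(single, "A", "B")
  expect_equal(dec$total, 0.7)
  expect_equal(dec$indirect, 0)

  set.seed(1)
  for (rep in 1:3) {
    net <- sim_network(8, 2, expected_degree = 3, n_qtl = 0)
    edges <- net$edges[net$edges$type == "phenotype", ]
    tot <- total_effect_matrix(net$Gamma)
    phen <- colnames(net$Gamma)
    for (pair in list(c(1, 5), c(2, 8), c(3, 7))) {
      s <- phen[pair[1]]
      t <- phen[pair[2]]
      expect_equal(total_effect_paths(edges, s, t), tot[s, t],
                   tolerance = 1e-10)
    }
  }
})

test_that("cycles are refused and two-cycles flagged", {
  cyc <- tibble::tibble(from = c("A", "B", "B"), to = c("B", "A", "C"),
                        coefficient = c(0.5, 0.5, 1))
  expect_warning(enumerate_paths(cyc, "A", "C"), "two-directional")
  expect_error(total_effect_paths(cyc, "A", "C"), "cycle")
  expect_error(suppressWarnings(decompose_effects(cyc, "A", "B")), "cycle")
  tab <- suppressWarnings(effect_table(cyc))
  expect_true(all(tab$cyclic))
})

test_that("conservation holds across random acyclic networks", {
  set.seed(2)
  for (rep in 1:5) {
    net <- sim_network(6, 2, expected_degree = 2.5, n_qtl = 0)
    edges <- net$edges
    phen <- colnames(net$Gamma)
    for (s in phen) for (t in phen) {
      if (s == t) next
      dec <- decompose_effects(edges, s, t)
      expect_equal(dec$total, dec$direct + dec$indirect, tolerance = 1e-8)
    }
  }
})

test_that("intervention regression equals the path-product total effect on
           simulated linear-Gaussian data", {
  set.seed(3)
  n <- 5000
  net <- sim_network(4, 3, expected_degree = 1, n_qtl = 1)
  X <- matrix(stats::rnorm(n * 3), n, 3,
              dimnames = list(NULL, rownames(net$B)))
  Y <- sim_phenotypes(net$Gamma, net$B, X, noise_sd = 1)$Y
  dat <- cbind(as.data.frame(Y), as.data.frame(X))
  edges <- net$edges
  tot <- total_effect_matrix(net$Gamma)
  phen <- colnames(net$Gamma)
  # phenotype sources: adjust for network parents
  A0 <- net$Gamma
  diag(A0) <- 0
  checked <- 0
  for (s in phen) for (t in phen) {
    if (s == t || tot[s, t] == 0) next
    parents <- c(phen[A0[, s] != 0], rownames(net$B)[net$B[, s] != 0])
    est <- total_effect_intervention(dat, s, t, parents = parents)
    expect_lt(abs(est - tot[s, t]), 0.05)
    checked <- checked + 1
  }
  expect_gt(checked, 0)
  # parentless (genotype) sources: simple regression estimates the total
  snp_tot <- net$B %*% (tot + diag(ncol(tot)))  # direct plus mediated
  for (k in rownames(net$B)) {
    for (t in phen) {
      if (snp_tot[k, t] == 0) next
      est <- total_effect_intervention(dat, k, t)
      expect_equal(est, marginal_effect(dat, k, t), tolerance = 1e-10)
      expect_lt(abs(est - snp_tot[k, t]), 0.06)
    }
  }
})

test_that("mediator regression needs the adjustment set", {
  set.seed(4)
  n <- 5000
  x <- stats::rnorm(n)
  m <- 1.2 * x + stats::rnorm(n)
  y <- 0.8 * m + 0.5 * x + stats::rnorm(n)
  dat <- data.frame(X = x, M = m, Y = y)
  simple <- marginal_effect(dat, "M", "Y")
  adjusted <- total_effect_intervention(dat, "M", "Y", parents = "X")
  expect_gt(abs(simple - 0.8), 0.1)       # biased without the parent
  expect_equal(adjusted, 0.8, tolerance = 0.05)
})

test_that("correlation identity reproduces the two-variable regression
           coefficient", {
  set.seed(5)
  for (rep in 1:5) {
    n <- 400
    z <- stats::rnorm(n)
    x <- 0.6 * z + stats::rnorm(n)
    y <- 0.5 * x - 0.7 * z + stats::rnorm(n)
    dat <- data.frame(X = x, Y = y, Z = z)
    b_id <- beta_adjusted(dat, "X", "Y", "Z")
    b_reg <- unname(stats::coef(stats::lm(Y ~ X + Z, dat))["X"])
    expect_equal(b_id, b_reg, tolerance = 1e-8)
  }
  # rho_XZ = 0 or missing Z reduces to the marginal slope
  dat <- data.frame(X = stats::rnorm(100), Y = stats::rnorm(100))
  expect_equal(beta_adjusted(dat, "X", "Y"), marginal_effect(dat, "X", "Y"))
})

test_that("degenerate inputs error clearly", {
  dat <- data.frame(X = rep(1, 10), Y = stats::rnorm(10))
  expect_error(marginal_effect(dat, "X", "Y"), "zero variance")
  dat2 <- data.frame(X = stats::rnorm(10))
  dat2$P <- dat2$X
  dat2$Y <- stats::rnorm(10)
  expect_error(total_effect_intervention(dat2, "X", "Y", parents = "P"),
               "collinear")
})

test_that("effect table reports the standard layout with marginals", {
  set.seed(6)
  n <- 2000
  net <- mediation_net(a = 0.5, b = 0.4, c = 0.3, d = 0.6, g = 0.7,
                       h = 0.5)
  # simulate from the DAG
  X <- stats::rnorm(n)
  A <- 0.5 * X + stats::rnorm(n, sd = 0.2)
  B <- 0.4 * X + 0.3 * A + stats::rnorm(n, sd = 0.2)
  D <- 0.6 * B + stats::rnorm(n, sd = 0.2)
  Y <- 0.7 * A + 0.5 * D + stats::rnorm(n, sd = 0.2)
  dat <- data.frame(X = X, A = A, B = B, D = D, Y = Y)
  tab <- effect_table(net, data = dat)
  expect_named(tab, c("outcome", "causal", "direct", "indirect", "total",
                      "marginal", "cyclic"))
  xy <- tab[tab$causal == "X" & tab$outcome == "Y", ]
  expect_equal(xy$direct, 0)
  expect_equal(xy$total, 0.5 * 0.7 + 0.4 * 0.6 * 0.5 +
                 0.5 * 0.3 * 0.6 * 0.5, tolerance = 1e-6)
  # X is parentless: its marginal estimates the total
  expect_equal(xy$marginal, xy$total, tolerance = 0.05)
})
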