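test_that("classical MDS recovers collinear and Euclidean configurations", {
  D <- matrix(c(0, 1, 2, 1, 0, 1, 2, 1, 0), 3, 3)
  fit <- classical_mds(D, k = 1)
  x <- sort(fit$coords[, 1])
  expect_equal(x, c(-1, 0, 1), ignore_attr = TRUE)
  # zero matrix -> all coordinates zero (no positive eigenvalues)
  expect_warning(z <- classical_mds(matrix(0, 4, 4), k = 2))
  expect_equal(ncol(z$coords), 0)
  # exact recovery of random 3-D Euclidean distances
  set.seed(8)
  pts <- matrix(rnorm(30), 10, 3)
  D3 <- as.matrix(dist(pts))
  fit3 <- classical_mds(D3, k = 3)
  Dhat <- as.matrix(dist(fit3$coords))
  expect_lt(max(abs(Dhat - D3)), 1e-8)
  expect_lt(max(abs(colMeans(fit3$coords))), 1e-10)
  expect_true(all(diff(fit3$eigenvalues) <= 1e-12))
})

test_that("NJ solves 3-taxon branch lengths and additive matrices exactly", {
  D <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  nwk <- nj_tree(D)
  tr <- attr(nwk, "phylo")
  # three-point equations: x+y=3, x+z=4, y+z=5 -> x=1, y=2, z=3
  bl <- stats::setNames(tr$edge.length,
                        tr$tip.label[tr$edge[, 2]])
  expect_equal(sort(unname(bl)), c(1, 2, 3))
  # additive 5-taxon matrix: path metric reproduced exactly
  tree <- ape::read.tree(text = "((a:2,b:3):1,(c:1,d:2):2,e:4);")
  Dadd <- ape::cophenetic.phylo(tree)
  rec <- attr(nj_tree(Dadd), "phylo")
  expect_equal(ape::cophenetic.phylo(rec)[rownames(Dadd), colnames(Dadd)],
               Dadd, tolerance = 1e-10)
  expect_equal(ape::dist.topo(ape::unroot(tree), ape::unroot(rec)), 0,
               ignore_attr = TRUE)
  # identical rows join as a zero-length cherry
  D2 <- matrix(c(0, 0, 5, 5, 0, 0, 5, 5, 5, 5, 0, 2, 5, 5, 2, 0), 4, 4,
               dimnames = list(letters[1:4], letters[1:4]))
  t2 <- attr(nj_tree(D2), "phylo")
  cp <- ape::cophenetic.phylo(t2)
  expect_equal(cp["a", "b"], 0)
  expect_error(nj_tree(D2, labels = c("a", "a", "b", "c")), "duplicate")
})

test_that("K = 1 admixture is the closed-form single-population MLE", {
  set.seed(3)
  sim <- sim_founders(20, 50, chromosomes = 1, seed = 3)
  fit <- admixture_fit(sim$dataset, 1)
  expect_equal(unname(fit$Q[, 1]), rep(1, 20))
  p <- allele_frequencies(sim$dataset)$p
  expect_equal(unname(fit$P[1, ]), p, tolerance = 1e-12)
  X <- sim$dataset$dosage
  pi <- pmin(pmax(rep(p, each = 20), 1e-10), 1 - 1e-10)
  expect_equal(fit$loglik,
               sum(X * log(pi) + (2 - X) * log(1 - pi)))
})

test_that("fixed opposite populations separate completely", {
  # two sources fixed for opposite alleles; unadmixed individuals
  X <- rbind(matrix(0L, 5, 40), matrix(2L, 5, 40))
  ds <- toy_dataset(X)
  fit <- admixture_fit(ds, 2, seed = 4, tol = 1e-8, max_iter = 2000)
  Qtrue <- rbind(matrix(c(1, 0), 5, 2, byrow = TRUE),
                 matrix(c(0, 1), 5, 2, byrow = TRUE))
  al <- align_q(fit$Q, Qtrue)
  expect_lt(max(abs(al$Q - Qtrue)), 1e-3)
})

test_that("EM log-likelihood is monotone and iterates stay feasible", {
  sim <- sim_admixture(K = 3, n = 40, m = 150, fst = 0.15, seed = 5)
  fit <- admixture_fit(sim$dataset, 3, seed = 2, max_iter = 60,
                       n_restarts = 2)
  expect_true(all(diff(fit$loglik_trace) >= -1e-7))
  expect_equal(unname(rowSums(fit$Q)), rep(1, 40), tolerance = 1e-9)
  expect_true(all(fit$Q >= 0))
  expect_true(all(fit$P >= 0 & fit$P <= 1))
  # with missing data too
  ds <- sim$dataset
  ds$dosage[sample(length(ds$dosage), 300)] <- NA
  fitm <- admixture_fit(ds, 2, seed = 2, max_iter = 60)
  expect_true(all(diff(fitm$loglik_trace) >= -1e-7))
  expect_error(admixture_fit(sim$dataset, 99), "K exceeds")
})

test_that("cross-validation prefers the generating K", {
  sim <- sim_admixture(K = 2, n = 60, m = 400, fst = 0.15,
                       dirichlet_alpha = 0.2, seed = 14)
  cv <- admixture_cv(sim$dataset, K_list = 1:3, folds = 3, seed = 14,
                     max_iter = 200)
  expect_equal(cv$selected_K, 2)
  # homogeneous population: K = 1 wins
  hom <- sim_founders(40, 300, chromosomes = 2, seed = 15)
  cvh <- admixture_cv(hom$dataset, K_list = 1:3, folds = 3, seed = 15,
                      max_iter = 200)
  expect_equal(cvh$selected_K, 1)
  # folds partition the observed entries
  expect_equal(dim(cv$fold_errors), c(3L, 3L))
})

test_that("MDS on IBS distances separates synthetic breeds", {
  panel <- sim_breed_panel(n_per_breed = 12, breeds = 3, m = 800,
                           fst = 0.1, seed = 20)
  D <- ibs_distance_matrix(panel$dataset)
  mds <- classical_mds(D, k = 2)
  breed <- panel$truth$breed
  co <- mds$coords
  within <- c()
  between <- c()
  for (i in 1:(nrow(co) - 1)) for (j in (i + 1):nrow(co)) {
    d <- sqrt(sum((co[i, ] - co[j, ])^2))
    if (breed[i] == breed[j]) within <- c(within, d)
    else between <- c(between, d)
  }
  expect_lt(mean(within), mean(between))
  # breed-mean distance matrix is symmetric with zero diagonal
  BD <- breed_distance_matrix(D, breed)
  expect_true(isSymmetric(BD))
  expect_equal(diag(BD), rep(0, 3), ignore_attr = TRUE)
})
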