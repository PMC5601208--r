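test_that("standardization gives mean 0, SD 1 over non-missing entries", {
  df <- data.frame(a = c(1, 2, 3, NA, 10), b = rep(2, 5), c = rnorm(5))
  expect_warning(out <- standardize_traits(df, c("a", "b")), "constant")
  expect_equal(mean(out$a, na.rm = TRUE), 0, tolerance = 1e-9)
  expect_equal(sd(out$a, na.rm = TRUE), 1, tolerance = 1e-9)
  expect_equal(out$b, df$b)  # constant column untouched
})

test_that("pearson matrix matches cor.test and flags degenerate input", {
  set.seed(2)
  x <- rnorm(20)
  m <- cbind(x = x, y = -x, z = rnorm(20))
  pm <- pearson_matrix(m)
  expect_equal(diag(pm$r), rep(1, 3), ignore_attr = TRUE)
  expect_equal(pm$r, t(pm$r))
  expect_equal(pm$r["x", "y"], -1, tolerance = 1e-12)
  expect_lt(pm$p["x", "y"], 1e-10)
  # large-sample consistency at rho = 0.5
  set.seed(3)
  n <- 1e4
  a <- rnorm(n); b <- 0.5 * a + sqrt(1 - 0.25) * rnorm(n)
  pm2 <- pearson_matrix(cbind(a, b))
  expect_lt(abs(pm2$r["a", "b"] - 0.5), 0.03)
  # correlation matrix of a real trait table is positive semi-definite
  set.seed(4)
  tm <- matrix(rnorm(200), 50, 4)
  ev <- eigen(pearson_matrix(tm)$r, symmetric = TRUE, only.values = TRUE)
  expect_true(all(ev$values > -1e-10))
  expect_warning(pearson_matrix(cbind(k = rep(1, 10), j = rnorm(10))),
                 "constant")
})

test_that("PCA strategy score has oriented unit loadings", {
  set.seed(5)
  n <- 1e5
  m <- matrix(rnorm(4 * n), n, 4,
              dimnames = list(NULL, c("time_in_patch", "foraging_effort",
                                      "size_of_patch", "n_patches")))
  sc <- suppressWarnings(pca_ee(m))   # clipping warning is exercised elsewhere
  expect_equal(sc$variance_explained, rep(0.25, 4), tolerance = 0.04)
  expect_equal(sum(sc$variance_explained), 1, tolerance = 1e-12)
  expect_equal(colSums(sc$loadings^2), rep(1, 4), ignore_attr = TRUE,
               tolerance = 1e-9)
  expect_gt(sc$loadings["time_in_patch", 1], 0)

  # two perfectly correlated columns concentrate PC1 on that pair
  set.seed(6)
  a <- rnorm(2000)
  m2 <- cbind(time_in_patch = a, foraging_effort = a,
              size_of_patch = rnorm(2000), n_patches = rnorm(2000))
  sc2 <- suppressWarnings(pca_ee(m2))
  expect_equal(abs(sc2$loadings["time_in_patch", 1]), 1 / sqrt(2),
               tolerance = 0.01)
  expect_equal(abs(sc2$loadings["foraging_effort", 1]), 1 / sqrt(2),
               tolerance = 0.01)

  # row order invariance of loadings and variance fractions
  perm <- sample(nrow(m2))
  sc3 <- suppressWarnings(pca_ee(m2[perm, ]))
  expect_equal(abs(sc3$loadings), abs(sc2$loadings), tolerance = 1e-9)
  expect_equal(sc3$variance_explained, sc2$variance_explained,
               tolerance = 1e-9)

  # affine rescaling of raw traits is absorbed by standardization
  m4 <- m2
  m4[, "size_of_patch"] <- 100 * m4[, "size_of_patch"] - 7
  sc4 <- suppressWarnings(pca_ee(m4))
  expect_equal(sc4$scores, sc2$scores, tolerance = 1e-8)

  expect_error(pca_ee(m2[1:4, ]), "5 complete rows")
})

test_that("log(x + 2) transform is monotone and clips below -2", {
  expect_equal(transform_pc1(-1), 0)
  expect_equal(transform_pc1(0), log(2))
  x <- sort(runif(50, -1.9, 3))   # unclipped region only
  expect_true(all(diff(transform_pc1(x)) > 0))
  expect_warning(y <- transform_pc1(c(-3, 0)), "clipped")
  expect_equal(y[1], log(1e-6))
})

test_that("boldness scores control observer and test number", {
  # identical scores for everyone: all centred estimates zero
  same <- data.frame(bird_id = rep(c("A", "B", "C"), each = 3),
                     observer = "O1", obs_number = rep(1:3, 3), score = 2)
  bs <- boldness_scores(same)
  expect_equal(bs$estimate, rep(0, 3), tolerance = 1e-9)

  # two birds, one observer, equal test counts: estimates -1 and +1
  two <- data.frame(bird_id = rep(c("A", "B"), each = 4), observer = "O1",
                    obs_number = rep(1:4, 2),
                    score = rep(c(1, 3), each = 4))
  bs2 <- boldness_scores(two)
  expect_equal(bs2$estimate[bs2$bird_id == "A"], -1, tolerance = 1e-9)
  expect_equal(bs2$estimate[bs2$bird_id == "B"], 1, tolerance = 1e-9)
  expect_equal(mean(bs2$estimate), 0, tolerance = 1e-12)

  # estimates invariant to observer relabeling
  set.seed(7)
  tests <- data.frame(bird_id = rep(sprintf("b%02d", 1:20), each = 5),
                      observer = sample(c("X", "Y", "Z"), 100, TRUE),
                      obs_number = rep(1:5, 20),
                      score = pmin(4, pmax(0, round(rnorm(100, 2, 1)))))
  bs3 <- boldness_scores(tests)
  relab <- tests
  relab$observer <- chartr("XYZ", "PQR", relab$observer)
  bs4 <- boldness_scores(relab)
  expect_equal(bs3$estimate, bs4$estimate, tolerance = 1e-9)

  # latent boldness recovered despite observer offsets (10 tests/bird)
  set.seed(8)
  latent <- rnorm(40)
  obs_off <- c(O1 = -0.6, O2 = 0, O3 = 0.7)
  sim <- do.call(rbind, lapply(1:40, function(b) {
    ob <- sample(names(obs_off), 10, TRUE)
    data.frame(bird_id = sprintf("b%02d", b), observer = ob,
               obs_number = 1:10,
               score = pmin(4, pmax(0, round(
                 2 + latent[b] + obs_off[ob] + rnorm(10, 0, 0.4)))))
  }))
  bs5 <- boldness_scores(sim)
  expect_gt(cor(bs5$estimate[order(bs5$bird_id)], latent), 0.95)

  # random-intercept mode agrees in ranking
  bs6 <- boldness_scores(sim, method = "random")
  expect_gt(cor(bs5$estimate, bs6$estimate[match(bs5$bird_id,
                                                 bs6$bird_id)]), 0.99)
  expect_error(boldness_scores(data.frame(bird_id = "A", observer = "O",
                                          obs_number = 1, score = 9)),
               "0..4")
})
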