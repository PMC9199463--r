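test_that("log-normalization matches the closed form", {
  m <- Matrix::sparseMatrix(i = c(1, 2), j = c(1, 1), x = c(1, 99),
                            dims = c(3, 2),
                            dimnames = list(paste0("g", 1:3), c("c1", "c2")))
  m[3, 2] <- 50
  norm <- logNormalize(m, scaleFactor = 1e4)
  # c=1, L=100, S=1e4 -> ln(1 + 1*1e4/100) = ln(101)
  expect_equal(norm["g1", "c1"], log(101), tolerance = 1e-12)
  expect_equal(norm["g3", "c1"], 0)          # zero count stays zero
  expect_error(logNormalize(m[, 1, drop = FALSE] * 0), "zero library")
})

test_that("log-normalization is monotone within genes at equal library size", {
  set.seed(8)
  m <- randomCounts(25, 15, seed = 8L)
  # equalize library sizes by padding a filler gene
  libs <- Matrix::colSums(m)
  filler <- max(libs) - libs + 1
  m2 <- rbind(m, Matrix::Matrix(filler, nrow = 1, sparse = TRUE,
                                dimnames = list("filler", colnames(m))))
  norm <- logNormalize(as(m2, "CsparseMatrix"))
  for (g in sample(rownames(m), 5)) {
    expect_identical(order(as.numeric(norm[g, ])), order(as.numeric(m[g, ])))
  }
})

test_that("VST scores match a literal dense reimplementation", {
  m <- randomCounts(50, 40, seed = 12L)
  top <- selectHvgVst(m, 50)
  score <- attr(top, "score")
  # dense step-by-step oracle
  d <- as.matrix(m)
  mu <- rowMeans(d)
  v <- apply(d, 1, var)
  pos <- v > 0
  fit <- loess(log10(v[pos]) ~ log10(mu[pos]), span = 0.3, degree = 2)
  sdExp <- sqrt(10^as.numeric(predict(fit)))
  clip <- sqrt(ncol(d))
  expected <- numeric(nrow(d))
  for (gi in which(pos)) {
    z <- (d[gi, ] - mu[gi]) / sdExp[match(gi, which(pos))]
    z <- pmin(pmax(z, -clip), clip)
    expected[gi] <- var(z)
  }
  expect_equal(unname(score[rownames(d)]), expected, tolerance = 1e-8)
})

test_that("constant genes never outrank varying genes and nTop caps", {
  m <- randomCounts(20, 30, seed = 13L)
  m[5, ] <- 7L   # constant but non-zero
  top <- selectHvgVst(m, 20)
  score <- attr(top, "score")
  expect_equal(unname(score[rownames(m)[5]]), 0)
  expect_true(match(rownames(m)[5], top) > sum(score > 0))
  expect_setequal(top, rownames(m))            # nTop = nGenes: permutation
  expect_warning(selectHvgVst(m, 50), "exceeds")
})

test_that("HVG selection is invariant to gene order permutation", {
  m <- randomCounts(40, 25, seed = 14L)
  set.seed(1)
  perm <- sample(nrow(m))
  a <- selectHvgVst(m, 10)
  b <- selectHvgVst(m[perm, ], 10)
  expect_identical(as.character(a), as.character(b))
})

test_that("collinear cells put all variance on PC1", {
  t_vals <- seq(0, 1, length.out = 12)
  m <- outer(c(1, 2, 3, 0.5), t_vals)   # cells on a line in gene space
  dimnames(m) <- list(paste0("g", 1:4), paste0("c", 1:12))
  emb <- scaleAndPca(m, rownames(m), nPcs = 2, clip = 100)
  expect_equal(varExplained(emb)[1], 1, tolerance = 1e-8)
})

test_that("PCA scores match an eigendecomposition-of-covariance oracle", {
  set.seed(15)
  m <- matrix(rnorm(20 * 10), 20, 10,
              dimnames = list(paste0("g", 1:20), paste0("c", 1:10)))
  emb <- scaleAndPca(m, rownames(m), nPcs = 4, clip = 100)
  # oracle: z-score genes, covariance of cells x genes, eigenvectors
  z <- t(scale(t(m)))
  y <- t(z)
  eig <- eigen(crossprod(y), symmetric = TRUE)
  oracle <- y %*% eig$vectors[, 1:4]
  for (k in 1:4) {
    upToSign <- min(max(abs(pcaScores(emb)[, k] - oracle[, k])),
                    max(abs(pcaScores(emb)[, k] + oracle[, k])))
    expect_lt(upToSign, 1e-6)
  }
})

test_that("duplicating every cell leaves component directions unchanged", {
  set.seed(16)
  m <- matrix(rpois(30 * 8, 4), 30, 8,
              dimnames = list(paste0("g", 1:30), paste0("c", 1:8)))
  m2 <- cbind(m, m)
  colnames(m2) <- paste0("c", 1:16)
  e1 <- scaleAndPca(m, rownames(m), nPcs = 3, clip = 100)
  e2 <- scaleAndPca(m2, rownames(m2), nPcs = 3, clip = 100)
  expect_equal(abs(e1@rotation), abs(e2@rotation), tolerance = 1e-6)
  expect_equal(pcaScores(e2)[1:8, ], pcaScores(e2)[9:16, ], tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("PCA reconstruction error is non-increasing in the PC count", {
  set.seed(17)
  m <- matrix(rnorm(15 * 12), 15, 12,
              dimnames = list(paste0("g", 1:15), paste0("c", 1:12)))
  errs <- vapply(1:6, function(k) {
    emb <- scaleAndPca(m, rownames(m), nPcs = k, clip = 100)
    z <- t(scale(t(m)))
    recon <- pcaScores(emb) %*% t(emb@rotation)
    sum((t(z) - recon)^2)
  }, 0)
  expect_true(all(diff(errs) <= 1e-8))
})

test_that("nPcs bounds are enforced", {
  m <- matrix(rnorm(20), 4, 5,
              dimnames = list(paste0("g", 1:4), paste0("c", 1:5)))
  expect_error(scaleAndPca(m, rownames(m), nPcs = 4), "smaller")
})
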