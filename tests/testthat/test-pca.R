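# Group-mean-covariance PCA: preprocessing postconditions, covariance
# algebra, eigenmode structure on constructed low-rank movies, projections
# and spectra, reconstructions, and the Gram-duality equivalence.

# two orthonormal Gaussian spatial patterns x sinusoids on a 16 x 16 grid
rank2Movie <- function(T = 300, a1 = 8, a2 = 4, f1 = 0.1, f2 = 0.05) {
    h <- 16; w <- 16
    p1 <- outer(dnorm(1:h, 5, 2), dnorm(1:w, 5, 2))
    p2 <- outer(dnorm(1:h, 12, 2), dnorm(1:w, 12, 2))
    p1 <- p1 / sqrt(sum(p1^2)); p2 <- p2 / sqrt(sum(p2^2))
    tt <- (0:(T - 1)) * 0.4
    m <- array(100, c(h * w, T)) +
        outer(as.numeric(p1), a1 * sin(2 * pi * f1 * tt)) +
        outer(as.numeric(p2), a2 * sin(2 * pi * f2 * tt + 1))
    fusMovie(array(m, c(h, w, T)))
}

test_that("PCA preprocessing centres and scales globally", {
    mv <- rank2Movie()
    pre <- preprocessForPca(list(mv))
    X <- pre[[1]]
    expect_lt(abs(mean(X)), 1e-10)
    expect_equal(sd(as.numeric(X)), 1, tolerance = 1e-10)
    # normalisation invariance: scaling the input leaves the output unchanged
    mv2 <- fusMovie(movieData(mv) * 3.5)
    expect_equal(preprocessForPca(list(mv2))[[1]], X, tolerance = 1e-9)
    # constant movie: zero global sd after filtering
    expect_error(preprocessForPca(list(fusMovie(array(7, c(16, 16, 300))))),
                 "zero global sd")
    expect_error(preprocessForPca(list(mv, fusMovie(array(1:400 + 0,
                                                          c(10, 10, 4))))),
                 "share one grid")
})

test_that("mean covariance is the average of per-acquisition covariances, PSD", {
    pre <- preprocessForPca(list(rank2Movie(200), rank2Movie(200, a1 = 5)))
    C1 <- tcrossprod(pre[[1]]) / (ncol(pre[[1]]) - 1)
    C2 <- tcrossprod(pre[[2]]) / (ncol(pre[[2]]) - 1)
    C <- groupMeanCovariance(pre)
    expect_equal(C, (C1 + C2) / 2, tolerance = 1e-12)
    expect_gt(min(eigen(C, symmetric = TRUE, only.values = TRUE)$values),
              -1e-8)
    expect_equal(groupMeanCovariance(pre[1]), C1, tolerance = 1e-12)
    expect_error(groupMeanCovariance(list(matrix(1:4, 4, 1))),
                 "single-frame")
})

test_that("eigenmodes recover constructed spectra exactly", {
    # covariance with eigenvalues 4 and 1 on orthonormal vectors
    v1 <- c(1, 0, 0, 0); v2 <- c(0, 1, 0, 0)
    C <- 4 * tcrossprod(v1) + 1 * tcrossprod(v2)
    md <- eigenModes(C, eigenvalueMin = 1e-9, nDisplay = 10)
    ev <- modeEigenvalues(md)
    expect_equal(ev[1] / ev[2], 4, tolerance = 1e-9)
    expect_error(eigenModes(matrix(1:9, 3, 3)), "symmetric")
    # identity covariance: all explained fractions equal
    mdI <- eigenModes(diag(5), eigenvalueMin = 1e-3)
    expect_equal(explainedVariance(mdI), rep(0.2, 5))
})

test_that("a rank-2 noise-free movie yields exactly 2 components, cum = 1", {
    mv <- rank2Movie()
    md <- pcaModes(list(mv), eigenvalueMin = 1e-9, nDisplay = 10)
    ev <- modeEigenvalues(md)
    expect_identical(sum(ev > 1e-6 * ev[1]), 2L)
    expect_equal(sum(explainedVariance(md)[1:2]), 1, tolerance = 1e-6)
    # explained fractions always sum to one; maps orthonormal
    expect_lt(abs(sum(explainedVariance(md)) - 1), 1e-9)
    expect_lt(max(abs(crossprod(md@maps) - diag(md@nRetained))), 1e-8)
    # full-rank reconstruction is exact; k = 0 is all-zero
    pre <- preprocessForPca(list(mv))
    rec <- reconstructFromModes(pre[[1]], md, 2)
    expect_lt(rec$residualFraction, 1e-6)
    expect_true(all(reconstructFromModes(pre[[1]], md, 0)$reconstruction == 0))
    expect_error(reconstructFromModes(pre[[1]], md, 11), "exceeds")
})

test_that("projections carry the temporal structure and are uncorrelated", {
    mv <- rank2Movie(500)
    md <- pcaModes(list(mv), eigenvalueMin = 1e-9)
    proj <- md@temporal[[1]]
    # component 1 is the 0.1 Hz mode: its spectrum peaks at the 0.1 Hz bin
    pk <- md@spectra$freqs[which.max(md@spectra$amplitude[, 1])]
    expect_lt(abs(pk - 0.1), 1 / (500 * 0.4) + 1e-9)
    expect_lt(abs(cor(proj[, 1], proj[, 2])), 0.05)
    # zero data give zero projections
    z <- projectModes(list(matrix(0, 256, 50)), md, dt = 0.4)
    expect_true(all(z@temporal[[1]] == 0))
})

test_that("Gram duality gives the same modes as the direct covariance", {
    mv1 <- rank2Movie(80); mv2 <- rank2Movie(80, a1 = 6, f1 = 0.12)
    pre <- preprocessForPca(list(mv1, mv2))
    direct <- eigenModes(groupMeanCovariance(pre), eigenvalueMin = 1e-9,
                         nDisplay = 5, gridDim = c(16L, 16L))
    dual <- fuswaves:::.eigenModesGram(pre, 1e-9, 5, c(16L, 16L))
    k <- min(direct@nRetained, dual@nRetained, 3)
    expect_equal(modeEigenvalues(dual)[1:k], modeEigenvalues(direct)[1:k],
                 tolerance = 1e-8)
    for (j in seq_len(k))
        expect_lt(1 - abs(sum(dual@maps[, j] * direct@maps[, j])), 1e-6)
    expect_equal(dual@totalVariance, direct@totalVariance, tolerance = 1e-8)
})

test_that("oscillation-rich scans concentrate variance in few modes", {
    spec <- acquisitionSpec(64, 64, 600)
    atlas <- buildAtlas(spec)
    co <- simulateCohort(2, c("VEH-like", "LPS-like"), spec, seed = 51,
                         atlas = atlas)
    cum10 <- function(arm) {
        ms <- lapply(Filter(function(s) s$arm == arm, co),
                     function(s) s$movie)
        sum(explainedVariance(pcaModes(ms))[1:10])
    }
    lps <- cum10("LPS-like"); veh <- cum10("VEH-like")
    expect_gt(lps, veh)                       # variance concentration contrast
    expect_lt(veh, 0.9)
})
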