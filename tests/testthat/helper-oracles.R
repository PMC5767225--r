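# Independent oracles used across the suite.  Each is deliberately a
# different algorithm/parameterization than the implementation it checks.

# one-sided amplitude spectrum by direct DFT summation (no FFT)
dftAmplitudeOracle <- function(x, trSeconds) {
    n <- length(x)
    nk <- n %/% 2L + 1L
    t <- 0:(n - 1L)
    amp <- vapply(0:(nk - 1L), function(k) {
        re <- sum(x * cos(2 * pi * k * t / n))
        im <- sum(x * sin(2 * pi * k * t / n))
        a <- sqrt(re^2 + im^2) * 2 / n
        if (k == 0L || (n %% 2L == 0L && k == n %/% 2L)) a / 2 else a
    }, numeric(1L))
    list(frequencies = (0:(nk - 1L)) / (n * trSeconds), amplitudes = amp)
}

# closed-form Pearson correlation
pearsonOracle <- function(x, y) {
    xm <- x - mean(x); ym <- y - mean(y)
    sum(xm * ym) / sqrt(sum(xm^2) * sum(ym^2))
}

# squared-hinge SVM via its dual QP solved with quadprog:
# min .5 a' (YKY + I/C) a - 1'a   s.t. a >= 0, y'a = 0
# (a different algorithm and parameterization than the primal BFGS path)
dualSvmOracle <- function(X, y, C = 1) {
    n <- nrow(X)
    K <- X %*% t(X)
    Q <- (y %o% y) * K + diag(n) / C
    sol <- quadprog::solve.QP(Dmat = Q + diag(n) * 1e-10, dvec = rep(1, n),
                              Amat = cbind(y, diag(n)),
                              bvec = rep(0, n + 1L), meq = 1L)
    a <- sol$solution
    w <- drop(t(X) %*% (a * y))
    sv <- which(a > 1e-8)
    b <- mean((1 - a[sv] / C) / y[sv] - X[sv, , drop = FALSE] %*% w)
    obj <- 0.5 * sum(w^2) + (C / 2) * sum(pmax(0, 1 - y * (X %*% w + b))^2)
    list(w = w, b = b, objective = obj)
}

# primal squared-hinge objective value for a given model
svmPrimalObjective <- function(model, X, y) {
    f <- drop(X %*% pairclass::weights(model)) + pairclass::bias(model)
    0.5 * sum(pairclass::weights(model)^2) +
        (model@cost / 2) * sum(pmax(0, 1 - y * f)^2)
}

# brute-force count of 3 mm-grid voxel centers within radiusMm of a center
bruteSphereCount <- function(radiusMm, voxelSize = c(3, 3, 3)) {
    r <- ceiling(radiusMm / min(voxelSize)) + 1L
    off <- as.matrix(expand.grid(-r:r, -r:r, -r:r))
    mm2 <- (off[, 1] * voxelSize[1])^2 + (off[, 2] * voxelSize[2])^2 +
           (off[, 3] * voxelSize[3])^2
    sum(mm2 <= radiusMm^2 + 1e-9)
}
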