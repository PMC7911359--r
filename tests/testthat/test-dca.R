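test_that("identity reweighting matches the pairwise-identity oracle", {
  ab <- smallAlphabet(4)
  # trivial cases
  same <- encFromStates(matrix(2L, 5, 8,
                               dimnames = list(paste0("s", 1:5), NULL)), ab)
  w <- computeWeights(same, 0.8)
  expect_equal(w$weights, rep(1 / 5, 5))
  expect_equal(w$Meff, 1)

  distinct <- encFromStates(rbind(s1 = rep(1L, 8), s2 = rep(2L, 8),
                                  s3 = rep(3L, 8)), ab)
  w2 <- computeWeights(distinct, 0.8)
  expect_equal(w2$weights, rep(1, 3))
  expect_equal(w2$Meff, 3)

  # 50 random rows against the O(M^2 L) scan, including a chunked pass
  st <- randomStates(50, 10, 4, seed = 21)
  enc <- encFromStates(st, ab)
  expect_equal(computeWeights(enc, 0.5)$weights, bfWeights(st, 0.5))
  expect_equal(computeWeights(enc, 0.5, chunk = 7L)$weights,
               bfWeights(st, 0.5))
  expect_equal(computeWeights(enc, 0.8)$weights, bfWeights(st, 0.8))
})

test_that("frequency counting obeys its limits and the direct-count oracle", {
  ab <- smallAlphabet(3)
  one <- encFromStates(matrix(c(1L, 2L, 3L, 2L), 1, 4,
                              dimnames = list("s1", NULL)), ab)
  # lambda = 0, single sequence: one-hot
  fr <- countFrequencies(one, lambda = 0)
  expect_equal(fr@f1[1, ], c(1, 0, 0))
  expect_equal(fr@f1[2, ], c(0, 1, 0))

  # large-lambda limit: f1 -> 1/q, f2 off-diagonal -> 1/q^2
  frBig <- countFrequencies(one, lambda = 1e9)
  expect_equal(frBig@f1, matrix(1 / 3, 4, 3), tolerance = 1e-6)
  expect_equal(frBig@f2[1:3, 4:6], matrix(1 / 9, 3, 3), tolerance = 1e-6)

  # random weighted MSA against the brute-force counter
  st <- randomStates(30, 5, 3, seed = 5)
  set.seed(6); wts <- runif(30, 0.2, 1)
  enc <- encFromStates(st, ab)
  fr2 <- countFrequencies(enc, weights = wts, lambda = 2.5)
  oracle <- bfFrequencies(st, wts, 2.5, 3)
  expect_equal(fr2@f1, oracle$f1, tolerance = 1e-12)
  for (i in 1:5) for (j in 1:5) {
    bi <- ((i - 1) * 3 + 1):(i * 3); bj <- ((j - 1) * 3 + 1):(j * 3)
    expect_equal(fr2@f2[bi, bj], oracle$f2[i, j, , ], tolerance = 1e-12,
                 ignore_attr = TRUE)
  }
})

test_that("frequency invariants hold: simplex rows, symmetry, marginalisation", {
  ab <- smallAlphabet(4)
  st <- randomStates(80, 6, 4, seed = 9)
  enc <- encFromStates(st, ab)
  wts <- computeWeights(enc, 0.9)$weights
  fr <- countFrequencies(enc, wts, lambda = 0)  # lambda 0: marginals exact
  expect_lt(max(abs(rowSums(fr@f1) - 1)), 1e-12)
  expect_lt(max(abs(fr@f2 - t(fr@f2))), 1e-12)
  # sum_b f2(i,j)(a,b) = f1(i,a) with consistent lambda scaling
  for (i in 1:6) for (j in setdiff(1:6, i)) {
    bi <- ((i - 1) * 4 + 1):(i * 4); bj <- ((j - 1) * 4 + 1):(j * 4)
    expect_equal(unname(rowSums(fr@f2[bi, bj])), unname(fr@f1[i, ]),
                 tolerance = 1e-12)
  }
  # f2(i,i)(a,b) = f1(i,a) delta(a,b)
  b1 <- 1:4
  expect_equal(fr@f2[b1, b1], diag(fr@f1[1, ]), ignore_attr = TRUE)
})

test_that("mean-field inversion recovers the closed-form 2x2 coupling", {
  # exact two-site, two-state distribution; reduced inversion is a hand
  # 2x2 inverse
  p <- matrix(c(0.35, 0.15, 0.10, 0.40), 2, 2)  # p(a,b), rows site 1
  f1 <- rbind(rowSums(p), colSums(p))
  fr <- freqsFromF1(f1, refState = 1L)
  bi <- 1:2; bj <- 3:4
  f2 <- fr@f2
  f2[bi, bj] <- p
  f2[bj, bi] <- t(p)
  fr@f2 <- f2
  m <- fitMFDCA(fr)
  # hand inversion over the non-reference state (state 2 each site):
  C11 <- f1[1, 2] * (1 - f1[1, 2])
  C22 <- f1[2, 2] * (1 - f1[2, 2])
  C12 <- p[2, 2] - f1[1, 2] * f1[2, 2]
  det <- C11 * C22 - C12^2
  eHand <- C12 / det            # -(C^-1)[12]
  # zero-sum projection of the reference-gauge block [[0,0],[0,eHand]]
  expected <- matrix(c(eHand, -eHand, -eHand, eHand) / 4, 2, 2)
  expect_equal(couplingBlock(m, 1, 2), expected, tolerance = 1e-9)
})

test_that("independent columns yield near-zero couplings and sub-null DI", {
  ab <- smallAlphabet(3)
  set.seed(31)
  L <- 4; q <- 3; M <- 20000
  profs <- matrix(runif(L * q, 0.5, 2), L, q)
  profs <- profs / rowSums(profs)
  st <- vapply(1:L, function(i)
    sample.int(q, M, replace = TRUE, prob = profs[i, ]), integer(M))
  rownames(st) <- paste0("s", 1:M)
  enc <- encFromStates(st, ab)
  fr <- countFrequencies(enc, lambda = M)
  m <- fitMFDCA(fr)
  fnorms <- vapply(1:(L - 1), function(i) max(vapply((i + 1):L, function(j)
    sqrt(sum(couplingBlock(m, i, j)^2)), numeric(1))), numeric(1))
  # sampling noise scales like 1/sqrt(M); any residual coupling should be
  # far below what a genuinely coupled pair produces at the same M
  expect_lt(max(fnorms), 0.2)
  coupled <- st
  coupled[, 2] <- coupled[, 1]          # copy column: maximal dependence
  frC <- countFrequencies(encFromStates(coupled, ab), lambda = M)
  mC <- fitMFDCA(frC)
  expect_gt(sqrt(sum(couplingBlock(mC, 1, 2)^2)), 10 * max(fnorms))

  # DI of the fit stays below the 99.9th percentile of a column-shuffle null
  diObs <- max(directInformation(m, fr)@ranking$di)
  nullMax <- vapply(1:25, function(r) {
    stS <- apply(st, 2, sample)
    rownames(stS) <- rownames(st)
    frS <- countFrequencies(encFromStates(stS, ab), lambda = M)
    max(directInformation(fitMFDCA(frS), frS)@ranking$di)
  }, numeric(1))
  expect_lte(diObs, quantile(nullMax, 0.999) * 1.5 + 1e-6)
})

test_that("fitted models satisfy the zero-sum gauge and symmetry invariants", {
  ab <- smallAlphabet(5)
  st <- randomStates(300, 6, 5, seed = 12)
  enc <- encFromStates(st, ab)
  fr <- countFrequencies(enc)
  m <- fitMFDCA(fr)
  expect_equal(m@gaugeTag, "zero-sum")
  for (i in 1:5) for (j in (i + 1):6) {
    blk <- couplingBlock(m, i, j)
    expect_lt(max(abs(rowSums(blk))), 1e-9)
    expect_lt(max(abs(colSums(blk))), 1e-9)
    expect_equal(blk, t(couplingBlock(m, j, i)), tolerance = 1e-12)
  }
  expect_true(all(couplingBlock(m, 2, 2) == 0))

  # singular correlation matrix is rejected with advice
  frBad <- fr
  frBad@f2 <- matrix(0, nrow(fr@f2), ncol(fr@f2))
  frBad@f1 <- fr@f1
  expect_error(fitMFDCA(frBad), "lambda")
})

test_that("direct information is zero at independence, symmetric, non-negative", {
  q <- 4
  m <- randomModel(3, q, seed = 3)
  # zero out the (1,2) block
  m@couplings[1:q, (q + 1):(2 * q)] <- 0
  m@couplings[(q + 1):(2 * q), 1:q] <- 0
  f1 <- matrix(runif(3 * q, 0.5, 2), 3, q); f1 <- f1 / rowSums(f1)
  fr <- freqsFromF1(f1)
  di <- directInformation(m, fr)
  expect_lt(abs(di@di[1, 2]), 1e-9)
  expect_true(all(di@di >= 0))
  expect_equal(di@di, t(di@di))
  expect_equal(diag(di@di), rep(0, 3))
  # ranking is descending with lexicographic ties
  expect_true(all(diff(di@ranking$di) <= 1e-15))
})

test_that("direct distribution matches the Sinkhorn matrix-scaling oracle", {
  set.seed(44)
  q <- 3
  for (rep in 1:5) {
    m <- randomModel(2, q, seed = 100 + rep, couplingSD = 0.8)
    f1 <- matrix(runif(2 * q, 0.3, 2), 2, q); f1 <- f1 / rowSums(f1)
    fr <- freqsFromF1(f1)
    di <- directInformation(m, fr, tol = 1e-12, maxSweeps = 10000)
    W <- exp(couplingBlock(m, 1, 2))
    P <- sinkhornDirect(W, f1[1, ], f1[2, ])
    # the scaled matrix has the required marginals
    expect_equal(rowSums(P), f1[1, ], tolerance = 1e-9)
    expect_equal(colSums(P), f1[2, ], tolerance = 1e-9)
    miOracle <- sum(P * log(P / outer(f1[1, ], f1[2, ])))
    expect_equal(di@di[1, 2], miOracle, tolerance = 1e-7)
  }
})

test_that("Hamiltonian evaluation matches the naive double loop", {
  m <- randomModel(1, 4, seed = 2)
  m@fields[1, ] <- c(1, 0, 0, 0)
  m@couplings[] <- 0
  expect_equal(hamiltonian(m, 1L), -1)

  zero <- randomModel(3, 3, seed = 1)
  zero@couplings[] <- 0; zero@fields[] <- 0
  expect_equal(hamiltonian(zero, c(1L, 2L, 3L)), 0)

  for (rep in 1:20) {
    m6 <- randomModel(6, 5, seed = 200 + rep)
    set.seed(300 + rep)
    s <- sample.int(5, 6, replace = TRUE)
    expect_equal(hamiltonian(m6, s), bfHamiltonian(m6, s), tolerance = 1e-12)
  }
  expect_error(hamiltonian(m, c(1L, 1L)), "length")
  expect_error(hamiltonian(randomModel(2, 3, 1), c(1L, 9L)), "1..q")
})

test_that("Hamiltonian differences are gauge invariant under field shifts", {
  m <- randomModel(5, 4, seed = 77)
  set.seed(78)
  s1 <- sample.int(4, 5, TRUE); s2 <- sample.int(4, 5, TRUE)
  d0 <- hamiltonian(m, s1) - hamiltonian(m, s2)
  mShift <- m
  mShift@fields[3, ] <- mShift@fields[3, ] + 2.71
  d1 <- hamiltonian(mShift, s1) - hamiltonian(mShift, s2)
  expect_equal(d0, d1, tolerance = 1e-9)
})

test_that("planted couplings are recovered by top-k DI at high Meff", {
  # iid-free check of the inference chain: sample a sparse planted world,
  # fit, rank by DI
  w <- makeToyWorld(nFamilies = 4, LHK = 8, LRR = 10, nInterfacePairs = 4,
                    couplingStrength = 3, fieldBias = 2, MPerFamily = 1500,
                    seed = 17)
  paired <- concatenatePairs(w@hkAlignment, w@rrAlignment, w@pairs)
  enc <- encodeAlignment(paired)
  cw <- computeWeights(enc)
  expect_gte(cw$Meff, 5000)
  fr <- countFrequencies(enc, cw$weights)
  m <- fitMFDCA(fr)
  eg <- as.matrix(expand.grid(i = 1:8, j = 9:18))
  di <- directInformation(m, fr, pairs = eg[order(eg[, 1], eg[, 2]), ])
  k <- nrow(maskPairs(w@mask))
  expect_gte(overlapWithTopDI(w@mask, di, k) / k, 0.8)
})

test_that("Potts models and DI tables round-trip through disk", {
  m <- randomModel(3, 4, seed = 5, provenance = "cognate")
  f <- withr::local_tempfile(fileext = ".rds")
  writePottsModel(m, f)
  expect_true(file.exists(paste0(f, ".json")))
  side <- jsonlite::read_json(paste0(f, ".json"))
  expect_equal(side$L, 3L)
  m2 <- readPottsModel(f)
  expect_equal(m2@couplings, m@couplings)

  f1 <- matrix(1 / 4, 3, 4)
  di <- directInformation(m, freqsFromF1(f1))
  tf <- withr::local_tempfile(fileext = ".tsv")
  writeDITable(di, tf)
  back <- read.delim(tf)
  expect_equal(back$di, di@ranking$di, tolerance = 1e-12)
})
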