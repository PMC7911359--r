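test_that("H_TCS sums masked couplings plus all fields, per brute force", {
  q <- 5
  m <- randomModel(8, q, seed = 51)   # 4 + 4 toy frame
  mask <- new("ContactMask",
              pairs = data.frame(hk_col = c(1L, 3L), rr_col = c(6L, 7L),
                                 min_dist = NA_real_),
              cutoffA = 12, metricTag = "x", LHK = 4L, LRR = 4L)
  set.seed(52)
  hk <- sample.int(q, 4, TRUE); rr <- sample.int(q, 4, TRUE)
  sc <- htcs(m, mask, hk, rr)
  expect_s4_class(sc, "ScoreComponents")
  expect_equal(sc@total, -sc@couplingSum - sc@fieldSum)
  expect_equal(sc@total, bfHtcs(m, mask, hk, rr), tolerance = 1e-12)

  # empty mask: pure field score
  emptyMask <- new("ContactMask",
                   pairs = data.frame(hk_col = integer(0),
                                      rr_col = integer(0),
                                      min_dist = numeric(0)),
                   cutoffA = 12, metricTag = "x", LHK = 4L, LRR = 4L)
  s <- c(hk, rr)
  expect_equal(htcs(m, emptyMask, hk, rr)@total,
               -sum(m@fields[cbind(1:8, s)]))

  expect_error(htcs(m, mask, hk[1:3], rr), "width")
})

test_that("H_TCS is blind to couplings outside the mask", {
  q <- 4
  m <- randomModel(6, q, seed = 61)
  mask <- new("ContactMask",
              pairs = data.frame(hk_col = 1L, rr_col = 4L,
                                 min_dist = NA_real_),
              cutoffA = 12, metricTag = "x", LHK = 3L, LRR = 3L)
  hk <- c(1L, 2L, 3L); rr <- c(4L, 1L, 2L)
  base <- htcs(m, mask, hk, rr)@total
  # perturb an inter-domain coupling NOT in the mask and both intra-domain
  # blocks: the score must not move
  m2 <- m
  touch <- function(mm, i, j) {
    bi <- ((i - 1) * q + 1):(i * q); bj <- ((j - 1) * q + 1):(j * q)
    mm@couplings[bi, bj] <- mm@couplings[bi, bj] + 5
    mm@couplings[bj, bi] <- t(mm@couplings[bi, bj])
    mm
  }
  m2 <- touch(m2, 2, 5)   # inter-domain, unmasked
  m2 <- touch(m2, 1, 2)   # within HK block
  m2 <- touch(m2, 5, 6)   # within RR block
  expect_equal(htcs(m2, mask, hk, rr)@total, base, tolerance = 1e-12)
})

test_that("specificity is the cognate-minus-null score difference", {
  q <- 4
  cog <- randomModel(6, q, seed = 71, provenance = "cognate")
  nul <- randomModel(6, q, seed = 72, provenance = "scrambled")
  mask <- randomMask(3, 3, 4, seed = 73)
  set.seed(74)
  hk <- sample.int(q, 3, TRUE); rr <- sample.int(q, 3, TRUE)
  # identical models cancel exactly
  cog2 <- cog; cog2@provenance <- "scrambled"
  expect_equal(htcsSpecific(cog, cog2, mask, hk, rr), 0)
  # two independent brute-force evaluations subtracted
  expect_equal(htcsSpecific(cog, nul, mask, hk, rr),
               bfHtcs(cog, mask, hk, rr) - bfHtcs(nul, mask, hk, rr),
               tolerance = 1e-12)
  # provenance guard
  notNull <- nul; notNull@provenance <- "cognate"
  expect_warning(htcsSpecific(cog, notNull, mask, hk, rr), "scrambled")
  expect_error(htcsSpecific(cog, notNull, mask, hk, rr,
                            checkProvenance = "error"), "scrambled")
})

test_that("specificity matrices equal element-wise recomputation", {
  q <- 21; ab <- pottsAlphabet()
  cog <- randomModel(7, q, seed = 81, provenance = "cognate")
  nul <- randomModel(7, q, seed = 82, provenance = "scrambled")
  mask <- randomMask(3, 4, 5, seed = 83)
  set.seed(84)
  syms <- alphabetSymbols(ab)
  hkRows <- setNames(vapply(1:3, function(i)
    paste(sample(syms, 3, TRUE), collapse = ""), character(1)),
    paste0("hk", 1:3))
  rrRows <- setNames(vapply(1:4, function(i)
    paste(sample(syms, 4, TRUE), collapse = ""), character(1)),
    paste0("rr", 1:4))
  hkA <- DomainAlignment(hkRows, domainTag = "HK")
  rrA <- DomainAlignment(rrRows, domainTag = "RR")
  sm <- specificityMatrix(cog, nul, mask, hkA, rrA)
  expect_equal(dim(scores(sm)), c(3L, 4L))
  hkE <- encodedStates(encodeAlignment(hkA, ab))
  rrE <- encodedStates(encodeAlignment(rrA, ab))
  for (h in 1:3) for (r in 1:4)
    expect_equal(scores(sm)[h, r],
                 htcsSpecific(cog, nul, mask, hkE[h, ], rrE[r, ]),
                 tolerance = 1e-12)

  # single pair matrix equals the scalar op
  sm1 <- specificityMatrix(cog, nul, mask, hkA@seqs[1] |> as.character() |>
                             setNames("hk1") |> DomainAlignment(domainTag = "HK"),
                           rrA@seqs[2] |> as.character() |>
                             setNames("rr2") |> DomainAlignment(domainTag = "RR"))
  expect_equal(unname(scores(sm1)[1, 1]),
               htcsSpecific(cog, nul, mask, hkE[1, ], rrE[2, ]))

  # permuting the RR input order permutes columns identically
  perm <- c(3, 1, 4, 2)
  smP <- specificityMatrix(cog, nul, mask, hkA,
                           DomainAlignment(rrRows[perm], domainTag = "RR"))
  expect_equal(scores(smP), scores(sm)[, perm])
})

test_that("empirical-repairing null is a constant offset of the cognate score", {
  q <- 4
  cog <- randomModel(6, q, seed = 91, provenance = "cognate")
  mask <- randomMask(3, 3, 3, seed = 92)
  st <- randomStates(4, 3, q, seed = 93)
  rownames(st) <- paste0("hk", 1:4)
  str <- randomStates(5, 3, q, seed = 94)
  rownames(str) <- paste0("rr", 1:5)
  sm <- specificityMatrix(cog, NULL, mask, st, str,
                          nullEstimator = "empirical_repairing",
                          repairRounds = 25, repairSeed = 7)
  # recompute the offset independently
  set.seed(7)
  hs <- sample.int(4, 25, TRUE); rs <- sample.int(5, 25, TRUE)
  h0 <- mean(vapply(1:25, function(k)
    bfHtcs(cog, mask, st[hs[k], ], str[rs[k], ]), numeric(1)))
  expect_equal(scores(sm)[2, 3],
               bfHtcs(cog, mask, st[2, ], str[3, ]) - h0, tolerance = 1e-9)
})

test_that("selection classification matches the argmin oracle incl. ties", {
  # cognate both row and column minimum
  s <- matrix(c(-5, 1, 2, 3, -4, 1, 0, 2, -6), 3, 3,
              dimnames = list(paste0("H", 1:3), paste0("R", 1:3)))
  cg <- data.frame(hk_id = paste0("H", 1:3), rr_id = paste0("R", 1:3))
  sm <- new("SpecificityMatrix", scores = s)
  calls <- classifySelection(sm, cg)
  expect_true(all(calls$positive & calls$negative))
  expect_true(all(calls$verdict == "true_positive"))

  # negative-only: cognate is the column minimum but not the row minimum
  s2 <- s
  s2["H1", "R2"] <- -9        # H1 now prefers the non-cognate R2
  calls2 <- classifySelection(new("SpecificityMatrix", scores = s2), cg)
  expect_false(calls2$positive[1])
  expect_true(calls2$negative[1])
  expect_equal(calls2$verdict[1], "true_positive")

  # a tie never evidences selection
  s3 <- s
  s3["H1", "R2"] <- s3["H1", "R1"]
  s3["H2", "R1"] <- s3["H1", "R1"]
  calls3 <- classifySelection(new("SpecificityMatrix", scores = s3), cg)
  expect_false(calls3$positive[1])
  expect_false(calls3$negative[1])
  expect_equal(calls3$verdict[1], "false_negative")

  # random matrices against the brute-force argmin scan
  for (rep in 1:30) {
    set.seed(400 + rep)
    r <- matrix(rnorm(16), 4, 4,
                dimnames = list(paste0("H", 1:4), paste0("R", 1:4)))
    cg4 <- data.frame(hk_id = paste0("H", 1:4),
                      rr_id = paste0("R", sample(1:4)))
    got <- classifySelection(new("SpecificityMatrix", scores = r), cg4)
    oracle <- bfClassify(r, cg4)
    expect_equal(got$positive, oracle$positive)
    expect_equal(got$negative, oracle$negative)
    expect_equal(got$verdict, oracle$verdict)
  }

  # missing ids are skipped with a report
  cgBad <- rbind(cg, data.frame(hk_id = "H9", rr_id = "R1"))
  callsB <- classifySelection(sm, cgBad)
  expect_equal(nrow(callsB), 3)
  expect_equal(attr(callsB, "skipped")$hk_id, "H9")
})

test_that("verdicts are invariant under strictly increasing transforms", {
  set.seed(123)
  s <- matrix(rnorm(20), 4, 5,
              dimnames = list(paste0("H", 1:4), paste0("R", 1:5)))
  cg <- data.frame(hk_id = paste0("H", 1:4), rr_id = paste0("R", c(2, 1, 4, 3)))
  base <- classifySelection(new("SpecificityMatrix", scores = s), cg)
  for (f in list(function(x) 3 * x + 7, function(x) exp(x),
                 function(x) x^3 + x)) {
    tr <- classifySelection(new("SpecificityMatrix", scores = f(s)), cg)
    expect_equal(tr$verdict, base$verdict)
    expect_equal(tr$positive, base$positive)
  }
})

test_that("classification verdicts survive uniform field-row shifts", {
  # adding a constant to one field row shifts every H_TCS equally
  q <- 21; ab <- pottsAlphabet()
  cog <- randomModel(7, q, seed = 131, provenance = "cognate")
  nul <- randomModel(7, q, seed = 132, provenance = "scrambled")
  mask <- randomMask(3, 4, 5, seed = 133)
  set.seed(134)
  hkS <- randomStates(4, 3, q, seed = 135); rownames(hkS) <- paste0("H", 1:4)
  rrS <- randomStates(4, 4, q, seed = 136); rownames(rrS) <- paste0("R", 1:4)
  cg <- data.frame(hk_id = paste0("H", 1:4), rr_id = paste0("R", 1:4))
  sm <- specificityMatrix(cog, nul, mask, hkS, rrS)
  cogS <- cog
  cogS@fields[2, ] <- cogS@fields[2, ] + 3.14
  smS <- specificityMatrix(cogS, nul, mask, hkS, rrS)
  expect_equal(scores(smS), scores(sm) - 3.14, tolerance = 1e-9)
  expect_equal(classifySelection(smS, cg)$verdict,
               classifySelection(sm, cg)$verdict)
})

test_that("validation metrics reproduce direct counting", {
  mkCalls <- function(pos, neg) {
    data.frame(hk_id = paste0("H", seq_along(pos)),
               rr_id = paste0("R", seq_along(pos)),
               positive = pos, negative = neg,
               verdict = ifelse(pos | neg, "true_positive", "false_negative"))
  }
  allTP <- mkCalls(rep(TRUE, 6), rep(FALSE, 6))
  expect_equal(validationMetrics(allTP)$sensitivity, 1.0)

  for (rep in 1:20) {
    set.seed(500 + rep)
    pos <- runif(12) < 0.5; neg <- runif(12) < 0.5
    vm <- validationMetrics(mkCalls(pos, neg))
    expect_equal(vm$tp, sum(pos | neg))
    expect_equal(vm$fn, sum(!(pos | neg)))
    expect_equal(vm$sensitivity, sum(pos | neg) / 12)
    expect_equal(vm$accuracy, vm$sensitivity)
    expect_equal(vm$fraction_both, sum(pos & neg) / 12)
    expect_equal(vm$fraction_negative_only, sum(neg & !pos) / 12)
    if (vm$tp > 0)
      expect_equal(vm$fraction_both_of_detected, sum(pos & neg) / vm$tp)
  }
})
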