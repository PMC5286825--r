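test_that("a single member gene gives its own z-scores as activity", {
  om <- makeOmics(5, 10, 10, seed = 2)
  v <- omicsValues(om)["G001", ] + c(rep(2, 10), rep(0, 10))  # make it case-high
  m <- rbind(G001 = v, omicsValues(om)[-1, ])
  om <- OmicsMatrix(m, sampleLabels(om))
  fit <- inferPathwayActivity(om, "G001")
  expect_equal(names(fit$corg), "G001")
  expect_equal(fit$activity, (v - mean(v)) / sd(v))
})

test_that("greedy CORG matches the exhaustive-subset optimum on the 3-gene toy", {
  set.seed(77)
  lab <- rep(c("case", "control"), each = 20)
  g1 <- rnorm(40) + ifelse(lab == "case", 2, 0)
  g2 <- rnorm(40) + ifelse(lab == "case", 2, 0)
  g3 <- rnorm(40)                      # pure noise
  m <- rbind(inf1 = g1, inf2 = g2, noise = g3)
  colnames(m) <- paste0("S", 1:40)
  om <- OmicsMatrix(m, lab)
  fit <- inferPathwayActivity(om, c("inf1", "inf2", "noise"))
  expect_false("noise" %in% names(fit$corg))
  expect_setequal(names(fit$corg), c("inf1", "inf2"))
  expect_equal(max(fit$trajectory), exhaustiveBestT(om, rownames(m)),
               tolerance = 1e-12)
  expect_true(all(diff(fit$trajectory) > 0))
})

test_that("duplicated informative genes are all accepted and the score never drops", {
  set.seed(5)
  lab <- rep(c("case", "control"), each = 15)
  base <- rnorm(30) + ifelse(lab == "case", 1.5, 0)
  m <- rbind(a = base, b = base, c = base)
  colnames(m) <- paste0("S", 1:30)
  om <- OmicsMatrix(m, lab)
  fit <- inferPathwayActivity(om, c("a", "b", "c"))
  # duplicates can never decrease |t|, but the increase is not strict, so
  # the greedy stops after the first gene; activity tracks the shared
  # pattern exactly
  expect_true(all(diff(fit$trajectory) >= 0))
  expect_equal(unname(cor(fit$activity, base)), 1, tolerance = 1e-12)
})

test_that("orientation follows the dominant direction of the members", {
  set.seed(6)
  lab <- rep(c("case", "control"), each = 15)
  down1 <- rnorm(30) - ifelse(lab == "case", 2, 0)
  down2 <- rnorm(30) - ifelse(lab == "case", 2, 0)
  m <- rbind(d1 = down1, d2 = down2)
  colnames(m) <- paste0("S", 1:30)
  om <- OmicsMatrix(m, lab)
  fit <- inferPathwayActivity(om, c("d1", "d2"))
  expect_lt(mean(fit$activity[lab == "case"]),
            mean(fit$activity[lab == "control"]))
})

test_that("discretization thresholds at the row median with ties going down", {
  act <- rbind(p1 = c(0.1, 0.9, -0.5, 0.4),   # median 0.25
               p2 = c(1, 2, 3, 4),
               p3 = c(2, 2, 2, 2))
  colnames(act) <- paste0("S", 1:4)
  prof <- makeProfile(act, labelsFor(2, 2) |> setNames(colnames(act)))
  st <- activityStates(discretizeActivity(prof))
  expect_equal(unname(st["p1", ]), c(-1, 1, -1, 1))
  expect_equal(sum(st["p2", ] == 1), 2)   # strictly increasing: median split
  expect_equal(unname(st["p3", ]), rep(-1, 4))
})

test_that("discretization is invariant to strictly monotone row transforms", {
  set.seed(13)
  act <- matrix(rnorm(40), 4, 10,
                dimnames = list(paste0("p", 1:4), paste0("S", 1:10)))
  lab <- setNames(rep(c("case", "control"), each = 5), colnames(act))
  st1 <- activityStates(discretizeActivity(makeProfile(act, lab)))
  st2 <- activityStates(discretizeActivity(makeProfile(exp(3 * act), lab)))
  expect_equal(st1, st2)
})

test_that("binarization follows the 2n-bit up/down layout and decodes back", {
  states <- matrix(c(1, -1, 1), 3, 1,
                   dimnames = list(c("A", "B", "C"), "S1"))
  lab <- c(S1 = "case")
  # a single-sample object is only used for encoding checks
  da <- new("DiscretizedActivity", states = states,
            labels = factor(lab, levels = c("case", "control")))
  btm <- binarize(da)
  expect_equal(unname(transactionBits(btm)[, 1]), c(1, 0, 1, 0, 1, 0))
  expect_equal(rownames(transactionBits(btm)),
               c("A:up", "B:up", "C:up", "A:down", "B:down", "C:down"))

  all1 <- new("DiscretizedActivity",
              states = matrix(1, 2, 1, dimnames = list(c("A", "B"), "S1")),
              labels = factor(lab, levels = c("case", "control")))
  expect_equal(unname(transactionBits(binarize(all1))[, 1]), c(1, 1, 0, 0))

  set.seed(14)
  for (i in 1:20) {
    st <- matrix(sample(c(-1, 1), 30, replace = TRUE), 5, 6,
                 dimnames = list(paste0("p", 1:5), paste0("S", 1:6)))
    da2 <- makeStates(st, setNames(rep(c("case", "control"), 3),
                                   colnames(st)))
    b <- binarize(da2)
    expect_equal(unname(colSums(transactionBits(b))), rep(5, 6))
    expect_equal(activityStates(decodeBinary(b)), st)
  }
})

test_that("invalid states are rejected by the transaction-matrix invariant", {
  expect_error(new("DiscretizedActivity",
                   states = matrix(c(1, 0), 2, 1,
                                   dimnames = list(c("A", "B"), "S1")),
                   labels = factor(c(S1 = "case"),
                                   levels = c("case", "control"))),
               "-1 or \\+1")
})

test_that("pathway-set activity reduces to the (signed) z-scored row for singletons", {
  set.seed(15)
  act <- matrix(rnorm(40), 2, 20,
                dimnames = list(c("A", "B"), paste0("S", 1:20)))
  act["A", 1:10] <- act["A", 1:10] + 2
  lab <- setNames(rep(c("case", "control"), each = 10), colnames(act))
  prof <- makeProfile(act, lab)
  up <- pathwaySetActivity(prof, "A:up")
  expect_equal(unname(cor(up$activity, act["A", ])), 1, tolerance = 1e-12)
  dn <- pathwaySetActivity(prof, "A:down")
  expect_equal(unname(cor(dn$activity, act["A", ])), -1, tolerance = 1e-12)
})

test_that("pathway-set combination beats singletons and drops noise pathways", {
  set.seed(16)
  lab <- setNames(rep(c("case", "control"), each = 20), paste0("S", 1:40))
  shift <- ifelse(lab == "case", 1.2, 0)
  act <- rbind(A = rnorm(40) + shift,
               B = rnorm(40) + shift,
               N = rnorm(40))
  colnames(act) <- names(lab)
  prof <- makeProfile(act, lab)

  fit2 <- pathwaySetActivity(prof, c("A:up", "B:up"))
  tA <- abs(moderatedT(scale(act["A", ])[, 1], lab))
  tB <- abs(moderatedT(scale(act["B", ])[, 1], lab))
  # exhaustive over the 3 subsets {A}, {B}, {A,B}
  expect_gte(max(fit2$trajectory), max(tA, tB))
  expect_setequal(fit2$selected, c("A:up", "B:up"))

  fit3 <- pathwaySetActivity(prof, c("A:up", "B:up", "N:up"))
  expect_false("N:up" %in% fit3$selected)
})

test_that("moderated t reduces to the pooled t without prior information", {
  set.seed(17)
  x <- rnorm(12)
  lab <- rep(c("case", "control"), each = 6)
  expect_equal(moderatedT(x, lab),
               unname(t.test(x[1:6], x[7:12], var.equal = TRUE)$statistic),
               tolerance = 1e-12)
  xeq <- c(1, 2, 3, 1, 2, 3)
  expect_equal(moderatedT(xeq, rep(c("case", "control"), each = 3)), 0,
               tolerance = 1e-12)
  expect_error(moderatedT(x[1:3], c("case", "case", "control")),
               "at least 2")
})

test_that("feature-wise moderated t shrinks the null spread and matches limma", {
  set.seed(18)
  m <- matrix(rnorm(200 * 12), 200, 12,
              dimnames = list(paste0("g", 1:200), paste0("S", 1:12)))
  lab <- rep(c("case", "control"), each = 6)
  mod <- moderatedTStats(m, lab)
  raw <- apply(m, 1, function(r) moderatedT(r, lab))
  expect_lt(sd(mod), sd(raw))
  expect_gt(attr(mod, "df.prior"), 0)

  # independent route: full limma lmFit + eBayes on the same data
  design <- cbind(1, as.integer(lab == "case"))
  eb <- limma::eBayes(limma::lmFit(m, design))
  expect_equal(as.numeric(mod), unname(eb$t[, 2]), tolerance = 1e-9)

  # below the feature threshold the prior is off and the raw t returns
  small <- moderatedTStats(m[1:10, ], lab)
  expect_equal(as.numeric(small), unname(raw[1:10]), tolerance = 1e-12)
  expect_equal(attr(small, "df.prior"), 0)
})

test_that("inverse expression/methylation relationships are counted per class", {
  lab <- setNames(rep(c("case", "control"), each = 4), paste0("S", 1:8))
  mkSt <- function(rows) makeStates(rows, lab)
  up <- rep(1, 8); dn <- rep(-1, 8)
  expr <- rbind(p1 = up, p2 = up, p3 = dn, p4 = up, p5 = dn)
  meth <- rbind(p1 = dn, p2 = dn, p3 = up, p4 = up, p5 = dn)
  colnames(expr) <- colnames(meth) <- names(lab)
  out <- inverseRelationshipCount(mkSt(expr), mkSt(meth), "case")
  expect_equal(out$nInverse, 3)
  expect_equal(unname(out$flags[c("p1", "p2", "p3")]), rep(TRUE, 3))

  same <- inverseRelationshipCount(mkSt(expr), mkSt(expr), "case")
  expect_equal(same$nInverse, 0)

  # majority ties are not inverse
  tie <- expr
  tie["p1", 1:2] <- c(1, -1) ; tie["p1", 3:4] <- c(-1, 1)
  out2 <- inverseRelationshipCount(mkSt(tie), mkSt(meth), "case")
  expect_false(out2$flags[["p1"]])

  # the two data types may have different sample sets
  lab2 <- setNames(rep(c("case", "control"), c(3, 3)), paste0("T", 1:6))
  meth2 <- matrix(-1, 5, 6, dimnames = list(rownames(expr), names(lab2)))
  out3 <- inverseRelationshipCount(mkSt(expr), makeStates(meth2, lab2),
                                   "case")
  expect_true(all(c("p1", "p2", "p4") %in%
                    names(which(out3$flags))))
})
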