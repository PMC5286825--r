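# A transaction matrix with a known cover structure: itemset {A:up, B:up}
# is 1 in exactly 4 case and 1 control sample out of 5 + 5.
mkRuleFixture <- function() {
  lab <- setNames(rep(c("case", "control"), each = 5), paste0("S", 1:10))
  st <- matrix(-1, 3, 10, dimnames = list(c("A", "B", "C"), names(lab)))
  st[c("A", "B"), c(1:4, 6)] <- 1
  st["C", ] <- rep(c(1, -1), 5)
  binarize(makeStates(st, lab))
}

test_that("rule metrics are exact count ratios", {
  btm <- mkRuleFixture()
  m <- ruleMetrics(c("A:up", "B:up"), btm, "case")
  expect_equal(m$support, 0.4)
  expect_equal(m$confidence, 0.8)
  expect_equal(m$lift, 1.6)
  expect_equal(m$nCover, 5L)
  expect_equal(m$nCoverClass, 4L)

  # class-pure itemset: all 5 case, 0 control
  lab <- sampleLabels(btm)
  st2 <- matrix(-1, 2, 10, dimnames = list(c("A", "B"), names(lab)))
  st2[, 1:5] <- 1
  btm2 <- binarize(makeStates(st2, lab))
  m2 <- ruleMetrics(c("A:up", "B:up"), btm2, "case")
  expect_equal(m2$confidence, 1.0)
  expect_equal(m2$lift, 2.0)

  # itemset covering everything is uninformative
  st3 <- matrix(1, 2, 10, dimnames = list(c("A", "B"), names(lab)))
  m3 <- ruleMetrics(c("A:up", "B:up"), binarize(makeStates(st3, lab)),
                    "case")
  expect_equal(m3$confidence, 0.5)
  expect_equal(m3$lift, 1.0)

  expect_error(ruleMetrics(character(), btm, "case"), "empty")
  expect_error(ruleMetrics("Z:up", btm, "case"), "unknown item")
})

test_that("rule filtering keeps confidence exactly 0.8 and rejects lift exactly 1", {
  btm <- mkRuleFixture()
  bc <- function(items, class) list(items = sort(items),
                                    pathways = sort(sub(":.*", "", items)),
                                    samples = "S1", class = class)
  rules <- generateRules(list(bc(c("A:up", "B:up"), "case")), btm)
  expect_equal(nrow(rules), 1L)           # confidence == 0.8 passes
  expect_equal(rules$lift, 1.6)

  lab <- sampleLabels(btm)
  # lift exactly 1: cover splits proportionally to the class prior
  stL <- matrix(-1, 2, 10, dimnames = list(c("A", "B"), names(lab)))
  stL[, c(1:2, 6:7)] <- 1
  btmL <- binarize(makeStates(stL, lab))
  expect_equal(ruleMetrics(c("A:up", "B:up"), btmL, "case")$lift, 1)
  expect_equal(nrow(generateRules(list(bc(c("A:up", "B:up"), "case")),
                                  btmL)), 0L)

  # confidence 0.79 < 0.8 is rejected: cover of 100 with 79 in class
  lab2 <- setNames(rep(c("case", "control"), each = 100),
                   sprintf("T%03d", 1:200))
  st2 <- matrix(-1, 2, 200, dimnames = list(c("A", "B"), names(lab2)))
  st2[, c(1:79, 101:121)] <- 1
  btm2 <- binarize(makeStates(st2, lab2))
  expect_equal(ruleMetrics(c("A:up", "B:up"), btm2, "case")$confidence,
               0.79)
  expect_equal(nrow(generateRules(list(bc(c("A:up", "B:up"), "case")),
                                  btm2)), 0L)
})

test_that("rule invariants hold on mined synthetic data", {
  set.seed(31)
  st <- matrix(sample(c(-1, 1), 8 * 24, replace = TRUE), 8, 24,
               dimnames = list(paste0("P", 1:8), paste0("S", 1:24)))
  lab <- setNames(rep(c("case", "control"), each = 12), colnames(st))
  btm <- binarize(makeStates(st, lab))
  bcs <- c(bimax(btm, "case", 2, 0.25), bimax(btm, "control", 2, 0.25))
  rules <- generateRules(bcs, btm, minConf = 0.5, minLift = 1)
  expect_gt(nrow(rules), 0L)
  N <- 24
  for (i in seq_len(nrow(rules))) {
    nClass <- 12
    expect_lte(rules$support[i], nClass / N)
    expect_lte(rules$lift[i], N / nClass)
    # confidence * P(itemset) == support exactly on counts
    expect_equal(rules$nCoverClass[i] / rules$nCover[i] *
                   (rules$nCover[i] / N), rules$support[i],
                 tolerance = 1e-15)
  }
})

test_that("cross-class duplicates keep the more significant rule", {
  r <- .rulesFrom <- function(itemset, class, sup, conf, lift) {
    data.frame(itemset = itemset, class = class, support = sup,
               confidence = conf, lift = lift, nCover = 1L,
               nCoverClass = 1L, stringsAsFactors = FALSE)
  }
  rules <- rbind(r("A:up|B:down", "case", 0.4, 0.8, 1.6),
                 r("A:up|B:down", "control", 0.3, 0.9, 1.2),
                 r("C:up|D:up", "control", 0.2, 0.9, 1.4))
  rules$items <- strsplit(rules$itemset, "|", fixed = TRUE)
  out <- deduplicateCrossClass(rules)
  expect_equal(nrow(out), 2L)
  expect_equal(out$class[out$itemset == "A:up|B:down"], "case")
  expect_equal(out$class[out$itemset == "C:up|D:up"], "control")

  tie <- rbind(r("X:up|Y:up", "case", 0.2, 0.8, 1.5),
               r("X:up|Y:up", "control", 0.2, 0.8, 1.5))
  tie$items <- strsplit(tie$itemset, "|", fixed = TRUE)
  expect_warning(kept <- deduplicateCrossClass(tie), "tie")
  expect_equal(kept$class, "case")
})

test_that("ranking orders by lift, then confidence, and truncates per class", {
  r <- function(itemset, class, sup, conf, lift) {
    data.frame(itemset = itemset, class = class, support = sup,
               confidence = conf, lift = lift, nCover = 1L,
               nCoverClass = 1L, stringsAsFactors = FALSE)
  }
  rules <- rbind(r("A:up|B:up", "case", 0.3, 0.9, 2.0),
                 r("C:up|D:up", "case", 0.3, 0.9, 1.6),
                 r("E:up|F:up", "case", 0.3, 0.9, 1.2),
                 r("G:up|H:up", "case", 0.3, 1.0, 1.6))
  rules$items <- strsplit(rules$itemset, "|", fixed = TRUE)
  top2 <- rankAndSelect(rules, topN = 2)
  expect_equal(top2$itemset, c("A:up|B:up", "G:up|H:up"))
  expect_equal(top2$rank, c(1L, 2L))
  suppressMessages(all4 <- rankAndSelect(rules, topN = 250))
  expect_equal(nrow(all4), 4L)
  # equal lift: higher confidence first
  expect_equal(all4$itemset[2:3], c("G:up|H:up", "C:up|D:up"))
  expect_error(rankAndSelect(rules, 0), "topN")
})

test_that("top-n bookkeeping mirrors a two-class marker budget", {
  # 500 case + 300 control candidate rules, topN 250 -> 250 + 250 kept
  # unless a class has fewer (here: control keeps all 300 -> capped at 250)
  r <- function(i, class) {
    data.frame(itemset = sprintf("%s%04d:up|Z:up", class, i), class = class,
               support = 0.3, confidence = 0.9,
               lift = 1 + i * 1e-4, nCover = 1L, nCoverClass = 1L,
               stringsAsFactors = FALSE)
  }
  rules <- do.call(rbind, c(lapply(1:500, r, class = "case"),
                            lapply(1:246, r, class = "control")))
  rules$items <- strsplit(rules$itemset, "|", fixed = TRUE)
  suppressMessages(sel <- rankAndSelect(rules, topN = 250))
  expect_equal(sum(sel$class == "case"), 250L)
  expect_equal(sum(sel$class == "control"), 246L)
  expect_equal(nrow(sel), 496L)
  expect_false(anyDuplicated(paste(sel$class, sel$rank)) > 0)
})

test_that("marker mining is deterministic", {
  set.seed(55)
  st <- matrix(sample(c(-1, 1), 6 * 20, replace = TRUE), 6, 20,
               dimnames = list(paste0("P", 1:6), paste0("S", 1:20)))
  lab <- setNames(rep(c("case", "control"), each = 10), colnames(st))
  btm <- binarize(makeStates(st, lab))
  m1 <- suppressMessages(minePathwaySetMarkers(btm, minConf = 0.5,
                                               topN = 50))
  m2 <- suppressMessages(minePathwaySetMarkers(btm, minConf = 0.5,
                                               topN = 50))
  expect_identical(m1, m2)
  f1 <- withr::local_tempfile(fileext = ".json")
  f2 <- withr::local_tempfile(fileext = ".json")
  writeMarkersJSON(m1, f1)
  writeMarkersJSON(m2, f2)
  expect_identical(readLines(f1), readLines(f2))
})
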