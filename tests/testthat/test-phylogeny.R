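test_that("two-sample tree places the shared loss on the trunk", {
  chars <- rbind(normal = c(0, 0, 0), S1 = c(1, 1, 0), S2 = c(1, 0, 1))
  colnames(chars) <- c("-18q", "+7p", "+12p")
  ph <- fit_parsimony_tree(chars, "Pt1")
  expect_equal(ph$score, 3)
  ev <- ph$events
  expect_equal(ev$segment[ev$character == "-18q"], "trunk")
  expect_setequal(ev$segment[ev$character %in% c("+7p", "+12p")], "branches")
  expect_equal(ev$direction, rep("gain", 3))
})

test_that("identical samples put every event on the trunk", {
  chars <- rbind(normal = c(0, 0, 0, 0),
                 S1 = c(1, 1, 0, 1), S2 = c(1, 1, 0, 1))
  colnames(chars) <- c("-18q", "+13q", "+20q", "-8p")
  ph <- fit_parsimony_tree(chars)
  expect_equal(ph$score, 3)  # number of shared events
  expect_true(all(ph$events$segment == "trunk"))
})

test_that("the search equals exhaustive enumeration on random instances", {
  set.seed(73)
  for (i in 1:40) {
    k <- sample(3:4, 1)
    n_char <- sample(3:6, 1)
    chars <- matrix(rbinom(k * n_char, 1, 0.5), k, n_char)
    rownames(chars) <- paste0("S", seq_len(k))
    colnames(chars) <- sprintf("+%dq", seq_len(n_char) + 1)
    chars <- rbind(normal = rep(0L, n_char), chars)
    ph <- fit_parsimony_tree(chars)
    expect_equal(ph$score, oracle_parsimony(chars), label = paste("case", i))
  }
})

test_that("ambiguous placements resolve to the root-nearest edge", {
  # forced balanced topology ((S1,S2),(S3,S4)); the character +7p present in
  # S1, S2, S3 admits two equally parsimonious 2-change placements:
  # trunk gain + terminal S4 loss (depths 1, 3), or a gain on the (S1,S2)
  # clade edge + a terminal S3 gain (depths 2, 3). The earliest placement
  # (trunk gain, S4 loss) must win. A shared gain vs two private gains is
  # never a tie (1 < 2 changes), so only this construction is ambiguous.
  chars <- rbind(normal = c(0, 0, 0, 0),
                 S1 = c(1, 0, 0, 1),
                 S2 = c(1, 0, 0, 1),
                 S3 = c(0, 1, 1, 1),
                 S4 = c(0, 1, 1, 0))
  colnames(chars) <- c("+5q", "+8q", "+9q", "+7p")
  ph <- fit_parsimony_tree(chars)
  expect_equal(ph$score, 1 + 1 + 1 + 2)
  ev <- ph$events[ph$events$character == "+7p", ]
  expect_equal(sort(ev$depth), c(1L, 3L))
  gain <- ev[ev$direction == "gain", ]
  loss <- ev[ev$direction == "loss", ]
  expect_equal(gain$segment, "trunk")
  expect_equal(ph$nodes$label[loss$edge], "S4")
})

test_that("characters shared by all tumor samples map to the trunk", {
  set.seed(79)
  chars <- matrix(rbinom(4 * 8, 1, 0.5), 4, 8)
  chars[, 1] <- 1L  # shared by all samples
  rownames(chars) <- paste0("S", 1:4)
  colnames(chars) <- sprintf("+%dq", 1:8)
  chars <- rbind(normal = rep(0L, 8), chars)
  ph <- fit_parsimony_tree(chars)
  ev1 <- ph$events[ph$events$character == "+1q", ]
  expect_equal(ev1$segment, "trunk")
  # a private character maps to the sample's terminal edge
  priv <- which(colSums(chars) == 1)
  if (length(priv)) {
    pc <- colnames(chars)[priv[1]]
    evp <- ph$events[ph$events$character == pc, ]
    expect_false(is.na(ph$nodes$label[evp$edge]))
  }
})

test_that("duplicating a sample never increases the parsimony score", {
  set.seed(83)
  for (i in 1:10) {
    k <- sample(3:4, 1)
    chars <- matrix(rbinom(k * 6, 1, 0.4), k, 6)
    rownames(chars) <- paste0("S", seq_len(k))
    colnames(chars) <- sprintf("+%dq", 1:6)
    chars <- rbind(normal = rep(0L, 6), chars)
    ph <- fit_parsimony_tree(chars)
    chars2 <- rbind(chars, Sdup = chars[2, ])
    ph2 <- fit_parsimony_tree(chars2)
    expect_lte(ph2$score, ph$score + 0)
  }
})

test_that("event mapping is deterministic across repeated runs", {
  set.seed(89)
  chars <- matrix(rbinom(5 * 10, 1, 0.5), 5, 10)
  rownames(chars) <- paste0("S", 1:5)
  colnames(chars) <- sprintf("+%dq", 1:10)
  chars <- rbind(normal = rep(0L, 10), chars)
  ph1 <- fit_parsimony_tree(chars)
  ph2 <- fit_parsimony_tree(chars)
  expect_identical(ph1$newick, ph2$newick)
  expect_identical(ph1$events, ph2$events)
})

test_that("parsimony scores agree with an independent implementation", {
  skip_if_not_installed("phangorn")
  set.seed(97)
  for (i in 1:5) {
    chars <- matrix(rbinom(5 * 8, 1, 0.5), 5, 8)
    rownames(chars) <- paste0("S", 1:5)
    colnames(chars) <- sprintf("+%dq", 1:8)
    chars <- rbind(normal = rep(0L, 8), chars)
    ph <- fit_parsimony_tree(chars)
    dat <- phangorn::phyDat(chars, type = "USER", levels = c(0, 1))
    tr <- ape::read.tree(text = ph$newick)
    expect_equal(ph$score, phangorn::parsimony(ape::unroot(tr), dat))
  }
})

test_that("segment scores average the timing classes per segment", {
  timing <- data.frame(event = c("-18q", "+13q", "+20q", "+7p", "+12p", "+9q",
                                 "-8p"),
                       d = 1:7, class = c(1L, 2L, 3L, 8L, 9L, 4L, 4L))
  chars <- rbind(normal = c(0, 0, 0), S1 = c(1, 1, 1), S2 = c(1, 1, 1))
  colnames(chars) <- c("-18q", "+13q", "+20q")
  ph <- fit_parsimony_tree(chars, "PtA")
  sc <- segment_and_score(ph, timing)
  expect_equal(nrow(sc), 1)
  expect_equal(as.character(sc$segment), "trunk")
  expect_equal(sc$score, 2)  # mean of classes 1, 2, 3

  # balanced topology forced by the two clade characters; S1's private events
  # (classes 8 and 9) sit below two branching nodes -> sub-branches
  chars2 <- rbind(normal = rep(0, 5),
                  S1 = c(1, 1, 0, 1, 1),
                  S2 = c(1, 1, 0, 0, 0),
                  S3 = c(1, 0, 1, 0, 0),
                  S4 = c(1, 0, 1, 0, 0))
  colnames(chars2) <- c("-18q", "+13q", "+9q", "+7p", "+12p")
  ph2 <- fit_parsimony_tree(chars2, "PtB")
  sc2 <- segment_and_score(ph2, timing)
  sub <- sc2[sc2$segment == "sub-branches", ]
  expect_equal(nrow(sub), 1)
  expect_equal(sub$score, mean(c(8, 9)))
})

test_that("the trend test requires multiple patients and finds planted trends", {
  one <- data.frame(patient = "p1", segment = c("trunk", "branches"),
                    score = c(1, 5))
  expect_error(test_segment_trend(one, n_perm = 10), "at least two patients")

  set.seed(101)
  scores <- do.call(rbind, lapply(1:20, function(i) {
    data.frame(patient = paste0("p", i),
               segment = c("trunk", "branches", "sub-branches"),
               score = c(runif(1, 1, 3), runif(1, 4, 6), runif(1, 7, 9)))
  }))
  res <- test_segment_trend(scores, n_perm = 2000, seed = 5)
  expect_lt(res$omnibus_p, 0.01)
  expect_true(all(res$pairwise$q < 0.05))
})

test_that("simulated multi-sample patients show trunk-early ordering", {
  sim <- suppressWarnings(simulate_cohort(simulation_config(
    n_patients = 60, p_extra_met = 1, epsilon = 0, focal_rate = 0,
    seed = 211)))
  meta <- sim$meta
  timing <- data.frame(event = sim$truth$events$event,
                       d = sim$truth$events$distance,
                       class = sim$truth$events$timing_class)
  scores <- list()
  for (pid in unique(meta$patient)) {
    samp <- meta$sample[meta$patient == pid]
    if (length(samp) < 3L) next
    ph <- fit_parsimony_tree(patient_character_matrix(sim$matrix, samp), pid)
    scores[[pid]] <- segment_and_score(ph, timing)
  }
  scores <- do.call(rbind, scores)
  trunk <- scores$score[scores$segment == "trunk"]
  deep <- scores$score[scores$segment != "trunk"]
  expect_gt(length(trunk), 10)
  expect_lt(mean(trunk), mean(deep))
})
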