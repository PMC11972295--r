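test_that("canonical event strings parse and format round-trip", {
  ev <- parse_ci_events(c("+7p", "-18q", "+8q23-q24", "+12p amp", "-1p36"))
  expect_equal(ev$direction, c("gain", "loss", "gain", "gain", "loss"))
  expect_equal(ev$focal, c(FALSE, FALSE, TRUE, FALSE, TRUE))
  expect_equal(ev$high_level, c(FALSE, FALSE, FALSE, TRUE, FALSE))
  expect_equal(ev$band_lo[3], 23)
  expect_equal(ev$band_hi[3], 24)
  expect_equal(format_ci_event(ev), c("+7p", "-18q", "+8q23-q24", "+12p amp",
                                      "-1p36"))
  expect_error(parse_ci_events("7p"), "malformed")
  expect_error(parse_ci_events("+23q"), "malformed")
})

test_that("default exclusion mask matches the excluded regions", {
  mask <- default_exclusion_mask()
  ev <- parse_ci_events(c("-1p36", "-1p32", "-13p", "-14p", "-15p", "-21p",
                          "-22p", "-1q12", "-9q12", "-16q11", "-Yq12",
                          "+7p", "-1p21", "-1p", "+8q23-q24"))
  excl <- event_excluded(ev, mask)
  expect_true(all(excl[1:11]))     # masked regions
  expect_false(any(excl[12:15]))   # 7p, proximal 1p focal, whole-arm 1p, 8q focal
})

test_that("ci_matrix validates codes and drops masked events with a warning", {
  m <- matrix(c(1, 0, 1, 1), 2, 2,
              dimnames = list(c("s1", "s2"), c("+13q", "-18q")))
  cm <- ci_matrix(m)
  expect_equal(unclass(cm)[, "-18q"], c(s1 = -1L, s2 = -1L))  # losses normalized

  m3 <- cbind(m, "-1p32" = c(1, 0))
  expect_warning(cm3 <- ci_matrix(m3, mask = default_exclusion_mask()),
                 "exclusion mask")
  expect_equal(colnames(cm3), c("+13q", "-18q"))

  mbad <- m; mbad[1, 1] <- 3
  expect_error(ci_matrix(mbad), "invalid code")

  mdup <- m; rownames(mdup) <- c("s1", "s1")
  expect_error(ci_matrix(mdup), "duplicate sample")

  # gain and loss of the same locus cannot co-occur in one sample
  mgl <- matrix(c(1, 0, -1, 0), 2, 2,
                dimnames = list(c("s1", "s2"), c("+13q", "-13q")))
  expect_error(ci_matrix(mgl), "both gain and loss")
})

test_that("CI matrix TSV round-trips up to column order", {
  m <- matrix(c(1, 1, 0, -1, 2, 0), 2, 3,
              dimnames = list(c("s1", "s2"), c("+13q", "-18q", "+12p")))
  cm <- ci_matrix(m)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_ci_matrix(cm, path)
  back <- read_ci_matrix(path, mask = NULL)
  expect_equal(unclass(back)[, colnames(cm)], unclass(cm)[, colnames(cm)])
  expect_error(read_ci_matrix(path, mask = NULL) -> ok, NA)
})

test_that("summarize_ci counts arms, focals, gains and losses", {
  m <- matrix(c(1, 1, -1, 0, 1, 0), 1, 6,
              dimnames = list("s1", c("+13q", "+12p amp", "-18q", "+7p",
                                      "+8q23-q24", "-4q")))
  s <- summarize_ci(ci_matrix(m))
  expect_equal(s$n_arm_aneuploidies, 3L)  # +13q, +12p amp, -18q
  expect_equal(s$n_focal, 1L)             # +8q23-q24
  expect_equal(s$n_gains, 3L)
  expect_equal(s$n_losses, 1L)
  expect_equal(s$n_total, 4L)
  expect_equal(s$n_total, s$n_gains + s$n_losses)
  expect_equal(s$n_total, s$n_arm_aneuploidies + s$n_focal)

  # acrocentric short arm never counted as aneuploidy
  m2 <- matrix(-1, 1, 1, dimnames = list("s1", "-13p"))
  s2 <- summarize_ci(ci_matrix(m2))  # unmasked on purpose
  expect_equal(s2$n_arm_aneuploidies, 0L)

  # all-zero sample
  m3 <- matrix(0L, 1, 2, dimnames = list("s1", c("+13q", "-18q")))
  expect_equal(summarize_ci(ci_matrix(m3))$n_total, 0L)
})

test_that("summarize_ci conserves the number of nonzero cells", {
  set.seed(41)
  cm <- random_ci_matrix(25, c("+13q", "-18q", "+20q", "-8p", "+8q23-q24",
                               "-4q", "+12p"))
  s <- summarize_ci(cm)
  expect_equal(sum(s$n_total), sum(unclass(cm) != 0L))
})

test_that("one metastasis per patient: priority, CI count, ties, warnings", {
  events <- c("+13q", "-18q", "+20q", "-8p")
  vals <- rbind(
    p1_liv  = c(1, -1, 1, -1),
    p1_brn  = c(1, -1, 1, 0),
    p2_livA = c(1, -1, 1, -1),   # 4 CIs
    p2_livB = c(1, -1, 0, 0),    # 2 CIs -> selected
    p3_lng  = c(1, 0, 0, 0),
    p4_livA = c(1, -1, 0, 0),    # tie with B on 2 CIs -> id order
    p4_livB = c(0, -1, 1, 0),
    p5_prim = c(1, 0, 0, 0))
  colnames(vals) <- events
  cm <- ci_matrix(vals)
  meta <- data.frame(
    sample = rownames(vals),
    patient = c("p1", "p1", "p2", "p2", "p3", "p4", "p4", "p5"),
    site = c("liver", "brain", "liver", "liver", "lung", "liver", "liver",
             "primary"),
    timing = c(rep("synchronous", 7), "primary"))
  expect_warning(sel <- select_one_met_per_patient(cm, meta), "p5")
  expect_equal(sel$sample[sel$patient == "p1"], "p1_brn")   # brain priority
  expect_equal(sel$sample[sel$patient == "p2"], "p2_livB")  # fewest CIs
  expect_equal(sel$sample[sel$patient == "p3"], "p3_lng")   # identity
  expect_equal(sel$sample[sel$patient == "p4"], "p4_livA")  # id tie-break
  expect_false("p5" %in% sel$patient)
})

test_that("cohort table validation enforces site/timing consistency", {
  meta <- data.frame(sample = "s1", patient = "p1", site = "primary",
                     timing = "synchronous")
  expect_error(cohort_table(meta), "coincide")
  meta$timing <- "primary"
  expect_s3_class(cohort_table(meta), "cohort_table")
})
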