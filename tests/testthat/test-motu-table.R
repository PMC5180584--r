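make_table <- function(counts, roles = NULL, layers = NULL,
                       templates = NULL, marine = NULL) {
  rn <- rownames(counts) %||% sprintf("m%02d", seq_len(nrow(counts)))
  cn <- colnames(counts) %||% sprintf("s%02d", seq_len(ncol(counts)))
  dimnames(counts) <- list(rn, cn)
  samples <- data.frame(sample_id = cn,
                        role = roles %||% rep("sample", ncol(counts)),
                        layer = layers %||% rep("A", ncol(counts)),
                        stringsAsFactors = FALSE)
  if (!is.null(templates)) samples$template <- templates
  motus <- data.frame(motu_id = rn,
                      marine = marine %||% rep(TRUE, nrow(counts)),
                      unassignable = rep(FALSE, nrow(counts)),
                      stringsAsFactors = FALSE)
  motu_table(counts, motus, samples)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("cumulative-frequency filter reproduces the worked example", {
  tab <- make_table(rbind(c(90, 6, 2, 1, 1)))
  out <- cumulative_frequency_filter(tab, 0.03)
  expect_equal(unname(out$counts[1, ]), c(90, 6, 2, 0, 0))

  # a single-sample row is never zeroed (its own cumulative fraction is 1)
  tab1 <- make_table(rbind(c(10)))
  expect_equal(unname(cumulative_frequency_filter(tab1, 0.03)$counts[1, 1]),
               10)

  # zero threshold is the identity
  set.seed(121)
  cnts <- matrix(rpois(60, 20), 10, 6)
  tab2 <- make_table(cnts)
  expect_equal(cumulative_frequency_filter(tab2, 0)$counts, tab2$counts)
})

test_that("cumulative filter zeroes tied counts together and re-applies stably", {
  # ties spanning the threshold stay: three 2s reach 6/100 >= 0.03
  tab2 <- make_table(rbind(c(88, 6, 2, 2, 2)))
  f2 <- cumulative_frequency_filter(tab2, 0.03)
  expect_equal(unname(f2$counts[1, ]), c(88, 6, 2, 2, 2))
  # a tied block below the threshold is zeroed as a whole
  tab4 <- make_table(rbind(a = c(2, 1)))
  expect_true(all(cumulative_frequency_filter(tab4, 0.35)$counts[1, ] ==
                    c(2, 0)))
  # zeroing removes < t of each row's reads, so re-application is the
  # identity whenever no entry's cumulative fraction lies inside the
  # sensitivity band [t, t/(1-t)) -- the generic case
  f2b <- cumulative_frequency_filter(f2, 0.03)
  expect_equal(f2b$counts, f2$counts)
  set.seed(161)
  tab5 <- make_table(matrix(rpois(60, 40), 10, 6))
  f5 <- cumulative_frequency_filter(tab5, 0.03)
  expect_equal(cumulative_frequency_filter(f5, 0.03)$counts, f5$counts)
  # rows that become all-zero are dropped
  tab3 <- make_table(rbind(a = c(100, 0, 0), b = c(1, 1, 98)))
  f3 <- cumulative_frequency_filter(tab3, 0.05)
  expect_equal(nrow(f3$counts), 2)
})

test_that("control-contaminated MOTUs are removed entirely, then controls dropped", {
  cnts <- rbind(m1 = c(10, 5, 1, 0), m2 = c(8, 3, 0, 0))
  tab <- make_table(cnts, roles = c("sample", "sample", "blank", "negative"))
  out <- remove_control_motus(tab)
  expect_equal(rownames(out$counts), "m2")
  expect_false(any(out$samples$role %in% c("blank", "negative")))
  # clean blanks leave the MOTU set unchanged
  cnts2 <- rbind(m1 = c(10, 5, 0, 0), m2 = c(8, 3, 0, 0))
  tab2 <- make_table(cnts2, roles = c("sample", "sample", "blank",
                                      "negative"))
  expect_equal(nrow(remove_control_motus(tab2)$counts), 2)
  # absent controls: warning, no-op
  tab3 <- make_table(cnts2[, 1:2])
  expect_warning(out3 <- remove_control_motus(tab3), "no control")
  expect_equal(out3$counts, tab3$counts)
})

test_that("non-marine MOTUs are dropped by the marine flag", {
  cnts <- matrix(5, 10, 2)
  tab <- make_table(cnts, marine = rep(c(TRUE, FALSE, TRUE, TRUE, TRUE),
                                       2)[1:10])
  tab$motus$marine <- c(rep(TRUE, 7), rep(FALSE, 3))
  out <- remove_nonmarine(tab)
  expect_equal(nrow(out$counts), 7)
  # all-marine table unchanged
  tab2 <- make_table(cnts)
  expect_equal(nrow(remove_nonmarine(tab2)$counts), 10)
})

test_that("layer partition yields the seven Venn regions and a consistent union", {
  cnts <- rbind(aOnly = c(3, 0, 0), all3 = c(1, 2, 5), bc = c(0, 4, 1))
  tab <- make_table(cnts, layers = c("A", "B", "C"))
  lp <- layer_partition(tab)
  expect_equal(lp$A_only, 1)
  expect_equal(lp$ABC, 1)
  expect_equal(lp$BC, 1)
  expect_equal(lp$union, 3)
  # union equals the sum of the seven regions
  expect_equal(lp$union, lp$A_only + lp$B_only + lp$C_only +
                 lp$AB + lp$AC + lp$BC + lp$ABC)
  # random tables keep the identity
  set.seed(131)
  cnts2 <- matrix(rbinom(300, 1, 0.3) * rpois(300, 5), 50, 6)
  tab2 <- make_table(cnts2, layers = rep(c("A", "B", "C"), 2))
  lp2 <- layer_partition(tab2)
  expect_equal(lp2$union, lp2$A_only + lp2$B_only + lp2$C_only +
                 lp2$AB + lp2$AC + lp2$BC + lp2$ABC)
  expect_equal(lp2$A, lp2$A_only + lp2$AB + lp2$AC + lp2$ABC)
})

test_that("dataset comparison arithmetic behaves on identical inputs", {
  set.seed(141)
  cnts <- matrix(rbinom(100, 1, 0.5), 20, 5)
  cnts[1, 1] <- 1
  tab <- make_table(cnts)
  cmp <- compare_datasets(tab, tab)
  expect_equal(cmp$pct_increase_total, 0)
  expect_equal(cmp$pct_increase_per_sample, 0)
  expect_equal(cmp$shared_fraction, 100)
  expect_error(compare_datasets(make_table(cnts[0, , drop = FALSE]), tab),
               "empty")
})

test_that("stage log tracks MOTUs and reads monotonically through filters", {
  set.seed(151)
  cnts <- matrix(rpois(80, 3), 20, 4)
  cnts[1, ] <- c(0, 0, 1, 0)
  tab <- make_table(cnts, roles = c("sample", "sample", "sample", "blank"))
  tab$motus$marine[5] <- FALSE
  out <- remove_nonmarine(remove_control_motus(
    cumulative_frequency_filter(tab, 0.03)))
  lg <- out$log
  expect_true(all(diff(lg$motus) <= 0))
  expect_true(all(diff(lg$reads) <= 0))
  expect_equal(nrow(lg), 4)
})
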