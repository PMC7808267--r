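test_that("a SIM parses into a validated design", {
  d <- smart_design(codiacs_sim())
  expect_s3_class(d, "smart_design")
  expect_equal(d$arms, c(0, 1))
  expect_equal(nrow(d$sim), 8)
  expect_equal(sum(vapply(d$options, length, 1L)), 4)  # branches
  expect_equal(unname(d$pi1), c(0.5, 0.5))
})

test_that("invalid SIMs are rejected with informative errors", {
  sim <- codiacs_sim()
  bad <- sim; bad$PI2[1] <- 0.4
  expect_error(smart_design(bad), "PI2 does not sum to 1")
  bad <- sim; bad$A2[2] <- 0
  expect_error(smart_design(bad), "duplicate sequence")
  bad <- sim; bad$SD[3] <- -1
  expect_error(smart_design(bad), "SD must be positive")
  bad <- sim; bad$P2[1:2] <- c(0.4, 0.4)
  expect_error(smart_design(bad), "P2 does not sum to 1")
  expect_error(smart_design(sim[, -4]), "missing column")
  bad <- sim; bad$PI1 <- 0.4
  expect_error(smart_design(bad), "PI1 does not sum to 1")
})

test_that("degenerate branches are accepted and flagged", {
  d <- smart_design(degenerate_sim())
  deg <- smartats:::degenerate_branches(d)
  expect_equal(deg$A1, c(1, 2))
  expect_equal(deg$O2, c(0, 1))
  # G = (1*2) + (2*1) = 4 strategies; df = (2+1-2+1)+(1+2-2+1)-1 = 3
  expect_equal(nrow(ats_strategies(d)), 4)
  expect_equal(smart_df(d), 3)
  expect_equal(smart_df(d), df_rank_oracle(d))
})

test_that("strategy enumeration reproduces the published strategy table", {
  s <- ats_strategies(smart_design(alcohol_sim()))
  expect_equal(nrow(s), 8)
  expect_equal(s$code,
               c("(1;3,2)", "(1;3,5)", "(1;4,2)", "(1;4,5)",
                 "(2;3,1)", "(2;3,5)", "(2;4,1)", "(2;4,5)"))
  # widening every stage-2 branch to three options
  expect_equal(nrow(ats_strategies(smart_design(alcohol_sim(TRUE)))), 18)
})

test_that("a branchless design has one strategy and no global test", {
  sim <- data.frame(SEQ = 1, A1 = 1, PI1 = 1, O2 = 0, P2 = 1, A2 = 2,
                    PI2 = 1, MEAN = 0, SD = 1)
  d <- smart_design(sim)
  expect_equal(nrow(ats_strategies(d)), 1)
  expect_error(smart_df(d), "single strategy")
})

test_that("G equals the sum over arms of per-category option products", {
  set.seed(401)
  for (i in 1:25) {
    d <- smart_design(random_sim())
    G <- sum(vapply(d$arms, function(a) {
      prod(vapply(d$options[[as.character(a)]], length, 1L))
    }, 1))
    expect_equal(nrow(ats_strategies(d)), G)
  }
})

test_that("patients consistent with a strategy share its realized sequence", {
  d <- smart_design(alcohol_sim())
  s <- ats_strategies(d)
  # CBT non-responder switched to MED supports strategies 1 and 3
  expect_true(is_consistent(1, 1, 2, s[1, ]))
  expect_true(is_consistent(1, 1, 2, s[3, ]))
  expect_false(is_consistent(1, 1, 2, s[2, ]))
  # MED-first strategies can never match a CBT-first record
  for (g in 5:8) expect_false(is_consistent(1, 1, 2, s[g, ]))
  expect_error(is_consistent(7, 0, 3, s[1, ]), "outside the design")
})

test_that("the consistent-strategy count is the product over unobserved branches", {
  set.seed(402)
  for (i in 1:10) {
    d <- smart_design(random_sim())
    s <- ats_strategies(d)
    dat <- sim_smart(d, 40)
    cons <- smartats:::consistency_matrix(dat$A1, dat$O2, dat$A2, s)
    expect_true(all(rowSums(cons) >= 1))
    for (j in seq_len(nrow(dat))) {
      a <- as.character(dat$A1[j])
      other <- setdiff(d$categories[[a]], dat$O2[j])
      expected <- prod(vapply(as.character(other),
                              function(r) length(d$options[[a]][[r]]), 1L))
      expect_equal(sum(cons[j, ]), expected)
      # all supporting strategies prescribe the observed sequence
      hits <- which(cons[j, ])
      expect_true(all(s$d0[hits] == dat$A1[j]))
      expect_true(all(s[hits, paste0("d0", dat$O2[j])] == dat$A2[j]))
    }
  }
})

test_that("degrees of freedom match the published designs", {
  expect_equal(smart_df(smart_design(codiacs_sim())), 5)
  expect_equal(smart_df(smart_design(alcohol_sim())), 5)
  expect_equal(smart_df(smart_design(alcohol_sim(TRUE))), 9)
  one_arm <- codiacs_sim()[1:4, ]
  one_arm$PI1 <- 1
  expect_equal(smart_df(smart_design(one_arm)), 2)
})

test_that("the closed-form df equals the contrast-space rank oracle", {
  set.seed(403)
  for (i in 1:50) {
    d <- smart_design(random_sim())
    expect_equal(smart_df(d), df_rank_oracle(d))
  }
})

test_that("df equals the rank of the design-stage contrast covariance", {
  set.seed(404)
  for (i in 1:10) {
    d <- smart_design(random_sim())
    m <- design_moments(d)
    C <- smartats:::contrast_matrix(length(m$theta))
    expect_equal(numerical_rank(C %*% m$sigma %*% t(C)), smart_df(d))
  }
})
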