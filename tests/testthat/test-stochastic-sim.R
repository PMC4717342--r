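test_that("lineage simulation honours the degenerate transmission rates", {
  all_on <- simulate_lineages(c(1, 1), n_lines = 40, n_generations = 4, seed = 1)
  expect_identical(nrow(all_on), 40L * 5L)
  expect_true(all(all_on$status == "coinfected"))

  all_off <- simulate_lineages(c(0, 0), n_lines = 10, n_generations = 3, seed = 1)
  expect_true(all(all_off$status[all_off$generation == 0] == "coinfected"))
  expect_true(all(all_off$status[all_off$generation > 0] == "uninfected"))
})

test_that("lineages never regain a lost strain and are reproducible by seed", {
  sim <- simulate_lineages(strain_params(0.7, 0.6), n_lines = 60,
                           n_generations = 6, seed = 99)
  expect_identical(nrow(sim), 60L * 7L)
  expect_identical(
    dplyr::count(sim, line_id, generation)$n,
    rep(1L, 60L * 7L)
  )
  has <- function(status, strain) status %in% c(strain, "coinfected")
  for (id in unique(sim$line_id)) {
    tr <- sim[sim$line_id == id, ]
    tr <- tr[order(tr$generation), ]
    expect_true(all(diff(has(tr$status, "strain1")) <= 0))
    expect_true(all(diff(has(tr$status, "strain2")) <= 0))
    expect_true(all(diff(tr$status == "uninfected") >= 0))
  }

  again <- simulate_lineages(strain_params(0.7, 0.6), n_lines = 60,
                             n_generations = 6, seed = 99)
  expect_identical(as.data.frame(sim), as.data.frame(again))
})

test_that("per-strain Bernoulli retention is distributed as the matrix rows", {
  # exact identity of the transition probabilities, row by row
  withr::with_seed(5, {
    for (i in 1:25) {
      params <- random_params()
      m <- unclass(transition_matrix(params))
      for (s in infection_statuses()) {
        expect_equal(unname(m[s, ]),
                     unname(bernoulli_row(s, params$p1, params$p2)),
                     tolerance = 1e-12)
      }
    }
  })

  # and statistical indistinguishability of whole trajectories at gen 4:
  # categorical row-sampling oracle vs the package engine, 10,000 lines each
  params <- strain_params(0.8, 0.7)
  m <- transition_matrix(params)
  withr::with_seed(17, {
    oracle_final <- replicate(10000, oracle_simulate_line(m, 4)[5])
  })
  sim <- simulate_lineages(params, n_lines = 10000, n_generations = 4, seed = 18)
  sim_final <- sim$status[sim$generation == 4]
  expected <- as.numeric(propagate(founder_distribution("coinfected"), m, 4))
  tab_o <- table(factor(oracle_final, infection_statuses()))
  tab_s <- table(factor(sim_final, infection_statuses()))
  expect_gt(chisq.test(tab_o, p = expected)$p.value, 1e-4)
  expect_gt(chisq.test(tab_s, p = expected)$p.value, 1e-4)
})

test_that("null distribution matches its analytic expectation", {
  params <- strain_params(0.96, 0.943)
  nd <- null_distribution(params, n_lines = 40, n_generations = 4,
                          n_sims = 10000, seed = 42)
  expect_identical(nrow(nd), 10000L)
  expect_true(all(nd$n_coinfected >= 0 & nd$n_coinfected <= 40))
  expected_mean <- 40 * (0.96 * 0.943)^4
  se <- sd(nd$n_coinfected) / sqrt(10000)
  expect_lt(abs(mean(nd$n_coinfected) - expected_mean), 3 * se)

  # degenerate case: perfect transmission keeps every line coinfected
  nd1 <- null_distribution(c(1, 1), 40, 4, 200, seed = 1)
  expect_true(all(nd1$n_coinfected == 40))
})

test_that("one-generation null counts follow the exact binomial law", {
  nd <- null_distribution(c(0.5, 0.5), n_lines = 10, n_generations = 1,
                          n_sims = 1000, seed = 7)
  # P(coinfected after 1 gen) = 0.25, lines independent
  obs <- table(factor(pmin(nd$n_coinfected, 6L), levels = 0:6))
  p <- dbinom(0:10, 10, 0.25)
  pooled_p <- c(p[1:6], sum(p[7:11]))  # pool the sparse upper tail
  expect_gt(chisq.test(obs, p = pooled_p)$p.value, 0.01)
})

test_that("empirical p-value implements the add-one doubled-tail rule", {
  small <- tibble::tibble(sim = 1:9, n_coinfected = 1:9)
  res <- empirical_p_value(small, observed = 2)
  expect_equal(res$tail_lower, 3 / 10)
  expect_equal(res$p_value, 0.6)
  expect_equal(res$p_uncorrected, min(1, 2 * 2 / 9))

  # observed equal to the entire null mass
  nd <- null_distribution(c(1, 1), 40, 4, 100, seed = 1)
  expect_equal(empirical_p_value(nd, 40)$p_value, 1)

  expect_error(empirical_p_value(nd, 41), "observed")
  expect_error(empirical_p_value(nd, -1), "observed")

  td <- tidy(res)
  expect_s3_class(td, "tbl_df")
  expect_identical(td$observed, 2L)
  gl <- glance(res)
  expect_identical(gl$n_sims, 9L)
})

test_that("the observed deficit of coinfected lines is highly significant", {
  nd <- null_distribution(strain_params(0.96, 0.943), 40, 4,
                          n_sims = 2000, seed = 3)
  res <- empirical_p_value(nd, observed = 11)
  expect_lt(res$p_value, 0.01)
  expect_gt(res$p_value, 0)
})

test_that("null p-values are stochastically at least uniform", {
  nd <- null_distribution(strain_params(0.96, 0.943), 40, 4,
                          n_sims = 4000, seed = 8)
  # draw observations from the null itself and test at a grid of levels
  withr::with_seed(9, {
    obs <- sample(nd$n_coinfected, 1000, replace = TRUE)
  })
  pvals <- vapply(obs, function(o) empirical_p_value(nd, o)$p_value, 0)
  expect_true(all(pvals > 0))
  for (alpha in c(0.01, 0.05, 0.1, 0.25)) {
    # conservative: P(p <= alpha) should not exceed alpha by more than noise
    expect_lte(mean(pvals <= alpha), alpha + 3 * sqrt(alpha * (1 - alpha) / 1000))
  }
})
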