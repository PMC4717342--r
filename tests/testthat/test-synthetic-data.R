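test_that("vertical generator collapses to the analytic model at gamma = 1", {
  cfg <- generator_config()  # p1 = 0.96, p2 = 0.943, gamma = 1
  v <- gen_vertical_experiment(cfg, n_mothers = 400, offspring_per_mother = 5,
                               mother_status = "coinfected", seed = 101)
  frac <- mean(v$status == "coinfected")
  p <- 0.96 * 0.943
  se <- sqrt(p * (1 - p) / nrow(v))
  expect_lt(abs(frac - p), 3 * se)

  s1 <- gen_vertical_experiment(cfg, n_mothers = 400, offspring_per_mother = 5,
                                mother_status = "strain1", seed = 102)
  se1 <- sqrt(0.96 * 0.04 / nrow(s1))
  expect_lt(abs(mean(s1$status == "strain1") - 0.96), 3 * se1)
  expect_true(all(s1$status %in% c("strain1", "uninfected")))
})

test_that("full competition abolishes co-transmission", {
  cfg <- generator_config(gamma = 0)
  v <- gen_vertical_experiment(cfg, n_mothers = 50, offspring_per_mother = 5,
                               mother_status = "coinfected", seed = 5)
  expect_identical(sum(v$status == "coinfected"), 0L)
})

test_that("segregation generator at gamma = 1 is the null model", {
  cfg <- generator_config(seed = 77)
  seg <- gen_segregation_experiment(cfg)
  expect_s3_class(seg, "lineage_tbl")
  expect_identical(max(seg$generation), 4L)
  nd <- null_distribution(cfg$params, n_lines = 40, n_generations = 4,
                          n_sims = 1, seed = 77)
  expect_identical(count_coinfected(seg), nd$n_coinfected[1])

  g0 <- gen_segregation_experiment(cfg, n_generations = 0)
  expect_true(all(g0$status == "coinfected"))
})

test_that("within-host competition depresses the final coinfected count", {
  cfg_comp <- generator_config(gamma = 0.8)
  counts <- withr::with_seed(31, {
    vapply(1:1000, function(i) {
      count_coinfected(gen_segregation_experiment(cfg_comp))
    }, 0L)
  })
  expect_lt(mean(counts), 40 * (0.96 * 0.943)^4)  # 26.8 under independence
  expect_lt(mean(counts) + 3 * sd(counts) / sqrt(1000), 26.8)
})

test_that("horizontal generator reproduces the protection pattern", {
  cfg <- generator_config(h = 0.75, rho = 0.45)
  n_off <- function(dat, strain) mean(vapply(dat$bands, function(b) strain %in% b, NA))

  un <- gen_horizontal_experiment(cfg, n_vials = 40, offspring_per_vial = 25,
                                  donor_status = "strain1",
                                  recipient_status = "uninfected", seed = 61)
  inf <- gen_horizontal_experiment(cfg, n_vials = 40, offspring_per_vial = 25,
                                   donor_status = "strain1",
                                   recipient_status = "strain2", seed = 62)
  acq_un <- mean(vapply(un$bands, function(b) 399L %in% b, NA))
  acq_inf <- mean(vapply(inf$bands, function(b) 399L %in% b, NA))
  se <- sqrt(0.75 * 0.25 / 1000)
  expect_lt(abs(acq_un - 0.75), 3 * se)
  expect_lt(abs(acq_inf - 0.75 * 0.45), 3 * sqrt(0.34 * 0.66 / 1000))
  # about twofold lower, as observed
  expect_gt(acq_un / acq_inf, 1.5)

  # no protection: acquisition independent of recipient status
  cfg1 <- generator_config(h = 0.75, rho = 1)
  inf1 <- gen_horizontal_experiment(cfg1, n_vials = 40, offspring_per_vial = 25,
                                    donor_status = "strain1",
                                    recipient_status = "strain2", seed = 63)
  acq1 <- mean(vapply(inf1$bands, function(b) 399L %in% b, NA))
  expect_lt(abs(acq1 - 0.75), 3 * se)

  # no horizontal transfer at all
  cfg0 <- generator_config(h = 0)
  off <- gen_horizontal_experiment(cfg0, n_vials = 4, offspring_per_vial = 25,
                                   donor_status = "strain1",
                                   recipient_status = "uninfected", seed = 64)
  expect_true(all(off$status == "uninfected"))
})

test_that("coinfected donors transfer both strains as a package", {
  cfg <- generator_config(h = 0.9)
  dat <- gen_horizontal_experiment(cfg, n_vials = 10, offspring_per_vial = 20,
                                   donor_status = "coinfected",
                                   recipient_status = "uninfected", seed = 71)
  # every acquisition event delivers both strains, so no singly infected
  expect_true(all(dat$status %in% c("uninfected", "coinfected")))
  p <- mean(dat$status == "coinfected")
  expect_lt(abs(p - 0.9), 3 * sqrt(0.9 * 0.1 / 200))
})

test_that("generator configs are read from key=value and JSON files", {
  kv <- withr::local_tempfile(fileext = ".cfg")
  writeLines(c("# demo", "p1 = 0.9", "p2=0.8", "gamma=0.7", "seed=5"), kv)
  cfg <- read_generator_config(kv)
  expect_equal(cfg$params$p1, 0.9)
  expect_equal(cfg$gamma, 0.7)
  expect_identical(cfg$seed, 5L)
  expect_equal(cfg$rho, 0.45)  # default preserved

  js <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(p1 = 0.96, p2 = 0.943, h = 0.5), js,
                       auto_unbox = TRUE)
  cfg2 <- read_generator_config(js)
  expect_equal(cfg2$h, 0.5)

  bad <- withr::local_tempfile(fileext = ".cfg")
  writeLines(c("p1=0.9", "p2=0.8", "bogus=1"), bad)
  expect_error(read_generator_config(bad), "bogus")
  missing <- withr::local_tempfile(fileext = ".cfg")
  writeLines("p1=0.9", missing)
  expect_error(read_generator_config(missing), "p2")
})
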