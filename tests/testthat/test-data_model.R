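test_that("iv_dataset validates, maps columns and handles missingness", {
  df <- data.frame(snp1 = c(0, 1, 2, 1, 0), snp2 = c(1, 1, 0, 2, 1),
                   bmi = rnorm(5), crp = rnorm(5), urate = rnorm(5))
  path <- write_fixture(df, "csv")
  ds <- read_iv_dataset(path, g_x = "snp1", g_z = "snp2", x = "bmi",
                        z = "crp", y = "urate")
  expect_s3_class(ds, "iv_dataset")
  expect_equal(nrow(ds), 5)
  expect_named(as.data.frame(ds), c("g_x", "g_z", "x", "z", "y"))

  # a missing outcome drops exactly that row, with a message
  df2 <- df; df2$urate[3] <- NA
  path2 <- write_fixture(df2, "tsv")
  expect_message(
    ds2 <- read_iv_dataset(path2, g_x = "snp1", g_z = "snp2", x = "bmi",
                           z = "crp", y = "urate"),
    "dropped 1")
  expect_equal(nrow(ds2), 4)
  expect_equal(attr(ds2, "n_dropped"), 1L)

  # constant instrument is rejected
  df3 <- df; df3$snp1 <- 1
  expect_error(iv_dataset(df3, g_x = "snp1", g_z = "snp2", x = "bmi",
                          z = "crp", y = "urate"),
               "zero sample variance")

  # unknown column named in the error
  expect_error(iv_dataset(df, g_x = "nope", g_z = "snp2", x = "bmi",
                          z = "crp", y = "urate"),
               "nope")
})

test_that("write/read round-trips numeric columns bit-for-bit", {
  set.seed(99)
  ds <- toy_dataset(n = 40)
  p <- tempfile(fileext = ".tsv")
  write_iv_dataset(ds, p)
  back <- read_iv_dataset(p)
  for (v in c("g_x", "g_z", "x", "z", "y")) {
    expect_identical(back[[v]], ds[[v]])
  }
})

test_that("residualize projects covariates out and is idempotent", {
  set.seed(3)
  n <- 300
  age <- rnorm(n, 50, 8)
  centre <- factor(sample(c("a", "b", "c"), n, TRUE))
  base <- toy_dataset(n = n, seed = 4)
  df <- as.data.frame(base)
  df$age <- age
  df$centre <- centre
  df$y <- df$y + 2 * age
  ds <- iv_dataset(df, covariates = c("age", "centre"))

  # no covariates requested -> identity
  expect_identical(residualize(ds, covariates = character()), ds)

  r <- residualize(ds)
  expect_lt(abs(cor(r$y, age)), 1e-10)
  expect_lt(abs(mean(r$y)), 1e-10)
  expect_lt(abs(mean(r$x)), 1e-10)

  # idempotent
  r2 <- residualize(r)
  expect_equal(r2$y, r$y, tolerance = 1e-10)
  expect_equal(r2$x, r$x, tolerance = 1e-10)

  # balanced one-factor design: residualization == per-group demeaning
  grp <- factor(rep(c("p", "q"), each = 100))
  df2 <- data.frame(g_x = rbinom(200, 2, 0.4), g_z = rbinom(200, 2, 0.4),
                    x = rnorm(200), z = rnorm(200),
                    y = rnorm(200) + ifelse(grp == "p", 3, -3),
                    grp = grp)
  ds2 <- iv_dataset(df2, covariates = "grp")
  r3 <- residualize(ds2)
  demeaned <- unsplit(lapply(split(df2$y, grp), function(v) v - mean(v)), grp)
  expect_equal(r3$y, demeaned, tolerance = 1e-10)

  # rank-deficient design names the collinear column
  df$age2 <- df$age
  ds3 <- iv_dataset(df, covariates = c("age", "age2"))
  expect_error(residualize(ds3), "age2")
})

test_that("weighted allele score is calibrated to slope 1", {
  set.seed(11)
  n <- 600
  G <- cbind(v1 = rbinom(n, 2, 0.3), v2 = rbinom(n, 2, 0.2),
             v3 = rbinom(n, 2, 0.4))
  w <- data.frame(variant_id = c("v1", "v2", "v3"), trait = "bmi",
                  weight = c(0.2, 0.5, 0.3))
  x <- drop(G %*% w$weight) * 0.7 + rnorm(n)
  sc <- weighted_allele_score(G, w, x)
  expect_equal(unname(ols_slope <- coef(lm(x ~ sc))[2]), 1, tolerance = 1e-8)

  # single variant: scaled score equals slope * genotype
  w1 <- w[1, ]
  x1 <- 0.4 * G[, "v1"] + rnorm(n)
  b <- coef(lm(x1 ~ G[, "v1"]))[2]
  sc1 <- weighted_allele_score(G[, "v1", drop = FALSE], w1, x1)
  expect_equal(as.numeric(sc1), unname(b * G[, "v1"]), tolerance = 1e-10)

  # R^2 is invariant under the rescaling
  r2_raw <- summary(lm(x ~ drop(G %*% w$weight)))$r.squared
  r2_scaled <- summary(lm(x ~ sc))$r.squared
  expect_equal(r2_scaled, r2_raw, tolerance = 1e-10)

  # multiplying all weights by a positive constant changes nothing
  w10 <- w; w10$weight <- w10$weight * 10
  sc10 <- weighted_allele_score(G, w10, x)
  expect_equal(as.numeric(sc10), as.numeric(sc), tolerance = 1e-10)

  # a useless score is refused: calibration variable orthogonal to the score
  gen <- matrix(rnorm(n), ncol = 1, dimnames = list(NULL, "v9"))
  junk <- resid(lm(rnorm(n) ~ gen[, 1]))
  expect_error(
    weighted_allele_score(gen,
                          data.frame(variant_id = "v9", trait = "t",
                                     weight = 1),
                          junk),
    "not a usable instrument")
})

test_that("variant weights reader enforces the three-column contract", {
  w <- data.frame(variant_id = c("rs1", "rs2"), trait = "bmi",
                  weight = c(0.1, -0.2))
  p <- write_fixture(w, "tsv")
  back <- read_variant_weights(p)
  expect_equal(back$weight, w$weight)
  p2 <- write_fixture(w[, c("variant_id", "weight")], "tsv")
  expect_error(read_variant_weights(p2), "trait")
})
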