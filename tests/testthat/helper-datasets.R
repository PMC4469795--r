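# small in-code fixtures shared across test files

# toy confounded dataset with known structure, quick to simulate
toy_dataset <- function(n = 500, seed = 1, bx = 1, gx_eff = 0.5,
                        gz_eff = 0.5, gz = 1, dx = 1) {
  set.seed(seed)
  g_x <- rbinom(n, 2, 0.3)
  g_z <- rbinom(n, 2, 0.3)
  u <- rnorm(n)
  x <- gx_eff * g_x + u + rnorm(n)
  z <- gz_eff * g_z + bx * x + u + rnorm(n)
  y <- dx * x + gz * z + u + rnorm(n)
  iv_dataset(data.frame(g_x = g_x, g_z = g_z, x = x, z = z, y = y))
}

# write a small delimited fixture and return its path
write_fixture <- function(df, ext = "csv") {
  path <- tempfile(fileext = paste0(".", ext))
  write.table(df, path, sep = if (ext == "csv") "," else "\t",
              quote = FALSE, row.names = FALSE)
  path
}

expect_estimate_close <- function(est, truth, tol) {
  expect_lt(abs(est - truth), tol)
}
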