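test_that("person_center splits values into within and between parts", {
  d <- tibble::tibble(participant_id = c("A", "A", "A", "B"),
                      satiety = c(1, 2, 3, 5))
  out <- person_center(d, "satiety", grand_center = FALSE)
  expect_equal(out$satiety_w, c(-1, 0, 1, 0))
  expect_equal(out$satiety_b, c(2, 2, 2, 5))
  # constant binary flag: within 0, between the constant
  d2 <- tibble::tibble(participant_id = "A", refined_grains = c(1, 1, 1))
  out2 <- person_center(d2, "refined_grains", grand_center = FALSE)
  expect_equal(out2$refined_grains_w, c(0, 0, 0))
  expect_equal(out2$refined_grains_b, c(1, 1, 1))
})

test_that("reconstruction and zero-sum-within hold to machine precision", {
  set.seed(41)
  for (rep in 1:10) {
    n_id <- sample(3:12, 1)
    rows <- sample(1:6, n_id, replace = TRUE) # includes single-meal people
    d <- tibble::tibble(
      participant_id = rep(sprintf("P%d", seq_len(n_id)), rows),
      sleep_h = rnorm(sum(rows), 6, 1),
      satiety = sample(1:6, sum(rows), replace = TRUE)
    )
    out <- person_center(d, c("sleep_h", "satiety"), grand_center = FALSE)
    expect_equal(out$sleep_h_w + out$sleep_h_b, d$sleep_h, tolerance = 1e-12)
    expect_equal(out$satiety_w + out$satiety_b, as.numeric(d$satiety),
                 tolerance = 1e-12)
    sums <- tapply(out$sleep_h_w, out$participant_id, sum)
    expect_true(all(abs(sums) < 1e-10))
  }
})

test_that("grand centering shifts between parts without touching within", {
  d <- tibble::tibble(participant_id = rep(c("A", "B"), each = 3),
                      sleep_h = c(5, 6, 7, 7, 8, 9))
  raw <- person_center(d, "sleep_h", grand_center = FALSE)
  gc <- person_center(d, "sleep_h", grand_center = TRUE)
  expect_equal(raw$sleep_h_w, gc$sleep_h_w)
  expect_equal(mean(gc$sleep_h_b), 0, tolerance = 1e-12)
})

test_that("centering a within column is idempotent", {
  d <- tibble::tibble(participant_id = rep(c("A", "B"), each = 4),
                      satiety = c(1, 3, 2, 4, 5, 6, 4, 5))
  out <- person_center(d, "satiety", grand_center = FALSE)
  d2 <- tibble::tibble(participant_id = d$participant_id,
                       satiety = out$satiety_w)
  out2 <- person_center(d2, "satiety", grand_center = FALSE)
  expect_equal(out2$satiety_w, out$satiety_w, tolerance = 1e-12)
})

test_that("continuous ICC recovers the generating variance ratio", {
  set.seed(42)
  n <- 500; k <- 10
  b <- rnorm(n, 0, 1)             # sigma2_b = 1
  y <- rep(b, each = k) + rnorm(n * k, 0, sqrt(3)) # sigma2_w = 3
  d <- tibble::tibble(participant_id = rep(seq_len(n), each = k), y = y)
  out <- icc_continuous(d, "y")
  expect_lt(abs(out$icc - 0.25), 0.03)
  # degenerate limits
  flat <- tibble::tibble(participant_id = rep(1:100, each = 8),
                         y = rnorm(800))
  expect_lt(icc_continuous(flat, "y")$icc, 0.06)
  const <- tibble::tibble(participant_id = rep(1:20, each = 5),
                          y = rep(rnorm(20), each = 5))
  expect_gt(icc_continuous(const, "y")$icc, 0.95)
})

test_that("binary ICC flags degenerate inputs and detects independence", {
  set.seed(43)
  d <- tibble::tibble(participant_id = rep(1:100, each = 8),
                      y = rbinom(800, 1, 0.4))
  expect_lt(icc_binary(d, "y")$icc, 0.08)
  allsame <- tibble::tibble(participant_id = rep(1:10, each = 3), y = 1)
  expect_error(icc_binary(allsame, "y"), "single outcome level")
})

test_that("variance_decomposition dispatches by measure type", {
  set.seed(44)
  d <- tibble::tibble(
    participant_id = rep(1:60, each = 6),
    sleep_h = rep(rnorm(60, 5.5, 1), each = 6) + rnorm(360, 0, 1),
    refined_grains = rbinom(360, 1, plogis(rep(rnorm(60, 0.8, 1), each = 6)))
  )
  vd <- variance_decomposition(d, c("sleep_h", "refined_grains"))
  expect_equal(vd$scale, c("continuous", "binary_latent"))
  expect_equal(vd$within_share, 1 - vd$icc)
  expect_true(all(vd$icc >= 0 & vd$icc <= 1))
})
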