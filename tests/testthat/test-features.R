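kp <- keypad_layout("grid3x3")
line <- keypad_layout("line1d")

test_that("repetition vector is one-hot at the previous response", {
  expect_equal(repetition_vector(3, 9), c(0, 0, 1, 0, 0, 0, 0, 0, 0))
  expect_equal(which(repetition_vector(1, 9) == 1), 1L)
  expect_equal(which(repetition_vector(9, 9) == 1), 9L)
  expect_error(repetition_vector(0, 9), "1..9")
  expect_error(repetition_vector(10, 9), "1..9")
})

test_that("side coding marks the opposite half +1, same half -1, 5 neutral", {
  expect_equal(side_vector(3), c(-1, -1, -1, -1, 0, 1, 1, 1, 1))
  expect_equal(side_vector(5), rep(0, 9))
  expect_equal(side_vector(9), c(1, 1, 1, 1, 0, -1, -1, -1, -1))
  expect_error(side_vector(3, K = 8), "9-digit")
})

test_that("mirroring the previous response flips every side entry", {
  for (prev in setdiff(1:9, 5))
    expect_equal(side_vector(prev) + side_vector(10 - prev), rep(0, 9))
})

test_that("keypad distances follow the unit-grid geometry", {
  expect_equal(distance_vector(5, kp),
               c(sqrt(2), 1, sqrt(2), 1, 0, 1, sqrt(2), 1, sqrt(2)))
  expect_equal(distance_vector(4, line)[7], 3)
  expect_equal(distance_vector(1, kp)[9], 2 * sqrt(2))
  expect_error(distance_vector(11, line), "not a digit")
})

test_that("grid distances are invariant under the square's symmetries", {
  # digit permutations induced by the 8 symmetries of the 3x3 grid
  coords <- cbind(ceiling(1:9 / 3), ((1:9 - 1) %% 3) + 1)
  apply_sym <- function(f) {
    newc <- t(apply(coords, 1, f))
    vapply(1:9, function(i)
      which(coords[, 1] == newc[i, 1] & coords[, 2] == newc[i, 2]), integer(1))
  }
  syms <- list(function(p) p,
               function(p) c(p[2], 4 - p[1]),          # rotate 90
               function(p) c(4 - p[1], 4 - p[2]),      # rotate 180
               function(p) c(4 - p[2], p[1]),          # rotate 270
               function(p) c(p[1], 4 - p[2]),          # horizontal flip
               function(p) c(4 - p[1], p[2]),          # vertical flip
               function(p) c(p[2], p[1]),              # main diagonal
               function(p) c(4 - p[2], 4 - p[1]))      # anti-diagonal
  for (f in syms) {
    perm <- apply_sym(f)
    for (prev in 1:9)  # D(a, b) = D(perm(a), perm(b))
      expect_equal(distance_vector(prev, kp),
                   distance_vector(perm[prev], kp)[perm],
                   tolerance = 1e-12)
  }
})

test_that("gap vector initializes to ones and updates by reset/increment", {
  expect_equal(init_gap(9), rep(1L, 9))
  expect_equal(init_gap(2), c(1L, 1L))
  expect_equal(log2(init_gap(9)), rep(0, 9))
  g1 <- update_gap(init_gap(9), 3)
  expect_equal(g1, c(2, 2, 1, 2, 2, 2, 2, 2, 2))
  expect_equal(update_gap(g1, 7), c(3, 3, 2, 3, 3, 3, 1, 3, 3))
  g <- c(5, 1, 9, 2, 2, 7, 3, 4, 6)
  out <- update_gap(g, 4)
  expect_equal(min(out), 1)
  expect_equal(which.min(out), 4L)
  expect_equal(g, c(5, 1, 9, 2, 2, 7, 3, 4, 6))  # input not mutated
  expect_error(update_gap(g, 0), "1..9")
  expect_error(update_gap(c(0, 1, 1), 1), ">= 1")
})

test_that("encoded gap rows are bounded by the prefix length and reset at
           the last response", {
  set.seed(41)
  for (rep in 1:5) {
    resp <- sample.int(9, 40, replace = TRUE)
    feats <- encode_features(resp, kp)
    for (t in seq_len(nrow(feats$G))) {
      expect_true(all(feats$G[t, ] <= t + 1))
      expect_equal(feats$G[t, resp[t]], 1)
    }
    expect_equal(feats$y, resp[-1])
    expect_equal(rowSums(feats$R), rep(1, 39))
  }
})

test_that("feature_state bundles the four predictors consistently", {
  st <- feature_state(3, update_gap(init_gap(9), 3), kp)
  expect_equal(st$r, repetition_vector(3, 9))
  expect_equal(st$s, side_vector(3))
  expect_equal(st$d, distance_vector(3, kp))
  expect_equal(sum(st$s), 0)
  expect_equal(st$s[5], 0)
  expect_equal(st$d[3], 0)
  expect_equal(min(st$g), 1)
})
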