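cm2 <- function(a, b, c, d, labels = c("A", "B")) {
  matrix(c(a, c, b, d), 2, 2, dimnames = list(true = labels,
                                              predicted = labels))
}

test_that("the confusion-derived joint has the documented structure", {
  perfect <- cm2(10, 0, 0, 10)
  j <- joint_from_confusions(perfect, perfect)
  expect_equal(sum(j), 1)
  expect_equal(j["A", "A", "A"], 0.5)
  expect_equal(j["B", "B", "B"], 0.5)
  expect_equal(sum(unclass(j)[cbind(1:2, 1:2, 1:2)]), 1)

  ## chance electrode Y: conditioning on it changes nothing
  chance <- cm2(5, 5, 5, 5)
  good <- cm2(9, 1, 2, 8)
  jy <- joint_from_confusions(good, chance)
  p_sx <- apply(unclass(jy), c(1, 2), sum)
  i_sx <- sum(p_sx * log2(p_sx / (rowSums(p_sx) %o% colSums(p_sx))))
  expect_equal(conditional_mutual_information(jy, "Ry"), i_sx,
               tolerance = 1e-12)

  ## symmetric inputs give an exchange-symmetric joint
  jsym <- joint_from_confusions(cm2(8, 2, 2, 8), cm2(8, 2, 2, 8))
  expect_equal(unclass(jsym), aperm(unclass(jsym), c(1, 3, 2)),
               ignore_attr = TRUE)

  expect_error(joint_from_confusions(cm2(10, 0, 0, 10), cm2(9, 1, 2, 9)),
               "counts differ")
  expect_error(joint_from_confusions(cm2(0, 0, 5, 5), cm2(0, 0, 5, 5)),
               "zero trials")
  expect_error(joint_from_confusions(perfect,
                                     cm2(10, 0, 0, 10, c("A", "C"))),
               "label sets")
})

test_that("conditional mutual information matches closed forms", {
  ## S, Rx, Ry mutually independent -> 0
  p <- array(1 / 8, dim = c(2, 2, 2))
  expect_equal(conditional_mutual_information(
    structure(p, class = c("joint_sr", "array"))), 0)
  ## Rx = S deterministic, Ry independent uniform -> 1 bit
  p2 <- array(0, dim = c(2, 2, 2))
  p2[1, 1, ] <- 0.25; p2[2, 2, ] <- 0.25
  expect_equal(conditional_mutual_information(
    structure(p2, class = c("joint_sr", "array"))), 1)
})

test_that("CMI equals the direct plug-in definition on random joints", {
  set.seed(123)
  errs <- replicate(1000, {
    j <- random_joint()
    abs(conditional_mutual_information(j, "Ry") - cmi_direct(j))
  })
  expect_lt(max(errs), 1e-10)
})

test_that("CMI is non-negative and vanishes under conditional independence", {
  set.seed(124)
  vals <- replicate(300, conditional_mutual_information(random_joint()))
  expect_true(all(vals >= 0))
  ## construct S independent of Rx given Ry: p = p(s) p(y) p(x|y)
  ps <- c(0.3, 0.7); py <- c(0.6, 0.4)
  pxy <- matrix(c(0.8, 0.2, 0.3, 0.7), 2, 2)   # p(x | y) in columns
  p <- array(0, dim = c(2, 2, 2))
  for (s in 1:2) for (x in 1:2) for (y in 1:2)
    p[s, x, y] <- ps[s] * py[y] * pxy[x, y]
  expect_lt(conditional_mutual_information(
    structure(p, class = c("joint_sr", "array")), "Ry"), 1e-12)
})

test_that("the chain rule holds against entropy computed from scratch", {
  H <- function(p) { p <- p[p > 0]; -sum(p * log2(p)) }
  set.seed(125)
  errs <- replicate(1000, {
    j <- unclass(random_joint())
    i_s_xy <- H(apply(j, 1, sum)) + H(apply(j, c(2, 3), sum)) - H(j)
    p_sy <- apply(j, c(1, 3), sum)
    i_s_y <- H(apply(j, 1, sum)) + H(apply(j, 3, sum)) - H(p_sy)
    i_s_x_given_y <- conditional_mutual_information(
      structure(j, class = c("joint_sr", "array")), "Ry")
    abs(i_s_xy - (i_s_y + i_s_x_given_y))
  })
  expect_lt(max(errs), 1e-10)
})

test_that("information tendency is antisymmetric with the expected sign", {
  good <- cm2(9, 1, 2, 8)
  soso <- cm2(7, 3, 4, 6)
  t_xy <- information_tendency(good, soso)
  t_yx <- information_tendency(soso, good)
  expect_equal(t_xy, -t_yx)
  expect_gt(t_xy, 0)                       # the better-decoded side wins
  expect_equal(information_tendency(good, good), 0)

  ## X perfect, Y chance: tendency equals I(S; Rx) = 1 bit (uniform prior)
  expect_equal(information_tendency(cm2(10, 0, 0, 10), cm2(5, 5, 5, 5)), 1)
})

test_that("plug-in CMI converges to the generating value as trials grow", {
  ## two binary symmetric channels with accuracies .8 and .65
  ax <- 0.8; ay <- 0.65
  exact_joint <- function() {
    p <- array(0, dim = c(2, 2, 2))
    for (s in 1:2) for (x in 1:2) for (y in 1:2)
      p[s, x, y] <- 0.5 * (if (x == s) ax else 1 - ax) *
        (if (y == s) ay else 1 - ay)
    structure(p, class = c("joint_sr", "array"))
  }
  truth <- cmi_direct(exact_joint())
  set.seed(126)
  med_err <- sapply(c(20, 80, 320), function(n) {
    errs <- replicate(40, {
      kx <- rbinom(2, n, ax); ky <- rbinom(2, n, ay)
      cx <- cm2(kx[1], n - kx[1], n - kx[2], kx[2])
      cy <- cm2(ky[1], n - ky[1], n - ky[2], ky[2])
      abs(conditional_mutual_information(
        joint_from_confusions(cx, cy), "Ry") - truth)
    })
    median(errs)
  })
  expect_true(all(diff(med_err) < 0))
})

test_that("the paired-prediction joint reproduces empirical frequencies", {
  truth <- c("A", "A", "B", "B", "A", "B")
  px <- c("A", "B", "B", "B", "A", "A")
  py <- c("A", "A", "A", "B", "B", "B")
  j <- joint_from_predictions(truth, px, py)
  expect_equal(sum(j), 1)
  expect_equal(j["A", "A", "A"], 1 / 6)
  expect_equal(apply(unclass(j), 1, sum), c(A = 0.5, B = 0.5))
})
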